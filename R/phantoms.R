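# ---------------------------------------------------------------------------
# Seeded multimodal phantom generator.
#
# A phantom case is a smooth composite of 3D Gaussian blobs shared by all
# modalities (so the volumes are co-registered by construction), viewed
# through per-modality monotone intensity-transfer curves that mimic the
# tissue-contrast differences between MR sequences.  A monotone axial
# intensity envelope gives slices a depth-dependent appearance so that the
# slice-index pretext task has a learnable signal, emulating the
# superior-inferior anatomical progression of real brain volumes.
# Background margins are exactly zero, like the air border of a skull-
# stripped acquisition.
# ---------------------------------------------------------------------------

#' Specify a synthetic multimodal phantom
#'
#' @param shape integer vector (depth, height, width) in voxels
#' @param n_blobs number of Gaussian blobs composing the "tissue" field
#' @param background_margin in-plane margin (voxels) forced to exactly zero
#' @param contrast_params list with per-modality monotone transfer parameters;
#'   each entry has `gain` and `gamma` applied as `gain * u^gamma` to the
#'   normalized tissue field `u` in `\[0, 1\]`
#' @param target_rule `"blend"` (default; smooth nonlinear mix) or `"mean"`
#'   (exact arithmetic mean, used for closed-form oracles)
#' @param axial_envelope range of the linear intensity modulation applied
#'   along the slice axis (first slice gets the first value, last slice the
#'   second); gives slices a depth-dependent cue
#' @param seed integer seed; generation is bit-reproducible given the spec
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(shape = c(16L, 160L, 180L),
                         n_blobs = 6L,
                         background_margin = 8L,
                         contrast_params = list(
                           source1 = list(gain = 1.0, gamma = 0.7),
                           source2 = list(gain = 0.9, gamma = 1.6)),
                         target_rule = c("blend", "mean"),
                         axial_envelope = c(0.55, 1.0),
                         seed = 1L) {
  target_rule <- match.arg(target_rule)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers (depth, height, width)")
  background_margin <- as.integer(background_margin)
  if (background_margin < 0L) stop("background_margin must be >= 0")
  if (2L * background_margin + 4L > min(shape[2:3]))
    stop("shape too small to hold the background margin plus a blob")
  if (n_blobs < 0L) stop("n_blobs must be >= 0")
  structure(list(shape = shape, n_blobs = as.integer(n_blobs),
                 background_margin = background_margin,
                 contrast_params = contrast_params,
                 target_rule = target_rule,
                 axial_envelope = axial_envelope,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %dx%dx%d, %d blobs, margin %d, rule '%s', seed %d\n",
              x$shape[1], x$shape[2], x$shape[3], x$n_blobs,
              x$background_margin, x$target_rule, x$seed))
  invisible(x)
}

# the deterministic source -> target mapping
apply_target_rule <- function(rule, s1, s2) {
  switch(rule,
    mean  = (s1 + s2) / 2,
    blend = (s1 + s2) / 2 + 0.25 * (s1 - s2)^2,
    stop("unknown target_rule: ", rule))
}

#' Generate one co-registered multimodal phantom case
#'
#' Produces two source-modality volumes and one target volume of identical
#' geometry.  The target is a known deterministic voxel-wise function of the
#' sources, so recovery by a synthesis model is verifiable.
#'
#' @param spec a [phantom_spec()]
#' @param case_id character label stored in the volumes
#' @return list of three `volume` objects: `source1`, `source2`, `target`
#' @export
generate_case <- function(spec, case_id = "case_01") {
  stopifnot(inherits(spec, "phantom_spec"))
  D <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  m <- spec$background_margin

  # Tissue field: sum of 3D Gaussian blobs, deterministic under seed.  The
  # first (up to) three blobs are fixed "anatomical landmarks" shared by
  # every case -- their z-staggered positions give each axial level a
  # consistent appearance across subjects, as real brain anatomy does; the
  # remaining blobs are case-specific.
  u <- array(0, dim = c(D, H, W))
  if (spec$n_blobs > 0L) {
    set.seed(spec$seed %% 1000000L * 1000L + sum(utf8ToInt(case_id)))
    nb <- spec$n_blobs
    zc <- runif(nb, 0.15 * D, 0.85 * D)
    hc <- runif(nb, m + 2, H - m - 2)
    wc <- runif(nb, m + 2, W - m - 2)
    sz <- runif(nb, 0.12 * D, 0.35 * D)
    sh <- runif(nb, 0.06, 0.20) * (H - 2 * m)
    sw <- runif(nb, 0.06, 0.20) * (W - 2 * m)
    amp <- runif(nb, 0.5, 1.0)
    ns <- min(3L, nb)   # shared landmark blobs
    zc[seq_len(ns)] <- (c(0.22, 0.50, 0.78) * D)[seq_len(ns)]
    hc[seq_len(ns)] <- (m + c(0.30, 0.65, 0.45) * (H - 2 * m))[seq_len(ns)]
    wc[seq_len(ns)] <- (m + c(0.35, 0.40, 0.70) * (W - 2 * m))[seq_len(ns)]
    sz[seq_len(ns)] <- 0.16 * D
    sh[seq_len(ns)] <- (c(0.12, 0.15, 0.10) * (H - 2 * m))[seq_len(ns)]
    sw[seq_len(ns)] <- (c(0.14, 0.11, 0.13) * (W - 2 * m))[seq_len(ns)]
    amp[seq_len(ns)] <- c(1.0, 0.9, 1.0)[seq_len(ns)]
    zg <- seq_len(D); hg <- seq_len(H); wg <- seq_len(W)
    for (b in seq_len(nb)) {
      ez <- exp(-0.5 * ((zg - zc[b]) / sz[b])^2)
      eh <- exp(-0.5 * ((hg - hc[b]) / sh[b])^2)
      ew <- exp(-0.5 * ((wg - wc[b]) / sw[b])^2)
      u <- u + amp[b] * (ez %o% eh %o% ew)
    }
    u <- u / max(u)
  }

  # exact-zero background margin (in-plane frame)
  if (m > 0L) {
    mask <- matrix(0, H, W)
    mask[(m + 1):(H - m), (m + 1):(W - m)] <- 1
    u <- sweep(u, c(2, 3), mask, `*`)
  }

  # monotone axial envelope: depth-dependent cue shared by all modalities
  env <- seq(spec$axial_envelope[1], spec$axial_envelope[2], length.out = D)
  u <- u * env

  cp <- spec$contrast_params
  s1 <- cp$source1$gain * u^cp$source1$gamma
  s2 <- cp$source2$gain * u^cp$source2$gamma
  tg <- apply_target_rule(spec$target_rule, s1, s2)

  list(source1 = volume(s1, modality = "source1", case_id = case_id),
       source2 = volume(s2, modality = "source2", case_id = case_id),
       target  = volume(tg, modality = "target",  case_id = case_id))
}

#' Generate several phantom cases
#' @param spec a [phantom_spec()]
#' @param n number of cases
#' @return named list of cases (each a list source1/source2/target)
#' @export
generate_cases <- function(spec, n) {
  ids <- sprintf("case_%02d", seq_len(n))
  out <- lapply(ids, function(id) generate_case(spec, id))
  names(out) <- ids
  out
}

#' Sample inpainting masks inside a patch
#'
#' Places `n_masks` rectangular masks uniformly at random inside the patch;
#' by default the masks are mutually non-overlapping.  The default geometry
#' (four 32x32 masks in a 128x128 patch) covers a quarter of the patch.
#'
#' @param patch_shape 2 integers (rows, cols)
#' @param n_masks number of masks
#' @param mask_size 2 integers, size of each mask
#' @param seed integer seed
#' @param allow_overlap if `FALSE` (default) masks may not overlap
#' @return a `mask_spec`: list with binary `mask` matrix (1 = masked) and a
#'   `boxes` matrix of (row0, col0, rows, cols) offsets (0-based)
#' @export
sample_masks <- function(patch_shape = c(128L, 128L), n_masks = 4L,
                         mask_size = c(32L, 32L), seed = 1L,
                         allow_overlap = FALSE) {
  patch_shape <- as.integer(patch_shape); mask_size <- as.integer(mask_size)
  if (any(mask_size > patch_shape))
    stop("mask larger than patch")
  if (n_masks * prod(mask_size) > prod(patch_shape))
    stop("masks cannot fit: total mask area exceeds patch area")
  mask <- matrix(0, patch_shape[1], patch_shape[2])
  boxes <- matrix(integer(0), ncol = 4)
  if (n_masks > 0L) {
    set.seed(seed)
    placed <- 0L; tries <- 0L
    while (placed < n_masks) {
      if ((tries <- tries + 1L) > 10000L)
        stop("masks cannot fit: could not place ", n_masks,
             " non-overlapping masks")
      r0 <- sample.int(patch_shape[1] - mask_size[1] + 1L, 1L) - 1L
      c0 <- sample.int(patch_shape[2] - mask_size[2] + 1L, 1L) - 1L
      rows <- (r0 + 1L):(r0 + mask_size[1])
      cols <- (c0 + 1L):(c0 + mask_size[2])
      if (!allow_overlap && any(mask[rows, cols] > 0)) next
      mask[rows, cols] <- 1
      boxes <- rbind(boxes, c(r0, c0, mask_size[1], mask_size[2]))
      placed <- placed + 1L
    }
  }
  structure(list(mask = mask, boxes = boxes, patch_shape = patch_shape,
                 seed = seed), class = "mask_spec")
}

#' Write a phantom case to NIfTI files
#'
#' One file per modality per case, so downstream stages treat phantoms
#' exactly like real co-registered acquisitions.
#'
#' @param case a case from [generate_case()]
#' @param dir output directory (created if missing)
#' @return invisible character vector of file paths
#' @export
write_case_nifti <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(case), function(mod) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", case[[mod]]$case_id, mod))
    write_volume(case[[mod]], p)
    p
  }, character(1))
  invisible(paths)
}
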