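# ---------------------------------------------------------------------------
# Volume container and preprocessing geometry: central crop, four-corner
# overlapping patch extraction, overlap-averaged stitching, [-1, 1] intensity
# scaling, and 3-slice triplet assembly.  Conventions: axis order is
# (slice, row, col); coordinates are 0-based half-open windows.
# ---------------------------------------------------------------------------

#' Construct a volume
#'
#' @param data 3D numeric array, axis order (slice, row, col)
#' @param modality modality label (e.g. `"T1"`, `"source1"`)
#' @param case_id case identifier
#' @param affine optional 4x4 affine carried through NIfTI round trips
#' @return an object of class `volume`
#' @export
volume <- function(data, modality = "unknown", case_id = "unknown",
                   affine = NULL) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, modality = modality, case_id = case_id,
                 affine = affine), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume [%s/%s]: %d slices of %dx%d, range [%.4g, %.4g]\n",
              x$case_id, x$modality, d[1], d[2], d[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Read a NIfTI file as a volume
#'
#' The on-disk NIfTI axis order (x, y, z) is mapped to the package's
#' (slice, row, col) convention with z as the slice axis.
#'
#' @param path `.nii`/`.nii.gz` file
#' @param modality,case_id labels attached to the volume
#' @return a `volume`
#' @export
read_volume <- function(path, modality = "unknown", case_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  volume(aperm(arr, c(3, 1, 2)), modality = modality, case_id = case_id,
         affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a volume to NIfTI
#' @param vol a `volume`
#' @param path output path (`.nii` or `.nii.gz`)
#' @export
write_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Central in-plane crop of a volume
#'
#' Each slice is cropped to the centered `crop_shape` window; when a margin
#' is odd the leading margin is rounded down.  A 240x240 slice cropped to
#' 160x180 keeps rows 40..199 and cols 30..209 (0-based).
#'
#' @param vol a `volume`
#' @param crop_shape 2 integers (rows, cols)
#' @return the cropped `volume`
#' @export
central_crop <- function(vol, crop_shape = c(160L, 180L)) {
  d <- dim(vol$data)
  crop_shape <- as.integer(crop_shape)
  if (any(crop_shape > d[2:3]))
    stop("crop shape ", paste(crop_shape, collapse = "x"),
         " exceeds slice shape ", paste(d[2:3], collapse = "x"))
  r0 <- (d[2] - crop_shape[1]) %/% 2L
  c0 <- (d[3] - crop_shape[2]) %/% 2L
  out <- vol$data[, (r0 + 1L):(r0 + crop_shape[1]),
                  (c0 + 1L):(c0 + crop_shape[2]), drop = FALSE]
  volume(out, vol$modality, vol$case_id, vol$affine)
}

#' Extract the four corner-anchored overlapping patches per slice
#'
#' A `H x W` plane yields patches anchored at row offsets `{0, H - p}` and
#' col offsets `{0, W - p}` (for 160x180 with 128x128 patches: rows `{0, 32}`,
#' cols `{0, 52}`).  When the patch equals the plane the duplicate offsets
#' collapse to a single patch.
#'
#' @param vol a `volume` (already cropped)
#' @param patch_shape 2 integers, patch size
#' @return list of `patch_record`s, each with fields `pixels`, `case_id`,
#'   `modality`, `slice_index` (0-based) and `crop_offset` (0-based row, col)
#' @export
extract_patches <- function(vol, patch_shape = c(128L, 128L)) {
  d <- dim(vol$data)
  p <- as.integer(patch_shape)
  if (any(p > d[2:3]))
    stop("patch ", paste(p, collapse = "x"), " larger than plane ",
         paste(d[2:3], collapse = "x"))
  if (any(2L * p < d[2:3]))
    stop("patch ", paste(p, collapse = "x"), " smaller than half the ",
         paste(d[2:3], collapse = "x"),
         " plane: four corner patches cannot cover it")
  roffs <- unique(c(0L, d[2] - p[1]))
  coffs <- unique(c(0L, d[3] - p[2]))
  out <- list()
  for (k in seq_len(d[1])) {
    for (ro in roffs) for (co in coffs) {
      out[[length(out) + 1L]] <- structure(
        list(pixels = vol$data[k, (ro + 1L):(ro + p[1]),
                               (co + 1L):(co + p[2])],
             case_id = vol$case_id, modality = vol$modality,
             slice_index = k - 1L, crop_offset = c(ro, co)),
        class = "patch_record")
    }
  }
  out
}

#' Stitch patches back into a plane, averaging overlaps
#'
#' Every output pixel is the arithmetic mean of all patch pixels covering
#' it.  Patches must jointly cover the full plane.
#'
#' @param patches list of `patch_record`s from one slice
#' @param plane_shape 2 integers, the plane size
#' @return numeric matrix `plane_shape`
#' @export
stitch_patches <- function(patches, plane_shape) {
  plane_shape <- as.integer(plane_shape)
  acc <- matrix(0, plane_shape[1], plane_shape[2])
  cnt <- matrix(0, plane_shape[1], plane_shape[2])
  for (p in patches) {
    px <- p$pixels
    ro <- p$crop_offset[1]; co <- p$crop_offset[2]
    rows <- (ro + 1L):(ro + nrow(px)); cols <- (co + 1L):(co + ncol(px))
    if (max(rows) > plane_shape[1] || max(cols) > plane_shape[2])
      stop("patch at offset (", ro, ",", co, ") exceeds the plane")
    acc[rows, cols] <- acc[rows, cols] + px
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop("incomplete coverage: pixel (", bad[1] - 1L, ",", bad[2] - 1L,
         ") (0-based) is covered by no patch")
  }
  acc / cnt
}

#' Scale volume intensities linearly to \[-1, 1\]
#'
#' Maps the volume's `\[min, max\]` to `\[-1, 1\]` and returns the parameters
#' needed for exact inversion.  A constant volume maps to all zeros (the
#' midpoint) so background-only phantom data pass through.
#'
#' @param vol a `volume`
#' @return list with the scaled `volume` and `params` (`min`, `max`)
#' @export
scale_intensity <- function(vol) {
  x <- vol$data
  lo <- min(x); hi <- max(x)
  y <- if (hi > lo) 2 * (x - lo) / (hi - lo) - 1 else x * 0
  list(volume = volume(y, vol$modality, vol$case_id, vol$affine),
       params = list(min = lo, max = hi))
}

#' Invert [scale_intensity()]
#' @param vol the scaled `volume` (or a bare array/matrix)
#' @param params the `params` returned by [scale_intensity()]
#' @return object of the same kind as `vol` on the original intensity scale
#' @export
unscale_intensity <- function(vol, params) {
  f <- function(y) {
    if (params$max > params$min)
      (y + 1) / 2 * (params$max - params$min) + params$min
    else y * 0 + params$min
  }
  if (inherits(vol, "volume"))
    volume(f(vol$data), vol$modality, vol$case_id, vol$affine)
  else f(vol)
}

#' Assemble 3-slice triplets with edge replication
#'
#' For each slice `k` (0-based) a stack of slices `(k-1, k, k+1)` is built;
#' at the volume boundary the edge slice is replicated.
#'
#' @param vol a `volume` with depth >= 3
#' @return list of `patch_record`s whose `pixels` is a (rows, cols, 3) array
#'   and whose `slice_index` runs 0..depth-1
#' @export
slice_triplets <- function(vol) {
  d <- dim(vol$data)
  if (d[1] < 3L) stop("slice_triplets needs depth >= 3, got ", d[1])
  lapply(seq_len(d[1]), function(k) {
    ks <- pmin(pmax(c(k - 1L, k, k + 1L), 1L), d[1])
    px <- array(0, dim = c(d[2], d[3], 3L))
    for (j in 1:3) px[, , j] <- vol$data[ks[j], , ]
    structure(list(pixels = px, case_id = vol$case_id,
                   modality = vol$modality, slice_index = k - 1L,
                   crop_offset = c(0L, 0L)),
              class = "patch_record")
  })
}
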