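# ---------------------------------------------------------------------------
# Configuration, case-level splitting, and the three-stage orchestration:
# self-supervised pretraining -> adversarial fusion training -> evaluation
# and interpretability plots.  Every stochastic component draws from the
# run seed; checkpoints embed the configuration that produced them.
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' The `"tiny"` profile (the package's CI-scale study condition) uses
#' 64x64 phantom planes of depth 12 with 32x32 patches and narrow
#' networks; the `"paper"` profile uses the full 160x180 crop geometry
#' with 128x128 patches and the tabulated discriminator widths.
#'
#' @param profile `"tiny"` or `"paper"`
#' @param seed integer run seed
#' @param output_dir artifact directory
#' @return nested configuration list of class `run_config`
#' @export
default_config <- function(profile = c("tiny", "paper"), seed = 1L,
                           output_dir = tempfile("fusionsynth_run_")) {
  profile <- match.arg(profile)
  tiny <- profile == "tiny"
  structure(list(
    profile = profile, seed = as.integer(seed), output_dir = output_dir,
    data = list(source = "phantom",
                n_cases = if (tiny) 5L else 20L,
                phantom = list(shape = if (tiny) c(12L, 64L, 64L)
                               else c(16L, 160L, 180L),
                               n_blobs = 6L,
                               background_margin = if (tiny) 6L else 8L,
                               target_rule = "blend"),
                nifti_dir = NULL),
    preprocess = list(crop_shape = if (tiny) NULL else c(160L, 180L),
                      patch_shape = if (tiny) c(32L, 32L)
                      else c(128L, 128L)),
    model = list(base_channels = if (tiny) 8L else 32L,
                 ratio = 8L,
                 disc_channels = if (tiny) c(16L, 32L, 64L, 128L)
                 else c(32L, 64L, 128L, 256L)),
    pretrain = list(steps = if (tiny) 300L else 2000L, batch_size = 4L,
                    lr = 1e-3, task = "joint", index_weight = 1),
    train = list(steps = if (tiny) 250L else 5000L, batch_size = 4L,
                 lr = 2e-4, lambda1 = 100, lambda2 = 10,
                 edge_mode = "soft"),
    split = list(fraction = 0.8),
    eval = list(psnr_mode = "paper", ssim_mode = "global")),
    class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; missing keys fall back to the profile defaults
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- default_config(profile = if (!is.null(y$profile)) y$profile
                         else "tiny")
  merge_cfg <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]]))
        merge_cfg(a[[k]], b[[k]]) else b[[k]]
    }
    a
  }
  structure(merge_cfg(unclass(base), y), class = "run_config")
}

#' Case-level train/test split
#'
#' Splitting happens at the case (volume) level, never at the slice level,
#' so adjacent slices of one case cannot leak across the split.
#'
#' @param case_ids character vector of case identifiers
#' @param fraction training fraction in (0, 1)
#' @param seed integer seed
#' @return list with `train` and `test` id vectors (disjoint, exhaustive)
#' @export
split_cases <- function(case_ids, fraction = 0.8, seed = 1L) {
  if (length(case_ids) < 2L) stop("need at least 2 cases to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  n <- length(case_ids)
  n_train <- min(n - 1L, max(1L, round(fraction * n)))
  sh <- sample(case_ids)
  list(train = sort(sh[seq_len(n_train)]), test = sort(sh[-seq_len(n_train)]))
}

# preprocess one case: optional central crop, per-volume [-1,1] scaling
prep_case <- function(case, crop_shape = NULL) {
  out <- list()
  for (mod in names(case)) {
    v <- case[[mod]]
    if (!is.null(crop_shape)) v <- central_crop(v, crop_shape)
    sc <- scale_intensity(v)
    out[[mod]] <- list(volume = sc$volume, params = sc$params)
  }
  out
}

# aligned patch triples (x1, x2, y) for the GAN stage
aligned_patches <- function(prep, patch_shape) {
  p1 <- extract_patches(prep$source1$volume, patch_shape)
  p2 <- extract_patches(prep$source2$volume, patch_shape)
  pt <- extract_patches(prep$target$volume, patch_shape)
  lapply(seq_along(p1), function(i)
    list(x1 = p1[[i]]$pixels, x2 = p2[[i]]$pixels, y = pt[[i]]$pixels))
}

#' Synthesize a full target volume from two source volumes
#'
#' Sources are scaled per volume to \[-1, 1\], sliced into the four corner
#' patches, synthesized patch-wise, stitched with overlap averaging, and
#' returned on the \[-1, 1\] scale (unscale with the target's parameters to
#' reach raw intensities).
#'
#' @param models a `synth_models`
#' @param vol1,vol2 co-registered source `volume`s
#' @param patch_shape patch size used at inference
#' @return `volume` of the synthesized target on the \[-1, 1\] scale
#' @export
synthesize_volume <- function(models, vol1, vol2, patch_shape) {
  s1 <- scale_intensity(vol1)$volume
  s2 <- scale_intensity(vol2)$volume
  d <- dim(s1$data)
  p1 <- extract_patches(s1, patch_shape)
  p2 <- extract_patches(s2, patch_shape)
  out <- array(0, dim = d)
  by_slice <- split(seq_along(p1),
                    vapply(p1, `[[`, integer(1), "slice_index"))
  for (k in names(by_slice)) {
    ix <- by_slice[[k]]
    x1 <- stack_batch(lapply(p1[ix], `[[`, "pixels"))
    x2 <- stack_batch(lapply(p2[ix], `[[`, "pixels"))
    yh <- synthesize_patches(models, x1, x2)
    recs <- lapply(seq_along(ix), function(j) {
      r <- p1[[ix[j]]]
      r$pixels <- yh[, , 1, j]
      r
    })
    out[as.integer(k) + 1L, , ] <- stitch_patches(recs, d[2:3])
  }
  volume(out, modality = "synthesized", case_id = vol1$case_id)
}

log_jsonl <- function(path, rec) {
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = path,
      append = TRUE, sep = "")
}

#' Run the full pipeline
#'
#' Stages: phantom generation (or NIfTI ingestion), case-level split,
#' self-supervised pretraining of both source backbones, adversarial fusion
#' training, test-split evaluation, and PCA interpretability plots.  Each
#' stage writes a checkpoint under `output_dir` and is skipped (resumed)
#' when its checkpoint already exists.
#'
#' @param cfg a `run_config` from [default_config()] or [read_config()]
#' @param skip_pretrain start adversarial training from random backbones
#' @param visualize render PCA feature plots
#' @return list with `metrics` (per test case), `models`, `split`,
#'   `history`, `manifest`
#' @export
run_pipeline <- function(cfg = default_config(), skip_pretrain = FALSE,
                         visualize = FALSE) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  log_path <- file.path(cfg$output_dir, "train_log.jsonl")

  # --- data ---------------------------------------------------------------
  if (identical(cfg$data$source, "phantom")) {
    ph <- cfg$data$phantom
    spec <- phantom_spec(shape = ph$shape, n_blobs = ph$n_blobs,
                         background_margin = ph$background_margin,
                         target_rule = ph$target_rule, seed = seed)
    cases <- generate_cases(spec, cfg$data$n_cases)
  } else {
    cases <- read_nifti_cases(cfg$data$nifti_dir)
  }
  sp <- split_cases(names(cases), cfg$split$fraction, seed)
  prepped <- lapply(cases, prep_case, crop_shape = cfg$preprocess$crop_shape)

  ps <- cfg$preprocess$patch_shape
  depth <- dim(cases[[1]]$source1$data)[1]

  # --- stage 1: self-supervised pretraining -------------------------------
  b <- cfg$model$base_channels
  bbs <- list(source1 = build_backbone_seeded(b, seed + 101L),
              source2 = build_backbone_seeded(b, seed + 102L))
  pre_trace <- list()
  if (!skip_pretrain && cfg$pretrain$steps > 0L) {
    for (mod in c("source1", "source2")) {
      ck <- file.path(cfg$output_dir, paste0("pretrain_", mod, ".rds"))
      if (file.exists(ck)) {
        bbs[[mod]] <- load_checkpoint(ck)$model
        next
      }
      # full-plane triplets: quadrant patches can miss the anatomy that
      # identifies the axial position, so the index task sees whole slices
      # (the backbone is fully convolutional and transfers to patches)
      trips <- list()
      for (id in sp$train) {
        v <- prepped[[id]][[mod]]$volume
        for (tr in slice_triplets(v)) trips[[length(trips) + 1L]] <- tr
      }
      im <- index_model_make(bbs[[mod]])
      res <- pretrain_index(im, trips, depth = depth,
                            steps = cfg$pretrain$steps,
                            seed = seed + match(mod, c("source1", "source2")),
                            batch_size = cfg$pretrain$batch_size,
                            lr = cfg$pretrain$lr,
                            index_weight = cfg$pretrain$index_weight,
                            mask_triplets = identical(cfg$pretrain$task,
                                                      "joint"))
      bbs[[mod]] <- res$model$backbone   # triplet front layer dropped
      pre_trace[[mod]] <- list(rec = res$trace_rec, idx = res$trace_idx)
      save_checkpoint(bbs[[mod]], cfg, ck)
      log_jsonl(log_path, list(stage = "pretrain", modality = mod,
                               final_rec = unname(utils::tail(res$trace_rec, 1)),
                               final_idx = unname(utils::tail(res$trace_idx, 1))))
    }
  }

  # --- stage 2: adversarial fusion training -------------------------------
  set.seed(seed + 500L)
  models <- build_synth_models(b, cfg$model$disc_channels, cfg$model$ratio)
  models$bb1 <- bbs$source1
  models$bb2 <- bbs$source2
  opts <- synth_opts_make(models, lr = cfg$train$lr)
  train_patches <- unlist(lapply(sp$train, function(id)
    aligned_patches(prepped[[id]], ps)), recursive = FALSE)
  gen_trace <- numeric(0)
  ck <- file.path(cfg$output_dir,
                  if (skip_pretrain) "train_scratch.rds" else "train.rds")
  if (file.exists(ck)) {
    st <- load_checkpoint(ck)
    models <- st$model
    gen_trace <- st$config$.gen_trace %||% numeric(0)
  } else if (cfg$train$steps > 0L) {
    set.seed(seed + 1000L)
    for (s in seq_len(cfg$train$steps)) {
      ix <- sample.int(length(train_patches),
                       min(cfg$train$batch_size, length(train_patches)))
      batch <- list(
        x1 = stack_batch(lapply(train_patches[ix], `[[`, "x1")),
        x2 = stack_batch(lapply(train_patches[ix], `[[`, "x2")),
        y = stack_batch(lapply(train_patches[ix], `[[`, "y")))
      st <- train_step(models, batch, opts,
                       lambda1 = cfg$train$lambda1,
                       lambda2 = cfg$train$lambda2,
                       edge_mode = cfg$train$edge_mode)
      models <- st$models; opts <- st$opts
      gen_trace[s] <- st$report$total
      if (s %% 25L == 0L)
        log_jsonl(log_path, list(stage = "train", step = s,
                                 total = st$report$total,
                                 grec = st$report$l_grec))
    }
    # recalibrate batch-norm running statistics of the synthesis path under
    # the final parameters (forward-only passes)
    for (r in 1:30) {
      ix <- sample.int(length(train_patches),
                       min(cfg$train$batch_size, length(train_patches)))
      invisible(synth_forward(
        models,
        stack_batch(lapply(train_patches[ix], `[[`, "x1")),
        stack_batch(lapply(train_patches[ix], `[[`, "x2")),
        training = TRUE))
    }
    cfg$.gen_trace <- gen_trace
    save_checkpoint(models, cfg, ck)
  }

  # --- stage 3: evaluation on the test split ------------------------------
  metrics <- list()
  maybe_crop <- function(v) if (is.null(cfg$preprocess$crop_shape)) v
    else central_crop(v, cfg$preprocess$crop_shape)
  for (id in sp$test) {
    syn <- synthesize_volume(models, maybe_crop(cases[[id]]$source1),
                             maybe_crop(cases[[id]]$source2), ps)
    truth <- maybe_crop(cases[[id]]$target)
    syn_raw <- unscale_intensity(syn, scale_intensity(truth)$params)
    met <- evaluate_volume(truth, syn_raw,
                           psnr_mode = cfg$eval$psnr_mode,
                           ssim_mode = cfg$eval$ssim_mode)
    metrics[[id]] <- met
    log_jsonl(log_path, list(stage = "evaluate", case = id,
                             mse = met$mse, psnr = met$psnr, ssim = met$ssim))
  }

  # --- stage 4: interpretability ------------------------------------------
  if (visualize) {
    id <- sp$test[1]
    ap <- aligned_patches(prepped[[id]], ps)
    pairs <- lapply(ap[seq_len(min(8L, length(ap)))],
                    function(p) list(x1 = p$x1, x2 = p$x2))
    cloud <- collect_features(models, pairs, 1:6)
    plot_feature_cloud(cloud, 2L, file.path(cfg$output_dir, "figures"))
  }

  manifest <- list(seed = seed, profile = cfg$profile,
                   split = sp, steps = cfg$train$steps,
                   checkpoints = list.files(cfg$output_dir, "\\.rds$"))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(metrics = metrics, models = models, split = sp,
       history = list(pretrain = pre_trace, gan = gen_trace),
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded backbone construction so pretrained and scratch runs share inits
build_backbone_seeded <- function(base_channels, seed) {
  set.seed(seed)
  build_backbone(backbone_config(base_channels))
}

# cut in-plane patches out of one slice-triplet record
patch_triplet <- function(tr, patch_shape) {
  d <- dim(tr$pixels)
  p <- as.integer(patch_shape)
  roffs <- unique(c(0L, d[1] - p[1]))
  coffs <- unique(c(0L, d[2] - p[2]))
  out <- list()
  for (ro in roffs) for (co in coffs) {
    r <- tr
    r$pixels <- tr$pixels[(ro + 1L):(ro + p[1]), (co + 1L):(co + p[2]), ,
                          drop = FALSE]
    r$crop_offset <- c(ro, co)
    out[[length(out) + 1L]] <- r
  }
  out
}

#' Read co-registered NIfTI cases from a directory
#'
#' Expects files named `<case>_<modality>.nii(.gz)` with modalities
#' `source1`, `source2`, `target` (the layout written by
#' [write_case_nifti()]).
#'
#' @param dir directory of NIfTI files
#' @return named list of cases
#' @export
read_nifti_cases <- function(dir) {
  fs <- list.files(dir, "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(fs) == 0L) stop("no NIfTI files in ", dir)
  meta <- regmatches(basename(fs),
                     regexec("^(.*)_(source1|source2|target)\\.nii(\\.gz)?$",
                             basename(fs)))
  cases <- list()
  for (i in seq_along(fs)) {
    if (length(meta[[i]]) < 3L) next
    id <- meta[[i]][2]; mod <- meta[[i]][3]
    if (is.null(cases[[id]])) cases[[id]] <- list()
    cases[[id]][[mod]] <- read_volume(fs[i], modality = mod, case_id = id)
  }
  cases
}
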