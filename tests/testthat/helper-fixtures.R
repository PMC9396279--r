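# Shared fixtures: tiny phantom geometry and numerical-gradient helpers.
# Everything is generated in code under fixed seeds; no stored data.

ns <- asNamespace("fusionsynth")

tiny_spec <- function(seed = 1L, target_rule = "blend") {
  phantom_spec(shape = c(12L, 64L, 64L), n_blobs = 6L,
               background_margin = 6L, target_rule = target_rule,
               seed = seed)
}

rand_t4 <- function(H, W, C, N, seed = 1L) {
  set.seed(seed)
  array(rnorm(H * W * C * N), dim = c(H, W, C, N))
}

# central-difference gradient of f at a subset of coordinates of x
num_grad_at <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# scaled training patches of one modality from a list of phantom cases
phantom_patches <- function(cases, ids, mod, patch_shape = c(32L, 32L)) {
  out <- list()
  for (id in ids) {
    v <- scale_intensity(cases[[id]][[mod]])$volume
    for (p in extract_patches(v, patch_shape))
      out[[length(out) + 1L]] <- p$pixels
  }
  out
}

# full-plane scaled slice triplets of one modality
phantom_triplets <- function(cases, ids, mod) {
  out <- list()
  for (id in ids) {
    v <- scale_intensity(cases[[id]][[mod]])$volume
    for (tr in slice_triplets(v)) out[[length(out) + 1L]] <- tr
  }
  out
}
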