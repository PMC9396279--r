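test_that("both discriminators honor the tabulated layer contract", {
  for (kind in c("pixel", "feature")) {
    d <- build_discriminator(kind)
    stages <- d[c("d1", "d2", "d3", "d4", "d5")]
    expect_length(stages, 5L)
    ch <- vapply(stages, function(s) dim(s$conv$W)[4], integer(1))
    expect_equal(unname(ch), c(32L, 64L, 128L, 256L, 1L))
    st <- vapply(stages, function(s) s$conv$stride, integer(1))
    expect_equal(unname(st), c(2L, 2L, 2L, 2L, 1L))
    expect_true(all(vapply(stages, function(s) !is.null(s$bn), logical(1))))
    acts <- vapply(stages, `[[`, character(1), "act")
    expect_true(all(acts == if (kind == "pixel") "lrelu" else "relu"))
    expect_true(all(vapply(stages, function(s) dim(s$conv$W)[1] == 3L,
                           logical(1))))
    # 128x128 input -> 8x8 single-channel map
    out <- ns$disc_fw(d, rand_t4(128, 128, 1, 1, seed = 61))$y
    expect_equal(dim(out), c(8, 8, 1, 1))
  }
})

test_that("the generator emits patches of the input size in both modes", {
  set.seed(62)
  for (hw in c(32L, 64L)) {
    models <- build_synth_models(4L, c(4L, 8L, 8L, 8L))
    x1 <- rand_t4(hw, hw, 1, 1, seed = 62)
    x2 <- rand_t4(hw, hw, 1, 1, seed = 63)
    y <- synthesize_patches(models, x1, x2)
    expect_equal(dim(y), c(hw, hw, 1, 1))
    expect_true(all(abs(y) <= 1))
    # single-modal mode: both streams fed the same image
    ym <- synthesize_patches(models, x1, x1)
    expect_equal(dim(ym), dim(y))
  }
})

test_that("swapping the source streams leaves the synthesized patch bit-identical", {
  set.seed(64)
  models <- build_synth_models(4L, c(4L, 8L, 8L, 8L))
  x1 <- rand_t4(32, 32, 1, 2, seed = 64)
  x2 <- rand_t4(32, 32, 1, 2, seed = 65)
  fs1 <- encode(models$bb1, x1); fs2 <- encode(models$bb2, x2)
  fu <- fusion_network(models$fusion, fs1, fs2)
  fu_sw <- fusion_network(models$fusion, fs2, fs1)
  y <- generate(models$gen, fu, fs1, fs2)$y
  y_sw <- generate(models$gen, fu_sw, fs2, fs1)$y
  expect_identical(y, y_sw)
})

test_that("Canny maps obey the closed-form cases", {
  expect_true(all(canny_features(matrix(0, 32, 32)) == 0))
  expect_error(canny_features(matrix(0, 8, 8), low = 0.5, high = 0.2),
               "low threshold")
  # centered filled square: edges form a thin closed contour on the boundary
  img <- matrix(0, 48, 48)
  img[16:32, 16:32] <- 1
  e <- canny_features(img, 0.1, 0.3, sigma = 1.4)
  idx <- which(e == 1, arr.ind = TRUE)
  expect_gt(nrow(idx), 20)
  # every edge pixel lies within 2 px of the square boundary
  dist_to_boundary <- apply(idx, 1, function(p) {
    dr <- min(abs(p[1] - 16), abs(p[1] - 32))
    dc <- min(abs(p[2] - 16), abs(p[2] - 32))
    inside_r <- p[1] >= 14 & p[1] <= 34
    inside_c <- p[2] >= 14 & p[2] <= 34
    if (inside_r && inside_c) min(dr, dc) else Inf
  })
  expect_true(all(dist_to_boundary <= 2))
  # all four sides carry edges (closed contour up to NMS discretization)
  expect_true(any(idx[, 1] <= 18) && any(idx[, 1] >= 30))
  expect_true(any(idx[, 2] <= 18) && any(idx[, 2] >= 30))
  # invariance under positive affine intensity change: checked on a smooth
  # field (the synthetic square's flat plateaus tie at the thresholds, where
  # floating-point rounding can flip individual pixels)
  set.seed(72)
  sm <- outer(seq(0, 3, length.out = 40), seq(0, 2, length.out = 40),
              function(a, b) sin(2 * a) * cos(3 * b) + 0.3 * sin(5 * a * b))
  es <- canny_features(sm, 0.1, 0.3)
  es2 <- canny_features(1.7 * sm + 4.2, 0.1, 0.3)
  expect_gt(mean(es == es2), 0.999)
  expect_gt(sum(es), 0)
})

test_that("the loss report composes per the additive objective", {
  set.seed(66)
  y <- rand_t4(32, 32, 1, 2, seed = 66)
  yh <- tanh(rand_t4(32, 32, 1, 2, seed = 67))
  half <- function(x) array(0.5, dim = c(2, 2, 1, dim(x)[4]))
  rep_ <- gan_losses(y, y, half, half, lambda1 = 3, lambda2 = 2,
                     l_rec = 0.25)
  expect_equal(rep_$l_grec, 0)
  # a discriminator stuck at probability 0.5 pays -2 log(0.5) per sample
  expect_equal(rep_$l_pixel_adv_d, -2 * log(0.5), tolerance = 1e-9)
  expect_equal(rep_$l_feature_adv_d, -2 * log(0.5), tolerance = 1e-9)
  expect_equal(rep_$l_pixel_adv, -log(0.5), tolerance = 1e-9)
  # lambda1 = lambda2 = 0 reduces the total to the adversarial terms
  r0 <- gan_losses(y, yh, half, half, lambda1 = 0, lambda2 = 0)
  expect_equal(r0$total, r0$l_pixel_adv + r0$l_feature_adv)
  # additive composition at arbitrary weights
  r <- gan_losses(y, yh, half, half, lambda1 = 3, lambda2 = 2, l_rec = 0.25)
  expect_equal(r$total,
               r$l_pixel_adv + r$l_feature_adv + 3 * r$l_grec + 2 * 0.25,
               tolerance = 1e-12)
  expect_error(gan_losses(y, yh, half, half, lambda1 = -1), "non-negative")
})

test_that("adversarial updates are isolated between generator and critics", {
  set.seed(68)
  models <- build_synth_models(4L, c(4L, 8L, 8L, 8L))
  opts <- synth_opts_make(models, lr = 1e-3)
  batch <- list(x1 = rand_t4(16, 16, 1, 2, seed = 68),
                x2 = rand_t4(16, 16, 1, 2, seed = 69),
                y = tanh(rand_t4(16, 16, 1, 2, seed = 70)))
  # zero learning rate: every parameter bit-identical after the step
  opts0 <- synth_opts_make(models, lr = 0)
  st0 <- train_step(models, batch, opts0)
  for (nm in c("bb1", "bb2", "fusion", "gen", "d_pixel", "d_feature"))
    expect_identical(ns$flatten_params(st0$models[[nm]]),
                     ns$flatten_params(models[[nm]]))
  # normal step: all sub-models move, and the report is additive
  st <- train_step(models, batch, opts)
  for (nm in c("gen", "d_pixel", "d_feature"))
    expect_false(identical(ns$flatten_params(st$models[[nm]]),
                           ns$flatten_params(models[[nm]])))
  r <- st$report
  expect_equal(r$total,
               r$l_pixel_adv + r$l_feature_adv + r$lambda1 * r$l_grec +
                 r$lambda2 * r$l_rec, tolerance = 1e-9)
  expect_true(all(vapply(r[c("l_grec", "l_rec")], `>=`, logical(1), 0)))
})

test_that("the soft edge surrogate is differentiable and matches finite differences", {
  set.seed(71)
  x <- rand_t4(8, 8, 1, 1, seed = 71)
  se <- ns$soft_edges_fw(x)
  ge <- array(rnorm(length(se$y)), dim = dim(se$y))
  gx <- ns$soft_edges_bw(se$cache, ge)
  idx <- sample(length(x), 15)
  ng <- num_grad_at(function(xx) sum(ns$soft_edges_fw(xx)$y * ge), x, idx)
  expect_lt(max(abs(ng - gx[idx])), 1e-5)
})
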