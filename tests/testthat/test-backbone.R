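test_that("encoder taps halve spatially and both modalities share shapes", {
  set.seed(21)
  bb1 <- build_backbone(backbone_config(8L))
  bb2 <- build_backbone(backbone_config(8L))
  x <- rand_t4(32, 32, 1, 2, seed = 21)
  fs1 <- encode(bb1, x, training = FALSE)
  fs2 <- encode(bb2, x, training = FALSE)
  expect_equal(dim(fs1$S1), c(32, 32, 8, 2))
  expect_equal(dim(fs1$S2), c(16, 16, 16, 2))
  expect_equal(dim(fs1$S3), c(8, 8, 32, 2))
  for (k in c("S1", "S2", "S3"))
    expect_identical(dim(fs1[[k]]), dim(fs2[[k]]))
  # different parameters give different features
  expect_false(identical(fs1$S1, fs2$S1))
  # determinism in eval mode
  fs1b <- encode(bb1, x, training = FALSE)
  expect_identical(fs1$S3, fs1b$S3)
  expect_error(encode(bb1, rand_t4(30, 30, 1, 1, seed = 1)), "divisible")
})

test_that("decoder restores the input shape for several input sizes", {
  set.seed(22)
  bb <- build_backbone(backbone_config(4L))
  for (hw in list(c(16, 16), c(32, 32), c(16, 24))) {
    x <- rand_t4(hw[1], hw[2], 1, 1, seed = 22)
    dc <- decode(bb, encode(bb, x), training = FALSE)
    expect_equal(dim(dc$recon), dim(x))
    expect_true(all(abs(dc$recon) <= 1))  # tanh output
  }
})

test_that("encoder uses LeakyReLU, decoder ReLU, batch norm everywhere", {
  bb <- build_backbone(backbone_config(4L))
  acts <- ns$backbone_activations(bb)
  expect_equal(unname(acts[c("e1", "e2", "e3")]), rep("lrelu", 3))
  expect_equal(unname(acts[c("d1a", "d1b", "d2a", "d2b")]), rep("relu", 4))
  expect_equal(unname(acts["out"]), "tanh")
  expect_true(all(ns$backbone_has_bn(bb)))
})

test_that("reconstruction loss matches an elementwise oracle", {
  expect_equal(reconstruction_loss(matrix(1, 4, 4), matrix(1, 4, 4)), 0)
  expect_equal(reconstruction_loss(matrix(1, 4, 4), matrix(0, 4, 4)), 1)
  set.seed(23)
  a <- matrix(rnorm(64), 8); b <- matrix(rnorm(64), 8)
  expect_equal(reconstruction_loss(a, b), sum(abs(a - b)) / 64,
               tolerance = 1e-12)
  expect_error(reconstruction_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               "mismatch")
})

test_that("backbone parameter gradients are finite, nonzero and numerically exact", {
  set.seed(24)
  bb <- build_backbone(backbone_config(4L))
  x <- rand_t4(16, 16, 1, 2, seed = 24)
  st <- ns$backbone_step_grads(bb, x, training = TRUE)
  fg <- ns$flatten_params(st$g)
  expect_true(all(vapply(fg, function(g) all(is.finite(g)), logical(1))))
  expect_gt(sum(vapply(fg, function(g) sum(abs(g)), numeric(1))), 0)
  fp <- ns$flatten_params(bb)
  loss_of <- function(net) {
    dc <- decode(net, encode(net, x, TRUE), TRUE)
    mean(abs(dc$recon - x))
  }
  for (nm in sample(names(fp), 4)) {
    p <- fp[[nm]]; i <- sample(length(p), 1); eps <- 1e-5
    pp <- p; pp[i] <- pp[i] + eps
    lp <- loss_of(ns$set_flat_params(bb, setNames(list(pp), nm)))
    pm <- p; pm[i] <- pm[i] - eps
    lm <- loss_of(ns$set_flat_params(bb, setNames(list(pm), nm)))
    expect_lt(abs((lp - lm) / (2 * eps) - fg[[nm]][i]), 1e-6)
  }
})

test_that("an overfit run on a single patch drives the L1 loss down sharply", {
  set.seed(25)
  bb <- build_backbone(backbone_config(8L))
  spec <- tiny_spec()
  case <- generate_case(spec, "case_01")
  v <- scale_intensity(case$source1)$volume
  patch <- v$data[6, 17:32, 17:32]
  opt <- ns$adam_make(bb, lr = 1e-3)
  losses <- numeric(400)
  for (s in 1:400) {
    st <- ns$backbone_step_grads(bb, array(patch, c(16, 16, 1, 1)),
                                 training = TRUE)
    losses[s] <- st$loss
    up <- ns$adam_step(bb, st$g, opt)
    bb <- up$net; opt <- up$opt
  }
  expect_lt(min(losses), 0.05 * losses[1])
})

test_that("updating one modality's backbone leaves the other untouched", {
  set.seed(26)
  bb1 <- build_backbone(backbone_config(4L))
  bb2 <- build_backbone(backbone_config(4L))
  before <- ns$flatten_params(bb2)
  x <- rand_t4(16, 16, 1, 2, seed = 26)
  st <- ns$backbone_step_grads(bb1, x, training = TRUE)
  up <- ns$adam_step(bb1, st$g, ns$adam_make(bb1, lr = 1e-3))
  expect_false(identical(ns$flatten_params(up$net), ns$flatten_params(bb1)))
  expect_identical(ns$flatten_params(bb2), before)
})
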