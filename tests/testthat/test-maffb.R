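test_that("element-wise fusion operations follow their definitions", {
  S1 <- ns$as_t4(matrix(c(1, 2), 1)); S2 <- ns$as_t4(matrix(c(3, 4), 1))
  fo <- fuse_ops(S1, S2)
  expect_equal(as.vector(fo$F_plus), c(4, 6))
  expect_equal(as.vector(fo$F_times), c(3, 8))
  expect_equal(as.vector(fo$F_max), c(3, 4))
  # symmetry
  sw <- fuse_ops(S2, S1)
  expect_identical(fo, sw[c("F_plus", "F_times", "F_max")])
  # all-zero second operand
  z <- S1 * 0
  fz <- fuse_ops(S1, z)
  expect_equal(fz$F_plus, S1)
  expect_true(all(fz$F_times == 0))
  expect_equal(fz$F_max, pmax(S1, 0))
  expect_error(fuse_ops(S1, ns$as_t4(matrix(0, 2, 2))), "mismatch")
})

test_that("channel descriptors and forced attention values are exact", {
  # one channel [[1,3],[5,7]]: average pool 4, max pool 7
  x <- array(c(1, 5, 3, 7), dim = c(2, 2, 1, 1))
  expect_equal(as.vector(ns$gap_fw(x)$y), 4)
  expect_equal(as.vector(ns$gmp_fw(x)$y), 7)
  # all MLP parameters zero -> sigmoid(0) = 0.5 per channel
  set.seed(41)
  at <- attention_make(4L, ratio = 2L)
  at$fc1$W[] <- 0; at$fc1$b[] <- 0; at$fc2$W[] <- 0; at$fc2$b[] <- 0
  M <- channel_attention(at, rand_t4(4, 4, 4, 3, seed = 41))
  expect_true(all(M == 0.5))
})

test_that("channel attention matches a straight-line recomputation", {
  set.seed(42)
  relu <- function(v) pmax(v, 0)
  sig <- function(v) 1 / (1 + exp(-v))
  for (rep in 1:25) {
    C <- sample(2:6, 1)
    at <- attention_make(C, ratio = 2L)
    x <- rand_t4(sample(2:5, 1), sample(2:5, 1), C, sample(1:3, 1),
                 seed = 42000 + rep)
    M <- channel_attention(at, x)
    for (n in seq_len(dim(x)[4])) {
      avg <- apply(x[, , , n, drop = FALSE], 3, mean)
      mx <- apply(x[, , , n, drop = FALSE], 3, max)
      expect_M <- sig(
        (at$fc2$W %*% relu(at$fc1$W %*% avg + at$fc1$b) + at$fc2$b) +
          (at$fc2$W %*% relu(at$fc1$W %*% mx + at$fc1$b) + at$fc2$b))
      expect_lt(max(abs(M[, n] - expect_M)), 1e-9)
    }
    expect_true(all(M > 0 & M < 1))
  }
})

test_that("a first-block MAFFB with identity-like weights matches a hand trace", {
  blk <- maffb_make(1L, 1L, prev_ch = 0L, ratio = 1L)
  # attention forced to 0.5; convs pass the centre pixel through
  blk$att$fc1$W[] <- 0; blk$att$fc1$b[] <- 0
  blk$att$fc2$W[] <- 0; blk$att$fc2$b[] <- 0
  blk$conv1$conv$W[] <- 0
  blk$conv1$conv$W[2, 2, , 1] <- 1  # sum the three fused channels
  blk$conv1$conv$b[] <- 0
  blk$conv2$conv$W[] <- 0
  blk$conv2$conv$W[2, 2, 1, 1] <- 1
  blk$conv2$conv$b[] <- 0
  S1 <- array(c(1, 3, 2, 4), dim = c(2, 2, 1, 1))
  S2 <- array(c(5, 7, 6, 8), dim = c(2, 2, 1, 1))
  out <- maffb_forward(blk, S1, S2, NULL, training = FALSE)$F
  f <- 1 / sqrt(1 + 1e-5)  # eval-mode BN with unit running variance
  expected <- pmax(f * pmax(f * 0.5 * (S1 + S2 + S1 * S2 + pmax(S1, S2)),
                            0), 0)
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("MAFFB and the fusion network are invariant to modality order", {
  set.seed(43)
  blk <- maffb_make(3L, 4L, prev_ch = 2L)
  S1 <- rand_t4(8, 8, 3, 2, seed = 43)
  S2 <- rand_t4(8, 8, 3, 2, seed = 44)
  Fp <- rand_t4(8, 8, 2, 2, seed = 45)
  a <- maffb_forward(blk, S1, S2, Fp)$F
  b <- maffb_forward(blk, S2, S1, Fp)$F
  expect_identical(a, b)
  expect_equal(dim(a)[1:2], dim(S1)[1:2])
  # whole fusion network
  bb1 <- build_backbone(backbone_config(4L))
  bb2 <- build_backbone(backbone_config(4L))
  fn <- build_fusion_net(4L)
  x1 <- rand_t4(16, 16, 1, 2, seed = 46)
  x2 <- rand_t4(16, 16, 1, 2, seed = 47)
  fs1 <- encode(bb1, x1); fs2 <- encode(bb2, x2)
  fw <- fusion_network(fn, fs1, fs2)
  sw <- fusion_network(fn, fs2, fs1)
  for (k in c("F1", "F2", "F3"))
    expect_identical(fw[[k]], sw[[k]])
})

test_that("fusion features have the configured widths and feed back to both encoders", {
  set.seed(48)
  b <- 4L
  bb1 <- build_backbone(backbone_config(b))
  bb2 <- build_backbone(backbone_config(b))
  fn <- build_fusion_net(b)
  x1 <- rand_t4(16, 16, 1, 2, seed = 48)
  x2 <- rand_t4(16, 16, 1, 2, seed = 49)
  fs1 <- encode(bb1, x1, TRUE); fs2 <- encode(bb2, x2, TRUE)
  fw <- fusion_network(fn, fs1, fs2, TRUE)
  expect_equal(dim(fw$F1), c(16, 16, b, 2))
  expect_equal(dim(fw$F2), c(8, 8, 2 * b, 2))
  expect_equal(dim(fw$F3), c(4, 4, 4 * b, 2))
  fs1_bad <- fs1; fs1_bad$S2 <- NULL
  expect_error(fusion_network(fn, fs1_bad, fs2), "missing tap level")
  # gradients from a loss on F3 reach both encoders' inputs
  gF3 <- array(1, dim = dim(fw$F3))
  fb <- ns$fusion_network_bw(fn, fw$cache, gF3 = gF3)
  g1 <- ns$encode_bw(bb1, fs1, fb$g_fs1$S1, fb$g_fs1$S2, fb$g_fs1$S3)
  g2 <- ns$encode_bw(bb2, fs2, fb$g_fs2$S1, fb$g_fs2$S2, fb$g_fs2$S3)
  expect_gt(sum(abs(g1$gx)), 0)
  expect_gt(sum(abs(g2$gx)), 0)
})

test_that("MAFFB rejects inconsistent inputs", {
  blk <- maffb_make(2L, 2L, prev_ch = 0L)
  S <- rand_t4(4, 4, 2, 1, seed = 50)
  expect_error(maffb_forward(blk, S, rand_t4(4, 4, 3, 1, seed = 1)),
               "mismatch")
  expect_error(maffb_forward(blk, S, S, F_prev = S), "prev_ch")
  blk2 <- maffb_make(2L, 2L, prev_ch = 2L)
  expect_error(maffb_forward(blk2, S, S, rand_t4(2, 2, 2, 1, seed = 1)),
               "incompatible")
})
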