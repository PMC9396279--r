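test_that("masking replaces only masked pixels with the fill value", {
  set.seed(31)
  x <- matrix(rnorm(32 * 32), 32)
  m0 <- sample_masks(c(32L, 32L), 0L, c(8L, 8L))
  expect_identical(mask_patch(x, m0), x)
  mfull <- sample_masks(c(32L, 32L), 1L, c(32L, 32L), seed = 2L)
  expect_true(all(mask_patch(x, mfull) == 0))
  m <- sample_masks(c(32L, 32L), 4L, c(8L, 8L), seed = 3L)
  xm <- mask_patch(x, m)
  expect_equal(mean(m$mask), 0.25)
  expect_identical(xm[m$mask == 0], x[m$mask == 0])
  expect_true(all(xm[m$mask == 1] == 0))
  expect_error(mask_patch(matrix(0, 16, 16), m), "does not match")
})

test_that("the triplet compressor preserves size and averages when told to", {
  set.seed(32)
  cl <- compress_make()
  stack <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  y <- compress_triplet(cl, stack)
  expect_equal(dim(y), c(16, 16, 1, 1))
  # parameters set to average the 3 slices exactly
  cl2 <- cl
  cl2$W[] <- 0; cl2$W[2, 2, , 1] <- 1 / 3; cl2$b[] <- 0
  y2 <- compress_triplet(cl2, stack)
  expect_equal(y2[, , 1, 1], apply(stack, c(1, 2), mean), tolerance = 1e-12)
  expect_error(compress_triplet(cl, array(0, dim = c(8, 8, 2))), "3 slices")
  # gradient reaches all three input slices
  fw <- ns$conv_fw(cl, ns$as_t4(stack))
  gy <- array(1, dim = dim(fw$y))
  gx <- ns$conv_bw(cl, fw$cache, gy)$gx
  for (j in 1:3) expect_gt(sum(abs(gx[, , j, 1])), 0)
})

test_that("zero pretraining steps leave the network bit-identical", {
  set.seed(33)
  bb <- build_backbone(backbone_config(4L))
  res <- pretrain_inpainting(bb, list(matrix(0, 16, 16)), steps = 0L)
  expect_identical(ns$flatten_params(res$backbone), ns$flatten_params(bb))
  expect_length(res$trace, 0L)
  expect_error(pretrain_inpainting(bb, list(), steps = 5L), "empty dataset")
})

test_that("dropping the index term reduces the joint objective to plain reconstruction", {
  set.seed(34)
  spec <- tiny_spec()
  case <- generate_case(spec, "case_01")
  v <- scale_intensity(case$source1)$volume
  trips <- slice_triplets(v)[1:4]
  im <- index_model_make(build_backbone(backbone_config(4L)))
  stacks <- ns$stack_batch(lapply(trips, `[[`, "pixels"))
  mids <- ns$stack_batch(lapply(trips, function(p) p$pixels[, , 2]))
  ys <- vapply(trips, function(p) p$slice_index / 11, numeric(1))
  s1 <- ns$index_step(im, stacks, mids, ys, index_weight = 1,
                      training = FALSE)
  s0 <- ns$index_step(im, stacks, mids, ys, index_weight = 0,
                      training = FALSE)
  # both components non-negative; recon part identical in the two runs
  expect_gte(s1$loss_rec, 0); expect_gte(s1$loss_idx, 0)
  expect_equal(s0$loss_rec, s1$loss_rec)
  # with weight 0 no index gradient reaches the branch
  expect_equal(sum(abs(ns$flatten_params(s0$g$branch)$`fc/W`)), 0)
  expect_gt(sum(abs(ns$flatten_params(s1$g$branch)$`fc/W`)), 0)
})

test_that("index pretraining records non-negative loss components per step", {
  set.seed(35)
  spec <- tiny_spec()
  cases <- generate_cases(spec, 2)
  trips <- phantom_triplets(cases, "case_01", "source1")
  im <- index_model_make(build_backbone(backbone_config(4L)))
  res <- pretrain_index(im, trips, depth = 12L, steps = 6L, seed = 1L,
                        batch_size = 2L)
  expect_length(res$trace_rec, 6L)
  expect_true(all(res$trace_rec >= 0))
  expect_true(all(res$trace_idx >= 0))
  expect_error(pretrain_index(im, trips, depth = 2L, steps = 1L),
               "depth >= 3")
})

test_that("pretrained encoder weights survive a checkpoint round trip bit-exactly", {
  set.seed(36)
  spec <- tiny_spec()
  cases <- generate_cases(spec, 1)
  patches <- phantom_patches(cases, "case_01", "source1")
  bb <- build_backbone(backbone_config(4L))
  res <- pretrain_inpainting(bb, patches, steps = 3L, seed = 2L, lr = 1e-3)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(res$backbone, list(), path)
  re <- load_checkpoint(path)$model
  expect_identical(ns$flatten_params(re), ns$flatten_params(res$backbone))
  # transplant into the synthesis bundle: features agree bit-exactly
  models <- build_synth_models(4L, c(4L, 8L, 8L, 8L))
  models$bb1 <- re
  x <- rand_t4(16, 16, 1, 1, seed = 36)
  expect_identical(encode(models$bb1, x)$S3, encode(res$backbone, x)$S3)
})

test_that("inpainting never alters unmasked pixels of the loss input", {
  set.seed(37)
  x <- matrix(rnorm(32 * 32), 32)
  m <- sample_masks(c(32L, 32L), 4L, c(8L, 8L), seed = 9L)
  xm <- mask_patch(x, m)
  expect_identical(xm[m$mask == 0], x[m$mask == 0])
})
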