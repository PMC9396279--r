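test_that("central crop selects the centered window", {
  set.seed(1)
  vol <- volume(array(rnorm(2 * 240 * 240), dim = c(2, 240, 240)))
  cr <- central_crop(vol, c(160L, 180L))
  # recompute the centered window indices independently
  r0 <- floor((240 - 160) / 2); c0 <- floor((240 - 180) / 2)
  expect_equal(r0, 40); expect_equal(c0, 30)
  expect_equal(cr$data, vol$data[, (r0 + 1):(r0 + 160), (c0 + 1):(c0 + 180)])
  # identity when crop equals the plane
  expect_equal(central_crop(vol, c(240L, 240L))$data, vol$data)
  # constant slice stays constant
  cv <- volume(array(3.5, dim = c(1, 10, 12)))
  expect_true(all(central_crop(cv, c(6L, 8L))$data == 3.5))
  expect_error(central_crop(cv, c(11L, 8L)), "exceeds")
})

test_that("four corner patches carry the stated offsets and cover the plane", {
  set.seed(2)
  vol <- volume(array(rnorm(160 * 180), dim = c(1, 160, 180)))
  ps <- extract_patches(vol, c(128L, 128L))
  offs <- t(vapply(ps, `[[`, integer(2), "crop_offset"))
  expect_equal(nrow(offs), 4L)
  expect_setequal(split(offs, row(offs)),
                  list(c(0L, 0L), c(0L, 52L), c(32L, 0L), c(32L, 52L)))
  # each patch covers its corner, union covers the plane
  cov <- matrix(0, 160, 180)
  for (p in ps) cov[p$crop_offset[1] + 1:128, p$crop_offset[2] + 1:128] <- 1
  expect_true(all(cov == 1))
  # patch equal to plane collapses to a single record
  one <- extract_patches(volume(array(1, dim = c(1, 128, 128))),
                         c(128L, 128L))
  expect_length(one, 1L)
  # constant plane gives constant patches
  cps <- extract_patches(volume(array(2, dim = c(1, 160, 180))),
                         c(128L, 128L))
  expect_true(all(vapply(cps, function(p) all(p$pixels == 2), logical(1))))
  expect_error(extract_patches(vol, c(200L, 128L)), "larger than plane")
})

test_that("stitching averages overlaps and round-trips extraction exactly", {
  set.seed(3)
  vol <- volume(array(rnorm(160 * 180), dim = c(1, 160, 180)))
  ps <- extract_patches(vol, c(128L, 128L))
  back <- stitch_patches(ps, c(160L, 180L))
  expect_equal(max(abs(back - vol$data[1, , ])), 0)
  # two overlapping constant patches: strip averages to 0.5
  mk <- function(v, ro, co) structure(
    list(pixels = matrix(v, 4, 4), crop_offset = c(ro, co)),
    class = "patch_record")
  plane <- stitch_patches(list(mk(0, 0L, 0L), mk(1, 0L, 2L)), c(4L, 6L))
  expect_true(all(plane[, 3:4] == 0.5))
  expect_true(all(plane[, 1:2] == 0))
  expect_true(all(plane[, 5:6] == 1))
  # incomplete coverage is an error naming the uncovered pixel
  expect_error(stitch_patches(list(mk(0, 0L, 0L)), c(8L, 8L)),
               "incomplete coverage")
})

test_that("extract/stitch round trip holds across random geometries", {
  set.seed(4)
  for (i in 1:6) {
    H <- sample(10:40, 1); W <- sample(10:40, 1)
    # four corner patches cover the plane iff the patch spans at least half
    p <- c(sample(ceiling(H / 2):H, 1), sample(ceiling(W / 2):W, 1))
    vol <- volume(array(rnorm(2 * H * W), dim = c(2, H, W)))
    ps <- extract_patches(vol, p)
    for (k in 0:1) {
      sl <- Filter(function(x) x$slice_index == k, ps)
      expect_equal(max(abs(stitch_patches(sl, c(H, W)) - vol$data[k + 1, , ])),
                   0)
    }
  }
})

test_that("intensity scaling maps extrema to [-1, 1] and inverts exactly", {
  v <- volume(array(c(-2, 0, 2, 1, -1, 0.5), dim = c(1, 2, 3)))
  sc <- scale_intensity(v)
  expect_equal(range(sc$volume$data), c(-1, 1))
  expect_equal(sc$volume$data[1, 1, 1], -1)  # min -2 -> -1
  expect_equal(sc$volume$data[1, 1, 2], 1)   # max 2 -> 1
  expect_equal(sc$volume$data[1, 2, 1], 0)   # 0 -> 0
  set.seed(5)
  r <- volume(array(rnorm(4 * 8 * 8) * 100 + 7, dim = c(4, 8, 8)))
  rt <- unscale_intensity(scale_intensity(r)$volume,
                          scale_intensity(r)$params)
  expect_equal(rt$data, r$data, tolerance = 1e-12)
  # constant volume maps to zeros, inverts to the constant
  cv <- volume(array(4, dim = c(1, 3, 3)))
  sc2 <- scale_intensity(cv)
  expect_true(all(sc2$volume$data == 0))
  expect_true(all(unscale_intensity(sc2$volume, sc2$params)$data == 4))
})

test_that("slice triplets replicate edges and label every slice", {
  set.seed(6)
  v <- volume(array(rnorm(5 * 8 * 8), dim = c(5, 8, 8)))
  tr <- slice_triplets(v)
  expect_length(tr, 5L)
  expect_equal(vapply(tr, `[[`, integer(1), "slice_index"), 0:4)
  expect_equal(tr[[1]]$pixels[, , 1], v$data[1, , ])  # edge replicated
  expect_equal(tr[[1]]$pixels[, , 2], v$data[1, , ])
  expect_equal(tr[[1]]$pixels[, , 3], v$data[2, , ])
  expect_equal(tr[[5]]$pixels[, , 3], v$data[5, , ])
  v3 <- volume(array(rnorm(3 * 4 * 4), dim = c(3, 4, 4)))
  mid <- slice_triplets(v3)[[2]]
  for (j in 1:3) expect_equal(mid$pixels[, , j], v3$data[j, , ])
  expect_error(slice_triplets(volume(array(0, dim = c(2, 4, 4)))),
               "depth >= 3")
})
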