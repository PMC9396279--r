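test_that("phantom generation is deterministic under seed and distinct across seeds", {
  spec <- tiny_spec(seed = 7L)
  a <- generate_case(spec, "case_01")
  b <- generate_case(spec, "case_01")
  expect_identical(a$source1$data, b$source1$data)
  expect_identical(a$target$data, b$target$data)
  spec2 <- tiny_spec(seed = 8L)
  c_ <- generate_case(spec2, "case_01")
  expect_false(identical(a$source1$data, c_$source1$data))
})

test_that("modalities are co-registered and margins are exactly zero", {
  spec <- tiny_spec()
  case <- generate_case(spec, "case_01")
  m <- spec$background_margin
  d <- dim(case$source1$data)
  for (mod in names(case)) {
    x <- case[[mod]]$data
    expect_identical(dim(x), d)
    expect_true(all(x[, seq_len(m), ] == 0))
    expect_true(all(x[, (d[2] - m + 1):d[2], ] == 0))
    expect_true(all(x[, , seq_len(m)] == 0))
    expect_true(all(x[, , (d[3] - m + 1):d[3]] == 0))
    expect_true(all(is.finite(x)))
  }
  # blob centroids computed independently from each modality agree
  centroid <- function(x) {
    w <- x / sum(x)
    idx <- which(w > 0, arr.ind = TRUE)
    colSums(idx * w[w > 0])
  }
  c1 <- centroid(case$source1$data)
  c2 <- centroid(case$source2$data)
  # same geometry, different monotone contrast: centroids close, support equal
  expect_identical(case$source1$data > 0, case$source2$data > 0)
  expect_true(all(abs(c1 - c2) < dim(case$source1$data) * 0.1))
})

test_that("degenerate blob-free spec yields all-zero volumes", {
  spec <- phantom_spec(shape = c(6L, 32L, 32L), n_blobs = 0L,
                       background_margin = 4L, target_rule = "mean")
  case <- generate_case(spec)
  expect_true(all(case$source1$data == 0))
  expect_true(all(case$source2$data == 0))
  expect_true(all(case$target$data == 0))
})

test_that("the mean target rule is exact and recoverable by least squares", {
  spec <- tiny_spec(target_rule = "mean")
  case <- generate_case(spec, "case_03")
  expect_equal(max(abs(case$target$data -
                         (case$source1$data + case$source2$data) / 2)), 0)
  # voxel-wise least squares of target on (source1, source2)
  df <- data.frame(y = as.vector(case$target$data),
                   s1 = as.vector(case$source1$data),
                   s2 = as.vector(case$source2$data))
  fit <- lm(y ~ 0 + s1 + s2, data = df)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(unname(coef(fit)), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("source intensities have positive spread and target follows the blend rule", {
  spec <- tiny_spec(target_rule = "blend")
  case <- generate_case(spec, "case_02")
  expect_gt(sd(case$source1$data), 0)
  s1 <- case$source1$data; s2 <- case$source2$data
  expect_equal(case$target$data, (s1 + s2) / 2 + 0.25 * (s1 - s2)^2)
})

test_that("mask sampling covers the stated fraction without overlap", {
  m <- sample_masks(c(128L, 128L), 4L, c(32L, 32L), seed = 5L)
  expect_equal(mean(m$mask), 4 * 1024 / 16384)   # 0.25
  expect_true(all(m$mask %in% c(0, 1)))
  expect_equal(nrow(m$boxes), 4L)
  # non-overlap: total painted area equals 4 * 32^2
  expect_equal(sum(m$mask), 4 * 32 * 32)
  m2 <- sample_masks(c(128L, 128L), 4L, c(32L, 32L), seed = 5L)
  expect_identical(m$mask, m2$mask)
  m0 <- sample_masks(c(128L, 128L), 0L, c(32L, 32L))
  expect_equal(sum(m0$mask), 0)
  expect_error(sample_masks(c(32L, 32L), 4L, c(32L, 32L)), "cannot fit")
})

test_that("phantom NIfTI round trip preserves voxels and labels", {
  spec <- phantom_spec(shape = c(4L, 24L, 24L), n_blobs = 3L,
                       background_margin = 3L)
  case <- generate_case(spec, "case_09")
  dir <- tempfile()
  paths <- write_case_nifti(case, dir)
  expect_length(list.files(dir), 3L)
  rv <- read_volume(file.path(dir, "case_09_target.nii.gz"),
                    modality = "target")
  expect_equal(rv$data, case$target$data, tolerance = 1e-6)
  cases <- read_nifti_cases(dir)
  expect_named(cases, "case_09")
  expect_setequal(names(cases$case_09), c("source1", "source2", "target"))
})
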