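# ---------------------------------------------------------------------------
# Image-quality metrics: MSE, PSNR, SSIM.
#
# PSNR "paper" mode uses the squared maximum intensity over BOTH images as
# the peak; "standard" mode uses a caller-supplied data range.  SSIM
# "global" mode evaluates the similarity formula once over the whole image;
# "windowed" mode is the conventional 11x11 Gaussian mean-SSIM.
# ---------------------------------------------------------------------------

as_img <- function(x) if (inherits(x, "volume")) x$data else x

check_same_shape <- function(y, g) {
  y <- as_img(y); g <- as_img(g)
  if (!identical(dim(y), dim(g)) || length(y) != length(g))
    stop("shape mismatch between images")
  list(y = y, g = g)
}

#' Mean squared error
#' @param y,g images (arrays or `volume`s) of identical shape
#' @return scalar MSE
#' @export
mse <- function(y, g) {
  v <- check_same_shape(y, g)
  mean((v$y - v$g)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' In `"paper"` mode the peak is the maximum intensity over both images:
#' `PSNR = 10 log10(max^2(y, g) / MSE)`.  In `"standard"` mode the peak is
#' the supplied `data_range`.  Identical images give `+Inf`.
#'
#' @param y,g images of identical shape
#' @param mode `"paper"` or `"standard"`
#' @param data_range peak used in `"standard"` mode
#' @return scalar dB (possibly `Inf`)
#' @export
psnr <- function(y, g, mode = c("paper", "standard"), data_range = 1) {
  mode <- match.arg(mode)
  v <- check_same_shape(y, g)
  m <- mean((v$y - v$g)^2)
  if (m == 0) return(Inf)
  peak <- if (mode == "paper") max(v$y, v$g) else data_range
  10 * log10(peak^2 / m)
}

#' Structural similarity
#'
#' `mode = "global"` evaluates means, variances and the covariance over the
#' whole image and applies the similarity formula once.  `mode = "windowed"`
#' computes the conventional mean-SSIM over an 11x11 Gaussian window
#' (sigma 1.5).  Constants are `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` with
#' `L = data_range`.
#'
#' @param y,g images of identical shape
#' @param mode `"global"` or `"windowed"`
#' @param data_range dynamic range L of the data
#' @return scalar in `\[-1, 1\]`
#' @export
ssim <- function(y, g, mode = c("global", "windowed"), data_range = 1) {
  mode <- match.arg(mode)
  v <- check_same_shape(y, g)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  if (mode == "global") {
    n <- length(v$y)
    muy <- mean(v$y); mug <- mean(v$g)
    vy <- sum((v$y - muy)^2) / (n - 1)
    vg <- sum((v$g - mug)^2) / (n - 1)
    cov <- sum((v$y - muy) * (v$g - mug)) / (n - 1)
    return(((2 * muy * mug + c1) * (2 * cov + c2)) /
             ((muy^2 + mug^2 + c1) * (vy + vg + c2)))
  }
  # windowed mean-SSIM on a 2D image
  y2 <- as_img(y); g2 <- as_img(g)
  if (length(dim(y2)) != 2L) stop("windowed SSIM expects a 2D image")
  if (any(dim(y2) < 11L))
    stop("windowed SSIM needs an image of at least 11x11 pixels")
  w <- gauss_kernel2(11L, 1.5)
  muy <- filt2(y2, w); mug <- filt2(g2, w)
  syy <- filt2(y2 * y2, w) - muy^2
  sgg <- filt2(g2 * g2, w) - mug^2
  syg <- filt2(y2 * g2, w) - muy * mug
  smap <- ((2 * muy * mug + c1) * (2 * syg + c2)) /
    ((muy^2 + mug^2 + c1) * (syy + sgg + c2))
  mean(smap)
}

gauss_kernel2 <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- outer(g, g)
  k / sum(k)
}

# 'valid' 2D correlation via the package's conv kernel
filt2 <- function(img, k) {
  x <- array(img, dim = c(dim(img), 1L, 1L))
  w <- array(k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))],
             dim = c(dim(k), 1L, 1L))
  y <- cpp_conv2d_fw(x, w, 0, 1L, 0L)
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Compute all quality metrics for one synthesized/ground-truth pair
#'
#' @param y ground truth, `g` synthesized (identical shapes)
#' @param g synthesized image
#' @param psnr_mode,ssim_mode see [psnr()] and [ssim()]
#' @param data_range dynamic range for standard-mode PSNR / SSIM constants
#' @return a `metrics_record`: list with `mse`, `psnr`, `ssim`, `n`
#' @export
metrics_record <- function(y, g, psnr_mode = "paper", ssim_mode = "global",
                           data_range = 1) {
  v <- check_same_shape(y, g)
  structure(list(mse = mse(v$y, v$g),
                 psnr = psnr(v$y, v$g, psnr_mode, data_range),
                 ssim = ssim(v$y, v$g, ssim_mode, data_range),
                 n = length(v$y)),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("MSE %.6g | PSNR %.4g dB | SSIM %.6g (n = %d)\n",
              x$mse, x$psnr, x$ssim, x$n))
  invisible(x)
}

#' Slice-wise volume evaluation
#'
#' Computes the metrics slice by slice on unscaled volumes and averages,
#' skipping the infinite-PSNR sentinel slices (identical slices) in the
#' PSNR average.
#'
#' @param truth,pred `volume`s of identical shape
#' @inheritParams metrics_record
#' @return a `metrics_record` of per-slice averages
#' @export
evaluate_volume <- function(truth, pred, psnr_mode = "paper",
                            ssim_mode = "global", data_range = NULL) {
  stopifnot(identical(dim(truth$data), dim(pred$data)))
  if (is.null(data_range))
    data_range <- max(truth$data) - min(truth$data)
  D <- dim(truth$data)[1]
  ms <- ps <- ss <- numeric(D)
  for (k in seq_len(D)) {
    yk <- truth$data[k, , ]; gk <- pred$data[k, , ]
    ms[k] <- mse(yk, gk)
    ps[k] <- psnr(yk, gk, psnr_mode, data_range)
    ss[k] <- ssim(yk, gk, ssim_mode, data_range)
  }
  structure(list(mse = mean(ms), psnr = mean(ps[is.finite(ps)]),
                 ssim = mean(ss), n = length(truth$data)),
            class = "metrics_record")
}
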