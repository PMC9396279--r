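# ---------------------------------------------------------------------------
# GAN-based generation stage.
#
# The generator compresses the deepest common features with two
# convolutions, refines them with three further MAFFBs (fed by the unique
# features of both modalities and the fusion network's common features at
# matching depth), and maps the last block's output to the synthetic image.
# Two independent discriminators critique the result: a pixel-level network
# on raw images and a feature-level network on Canny edge maps, each five
# conv+BN stages with channels 32/64/128/256/1 and strides 2/2/2/2/1.
# Adversarial terms use the standard non-saturating formulation
# (real -> log D, fake -> log(1 - D)).
# ---------------------------------------------------------------------------

#' Build the generator
#' @param base_channels backbone base width
#' @param ratio attention bottleneck ratio of the generator MAFFBs
#' @return a `generator` layer tree
#' @export
build_generator <- function(base_channels = 16L, ratio = 8L) {
  b <- as.integer(base_channels)
  structure(list(
    head1 = cblock_make(4L * b, 2L * b, act = "relu"),
    head2 = cblock_make(2L * b, b, act = "relu"),
    maffb4 = maffb_make(4L * b, 4L * b, prev_ch = b, ratio = ratio),
    maffb5 = maffb_make(2L * b, 2L * b, prev_ch = 6L * b, ratio = ratio),
    maffb6 = maffb_make(b, b, prev_ch = 3L * b, ratio = ratio),
    out = conv_make(b, 1L),
    base = b), class = "generator")
}

#' Synthesize a patch from common and unique features
#'
#' @param gen a `generator`
#' @param fused output of [fusion_network()] (`F1`, `F2`, `F3`)
#' @param fs1,fs2 the two modalities' `feature_set`s
#' @param training batch-statistics mode
#' @return list with the synthesized patch `y` (4D, tanh range) and `cache`
#' @export
generate <- function(gen, fused, fs1, fs2, training = FALSE) {
  h1 <- cblock_fw(gen$head1, fused$F3, training)
  h2 <- cblock_fw(gen$head2, h1$y, training)
  m4 <- maffb_forward(gen$maffb4, fs1$S3, fs2$S3, h2$y, training)
  u4 <- upsample2_fw(m4$F)
  p5 <- concat_ch(u4$y, fused$F2)
  m5 <- maffb_forward(gen$maffb5, fs1$S2, fs2$S2, p5, training)
  u5 <- upsample2_fw(m5$F)
  p6 <- concat_ch(u5$y, fused$F1)
  m6 <- maffb_forward(gen$maffb6, fs1$S1, fs2$S1, p6, training)
  oc <- conv_fw(gen$out, m6$F)
  oa <- act_fw("tanh", oc$y)
  list(y = oa$y,
       cache = list(h1 = h1$cache, h2 = h2$cache, m4 = m4$cache,
                    m5 = m5$cache, m6 = m6$cache, oc = oc$cache,
                    oa = oa$cache,
                    w4 = dim(m4$F)[3], w5 = dim(m5$F)[3],
                    m4_out = m4$F, m5_out = m5$F, m6_out = m6$F))
}

# backward through the generator: gradients w.r.t. the fused features and
# both tap sets, plus the generator parameter-gradient tree
generate_bw <- function(gen, cache, g_img) {
  g <- act_bw("tanh", cache$oa, g_img)
  co <- conv_bw(gen$out, cache$oc, g)
  b6 <- maffb_bw(gen$maffb6, cache$m6, co$gx)
  sp6 <- split_ch(b6$g_prev, c(dim(b6$g_prev)[3] - gen$base, gen$base))
  gF1 <- sp6[[2]]
  b5 <- maffb_bw(gen$maffb5, cache$m5, upsample2_bw(sp6[[1]]))
  sp5 <- split_ch(b5$g_prev, c(cache$w4, 2L * gen$base))
  gF2 <- sp5[[2]]
  b4 <- maffb_bw(gen$maffb4, cache$m4, upsample2_bw(sp5[[1]]))
  h2b <- cblock_bw(gen$head2, cache$h2, b4$g_prev)
  h1b <- cblock_bw(gen$head1, cache$h1, h2b$gx)
  gF3 <- h1b$gx
  list(gF1 = gF1, gF2 = gF2, gF3 = gF3,
       g_fs1 = list(S1 = b6$gS1, S2 = b5$gS1, S3 = b4$gS1),
       g_fs2 = list(S1 = b6$gS2, S2 = b5$gS2, S3 = b4$gS2),
       g = list(head1 = h1b$g, head2 = h2b$g, maffb4 = b4$g,
                maffb5 = b5$g, maffb6 = b6$g, out = co$g))
}

#' Build a discriminator
#'
#' Five conv+BN stages.  With the default channels (32, 64, 128, 256, 1)
#' and strides (2, 2, 2, 2, 1), a 128x128 input yields a 1-channel 8x8
#' output map, read as logits by the adversarial loss.
#'
#' @param kind `"pixel"` (LeakyReLU 0.2) or `"feature"` (ReLU)
#' @param channels the four hidden channel widths
#' @param in_ch input channels
#' @return a `discriminator` layer tree
#' @export
build_discriminator <- function(kind = c("pixel", "feature"),
                                channels = c(32L, 64L, 128L, 256L),
                                in_ch = 1L) {
  kind <- match.arg(kind)
  act <- if (kind == "pixel") "lrelu" else "relu"
  ch <- as.integer(channels)
  structure(list(
    d1 = cblock_make(in_ch, ch[1], stride = 2L, act = act),
    d2 = cblock_make(ch[1], ch[2], stride = 2L, act = act),
    d3 = cblock_make(ch[2], ch[3], stride = 2L, act = act),
    d4 = cblock_make(ch[3], ch[4], stride = 2L, act = act),
    d5 = cblock_make(ch[4], 1L, stride = 1L, act = act),
    kind = kind), class = "discriminator")
}

disc_fw <- function(dsc, x, training = FALSE) {
  f1 <- cblock_fw(dsc$d1, x, training)
  f2 <- cblock_fw(dsc$d2, f1$y, training)
  f3 <- cblock_fw(dsc$d3, f2$y, training)
  f4 <- cblock_fw(dsc$d4, f3$y, training)
  f5 <- cblock_fw(dsc$d5, f4$y, training)
  list(y = f5$y,
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                    f4 = f4$cache, f5 = f5$cache))
}

disc_bw <- function(dsc, cache, gy) {
  b5 <- cblock_bw(dsc$d5, cache$f5, gy)
  b4 <- cblock_bw(dsc$d4, cache$f4, b5$gx)
  b3 <- cblock_bw(dsc$d3, cache$f3, b4$gx)
  b2 <- cblock_bw(dsc$d2, cache$f2, b3$gx)
  b1 <- cblock_bw(dsc$d1, cache$f1, b2$gx)
  list(gx = b1$gx,
       g = list(d1 = b1$g, d2 = b2$g, d3 = b3$g, d4 = b4$g, d5 = b5$g))
}

# ---------------------------------------------------------------------------
# Edge extraction
# ---------------------------------------------------------------------------

#' Canny edge map of a patch
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding.  Thresholds are relative to the image's maximum
#' gradient magnitude, so the edge map is invariant under positive affine
#' intensity changes; a constant image yields no edges.
#'
#' @param img 2D patch
#' @param low,high hysteresis thresholds in (0, 1), `low < high`
#' @param sigma Gaussian smoothing width in pixels
#' @return binary matrix (1 = edge) of the same size
#' @export
canny_features <- function(img, low = 0.1, high = 0.3, sigma = 1.4) {
  if (low >= high) stop("canny: low threshold must be < high threshold")
  img <- as_img(img)
  if (length(dim(img)) != 2L) stop("canny expects a 2D patch")
  cpp_canny(img, low, high, sigma)
}

# differentiable edge surrogate: Sobel magnitude squashed by tanh.  Used on
# the generator's path through the feature-level discriminator, where hard
# Canny (non-maximum suppression + hysteresis) has no useful gradient.
sobel_w <- local({
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  ky <- t(kx)                                          # d/drow
  w <- array(0, dim = c(3, 3, 1, 2))
  w[, , 1, 1] <- ky; w[, , 1, 2] <- kx
  w
})

soft_edges_fw <- function(x, tau = 1.0) {
  g <- cpp_conv2d_fw(x, sobel_w, c(0, 0), 1L, 1L)
  d <- dim(g)
  gy <- g[, , 1, , drop = FALSE]; gx <- g[, , 2, , drop = FALSE]
  mag <- sqrt(gy^2 + gx^2 + 1e-8)
  e <- tanh(mag / tau)
  list(y = e, cache = list(x = x, gy = gy, gx = gx, mag = mag, e = e,
                           tau = tau))
}

soft_edges_bw <- function(cache, ge) {
  dmag <- ge * (1 - cache$e^2) / cache$tau
  gg <- concat_ch(dmag * cache$gy / cache$mag, dmag * cache$gx / cache$mag)
  cpp_conv2d_bw(cache$x, sobel_w, gg, 1L, 1L)$gx
}

# ---------------------------------------------------------------------------
# Losses
# ---------------------------------------------------------------------------

# probability map of a discriminator (or a mock function in tests)
disc_prob <- function(D, x, training = FALSE) {
  if (is.function(D)) return(list(p = D(x), cache = NULL))
  f <- disc_fw(D, x, training)
  list(p = 1 / (1 + exp(-f$y)), cache = f$cache, z = f$y)
}

bce_from_prob <- function(p, target) {
  eps <- 1e-12
  -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
}

#' Assemble the generation-stage loss report
#'
#' Components: `l_grec` (L1 between real and generated image), the
#' adversarial terms of both discriminators in generator view (`l_pixel_adv`,
#' `l_feature_adv`: non-saturating `-log D(fake)`) and discriminator view
#' (`l_pixel_adv_d`, `l_feature_adv_d`: `-log D(real) - log(1 - D(fake))`),
#' and optionally `l_rec` (backbone reconstruction loss).  The `total`
#' follows the additive composition
#' `l_pixel_adv + l_feature_adv + lambda1 * l_grec + lambda2 * l_rec`.
#'
#' @param y real patch, `yhat` generated patch (identical shapes)
#' @param yhat generated patch
#' @param d_pixel,d_feature discriminators (layer trees), or functions
#'   mapping an image batch to a probability map (useful for closed-form
#'   checks)
#' @param lambda1,lambda2 non-negative trade-off weights
#' @param l_rec reconstruction-loss value to fold into the total (0 if
#'   not supplied)
#' @param canny_low,canny_high,canny_sigma edge-extraction settings for the
#'   feature-level terms
#' @return a `loss_report`
#' @export
gan_losses <- function(y, yhat, d_pixel, d_feature, lambda1 = 100,
                       lambda2 = 10, l_rec = 0,
                       canny_low = 0.1, canny_high = 0.3, canny_sigma = 1.4) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be non-negative")
  y <- as_t4(y); yhat <- as_t4(yhat)
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  l_grec <- mean(abs(y - yhat))
  p_real <- disc_prob(d_pixel, y)$p
  p_fake <- disc_prob(d_pixel, yhat)$p
  N <- dim(y)[4]
  edge <- function(b) {
    out <- array(0, dim = dim(b))
    for (n in seq_len(N))
      out[, , 1, n] <- canny_features(b[, , 1, n], canny_low, canny_high,
                                      canny_sigma)
    out
  }
  f_real <- disc_prob(d_feature, edge(y))$p
  f_fake <- disc_prob(d_feature, edge(yhat))$p
  l_pixel_adv <- bce_from_prob(p_fake, 1)
  l_feature_adv <- bce_from_prob(f_fake, 1)
  l_pixel_adv_d <- bce_from_prob(p_real, 1) + bce_from_prob(p_fake, 0)
  l_feature_adv_d <- bce_from_prob(f_real, 1) + bce_from_prob(f_fake, 0)
  structure(list(l_grec = l_grec, l_pixel_adv = l_pixel_adv,
                 l_feature_adv = l_feature_adv, l_rec = l_rec,
                 l_pixel_adv_d = l_pixel_adv_d,
                 l_feature_adv_d = l_feature_adv_d,
                 lambda1 = lambda1, lambda2 = lambda2,
                 total = l_pixel_adv + l_feature_adv + lambda1 * l_grec +
                   lambda2 * l_rec),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(paste0("loss: total %.4f | grec %.4f | pix-adv %.4f | ",
                     "feat-adv %.4f | rec %.4f (l1=%g, l2=%g)\n"),
              x$total, x$l_grec, x$l_pixel_adv, x$l_feature_adv, x$l_rec,
              x$lambda1, x$lambda2))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Full synthesis forward/backward and one adversarial training step
# ---------------------------------------------------------------------------

#' Bundle of all synthesis-stage models
#' @param base_channels backbone base width
#' @param disc_channels hidden widths of both discriminators
#' @param ratio attention bottleneck ratio
#' @return a `synth_models` list: `bb1`, `bb2`, `fusion`, `gen`, `d_pixel`,
#'   `d_feature`
#' @export
build_synth_models <- function(base_channels = 16L,
                               disc_channels = c(32L, 64L, 128L, 256L),
                               ratio = 8L) {
  structure(list(
    bb1 = build_backbone(backbone_config(base_channels)),
    bb2 = build_backbone(backbone_config(base_channels)),
    fusion = build_fusion_net(base_channels, ratio),
    gen = build_generator(base_channels, ratio),
    d_pixel = build_discriminator("pixel", disc_channels),
    d_feature = build_discriminator("feature", disc_channels)),
    class = "synth_models")
}

# forward the whole synthesis pipeline on a batch of paired source patches
synth_forward <- function(models, x1, x2, training = FALSE) {
  x1 <- as_t4(x1); x2 <- as_t4(x2)
  fs1 <- encode(models$bb1, x1, training)
  fs2 <- encode(models$bb2, x2, training)
  fused <- fusion_network(models$fusion, fs1, fs2, training)
  gn <- generate(models$gen, fused, fs1, fs2, training)
  list(yhat = gn$y, fs1 = fs1, fs2 = fs2, fused = fused, gen_cache = gn$cache,
       x1 = x1, x2 = x2)
}

#' Synthesize patches with a trained model bundle (inference mode)
#' @param models a `synth_models`
#' @param x1,x2 source patches (2D, 3D or 4D batches)
#' @return 4D array of synthesized patches
#' @export
synthesize_patches <- function(models, x1, x2) {
  synth_forward(models, x1, x2, training = FALSE)$yhat
}

#' One adversarial training step
#'
#' Alternating update: both discriminators first (on the current generator
#' output, held fixed), then the generator together with the fusion network
#' and both backbones under the composite objective (non-saturating
#' adversarial terms, `lambda1` times the synthesis L1, `lambda2` times the
#' backbone reconstruction L1).  The feature-level adversarial gradient
#' reaches the generator through a differentiable soft-edge surrogate
#' (Sobel magnitude through tanh) while the discriminator itself trains on
#' hard Canny maps.
#'
#' @param models a `synth_models`
#' @param batch list with `x1`, `x2`, `y` (4D arrays, \[-1, 1\] scale)
#' @param opts optimizer bundle from [synth_opts_make()]
#' @param lambda1,lambda2 trade-off weights
#' @param edge_mode `"soft"` routes the generator's feature-level gradient
#'   through the soft surrogate; `"canny"` feeds the discriminator hard
#'   Canny maps in the generator step too (no gradient contribution)
#' @param canny_low,canny_high,canny_sigma edge-extraction settings
#' @return list with updated `models`, `opts` and a `loss_report`
#' @export
train_step <- function(models, batch, opts, lambda1 = 100, lambda2 = 10,
                       edge_mode = c("soft", "canny"),
                       canny_low = 0.1, canny_high = 0.3, canny_sigma = 1.4) {
  edge_mode <- match.arg(edge_mode)
  x1 <- as_t4(batch$x1); x2 <- as_t4(batch$x2); y <- as_t4(batch$y)
  N <- dim(y)[4]

  fw <- synth_forward(models, x1, x2, training = TRUE)
  yhat <- fw$yhat

  hard_edges <- function(b) {
    out <- array(0, dim = dim(b))
    for (n in seq_len(N))
      out[, , 1, n] <- canny_features(b[, , 1, n], canny_low, canny_high,
                                      canny_sigma)
    out
  }

  # --- discriminator updates (generator frozen) ---------------------------
  upd_disc <- function(D, opt, real, fake) {
    fr <- disc_fw(D, real, training = TRUE)
    br <- bce_logits(fr$y, 1)
    gr <- disc_bw(D, fr$cache, br$grad)
    ff <- disc_fw(D, fake, training = TRUE)
    bf <- bce_logits(ff$y, 0)
    gf <- disc_bw(D, ff$cache, bf$grad)
    up <- adam_step(D, grad_add(gr$g, gf$g), opt)
    list(D = up$net, opt = up$opt, loss = br$value + bf$value)
  }
  dp <- upd_disc(models$d_pixel, opts$d_pixel, y, yhat)
  models$d_pixel <- dp$D; opts$d_pixel <- dp$opt
  ey <- hard_edges(y); eyh <- hard_edges(yhat)
  df <- upd_disc(models$d_feature, opts$d_feature, ey, eyh)
  models$d_feature <- df$D; opts$d_feature <- df$opt

  # --- generator + fusion + backbone update -------------------------------
  # pixel-level adversarial gradient
  fp <- disc_fw(models$d_pixel, yhat, training = TRUE)
  bp <- bce_logits(fp$y, 1)
  g_yhat <- disc_bw(models$d_pixel, fp$cache, bp$grad)$gx
  # feature-level adversarial gradient through the soft surrogate
  if (edge_mode == "soft") {
    se <- soft_edges_fw(yhat)
    ffw <- disc_fw(models$d_feature, se$y, training = TRUE)
    bf2 <- bce_logits(ffw$y, 1)
    g_edge <- disc_bw(models$d_feature, ffw$cache, bf2$grad)$gx
    g_yhat <- g_yhat + soft_edges_bw(se$cache, g_edge)
  } else {
    ffw <- disc_fw(models$d_feature, eyh, training = TRUE)
    bf2 <- bce_logits(ffw$y, 1)
  }
  # synthesis L1
  lg <- l1_loss(yhat, y)
  g_yhat <- g_yhat + lambda1 * lg$grad

  gb <- generate_bw(models$gen, fw$gen_cache, g_yhat)
  fb <- fusion_network_bw(models$fusion, fw$fused$cache,
                          gb$gF1, gb$gF2, gb$gF3)
  # backbone reconstruction term (lambda2 * L_rec, both modalities)
  l_rec <- 0
  dgs <- list(bb1 = NULL, bb2 = NULL)
  for (mod in c(1, 2)) {
    bb <- models[[paste0("bb", mod)]]
    fs <- fw[[paste0("fs", mod)]]
    x <- fw[[paste0("x", mod)]]
    dbw_g <- NULL
    g_taps <- grad_add(fb[[paste0("g_fs", mod)]], gb[[paste0("g_fs", mod)]])
    if (lambda2 > 0) {
      dc <- decode(bb, fs, training = TRUE)
      lr_ <- l1_loss(dc$recon, x)
      l_rec <- l_rec + lr_$value
      dbw <- decode_bw(bb, dc$cache, lambda2 * lr_$grad)
      g_taps <- grad_add(g_taps, list(S1 = dbw$g_s1, S2 = dbw$g_s2,
                                      S3 = dbw$g_s3))
      dbw_g <- dbw$g
    }
    ebw <- encode_bw(bb, fs, g_taps$S1, g_taps$S2, g_taps$S3)
    dgs[[paste0("bb", mod)]] <- if (is.null(dbw_g)) ebw$g else c(ebw$g, dbw_g)
  }

  for (nm in c("gen", "fusion", "bb1", "bb2")) {
    g <- switch(nm, gen = gb$g, fusion = fb$g, bb1 = dgs$bb1, bb2 = dgs$bb2)
    up <- adam_step(models[[nm]], g, opts[[nm]])
    models[[nm]] <- up$net; opts[[nm]] <- up$opt
  }

  report <- structure(list(
    l_grec = lg$value, l_pixel_adv = bp$value, l_feature_adv = bf2$value,
    l_rec = l_rec, l_pixel_adv_d = dp$loss, l_feature_adv_d = df$loss,
    lambda1 = lambda1, lambda2 = lambda2,
    total = bp$value + bf2$value + lambda1 * lg$value + lambda2 * l_rec),
    class = "loss_report")
  if (!is.finite(report$total))
    stop("NaN/Inf loss at optimizer step ", opts$gen$t,
         " (grec=", lg$value, ", pix=", bp$value, ", feat=", bf2$value, ")")
  list(models = models, opts = opts, report = report)
}

#' Create the optimizer bundle for adversarial training
#' @param models a `synth_models`
#' @param lr learning rate (Adam, betas 0.5/0.999)
#' @return list of Adam states, one per sub-model
#' @export
synth_opts_make <- function(models, lr = 2e-4) {
  list(bb1 = adam_make(models$bb1, lr = lr),
       bb2 = adam_make(models$bb2, lr = lr),
       fusion = adam_make(models$fusion, lr = lr),
       gen = adam_make(models$gen, lr = lr),
       d_pixel = adam_make(models$d_pixel, lr = lr),
       d_feature = adam_make(models$d_feature, lr = lr))
}
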