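# ---------------------------------------------------------------------------
# Per-modality feature-extraction backbone: a symmetric U-Net auto-encoder
# with two skip connections.  Encoder convolutions use LeakyReLU, decoder
# convolutions ReLU, batch normalization after every convolution (the output
# convolution uses tanh and no normalization so reconstructions live on the
# [-1, 1] intensity scale).  The encoder exports "unique" feature maps at
# three tap levels: full resolution, half resolution, and the bottleneck --
# one stream per fusion block.
# ---------------------------------------------------------------------------

#' Backbone configuration
#' @param base_channels channel width of the first encoder level (doubles
#'   per pooling level)
#' @param lrelu_slope negative slope of the encoder LeakyReLU
#' @param out_act activation of the reconstruction layer (`"tanh"` for
#'   `\[-1, 1\]`-scaled data, `"linear"` otherwise)
#' @return a `backbone_config` list
#' @export
backbone_config <- function(base_channels = 16L, lrelu_slope = 0.2,
                            out_act = "tanh") {
  structure(list(base_channels = as.integer(base_channels),
                 depth = 2L, lrelu_slope = lrelu_slope, out_act = out_act),
            class = "backbone_config")
}

#' Build a backbone
#'
#' @param cfg a [backbone_config()]
#' @param in_ch input channel count (1 for a single slice)
#' @return a layer tree of class `backbone`
#' @export
build_backbone <- function(cfg = backbone_config(), in_ch = 1L) {
  b <- cfg$base_channels; s <- cfg$lrelu_slope
  structure(list(
    e1 = cblock_make(in_ch, b,      act = "lrelu", slope = s),
    e2 = cblock_make(b,     2L * b, act = "lrelu", slope = s),
    e3 = cblock_make(2L * b, 4L * b, act = "lrelu", slope = s),
    d1a = cblock_make(4L * b, 2L * b, act = "relu"),
    d1b = cblock_make(4L * b, 2L * b, act = "relu"),   # after skip concat
    d2a = cblock_make(2L * b, b,      act = "relu"),
    d2b = cblock_make(2L * b, b,      act = "relu"),   # after skip concat
    out = conv_make(b, 1L),
    cfg = cfg), class = "backbone")
}

#' Encode a batch of patches into a feature set
#'
#' @param bb a `backbone`
#' @param x 4D array (H, W, C, N); H and W must be divisible by 4
#' @param training use batch statistics in the normalization layers
#' @return a `feature_set`: list with tap maps `S1` (H, base), `S2`
#'   (H/2, 2*base), `S3` (H/4, 4*base) and a `cache` for backprop
#' @export
encode <- function(bb, x, training = FALSE) {
  x <- as_t4(x)
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("input spatial size must be divisible by 2^depth = 4")
  f1 <- cblock_fw(bb$e1, x, training);  s1 <- f1$y
  p1 <- maxpool2_fw(s1)
  f2 <- cblock_fw(bb$e2, p1$y, training); s2 <- f2$y
  p2 <- maxpool2_fw(s2)
  f3 <- cblock_fw(bb$e3, p2$y, training); s3 <- f3$y
  structure(list(S1 = s1, S2 = s2, S3 = s3,
                 cache = list(f1 = f1$cache, p1 = p1$cache,
                              f2 = f2$cache, p2 = p2$cache,
                              f3 = f3$cache)),
            class = "feature_set")
}

#' Decode a feature set into a reconstruction
#'
#' Skip connections consume the tap maps `S1` and `S2` from the paired
#' encoder, so the reconstruction has the input's spatial shape.
#'
#' @param bb the `backbone` that produced `fs`
#' @param fs a `feature_set` from [encode()]
#' @param training use batch statistics in the normalization layers
#' @return list with `recon` (4D array) and `cache`
#' @export
decode <- function(bb, fs, training = FALSE) {
  u1 <- upsample2_fw(fs$S3)
  a1 <- cblock_fw(bb$d1a, u1$y, training)
  c1 <- concat_ch(a1$y, fs$S2)
  b1 <- cblock_fw(bb$d1b, c1, training)
  u2 <- upsample2_fw(b1$y)
  a2 <- cblock_fw(bb$d2a, u2$y, training)
  c2 <- concat_ch(a2$y, fs$S1)
  b2 <- cblock_fw(bb$d2b, c2, training)
  oc <- conv_fw(bb$out, b2$y)
  oa <- act_fw(bb$cfg$out_act, oc$y)
  list(recon = oa$y, d1_out = b1$y,
       cache = list(a1 = a1$cache, b1 = b1$cache, a2 = a2$cache,
                    b2 = b2$cache, oc = oc$cache, oa = oa$cache,
                    w1 = dim(a1$y)[3], w2 = dim(a2$y)[3]))
}

# Backward through decode: returns gradients w.r.t. the tap maps plus the
# parameter-gradient tree for the decoder layers.  g_d1 is an optional
# extra gradient injected at the first decoder level's output (used by the
# slice-index branch).
decode_bw <- function(bb, dc, g_recon, g_d1 = NULL) {
  g <- act_bw(bb$cfg$out_act, dc$oa, g_recon)
  co <- conv_bw(bb$out, dc$oc, g)
  bb2 <- cblock_bw(bb$d2b, dc$b2, co$gx)
  sp2 <- split_ch(bb2$gx, c(dc$w2, dim(bb2$gx)[3] - dc$w2))
  ga2 <- cblock_bw(bb$d2a, dc$a2, sp2[[1]])
  g_s1 <- sp2[[2]]
  gu2 <- upsample2_bw(ga2$gx)
  if (!is.null(g_d1)) gu2 <- gu2 + g_d1
  bb1 <- cblock_bw(bb$d1b, dc$b1, gu2)
  sp1 <- split_ch(bb1$gx, c(dc$w1, dim(bb1$gx)[3] - dc$w1))
  ga1 <- cblock_bw(bb$d1a, dc$a1, sp1[[1]])
  g_s2 <- sp1[[2]]
  g_s3 <- upsample2_bw(ga1$gx)
  list(g_s1 = g_s1, g_s2 = g_s2, g_s3 = g_s3,
       g = list(d1a = ga1$g, d1b = bb1$g, d2a = ga2$g, d2b = bb2$g,
                out = co$g))
}

# Backward through encode given gradients on the three tap maps; returns
# gradient w.r.t. the input and the encoder parameter-gradient tree.
encode_bw <- function(bb, fs, g_s1 = NULL, g_s2 = NULL, g_s3 = NULL) {
  ec <- fs$cache
  zero_like <- function(x) array(0, dim = dim(x))
  if (is.null(g_s3)) g_s3 <- zero_like(fs$S3)
  if (is.null(g_s2)) g_s2 <- zero_like(fs$S2)
  if (is.null(g_s1)) g_s1 <- zero_like(fs$S1)
  g3 <- cblock_bw(bb$e3, ec$f3, g_s3)
  gp2 <- maxpool2_bw(ec$p2, g3$gx)
  g2 <- cblock_bw(bb$e2, ec$f2, gp2 + g_s2)
  gp1 <- maxpool2_bw(ec$p1, g2$gx)
  g1 <- cblock_bw(bb$e1, ec$f1, gp1 + g_s1)
  list(gx = g1$gx, g = list(e1 = g1$g, e2 = g2$g, e3 = g3$g))
}

#' Pixel-wise L1 reconstruction loss
#'
#' Mean absolute difference between an image and its reconstruction.
#'
#' @param x,xhat arrays of identical shape
#' @return scalar mean absolute error
#' @export
reconstruction_loss <- function(x, xhat) {
  if (!identical(dim(as_t4(x)), dim(as_t4(xhat))))
    stop("shape mismatch between image and reconstruction")
  mean(abs(x - xhat))
}

# one full autoencoder pass + L1 loss backward; returns loss, recon and the
# complete parameter-gradient tree for Adam.  Extra gradients on the tap
# maps (from downstream fusion) can be injected.
backbone_step_grads <- function(bb, x, target = NULL, training = TRUE,
                                loss_scale = 1) {
  x <- as_t4(x)
  if (is.null(target)) target <- x
  fs <- encode(bb, x, training)
  dc <- decode(bb, fs, training)
  ll <- l1_loss(dc$recon, as_t4(target))
  dbw <- decode_bw(bb, dc$cache, ll$grad * loss_scale)
  ebw <- encode_bw(bb, fs, dbw$g_s1, dbw$g_s2, dbw$g_s3)
  list(loss = ll$value, recon = dc$recon,
       g = c(ebw$g, dbw$g))
}

# introspection helper used by architecture-contract tests
backbone_activations <- function(bb) {
  c(e1 = bb$e1$act, e2 = bb$e2$act, e3 = bb$e3$act,
    d1a = bb$d1a$act, d1b = bb$d1b$act, d2a = bb$d2a$act, d2b = bb$d2b$act,
    out = bb$cfg$out_act)
}

backbone_has_bn <- function(bb) {
  vapply(bb[c("e1", "e2", "e3", "d1a", "d1b", "d2a", "d2b")],
         function(l) !is.null(l$bn), logical(1))
}
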