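# ---------------------------------------------------------------------------
# Multimodal attention feature fusion block (MAFFB) and the 3-block fusion
# network.  A MAFFB fuses two shape-identical unique feature maps by
# element-wise sum, product and maximum, stacks the three results, weighs
# channels with an attention map computed from pooled channel descriptors
# through a shared two-layer MLP, convolves, concatenates the previous
# block's common features, and convolves again.  Everything downstream of
# the three symmetric fusion operations is order-independent, so the whole
# network is invariant to swapping the two modality streams.
# ---------------------------------------------------------------------------

#' Element-wise fusion operations
#'
#' @param S1,S2 shape-identical feature maps (arrays)
#' @return list with `F_plus` (sum), `F_times` (product), `F_max` (maximum)
#' @export
fuse_ops <- function(S1, S2) {
  if (!identical(dim(S1), dim(S2))) stop("fuse_ops: shape mismatch")
  list(F_plus = S1 + S2, F_times = S1 * S2, F_max = pmax(S1, S2))
}

#' Build a channel-attention module
#'
#' Global average and max pooling per channel feed a shared two-layer
#' (1x1-conv equivalent) MLP with a ReLU bottleneck; the two paths are
#' summed and squashed by a sigmoid into a per-channel gate in (0, 1).
#'
#' @param channels channel count of the map the attention gates
#' @param ratio bottleneck reduction ratio of the shared MLP
#' @return an `attention` layer list
#' @export
attention_make <- function(channels, ratio = 8L) {
  hidden <- max(1L, channels %/% ratio)
  list(fc1 = fc_make(channels, hidden), fc2 = fc_make(hidden, channels),
       channels = channels)
}

attention_fw <- function(at, x) {
  ga <- gap_fw(x); gm <- gmp_fw(x)
  a1 <- fc_fw(at$fc1, ga$y); a1a <- act_fw("relu", a1$y)
  a2 <- fc_fw(at$fc2, a1a$y)
  m1 <- fc_fw(at$fc1, gm$y); m1a <- act_fw("relu", m1$y)
  m2 <- fc_fw(at$fc2, m1a$y)
  sg <- act_fw("sigmoid", a2$y + m2$y)
  list(M = sg$y,    # (C, N) gate in (0, 1)
       cache = list(ga = ga$cache, gm = gm$cache, a1 = a1$cache,
                    a1a = a1a$cache, a2 = a2$cache, m1 = m1$cache,
                    m1a = m1a$cache, m2 = m2$cache, sg = sg$cache))
}

attention_bw <- function(at, cache, gM) {
  gz <- act_bw("sigmoid", cache$sg, gM)
  # average-pool path
  ba2 <- fc_bw(at$fc2, cache$a2, gz)
  ga1 <- act_bw("relu", cache$a1a, ba2$gx)
  ba1 <- fc_bw(at$fc1, cache$a1, ga1)
  # max-pool path (shared parameters: gradients accumulate)
  bm2 <- fc_bw(at$fc2, cache$m2, gz)
  gm1 <- act_bw("relu", cache$m1a, bm2$gx)
  bm1 <- fc_bw(at$fc1, cache$m1, gm1)
  gx <- gap_bw(cache$ga, ba1$gx) + gmp_bw(cache$gm, bm1$gx)
  list(gx = gx,
       g = list(fc1 = grad_add(ba1$g, bm1$g), fc2 = grad_add(ba2$g, bm2$g)))
}

#' Channel attention map of a feature map
#'
#' Convenience forward pass of a standalone attention module.
#'
#' @param at an `attention` module from [attention_make()]
#' @param x 4D array (H, W, C, N)
#' @return matrix (C, N) of gates in (0, 1)
#' @export
channel_attention <- function(at, x) attention_fw(at, as_t4(x))$M

# scale each channel of x by the per-channel gate M (C, N)
scale_by_channel <- function(x, M) {
  d <- dim(x)
  sweep(x, c(3, 4), M, `*`)
}

#' Build one MAFFB
#'
#' @param in_ch channel count C of each unique input map
#' @param out_ch channel count of the common output features
#' @param prev_ch channel count of the previous block's (aligned) common
#'   features, or 0 for the first block
#' @param ratio attention MLP bottleneck ratio
#' @return a `maffb` layer list
#' @export
maffb_make <- function(in_ch, out_ch, prev_ch = 0L, ratio = 8L) {
  structure(list(
    att = attention_make(3L * in_ch, ratio),
    conv1 = cblock_make(3L * in_ch, out_ch, act = "relu"),
    conv2 = cblock_make(out_ch + prev_ch, out_ch, act = "relu"),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
    prev_ch = as.integer(prev_ch)), class = "maffb")
}

#' Forward pass of one MAFFB
#'
#' @param blk a `maffb`
#' @param S1,S2 shape-identical unique feature maps (4D)
#' @param F_prev previous common features (4D, `prev_ch` channels, same
#'   spatial size) or `NULL` for the first block
#' @param training batch-statistics mode for the normalization layers
#' @return list with the common features `F` and a backprop `cache`
#' @export
maffb_forward <- function(blk, S1, S2, F_prev = NULL, training = FALSE) {
  S1 <- as_t4(S1); S2 <- as_t4(S2)
  if (!identical(dim(S1), dim(S2))) stop("maffb: S1/S2 shape mismatch")
  if (is.null(F_prev) != (blk$prev_ch == 0L))
    stop("maffb: F_prev presence must match the block's prev_ch")
  fo <- fuse_ops(S1, S2)
  Fc <- concat_ch(fo$F_plus, fo$F_times, fo$F_max)
  af <- attention_fw(blk$att, Fc)
  Fa <- scale_by_channel(Fc, af$M)
  c1 <- cblock_fw(blk$conv1, Fa, training)
  h <- if (is.null(F_prev)) c1$y else {
    F_prev <- as_t4(F_prev)
    if (!identical(dim(F_prev)[c(1, 2, 4)], dim(S1)[c(1, 2, 4)]))
      stop("maffb: F_prev spatially incompatible with the unique inputs")
    concat_ch(c1$y, F_prev)
  }
  c2 <- cblock_fw(blk$conv2, h, training)
  list(F = c2$y,
       cache = list(S1 = S1, S2 = S2, Fc = Fc, M = af$M, att = af$cache,
                    c1 = c1$cache, c2 = c2$cache, has_prev = !is.null(F_prev),
                    w1 = dim(c1$y)[3]))
}

maffb_bw <- function(blk, cache, gF) {
  b2 <- cblock_bw(blk$conv2, cache$c2, gF)
  if (cache$has_prev) {
    sp <- split_ch(b2$gx, c(cache$w1, blk$prev_ch))
    g_c1 <- sp[[1]]; g_prev <- sp[[2]]
  } else {
    g_c1 <- b2$gx; g_prev <- NULL
  }
  b1 <- cblock_bw(blk$conv1, cache$c1, g_c1)
  gFa <- b1$gx
  # d/dFc of (M * Fc): through the product and through the attention map
  gFc <- scale_by_channel(gFa, cache$M)
  gM <- apply(gFa * cache$Fc, c(3, 4), sum)
  ab <- attention_bw(blk$att, cache$att, gM)
  gFc <- gFc + ab$gx
  C <- blk$in_ch
  sp3 <- split_ch(gFc, c(C, C, C))
  ge <- sp3[[1]]; gp <- sp3[[2]]; gm <- sp3[[3]]
  m1 <- cache$S1 >= cache$S2   # ties route to S1; values unaffected
  gS1 <- ge + gp * cache$S2 + gm * m1
  gS2 <- ge + gp * cache$S1 + gm * !m1
  list(gS1 = gS1, gS2 = gS2, g_prev = g_prev,
       g = list(att = ab$g, conv1 = b1$g, conv2 = b2$g))
}

#' Build the 3-block fusion network
#'
#' Block k fuses the tap-level-k unique features of both modalities with
#' the (average-pooled) output of block k-1.
#'
#' @param base_channels backbone base width (tap widths are base, 2*base,
#'   4*base)
#' @param ratio attention bottleneck ratio
#' @return a `fusion_net` layer list
#' @export
build_fusion_net <- function(base_channels = 16L, ratio = 8L) {
  b <- as.integer(base_channels)
  structure(list(
    maffb1 = maffb_make(b,      b,      0L,     ratio),
    maffb2 = maffb_make(2L * b, 2L * b, b,      ratio),
    maffb3 = maffb_make(4L * b, 4L * b, 2L * b, ratio),
    base = b), class = "fusion_net")
}

#' Run the fusion network on two modality feature sets
#'
#' @param fn a `fusion_net`
#' @param fs1,fs2 `feature_set`s of the two modalities (from [encode()])
#' @param training batch-statistics mode
#' @return list with common features `F1`, `F2`, `F3` and a `cache`
#' @export
fusion_network <- function(fn, fs1, fs2, training = FALSE) {
  for (k in c("S1", "S2", "S3"))
    if (is.null(fs1[[k]]) || is.null(fs2[[k]]))
      stop("fusion_network: missing tap level ", k)
  m1 <- maffb_forward(fn$maffb1, fs1$S1, fs2$S1, NULL, training)
  p1 <- avgpool2_fw(m1$F)
  m2 <- maffb_forward(fn$maffb2, fs1$S2, fs2$S2, p1$y, training)
  p2 <- avgpool2_fw(m2$F)
  m3 <- maffb_forward(fn$maffb3, fs1$S3, fs2$S3, p2$y, training)
  list(F1 = m1$F, F2 = m2$F, F3 = m3$F,
       cache = list(m1 = m1$cache, m2 = m2$cache, m3 = m3$cache,
                    p1 = p1$cache, p2 = p2$cache))
}

# backward: given gradients on F1..F3, return per-modality tap gradients and
# the parameter-gradient tree
fusion_network_bw <- function(fn, cache, gF1 = NULL, gF2 = NULL, gF3 = NULL) {
  zl <- function(c_) array(0, dim = dim(c_))
  b3 <- maffb_bw(fn$maffb3, cache$m3,
                 if (is.null(gF3)) zl(cache$m3$S1) * 0 else gF3)
  gp2 <- avgpool2_bw(cache$p2, b3$g_prev)
  g2 <- if (is.null(gF2)) gp2 else gF2 + gp2
  b2 <- maffb_bw(fn$maffb2, cache$m2, g2)
  gp1 <- avgpool2_bw(cache$p1, b2$g_prev)
  g1 <- if (is.null(gF1)) gp1 else gF1 + gp1
  b1 <- maffb_bw(fn$maffb1, cache$m1, g1)
  list(g_fs1 = list(S1 = b1$gS1, S2 = b2$gS1, S3 = b3$gS1),
       g_fs2 = list(S1 = b1$gS2, S2 = b2$gS2, S3 = b3$gS2),
       g = list(maffb1 = b1$g, maffb2 = b2$g, maffb3 = b3$g))
}
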