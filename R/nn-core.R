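#' @useDynLib fusionsynth, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif prcomp sd
NULL

# ---------------------------------------------------------------------------
# Tensor helpers.  Every activation tensor is a 4D array (H, W, C, N);
# convolution weights are (k, k, Cin, Cout).  The engine is deliberately
# small: plain forward functions returning a cache, and matching backward
# functions returning input gradients plus a parameter-gradient tree whose
# shape mirrors the layer tree (leaves named W, b, gamma, beta).
# ---------------------------------------------------------------------------

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a bare vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2D/3D/4D array")
  x
}

t4_zeros <- function(H, W, C, N) array(0, dim = c(H, W, C, N))

# He-style initialisation for conv weights
init_conv_w <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

# --- convolution -----------------------------------------------------------

conv_make <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(W = init_conv_w(k, in_ch, out_ch), b = numeric(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}

conv_fw <- function(ly, x) {
  y <- cpp_conv2d_fw(x, ly$W, ly$b, ly$stride, ly$pad)
  list(y = y, cache = x)
}

conv_bw <- function(ly, cache, gy) {
  r <- cpp_conv2d_bw(cache, ly$W, gy, ly$stride, ly$pad)
  list(gx = r$gx, g = list(W = r$gw, b = r$gb))
}

# --- batch normalization ---------------------------------------------------
# Buffers (running mean/var) live in an environment so forward passes in
# training mode can update them without threading state through callers.

bn_make <- function(ch, momentum = 0.1) {
  list(gamma = rep(1, ch), beta = numeric(ch),
       stats = local({
         e <- new.env(parent = emptyenv())
         e$rm <- numeric(ch); e$rv <- rep(1, ch); e
       }),
       momentum = momentum, eps = 1e-5)
}

bn_fw <- function(ly, x, training) {
  d <- dim(x); C <- d[3]
  m <- prod(d[c(1, 2, 4)])
  xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colSums(xc * xc) / m
    ly$stats$rm <- (1 - ly$momentum) * ly$stats$rm + ly$momentum * mu
    ly$stats$rv <- (1 - ly$momentum) * ly$stats$rv + ly$momentum * v
  } else {
    mu <- ly$stats$rm; v <- ly$stats$rv
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(v + ly$eps)
  xn <- sweep(xc, 2, istd, `*`)
  y <- sweep(xn, 2, ly$gamma, `*`)
  y <- sweep(y, 2, ly$beta, `+`)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, cache = list(xn = xn, istd = istd, d = d, m = m,
                           training = training))
}

bn_bw <- function(ly, cache, gy) {
  d <- cache$d; C <- d[3]; m <- cache$m
  gym <- aperm(gy, c(1, 2, 4, 3)); dim(gym) <- c(m, C)
  xn <- cache$xn
  ggamma <- colSums(gym * xn)
  gbeta <- colSums(gym)
  gxn <- sweep(gym, 2, ly$gamma, `*`)
  if (cache$training) {
    # full batch-norm backward (batch statistics participate)
    t1 <- sweep(gxn, 2, colMeans(gxn))
    t2 <- sweep(xn, 2, colMeans(gxn * xn) , `*`)
    gxm <- sweep(t1 - t2, 2, cache$istd, `*`)
  } else {
    gxm <- sweep(gxn, 2, cache$istd, `*`)
  }
  dim(gxm) <- c(d[1], d[2], d[4], d[3])
  gx <- aperm(gxm, c(1, 2, 4, 3))
  list(gx = gx, g = list(gamma = ggamma, beta = gbeta))
}

# --- activations -----------------------------------------------------------

act_fw <- function(kind, x, slope = 0.2) {
  switch(kind,
    linear  = list(y = x, cache = NULL),
    relu    = list(y = pmax(x, 0), cache = x >= 0),
    lrelu   = list(y = ifelse(x >= 0, x, slope * x), cache = x >= 0),
    tanh    = { y <- tanh(x); list(y = y, cache = y) },
    sigmoid = { y <- 1 / (1 + exp(-x)); list(y = y, cache = y) },
    stop("unknown activation: ", kind))
}

act_bw <- function(kind, cache, gy, slope = 0.2) {
  switch(kind,
    linear  = gy,
    relu    = gy * cache,
    lrelu   = gy * ifelse(cache, 1, slope),
    tanh    = gy * (1 - cache^2),
    sigmoid = gy * cache * (1 - cache),
    stop("unknown activation: ", kind))
}

# --- conv + BN + activation block (the paper's universal building unit) ----

cblock_make <- function(in_ch, out_ch, k = 3L, stride = 1L,
                        act = "relu", bn = TRUE, slope = 0.2) {
  list(conv = conv_make(in_ch, out_ch, k, stride),
       bn = if (bn) bn_make(out_ch) else NULL,
       act = act, slope = slope)
}

cblock_fw <- function(blk, x, training) {
  cf <- conv_fw(blk$conv, x)
  h <- cf$y; bc <- NULL
  if (!is.null(blk$bn)) {
    bf <- bn_fw(blk$bn, h, training)
    h <- bf$y; bc <- bf$cache
  }
  af <- act_fw(blk$act, h, blk$slope)
  list(y = af$y, cache = list(cf = cf$cache, bc = bc, ac = af$cache))
}

cblock_bw <- function(blk, cache, gy) {
  g <- act_bw(blk$act, cache$ac, gy, blk$slope)
  gbn <- NULL
  if (!is.null(blk$bn)) {
    bb <- bn_bw(blk$bn, cache$bc, g)
    g <- bb$gx; gbn <- bb$g
  }
  cb <- conv_bw(blk$conv, cache$cf, g)
  list(gx = cb$gx, g = list(conv = cb$g, bn = gbn))
}

# --- fully connected -------------------------------------------------------

fc_make <- function(in_dim, out_dim) {
  list(W = matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                  out_dim, in_dim),
       b = numeric(out_dim))
}

fc_fw <- function(ly, x) {           # x: (in_dim, N)
  list(y = ly$W %*% x + ly$b, cache = x)
}

fc_bw <- function(ly, cache, gy) {
  list(gx = crossprod(ly$W, gy),
       g = list(W = gy %*% t(cache), b = rowSums(gy)))
}

# --- pooling / resampling wrappers ----------------------------------------

maxpool2_fw <- function(x) {
  r <- cpp_maxpool2_fw(x)
  list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}
maxpool2_bw <- function(cache, gy) cpp_maxpool2_bw(cache$idx, gy, cache$H, cache$W)

avgpool2_fw <- function(x) list(y = cpp_avgpool2_fw(x),
                                cache = c(dim(x)[1], dim(x)[2]))
avgpool2_bw <- function(cache, gy) cpp_avgpool2_bw(gy, cache[1], cache[2])

upsample2_fw <- function(x) list(y = cpp_upsample2_fw(x), cache = NULL)
upsample2_bw <- function(gy) cpp_upsample2_bw(gy)

# global average / max pooling over (H, W): return (C, N) matrices
gap_fw <- function(x) {
  d <- dim(x); m <- matrix(x, d[1] * d[2], d[3] * d[4])
  list(y = matrix(colMeans(m), d[3], d[4]), cache = d)
}
gap_bw <- function(cache, gy) {      # gy: (C, N)
  d <- cache
  g <- matrix(rep(as.vector(gy) / (d[1] * d[2]), each = d[1] * d[2]),
              d[1] * d[2], d[3] * d[4])
  array(g, dim = d)
}

gmp_fw <- function(x) {
  d <- dim(x); m <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(m), ties.method = "first")
  y <- m[cbind(idx, seq_along(idx))]
  list(y = matrix(y, d[3], d[4]), cache = list(idx = idx, d = d))
}
gmp_bw <- function(cache, gy) {
  d <- cache$d
  g <- matrix(0, d[1] * d[2], d[3] * d[4])
  g[cbind(cache$idx, seq_along(cache$idx))] <- as.vector(gy)
  array(g, dim = d)
}

# channel concatenation and its split
concat_ch <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , (at + 1L):(at + cc), ] <- x
    at <- at + cc
  }
  out
}

split_ch <- function(g, widths) {
  at <- 0L
  lapply(widths, function(cc) {
    sl <- g[, , (at + 1L):(at + cc), , drop = FALSE]
    at <<- at + cc
    sl
  })
}

# ---------------------------------------------------------------------------
# Parameter trees: extract/assign the learnable leaves of a layer tree and
# run Adam over the flattened collection.
# ---------------------------------------------------------------------------

PARAM_NAMES <- c("W", "b", "gamma", "beta")

flatten_params <- function(x, path = "") {
  out <- list()
  if (!is.list(x)) return(out)
  nms <- names(x)
  for (i in seq_along(x)) {
    nm <- if (is.null(nms) || nms[i] == "") as.character(i) else nms[i]
    p <- if (path == "") nm else paste0(path, "/", nm)
    el <- x[[i]]
    if (is.numeric(el) && nm %in% PARAM_NAMES) out[[p]] <- el
    else if (is.list(el)) out <- c(out, flatten_params(el, p))
  }
  out
}

assign_param <- function(tree, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  expr <- tree
  # recursive assignment
  rec <- function(node, parts) {
    key <- parts[1]
    if (length(parts) == 1L) { node[[key]] <- value; return(node) }
    node[[key]] <- rec(node[[key]], parts[-1])
    node
  }
  rec(tree, parts)
}

set_flat_params <- function(tree, flat) {
  for (p in names(flat)) tree <- assign_param(tree, p, flat[[p]])
  tree
}

#' Create an Adam optimizer state for a network
#' @param net a layer tree
#' @param lr learning rate
#' @param beta1,beta2 Adam moment decay rates
#' @keywords internal
adam_make <- function(net, lr = 2e-4, beta1 = 0.5, beta2 = 0.999) {
  fp <- flatten_params(net)
  list(m = lapply(fp, function(x) x * 0), v = lapply(fp, function(x) x * 0),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = 1e-8)
}

adam_step <- function(net, grads, opt) {
  fp <- flatten_params(net)
  fg <- flatten_params(grads)
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr <- sqrt(1 - b2^opt$t) / (1 - b1^opt$t)
  for (p in names(fp)) {
    g <- fg[[p]]
    if (is.null(g)) next
    opt$m[[p]] <- b1 * opt$m[[p]] + (1 - b1) * g
    opt$v[[p]] <- b2 * opt$v[[p]] + (1 - b2) * g * g
    fp[[p]] <- fp[[p]] - opt$lr * corr * opt$m[[p]] / (sqrt(opt$v[[p]]) + opt$eps)
  }
  list(net = set_flat_params(net, fp), opt = opt)
}

# add two gradient trees of identical shape (either may have NULL leaves)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  keys <- union(names(a), names(b))
  for (k in keys) out[[k]] <- grad_add(a[[k]], b[[k]])
  out
}

# ---------------------------------------------------------------------------
# Losses
# ---------------------------------------------------------------------------

# mean absolute error with gradient w.r.t. the first argument
l1_loss <- function(a, b) {
  d <- a - b
  n <- length(d)
  list(value = mean(abs(d)), grad = sign(d) / n)
}

l2_loss <- function(a, b) {
  d <- a - b
  n <- length(d)
  list(value = mean(d * d), grad = 2 * d / n)
}

# binary cross-entropy on logits, mean over all elements
bce_logits <- function(z, target) {
  p <- 1 / (1 + exp(-z))
  eps <- 1e-12
  v <- -mean(target * log(p + eps) + (1 - target) * log(1 - p + eps))
  list(value = v, grad = (p - target) / length(z), prob = p)
}

# serialize a network (convert BN stat environments to plain lists)
net_freeze <- function(x) {
  if (is.environment(x)) return(list(rm = x$rm, rv = x$rv, .bnstats = TRUE))
  if (is.list(x)) return(lapply(x, net_freeze))
  x
}

net_thaw <- function(x) {
  if (is.list(x) && isTRUE(x$.bnstats)) {
    e <- new.env(parent = emptyenv()); e$rm <- x$rm; e$rv <- x$rv
    return(e)
  }
  if (is.list(x)) return(lapply(x, net_thaw))
  x
}

#' Save a model checkpoint
#'
#' Writes a single-file checkpoint containing the full layer tree (parameters
#' and batch-norm running statistics) together with the configuration that
#' built it, so a checkpoint is self-describing.
#'
#' @param model a layer tree (any network built by this package)
#' @param config the configuration list used to build the model
#' @param path output file path
#' @export
save_checkpoint <- function(model, config, path) {
  saveRDS(list(format = "fusionsynth-checkpoint-v1",
               config = config, model = net_freeze(model)), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path checkpoint file
#' @return list with elements `model` and `config`
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "fusionsynth-checkpoint-v1"))
    stop("not a fusionsynth checkpoint: ", path)
  list(model = net_thaw(x$model), config = x$config)
}
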