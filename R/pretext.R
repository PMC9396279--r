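# ---------------------------------------------------------------------------
# Self-supervised pre-training of a backbone.
#
# Two pretext tasks: masked-patch inpainting (2D context) and slice-index
# regression on 3-slice stacks (3D context).  The tasks share the
# reconstruction loss; the index task adds a squared-error term on the
# normalized slice position.  By default the two are trained jointly with
# one optimizer; after pre-training the triplet front layer is dropped and
# the backbone transfers to the synthesis stage on single slices.
# ---------------------------------------------------------------------------

#' Mask a patch for inpainting
#'
#' Masked pixels are replaced by the fill value (0, the midpoint of the
#' \[-1, 1\] intensity scale); unmasked pixels are untouched.  For multi-
#' channel stacks the same in-plane mask is applied to every channel.
#'
#' @param x a patch: matrix or (rows, cols, channels) array
#' @param m a `mask_spec` from [sample_masks()]
#' @param fill fill value for masked pixels
#' @return the masked patch, same shape as `x`
#' @export
mask_patch <- function(x, m, fill = 0) {
  d <- dim(x)
  if (!identical(dim(m$mask), d[1:2]))
    stop("mask shape ", paste(dim(m$mask), collapse = "x"),
         " does not match patch ", paste(d[1:2], collapse = "x"))
  keep <- m$mask == 0
  if (length(d) == 2L) return(ifelse(keep, x, fill))
  out <- x
  for (j in seq_len(d[3])) out[, , j] <- ifelse(keep, x[, , j], fill)
  out
}

#' Build the slice-index prediction branch
#'
#' Four conv+BN+ReLU stages, global average pooling, and one fully
#' connected layer to a scalar.  Attaches to the first decoder level.
#'
#' @param in_ch channel count of the decoder level the branch reads
#' @return an `index_branch` layer list
#' @export
index_branch_make <- function(in_ch) {
  structure(list(
    c1 = cblock_make(in_ch, in_ch, act = "relu"),
    c2 = cblock_make(in_ch, in_ch, act = "relu"),
    c3 = cblock_make(in_ch, in_ch, act = "relu"),
    c4 = cblock_make(in_ch, in_ch, act = "relu"),
    fc = fc_make(in_ch, 1L)), class = "index_branch")
}

index_branch_fw <- function(br, x, training) {
  f1 <- cblock_fw(br$c1, x, training)
  f2 <- cblock_fw(br$c2, f1$y, training)
  f3 <- cblock_fw(br$c3, f2$y, training)
  f4 <- cblock_fw(br$c4, f3$y, training)
  gp <- gap_fw(f4$y)
  fo <- fc_fw(br$fc, gp$y)
  list(yhat = as.vector(fo$y),
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                    f4 = f4$cache, gp = gp$cache, fo = fo$cache))
}

index_branch_bw <- function(br, cache, g_yhat) {
  bf <- fc_bw(br$fc, cache$fo, matrix(g_yhat, nrow = 1))
  gg <- gap_bw(cache$gp, bf$gx)
  b4 <- cblock_bw(br$c4, cache$f4, gg)
  b3 <- cblock_bw(br$c3, cache$f3, b4$gx)
  b2 <- cblock_bw(br$c2, cache$f2, b3$gx)
  b1 <- cblock_bw(br$c1, cache$f1, b2$gx)
  list(gx = b1$gx,
       g = list(c1 = b1$g, c2 = b2$g, c3 = b3$g, c4 = b4$g, fc = bf$g))
}

#' Build the 3-slice compression layer
#'
#' A single convolution that compresses a 3-slice stack into one channel
#' without changing the spatial size (linear activation, so setting its
#' weights to 1/3 at the kernel centre averages the slices exactly).
#'
#' @return a conv layer
#' @export
compress_make <- function() conv_make(3L, 1L)

#' Compress a 3-slice stack to a single-channel map
#' @param cl the compression layer from [compress_make()]
#' @param stack (rows, cols, 3) array or (rows, cols, 3, N) batch
#' @return single-channel batch (rows, cols, 1, N)
#' @export
compress_triplet <- function(cl, stack) {
  x <- as_t4(stack)
  if (dim(x)[3] != 3L) stop("compress_triplet expects exactly 3 slices")
  conv_fw(cl, x)$y
}

# stack a list of 2D patches (or (H,W,C) arrays) into a 4D batch
stack_batch <- function(patches) {
  d <- dim(patches[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, dim = c(d, length(patches)))
  for (i in seq_along(patches)) out[, , , i] <- patches[[i]]
  out
}

#' Pre-train a backbone by masked-patch inpainting
#'
#' Each step draws a seeded mini-batch, masks it with freshly sampled
#' rectangles, and minimizes the L1 reconstruction loss of the original
#' patch with Adam.
#'
#' @param bb a `backbone`
#' @param patches list of 2D patches on the \[-1, 1\] scale
#' @param steps number of optimizer steps (0 leaves the network untouched)
#' @param seed integer seed controlling batches and masks
#' @param batch_size mini-batch size
#' @param lr Adam learning rate
#' @param n_masks,mask_frac number of square masks per patch and the side
#'   of each mask as a fraction of the patch side (default four masks of a
#'   quarter side each, i.e. 25% masked area on the default geometry)
#' @return list with the trained `backbone` and the per-step loss `trace`
#' @export
pretrain_inpainting <- function(bb, patches, steps, seed = 1L,
                                batch_size = 8L, lr = 2e-4,
                                n_masks = 4L, mask_frac = 0.25) {
  if (length(patches) == 0L) stop("empty dataset")
  if (steps == 0L) return(list(backbone = bb, trace = numeric(0)))
  set.seed(seed)
  opt <- adam_make(bb, lr = lr)
  trace <- numeric(steps)
  ps <- dim(patches[[1]])[1:2]
  msz <- pmax(2L, as.integer(round(ps * mask_frac)))
  for (s in seq_len(steps)) {
    ix <- sample.int(length(patches), min(batch_size, length(patches)))
    orig <- stack_batch(patches[ix])
    msk <- orig
    for (j in seq_along(ix)) {
      m <- sample_masks(ps, n_masks, msz,
                        seed = sample.int(.Machine$integer.max, 1L))
      msk[, , 1, j] <- mask_patch(orig[, , 1, j], m)
    }
    st <- backbone_step_grads(bb, msk, target = orig, training = TRUE)
    trace[s] <- st$loss
    up <- adam_step(bb, st$g, opt)
    bb <- up$net; opt <- up$opt
  }
  # recalibrate batch-norm running statistics under the final parameters
  # (forward-only passes; parameters untouched) so inference-mode
  # normalization matches what training converged to
  for (r in 1:30) {
    ix <- sample.int(length(patches), min(batch_size, length(patches)))
    invisible(decode(bb, encode(bb, stack_batch(patches[ix]), TRUE), TRUE))
  }
  list(backbone = bb, trace = trace)
}

#' Masked-region L1 error of a trained inpainter vs. a mean-fill baseline
#'
#' The baseline fills each masked region with the mean of the patch's
#' unmasked pixels.  Used to verify that inpainting pre-training learned
#' contextual structure.
#'
#' @param bb a (pre-trained) `backbone`
#' @param patches evaluation patches
#' @param seed seed for the evaluation masks
#' @param n_masks,mask_frac mask geometry as in [pretrain_inpainting()]
#' @return list with `model_l1` and `baseline_l1` over masked pixels
#' @export
inpainting_eval <- function(bb, patches, seed = 99L, n_masks = 4L,
                            mask_frac = 0.25) {
  ps <- dim(patches[[1]])[1:2]
  msz <- pmax(2L, as.integer(round(ps * mask_frac)))
  set.seed(seed)
  err_m <- err_b <- 0; npx <- 0
  for (p in patches) {
    m <- sample_masks(ps, n_masks, msz,
                      seed = sample.int(.Machine$integer.max, 1L))
    xm <- mask_patch(p, m)
    fs <- encode(bb, array(xm, dim = c(ps, 1, 1)), training = FALSE)
    rec <- decode(bb, fs, training = FALSE)$recon[, , 1, 1]
    fill <- mean(p[m$mask == 0])
    sel <- m$mask == 1
    err_m <- err_m + sum(abs(rec[sel] - p[sel]))
    err_b <- err_b + sum(abs(fill - p[sel]))
    npx <- npx + sum(sel)
  }
  list(model_l1 = err_m / npx, baseline_l1 = err_b / npx)
}

#' Build the slice-index pre-training model
#'
#' Front compression layer + backbone + index branch on the first decoder
#' level.
#'
#' @param bb a `backbone`
#' @return an `index_model` list
#' @export
index_model_make <- function(bb) {
  structure(list(compress = compress_make(), backbone = bb,
                 branch = index_branch_make(2L * bb$cfg$base_channels)),
            class = "index_model")
}

# forward + loss + full gradient tree of the index model on one batch
index_step <- function(model, stacks, mids, ys, index_weight = 1,
                       training = TRUE) {
  cf <- conv_fw(model$compress, stacks)
  fs <- encode(model$backbone, cf$y, training)
  dc <- decode(model$backbone, fs, training)
  br <- index_branch_fw(model$branch, dc$d1_out, training)
  lr_ <- l1_loss(dc$recon, mids)
  li <- list(value = mean((ys - br$yhat)^2),
             grad = 2 * (br$yhat - ys) / length(ys))
  bbw <- index_branch_bw(model$branch, br$cache, index_weight * li$grad)
  dbw <- decode_bw(model$backbone, dc$cache, lr_$grad, g_d1 = bbw$gx)
  ebw <- encode_bw(model$backbone, fs, dbw$g_s1, dbw$g_s2, dbw$g_s3)
  ccb <- conv_bw(model$compress, cf$cache, ebw$gx)
  list(loss_rec = lr_$value, loss_idx = li$value, yhat = br$yhat,
       g = list(compress = ccb$g, backbone = c(ebw$g, dbw$g),
                branch = bbw$g))
}

#' Pre-train by slice-index regression
#'
#' Joint loss: L1 reconstruction of the middle slice plus `index_weight`
#' times the squared error of the predicted normalized slice index (the
#' true index divided by depth - 1, so positions live in \[0, 1\]).  Setting
#' `index_weight = 0` reduces the objective to plain reconstruction.
#'
#' @param model an `index_model` from [index_model_make()]
#' @param triplets list of `patch_record`s from [slice_triplets()] (pixels
#'   on the \[-1, 1\] scale)
#' @param depth volume depth used to normalize indices
#' @param steps optimizer steps
#' @param seed integer seed
#' @param batch_size,lr optimizer settings
#' @param index_weight weight of the squared-error index term
#' @param mask_triplets if `TRUE` (joint pretext mode) triplets are masked
#'   as in inpainting so one optimizer serves both pretext tasks
#' @return list with the trained `index_model` and loss traces
#' @export
pretrain_index <- function(model, triplets, depth, steps, seed = 1L,
                           batch_size = 8L, lr = 2e-4, index_weight = 1,
                           mask_triplets = FALSE) {
  if (depth < 3L) stop("slice-index pre-training needs depth >= 3")
  if (length(triplets) == 0L) stop("empty dataset")
  if (steps == 0L)
    return(list(model = model, trace_rec = numeric(0), trace_idx = numeric(0)))
  set.seed(seed)
  opt <- adam_make(model, lr = lr)
  tr <- ti <- numeric(steps)
  ps <- dim(triplets[[1]]$pixels)[1:2]
  msz <- pmax(2L, as.integer(round(ps * 0.25)))
  for (s in seq_len(steps)) {
    ix <- sample.int(length(triplets), min(batch_size, length(triplets)))
    stacks <- stack_batch(lapply(triplets[ix], `[[`, "pixels"))
    if (mask_triplets) {
      for (j in seq_along(ix)) {
        m <- sample_masks(ps, 4L, msz,
                          seed = sample.int(.Machine$integer.max, 1L))
        stacks[, , , j] <- mask_patch(stacks[, , , j], m)
      }
    }
    mids <- stack_batch(lapply(triplets[ix],
                               function(p) p$pixels[, , 2]))
    ys <- vapply(triplets[ix], function(p) p$slice_index / (depth - 1),
                 numeric(1))
    st <- index_step(model, stacks, mids, ys, index_weight, training = TRUE)
    tr[s] <- st$loss_rec; ti[s] <- st$loss_idx
    up <- adam_step(model, st$g, opt)
    model <- up$net; opt <- up$opt
  }
  # recalibrate batch-norm running statistics under the final parameters
  # (forward-only; unmasked inputs, as used at prediction time)
  for (r in 1:30) {
    ix <- sample.int(length(triplets), min(batch_size, length(triplets)))
    stacks <- stack_batch(lapply(triplets[ix], `[[`, "pixels"))
    cf <- conv_fw(model$compress, stacks)
    fs <- encode(model$backbone, cf$y, TRUE)
    dc <- decode(model$backbone, fs, TRUE)
    invisible(index_branch_fw(model$branch, dc$d1_out, TRUE))
  }
  list(model = model, trace_rec = tr, trace_idx = ti)
}

#' Predict normalized slice indices with a trained index model
#' @param model an `index_model`
#' @param triplets list of triplet `patch_record`s
#' @return numeric vector of predicted normalized indices
#' @export
predict_index <- function(model, triplets) {
  stacks <- stack_batch(lapply(triplets, `[[`, "pixels"))
  cf <- conv_fw(model$compress, stacks)
  fs <- encode(model$backbone, cf$y, training = FALSE)
  dc <- decode(model$backbone, fs, training = FALSE)
  index_branch_fw(model$branch, dc$d1_out, training = FALSE)$yhat
}
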