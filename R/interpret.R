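# ---------------------------------------------------------------------------
# Interpretability: project unique and common features of the six MAFFBs
# (three in the fusion network, three in the generator) into 2D/3D via PCA
# and quantify how central the common features sit between the two
# modalities' unique features.  Feature vectors are global-average-pooled
# per channel so dimensions stay comparable across spatial sizes.
# ---------------------------------------------------------------------------

# per-channel global average pooling of one sample's feature map -> vector
gap_vec <- function(x, n) {
  d <- dim(x)
  colMeans(matrix(x[, , , n], d[1] * d[2], d[3]))
}

#' Collect unique and common feature vectors from a model
#'
#' Runs the synthesis pipeline in inference mode on a set of paired source
#' patches and records, for each requested MAFFB, the pooled unique
#' features of both modalities and the block's common output features.
#'
#' @param models a `synth_models`
#' @param pairs list of `list(x1 =, x2 =)` source patch pairs
#' @param blocks integer block ids in 1..6 (1-3 fusion network, 4-6
#'   generator)
#' @return a `feature_cloud`: list per block with matrices `unique1`,
#'   `unique2`, `common` (samples in rows)
#' @export
collect_features <- function(models, pairs, blocks = 1:6) {
  if (!all(blocks %in% 1:6)) stop("unknown block id: blocks must be in 1..6")
  out <- lapply(blocks, function(b) list(unique1 = NULL, unique2 = NULL,
                                         common = NULL))
  names(out) <- paste0("MAFFB_", blocks)
  for (pr in pairs) {
    fw <- synth_forward(models, pr$x1, pr$x2, training = FALSE)
    # unique inputs per block: fusion blocks 1..3 and generator blocks
    # 4..6 read tap levels S3, S2, S1 respectively
    uniq <- list(`1` = list(fw$fs1$S1, fw$fs2$S1),
                 `2` = list(fw$fs1$S2, fw$fs2$S2),
                 `3` = list(fw$fs1$S3, fw$fs2$S3),
                 `4` = list(fw$fs1$S3, fw$fs2$S3),
                 `5` = list(fw$fs1$S2, fw$fs2$S2),
                 `6` = list(fw$fs1$S1, fw$fs2$S1))
    comm <- list(`1` = fw$fused$F1, `2` = fw$fused$F2, `3` = fw$fused$F3,
                 `4` = fw$gen_cache$m4_out, `5` = fw$gen_cache$m5_out,
                 `6` = fw$gen_cache$m6_out)
    N <- dim(fw$yhat)[4]
    for (b in blocks) {
      key <- paste0("MAFFB_", b)
      u <- uniq[[as.character(b)]]
      cm <- comm[[as.character(b)]]
      for (n in seq_len(N)) {
        out[[key]]$unique1 <- rbind(out[[key]]$unique1, gap_vec(u[[1]], n))
        out[[key]]$unique2 <- rbind(out[[key]]$unique2, gap_vec(u[[2]], n))
        out[[key]]$common <- rbind(out[[key]]$common, gap_vec(cm, n))
      }
    }
  }
  structure(out, class = "feature_cloud")
}

#' Project a feature cloud by principal component analysis
#'
#' All three roles of one block are centered and projected jointly so that
#' their relative geometry is preserved.  The component sign convention is
#' that the loading of largest magnitude is positive, making projections
#' deterministic.
#'
#' @param cloud one block's entry of a `feature_cloud` (list with matrices
#'   `unique1`, `unique2`, `common`), or any matrix-valued list
#' @param dims 2 or 3
#' @return list of projected matrices plus `var_explained`
#' @export
pca_project <- function(cloud, dims = 2L) {
  mats <- cloud[c("unique1", "unique2", "common")]
  X <- do.call(rbind, mats)
  if (nrow(X) < dims + 1L) stop("need at least dims + 1 points")
  if (all(apply(X, 2, sd) == 0)) stop("degenerate cloud: all points identical")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  dims <- min(dims, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(dims), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(dims)) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  ctr <- pc$center
  proj <- lapply(mats, function(m) sweep(m, 2, ctr) %*% rot)
  ve <- sum(pc$sdev[seq_len(dims)]^2) / sum(pc$sdev^2)
  c(proj, list(var_explained = ve, rotation = rot, center = ctr))
}

#' Centrality of the common features between the two unique clouds
#'
#' Reports `d = ||centroid(common) - midpoint(centroid(u1), centroid(u2))||
#' / ||centroid(u1) - centroid(u2)||`.  `d = 0` means the common features
#' sit exactly midway between the modalities; this is a diagnostic, not a
#' test criterion.
#'
#' @param proj a projected cloud from [pca_project()] (or any list with
#'   `unique1`, `unique2`, `common` point matrices)
#' @return scalar `d`
#' @export
centrality_diagnostic <- function(proj) {
  for (k in c("unique1", "unique2", "common"))
    if (is.null(proj[[k]])) stop("missing role: ", k)
  c1 <- colMeans(proj$unique1)
  c2 <- colMeans(proj$unique2)
  cc <- colMeans(proj$common)
  mid <- (c1 + c2) / 2
  sqrt(sum((cc - mid)^2)) / sqrt(sum((c1 - c2)^2))
}

#' Render the PCA scatter plots of a feature cloud
#'
#' Writes one PNG per block (2D scatter; for `dims = 3` the first two
#' components are drawn with the third mapped to symbol size) plus a CSV of
#' the projected coordinates.
#'
#' @param cloud a `feature_cloud`
#' @param dims 2 or 3
#' @param out_dir output directory
#' @return invisible data frame of projected coordinates
#' @export
plot_feature_cloud <- function(cloud, dims = 2L, out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (key in names(cloud)) {
    proj <- pca_project(cloud[[key]], dims)
    grDevices::png(file.path(out_dir, paste0(key, "_pca", dims, "d.png")),
                   width = 640, height = 640)
    cols <- c(unique1 = "red", unique2 = "darkgreen", common = "blue")
    allp <- rbind(proj$unique1, proj$unique2, proj$common)
    graphics::plot(allp[, 1], allp[, 2], type = "n",
                   xlab = "PC1", ylab = "PC2", main = key)
    for (role in names(cols)) {
      m <- proj[[role]]
      cex <- if (dims >= 3L) 0.8 + (m[, 3] - min(allp[, 3])) /
        max(1e-12, diff(range(allp[, 3]))) else 1
      graphics::points(m[, 1], m[, 2], col = cols[role], pch = 19, cex = cex)
      rows[[length(rows) + 1L]] <- data.frame(
        block = key, role = role, m, check.names = FALSE)
    }
    graphics::legend("topright", legend = names(cols), col = cols, pch = 19)
    grDevices::dev.off()
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(out_dir, "pca_coordinates.csv"),
                   row.names = FALSE)
  invisible(df)
}
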