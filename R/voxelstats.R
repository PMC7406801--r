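#' Voxel-wise two-sample group contrast with multiplicity correction
#'
#' Computes a pooled-variance (or Welch) two-sample t statistic at every
#' in-mask voxel, two-tailed p-values, and the mask of voxels surviving both
#' the uncorrected voxel threshold and the chosen multiplicity correction.
#' Surviving voxels are grouped into connected clusters.
#'
#' @param volumes_a,volumes_b Lists of 3D metric volumes (one per subject,
#'   at least 2 per group, identical shapes).
#' @param mask Optional boolean 3D array restricting the analysis.
#' @param p_voxel Uncorrected voxel-level threshold (default 0.001).
#' @param correction One of `"FDR"` (Benjamini-Hochberg), `"FWER"`
#'   (Bonferroni) or `"none"`, applied over in-mask voxels at level `alpha`.
#' @param alpha Correction level (default 0.05).
#' @param fa_threshold Optional: voxels whose across-subject mean metric is
#'   at or below this value are excluded first (the FA > 0.2 masking rule
#'   used for white-matter skeletons).
#' @param welch Use Welch's t instead of the pooled-variance t.
#' @param connectivity Cluster connectivity (6, 18 or 26; default 26).
#' @return An object of class `cluster_result`: `t_map`, `p_map` (NA outside
#'   the analysis mask), `surviving_mask`, `clusters` (list with `voxels`
#'   index matrix, `size`, `peak_coord`, `peak_t`), and counts of voxels
#'   excluded for zero variance or by the metric threshold.
#' @export
voxelwise_group_test <- function(volumes_a, volumes_b, mask = NULL,
                                 p_voxel = 0.001,
                                 correction = c("FDR", "FWER", "none"),
                                 alpha = 0.05, fa_threshold = NULL,
                                 welch = FALSE, connectivity = 26L) {
  correction <- match.arg(correction)
  if (length(volumes_a) < 2 || length(volumes_b) < 2) {
    stop("need at least 2 subjects per group")
  }
  sp <- dim(volumes_a[[1]])
  all_vols <- c(volumes_a, volumes_b)
  if (!all(vapply(all_vols, function(v) identical(dim(v), sp), TRUE))) {
    stop("all volumes must share one shape")
  }
  A <- vapply(volumes_a, as.numeric, numeric(prod(sp)))
  B <- vapply(volumes_b, as.numeric, numeric(prod(sp)))
  use <- if (is.null(mask)) rep(TRUE, prod(sp)) else as.logical(mask)
  n_thresh <- 0L
  if (!is.null(fa_threshold)) {
    gm <- rowMeans(cbind(A, B))
    drop_thr <- use & gm <= fa_threshold
    n_thresh <- sum(drop_thr)
    use <- use & !drop_thr
  }
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- .row_vars(A); v2 <- .row_vars(B)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  zero_var <- use & !is.finite(tstat) | (use & (if (welch) se2 else sp2) == 0)
  n_zero <- sum(zero_var & use)
  use <- use & !zero_var
  pval <- 2 * stats::pt(-abs(tstat), df)
  t_map <- array(NA_real_, sp); p_map <- array(NA_real_, sp)
  t_map[use] <- tstat[use]; p_map[use] <- pval[use]
  p_in <- pval[use]
  gate <- switch(correction,
                 FDR  = stats::p.adjust(p_in, "BH") <= alpha,
                 FWER = stats::p.adjust(p_in, "bonferroni") <= alpha,
                 none = rep(TRUE, length(p_in)))
  surv <- array(FALSE, sp)
  surv[use] <- (p_in <= p_voxel) & gate
  clusters <- extract_clusters(surv, connectivity = connectivity)
  clusters <- lapply(clusters, function(cl) {
    tv <- t_map[cl$voxels]
    peak <- which.max(abs(tv))
    cl$peak_coord <- cl$voxels[peak, ]
    cl$peak_t <- tv[peak]
    cl
  })
  structure(list(t_map = t_map, p_map = p_map, surviving_mask = surv,
                 clusters = clusters, correction = correction, alpha = alpha,
                 p_voxel = p_voxel, n_excluded_zero_variance = n_zero,
                 n_excluded_threshold = n_thresh,
                 df = if (welch) NULL else df),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Voxel-wise contrast: %d surviving voxel(s) in %d cluster(s) [%s at alpha=%g, p_voxel<=%g]\n",
              sum(x$surviving_mask), length(x$clusters), x$correction,
              x$alpha, x$p_voxel))
  if (x$n_excluded_zero_variance)
    cat(sprintf("  %d voxel(s) excluded for zero pooled variance\n",
                x$n_excluded_zero_variance))
  invisible(x)
}

.connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = off[rowSums(abs(off)) == 1, , drop = FALSE],
         "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
         "26" = off,
         stop("'connectivity' must be one of 6, 18, 26"))
}

#' Connected clusters of a boolean volume
#'
#' Labels the connected components of `mask` under the stated connectivity
#' and returns them sorted by size (descending), ties broken by the
#' lexicographically smallest member coordinate.
#'
#' @param mask Boolean 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @return A list of clusters, each a list with `voxels` (an n x 3 matrix of
#'   1-based voxel coordinates) and `size`. An empty mask gives an empty
#'   list.
#' @export
extract_clusters <- function(mask, connectivity = 26L) {
  sp <- dim(mask)
  stopifnot(length(sp) == 3L)
  idx <- which(mask)
  if (!length(idx)) return(list())
  off <- .connectivity_offsets(connectivity)
  lab <- array(.Machine$integer.max, sp)
  lab[idx] <- seq_along(idx)
  # min-label propagation over the neighborhood until a fixed point
  repeat {
    cur <- lab
    for (k in seq_len(nrow(off))) {
      sh <- .shift3d(cur, off[k, ], fill = .Machine$integer.max)
      cur[idx] <- pmin(cur[idx], sh[idx])
    }
    if (identical(cur, lab)) break
    lab <- cur
  }
  comp <- split(idx, lab[idx])
  clusters <- lapply(comp, function(v) {
    vox <- arrayInd(v, sp)
    colnames(vox) <- c("x", "y", "z")
    list(voxels = vox, size = nrow(vox))
  })
  key <- vapply(clusters, function(cl) {
    first <- cl$voxels[order(cl$voxels[, 1], cl$voxels[, 2], cl$voxels[, 3])[1], ]
    sprintf("%06d_%04d%04d%04d", 999999 - cl$size, first[1], first[2], first[3])
  }, "")
  unname(clusters[order(key)])
}

# shift a 3D array by an offset, filling the border
.shift3d <- function(a, off, fill = 0L) {
  sp <- dim(a)
  out <- array(fill, sp)
  src <- dst <- list()
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { dst[[ax]] <- (1 + o):sp[ax]; src[[ax]] <- 1:(sp[ax] - o) }
    else        { dst[[ax]] <- 1:(sp[ax] + o); src[[ax]] <- (1 - o):sp[ax] }
    if (abs(o) >= sp[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mean metric inside cluster masks, per subject
#'
#' Builds the "volume of interest" feature matrix: entry (i, j) is the mean
#' of subject i's metric volume over mask j.
#'
#' @param volumes List of per-subject 3D metric volumes.
#' @param masks List of boolean cluster masks (or a single mask).
#' @return A subjects x masks numeric matrix.
#' @export
extract_mask_features <- function(volumes, masks) {
  if (is.array(masks)) masks <- list(masks)
  if (!length(masks)) stop("'masks' must be non-empty")
  sp <- dim(volumes[[1]])
  out <- matrix(NA_real_, length(volumes), length(masks))
  for (j in seq_along(masks)) {
    mj <- as.logical(masks[[j]])
    if (!any(mj)) stop(sprintf("mask %d selects no voxels", j))
    if (!identical(dim(masks[[j]]), sp)) stop("mask shape mismatch")
    for (i in seq_along(volumes)) out[i, j] <- mean(volumes[[i]][mj])
  }
  rownames(out) <- names(volumes)
  colnames(out) <- names(masks) %||% sprintf("cluster%02d", seq_along(masks))
  out
}
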