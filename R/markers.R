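# Cell-type specificity scoring and marker selection --------------------------

#' Tau specificity index
#'
#' For a gene with non-negative expression `x` over n >= 2 clusters,
#' `tau = sum(1 - x / max(x)) / (n - 1)`: 0 for uniform expression, 1 when
#' exactly one cluster is nonzero.  Negative (log-scale) values are floored
#' at 0 first; genes with all-zero expression get `NA`.
#'
#' @param cluster_expr Genes x clusters matrix of mean log-scale expression.
#' @return Named numeric vector of tau values in `[0, 1]` (or `NA`).
#' @export
tau_specificity <- function(cluster_expr) {
  m <- as.matrix(cluster_expr)
  if (ncol(m) < 2) stopf("tau requires at least 2 clusters")
  m <- pmax(m, 0)
  mx <- apply(m, 1L, max)
  tau <- rowSums(1 - m / ifelse(mx > 0, mx, NA)) / (ncol(m) - 1L)
  setNames(tau, rownames(m))
}

#' Rank clusters per gene by expression
#'
#' Dense descending ranks: the cluster with the highest expression is rank
#' 1, the second highest rank 2, and so on; tied clusters share the smaller
#' rank.
#'
#' @param cluster_expr Genes x clusters matrix.
#' @return Integer matrix of the same shape.
#' @export
rank_clusters <- function(cluster_expr) {
  m <- as.matrix(cluster_expr)
  out <- t(apply(m, 1L, function(x) {
    vals <- sort(unique(x), decreasing = TRUE)
    match(x, vals)
  }))
  dimnames(out) <- dimnames(m)
  storage.mode(out) <- "integer"
  out
}

#' Select marker genes for one cluster
#'
#' Among genes ranked 1 in the cluster with tau at least `min_tau`, the top
#' `top_n` by expression in that cluster (fewer if fewer qualify).  The
#' tau + rank-1 rule replaces by-eye specificity screening with an
#' automatable criterion.
#'
#' @param cluster_expr Genes x clusters matrix.
#' @param cluster Cluster (column) name or index.
#' @param top_n Maximum number of markers (default 10).
#' @param min_tau Specificity threshold (default 0.8).
#' @return Character vector of marker gene ids, ordered by expression.
#' @export
select_markers <- function(cluster_expr, cluster, top_n = 10L,
                           min_tau = 0.8) {
  m <- as.matrix(cluster_expr)
  if (is.character(cluster)) {
    if (!cluster %in% colnames(m)) stopf("unknown cluster '%s'", cluster)
    cluster <- match(cluster, colnames(m))
  } else if (cluster < 1 || cluster > ncol(m)) {
    stopf("unknown cluster index %d", cluster)
  }
  tau <- tau_specificity(m)
  ranks <- rank_clusters(m)
  ok <- which(ranks[, cluster] == 1L & !is.na(tau) & tau >= min_tau)
  ok <- ok[order(m[ok, cluster], decreasing = TRUE)]
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ids[head(ok, top_n)]
}

#' Smoothed temporal profile of a marker gene set
#'
#' Averages expression over the set's genes per sample, then fits a local
#' linear (tricube-weighted) regression of the mean against age with span
#' `bandwidth`, returning the smoothed profile and a pointwise 95% band
#' (+/- 1.96 standard errors of the local fit).
#'
#' @param log2cpm Genes x samples matrix.
#' @param markers Character vector of marker gene ids (non-empty).
#' @param sample_table Aligned sample table (uses `age_days`).
#' @param bandwidth Fractional smoothing span in (0, 1]; values near 1
#'   approach a global linear fit.
#' @param n_points Number of evaluation points across the age range.
#' @return data.frame with `age_days`, `fit`, `lower`, `upper`.
#' @export
marker_profile <- function(log2cpm, markers, sample_table, bandwidth = 0.75,
                           n_points = 101L) {
  if (!length(markers)) stopf("empty marker set")
  missing <- setdiff(markers, rownames(log2cpm))
  if (length(missing))
    stopf("markers absent from the matrix: %s",
          paste(missing, collapse = ", "))
  check_sample_table(sample_table, cols = "age_days")
  y <- colMeans(log2cpm[markers, , drop = FALSE])
  age <- sample_table$age_days
  lo <- loess(y ~ age, span = bandwidth, degree = 1,
              family = "gaussian",
              control = stats::loess.control(surface = "direct"))
  grid <- seq(min(age), max(age), length.out = n_points)
  pr <- predict(lo, newdata = data.frame(age = grid), se = TRUE)
  data.frame(age_days = grid, fit = pr$fit,
             lower = pr$fit - 1.96 * pr$se.fit,
             upper = pr$fit + 1.96 * pr$se.fit)
}
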