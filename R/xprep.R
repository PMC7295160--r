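# Expression normalization, filtering and adjustment --------------------------

#' Convert counts to log2 counts per million
#'
#' Uses the offset convention
#' `log2CPM = log2((count + 0.5) / (libsize + 1) * 1e6)` with per-sample
#' library sizes taken as column sums.  Pseudocount-free CPM
#' (`count / libsize * 1e6`) is attached as attribute `"cpm"` for use by the
#' expressed-gene filter.
#'
#' @param counts Non-negative integer genes x samples matrix.
#' @return Matrix of log2CPM values with attribute `"cpm"`.
#' @export
compute_log2cpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stopf("all-zero sample(s): %s",
          paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
  log2cpm <- log2(sweep(counts + 0.5, 2L, lib + 1, `/`) * 1e6)
  attr(log2cpm, "cpm") <- sweep(counts, 2L, lib, `/`) * 1e6
  log2cpm
}

#' Expressed-gene filter
#'
#' A gene is kept if, in at least one (period, sex) stratum with at least one
#' sample, CPM >= `cpm_min` in at least half the stratum's samples (the
#' fraction comparison is exact: 3 of 6 passes, 1 of 3 fails).
#'
#' @param cpm Pseudocount-free CPM matrix (genes x samples), e.g. the `"cpm"`
#'   attribute of [compute_log2cpm()].
#' @param sample_table Sample table aligned with `cpm` columns.
#' @param cpm_min CPM threshold (default 1).
#' @param min_fraction Required fraction of stratum samples (default 0.5).
#' @return Character vector of retained gene ids (possibly empty).
#' @export
filter_expressed <- function(cpm, sample_table, cpm_min = 1,
                             min_fraction = 0.5) {
  check_sample_table(sample_table, cols = c("period", "sex"))
  if (ncol(cpm) != nrow(sample_table))
    stopf("cpm columns and sample table rows must agree")
  strata <- interaction(sample_table$period, sample_table$sex, drop = TRUE)
  keep <- rep(FALSE, nrow(cpm))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    frac <- rowMeans(cpm[, idx, drop = FALSE] >= cpm_min)
    keep <- keep | frac >= min_fraction
  }
  rownames(cpm)[keep] %||% which(keep)
}

# design matrix for period (categorical) + sex; drops unused period levels
period_sex_design <- function(sample_table) {
  model.matrix(~ factor(period) + sex,
               data = data.frame(period = sample_table$period,
                                 sex = sample_table$sex))
}

#' Remove hidden technical structure by residual principal components
#'
#' Each gene's log2CPM is regressed on developmental period (categorical)
#' and sex; the top `n_hidden` principal components of the residual matrix
#' are computed by singular value decomposition, and their reconstruction is
#' subtracted from the log2CPM matrix.  Period and sex signal is retained
#' (it re-enters the eQTL model as covariates); only structure orthogonal to
#' the known design is removed.
#'
#' @param log2cpm Genes x samples matrix.
#' @param sample_table Sample table aligned with columns.
#' @param n_hidden Number of residual PCs to remove (0 = identity).
#' @return Adjusted matrix; the removed sample-space components are attached
#'   as attribute `"hidden_components"`.
#' @export
adjust_expression <- function(log2cpm, sample_table, n_hidden) {
  check_sample_table(sample_table, cols = c("period", "sex"))
  if (n_hidden < 0) stopf("n_hidden must be >= 0")
  if (n_hidden >= min(dim(log2cpm)))
    stopf("n_hidden (%d) must be < min(genes, samples) = %d",
          n_hidden, min(dim(log2cpm)))
  if (n_hidden == 0) return(log2cpm)
  X <- period_sex_design(sample_table)
  qr_x <- qr(X)
  resid <- t(qr.resid(qr_x, t(log2cpm)))         # genes x samples
  sv <- svd(resid, nu = 0, nv = n_hidden)
  V <- sv$v                                       # samples x n_hidden
  adjusted <- log2cpm - resid %*% V %*% t(V)
  attr(adjusted, "hidden_components") <- V
  adjusted
}

#' Partition principal-component variance among covariates
#'
#' Computes sample-space principal components of the centered log2CPM matrix
#' and, for each PC and covariate, the partial R-squared from nested linear
#' models (full model with all covariates versus the model dropping that
#' covariate).
#'
#' @param log2cpm Genes x samples matrix.
#' @param covariates data.frame of per-sample covariates (factors or
#'   numeric).
#' @param n_pcs Number of PCs to report (default 5).
#' @return data.frame with columns `pc`, `variance_fraction`, one row per
#'   (PC, covariate), `covariate`, `partial_r2`.
#' @export
pca_variance_partition <- function(log2cpm, covariates, n_pcs = 5L) {
  if (nrow(covariates) != ncol(log2cpm))
    stopf("covariates rows must match log2cpm columns")
  centered <- log2cpm - rowMeans(log2cpm)
  pc <- stats::prcomp(t(centered), center = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)

  full_formula <- stats::as.formula(
    paste("y ~", paste(names(covariates), collapse = " + ")))
  # detect aliased (collinear) covariate columns on the full design
  X <- model.matrix(full_formula,
                    data = cbind(y = pc$x[, 1], covariates))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stopf("collinear covariates; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }

  out <- do.call(rbind, lapply(seq_len(n_pcs), function(i) {
    d <- cbind(y = pc$x[, i], covariates)
    full <- lm(full_formula, data = d)
    rss_full <- sum(stats::residuals(full)^2)
    pr2 <- vapply(names(covariates), function(v) {
      red <- stats::update(full, stats::as.formula(paste(". ~ . -", v)))
      rss_red <- sum(stats::residuals(red)^2)
      if (rss_red <= 0) return(0)
      (rss_red - rss_full) / rss_red
    }, numeric(1))
    data.frame(pc = i, variance_fraction = varfrac[i],
               covariate = names(covariates), partial_r2 = pr2,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "variance_fractions") <- varfrac
  out
}

#' Default sex-inference marker configuration
#'
#' XIST (higher in females) plus a configurable list of chromosome-Y genes
#' (higher in males); the defaults name widely used Y-linked markers.
#'
#' @param chry Character vector of chromosome-Y marker gene ids.
#' @return List with elements `xist` and `chry`.
#' @export
sex_marker_config <- function(chry = c("RPS4Y1", "ZFY", "USP9Y", "DDX3Y",
                                       "UTY", "NLGN4Y", "KDM5D", "EIF1AY")) {
  list(xist = "XIST", chry = chry)
}

#' Infer sample sex from marker-gene expression
#'
#' For each available marker gene, samples are split at the midpoint of the
#' two cluster means from one-dimensional 2-means clustering; XIST votes
#' female on the high side, chromosome-Y markers vote male on the high side.
#' The call is the per-sample majority vote; samples whose minority vote
#' share is at least `ambiguity` are flagged, as are calls made from a
#' single marker.
#'
#' @param log2cpm Genes x samples matrix with marker genes among rownames.
#' @param marker_config List as from [sex_marker_config()].
#' @param ambiguity Minority-vote fraction at/above which a call is flagged
#'   (default 0.25).
#' @return data.frame with columns `sample_id`, `sex`, `male_votes`,
#'   `n_markers`, `ambiguous`.
#' @export
infer_sex <- function(log2cpm, marker_config = sex_marker_config(),
                      ambiguity = 0.25) {
  markers <- c(marker_config$xist, marker_config$chry)
  present <- intersect(markers, rownames(log2cpm))
  if (!length(present)) stopf("no sex marker genes present in the matrix")
  votes <- sapply(present, function(g) {
    x <- log2cpm[g, ]
    if (diff(range(x)) < 1e-12) return(rep(NA, length(x)))
    km <- kmeans(matrix(x, ncol = 1L),
                 centers = matrix(range(x), ncol = 1L))
    cut <- mean(km$centers)
    high <- x > cut
    if (g %in% marker_config$chry) high else !high   # TRUE votes male
  })
  votes <- matrix(votes, ncol = length(present),
                  dimnames = list(colnames(log2cpm), present))
  n_inform <- rowSums(!is.na(votes))
  if (all(n_inform == 0))
    stopf("no informative (bimodal) sex marker genes in the matrix")
  male_frac <- rowMeans(votes, na.rm = TRUE)
  data.frame(
    sample_id = colnames(log2cpm) %||% seq_len(ncol(log2cpm)),
    sex = ifelse(male_frac > 0.5, "male", "female"),
    male_votes = rowSums(votes, na.rm = TRUE),
    n_markers = n_inform,
    ambiguous = pmin(male_frac, 1 - male_frac) >= ambiguity | n_inform <= 1L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Epoch-3 minus epoch-1 expression deltas
#'
#' Per gene, the median log2CPM over epoch-1 and epoch-3 samples and their
#' difference; genes are flagged epoch-specific when the other epoch's median
#' falls at or below `floor` (binary presence/absence rather than
#' amplification).
#'
#' @param log2cpm Genes x samples matrix.
#' @param sample_table Sample table aligned with columns.
#' @param floor Specificity floor in log2CPM units (default -5).
#' @return data.frame with columns `gene_id`, `median_epoch1`,
#'   `median_epoch3`, `delta`, `epoch3_specific`, `epoch1_specific`.
#' @export
epoch_delta <- function(log2cpm, sample_table, floor = -5) {
  check_sample_table(sample_table, cols = "epoch")
  e1 <- sample_table$epoch == 1L
  e3 <- sample_table$epoch == 3L
  if (!any(e1) || !any(e3))
    stopf("cohort lacks epoch-1 or epoch-3 samples")
  m1 <- apply(log2cpm[, e1, drop = FALSE], 1L, median)
  m3 <- apply(log2cpm[, e3, drop = FALSE], 1L, median)
  data.frame(
    gene_id = rownames(log2cpm) %||% seq_len(nrow(log2cpm)),
    median_epoch1 = m1, median_epoch3 = m3, delta = m3 - m1,
    epoch3_specific = m1 <= floor,
    epoch1_specific = m3 <= floor,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
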