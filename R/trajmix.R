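# Finite mixture of polynomial expression trajectories (EM) -------------------
#
# Each gene is one observation sequence across samples; component k has a
# polynomial mean curve on transformed age and its own Gaussian noise
# variance.  Mirrors a mixture-of-regressions model: the E-step computes
# per-gene responsibilities, the M-step refits weighted polynomial least
# squares and variances, and components whose prior falls below a minimum
# threshold are pruned.

#' Interquartile-range normalization
#'
#' Per gene: `(x - median(x)) / IQR(x)`, with quartiles by the default
#' linear-interpolation convention.  Genes with zero IQR are returned
#' unchanged and flagged via the `"zero_iqr"` attribute.
#'
#' @param log2cpm Genes x samples matrix.
#' @return Normalized matrix with logical attribute `"zero_iqr"`.
#' @export
iqr_normalize <- function(log2cpm) {
  med <- apply(log2cpm, 1L, median)
  iqr <- apply(log2cpm, 1L, stats::IQR)
  zero <- iqr == 0
  out <- log2cpm
  keep <- !zero
  out[keep, ] <- (log2cpm[keep, , drop = FALSE] - med[keep]) / iqr[keep]
  attr(out, "zero_iqr") <- zero
  out
}

# polynomial design matrix on internally rescaled age (conditioning); the
# rescaling is recorded so fitted curves can be evaluated at new ages
poly_basis <- function(ages, degree, center = NULL, scale = NULL) {
  center <- center %||% mean(ages)
  scale <- scale %||% max(sd(ages), 1e-12)
  u <- (ages - center) / scale
  b <- outer(u, 0:degree, `^`)
  attr(b, "center") <- center
  attr(b, "scale") <- scale
  b
}

# log N(x; m, s2) summed over samples for every gene x component
component_loglik <- function(x, fitted, sigma2) {
  S <- ncol(x)
  xm <- x %*% fitted                                   # genes x K
  rss <- rowSums(x^2) - 2 * xm +
    matrix(colSums(fitted^2), nrow(x), ncol(fitted), byrow = TRUE)
  -S / 2 * log(2 * pi) -
    matrix(S / 2 * log(sigma2), nrow(x), length(sigma2), byrow = TRUE) -
    sweep(rss, 2L, 2 * sigma2, `/`)
}

em_once <- function(x, basis, K, min_prior, max_iter, tol) {
  G <- nrow(x); S <- ncol(x)
  bt_b <- crossprod(basis)
  # init: random hard assignment
  resp <- matrix(0, G, K)
  resp[cbind(seq_len(G), sample.int(K, G, replace = TRUE))] <- 1
  pi_k <- rep(1 / K, K)
  sigma2 <- rep(1, K)
  coef <- NULL
  loglik <- -Inf
  trace <- numeric(0)
  prune_iters <- integer(0)

  for (iter in seq_len(max_iter)) {
    # M-step: weighted polynomial least squares per component
    w <- colSums(resp)
    w <- pmax(w, 1e-12)
    xbar <- crossprod(resp, x) / w                     # K x S weighted means
    coef <- t(solve(bt_b, crossprod(basis, t(xbar)))) # K x (deg+1)
    fitted <- basis %*% t(coef)                        # S x K
    xm <- x %*% fitted
    rss_gk <- rowSums(x^2) - 2 * xm +
      matrix(colSums(fitted^2), G, K, byrow = TRUE)
    sigma2 <- pmax(colSums(resp * rss_gk) / (S * w), 1e-10)
    pi_k <- w / G

    # E-step
    ll_gk <- component_loglik(x, fitted, sigma2)
    lw <- sweep(ll_gk, 2L, log(pi_k), `+`)
    lse <- row_logsumexp(lw)
    new_loglik <- sum(lse)
    if (!is.finite(new_loglik))
      stopf("non-finite mixture log-likelihood at iteration %d", iter)
    resp <- exp(lw - lse)

    trace <- c(trace, new_loglik)
    converged <- is.finite(loglik) &&
      abs(new_loglik - loglik) <= tol * (abs(loglik) + 1e-12)
    loglik <- new_loglik

    # prune components whose prior collapses (adjacent classes merge)
    if (K > 1L && any(pi_k < min_prior)) {
      drop <- which.min(pi_k)
      keep <- setdiff(seq_len(K), drop)
      resp <- resp[, keep, drop = FALSE]
      resp <- resp / rowSums(resp)
      pi_k <- pi_k[keep] / sum(pi_k[keep])
      sigma2 <- sigma2[keep]
      coef <- coef[keep, , drop = FALSE]
      K <- K - 1L
      loglik <- -Inf          # likelihood not comparable across K
      prune_iters <- c(prune_iters, iter)
      next
    }
    if (converged) break
  }
  list(K = K, coef = coef, sigma2 = sigma2, pi = pi_k, resp = resp,
       loglik = loglik, loglik_trace = trace, prune_iters = prune_iters,
       n_iter = iter)
}

#' Fit a finite mixture of polynomial trajectories by EM
#'
#' @param normalized Genes x samples matrix (typically IQR-normalized
#'   log2CPM).
#' @param ages Per-sample transformed ages (e.g. `log2` post-conception
#'   days); length must equal `ncol(normalized)`.
#' @param K Number of mixture components requested (1..10); components whose
#'   mixing proportion falls below `min_prior` are pruned during EM, so the
#'   final K can be smaller.
#' @param degree Polynomial degree of the mean curves (default 4).
#' @param min_prior Minimum mixing proportion before a component is pruned
#'   (default 0.05).
#' @param n_starts Number of random restarts; the best final log-likelihood
#'   wins (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed Integer RNG seed.
#' @return Object of class `trajectory_fit`: list with `K`, `coef`
#'   (K x degree+1, on the internally rescaled age recorded in
#'   `age_center`/`age_scale`), `sigma2`, `pi`, `resp` (genes x K), `loglik`,
#'   `aic`, `bic`, `degree`, `n_genes`, `ages`.
#' @export
fit_mixture <- function(normalized, ages, K, degree = 4L, min_prior = 0.05,
                        n_starts = 10L, max_iter = 200L, tol = 1e-6,
                        seed = 1L) {
  x <- as.matrix(normalized)
  if (length(ages) != ncol(x)) stopf("ages must match matrix columns")
  if (K < 1 || K > 10) stopf("K must be in 1..10")
  if (ncol(x) < degree + 2) stopf("need at least degree + 2 samples")
  basis <- poly_basis(ages, degree)

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- em_once(x, basis, K, min_prior, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  G <- nrow(x)
  # free parameters: K curves x (degree+1 coefs + 1 variance) + K-1 mixing
  p <- best$K * (degree + 2L) + (best$K - 1L)
  out <- c(best, list(
    degree = degree, n_genes = G, n_params = p,
    aic = 2 * p - 2 * best$loglik,
    bic = p * log(G) - 2 * best$loglik,
    ages = ages,
    age_center = attr(basis, "center"),
    age_scale = attr(basis, "scale"),
    gene_ids = rownames(x)
  ))
  class(out) <- "trajectory_fit"
  out
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "Trajectory mixture fit: K = %d (degree %d), %d genes\n", x$K,
    x$degree, x$n_genes))
  cat(sprintf("  loglik %.2f | AIC %.1f | BIC %.1f\n", x$loglik, x$aic,
              x$bic))
  cat("  mixing:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate fitted component curves at given ages
#'
#' @param fit A `trajectory_fit`.
#' @param ages Transformed ages at which to evaluate.
#' @return ages x K matrix of fitted means.
#' @export
fitted_curves <- function(fit, ages) {
  basis <- poly_basis(ages, fit$degree, fit$age_center, fit$age_scale)
  basis %*% t(fit$coef)
}

#' Compare mixture fits across K by information criteria
#'
#' `AIC = 2p - 2 loglik`, `BIC = p log(G) - 2 loglik` with
#' `p = K (degree + 2) + (K - 1)` free parameters and `G` genes.  The chosen
#' K minimizes BIC (ties to the smallest K) unless overridden.
#'
#' @param fits List of `trajectory_fit` objects (e.g. over K = 2..5).
#' @param override Optional K forcing the choice.
#' @return data.frame with columns `K`, `loglik`, `aic`, `bic`; the chosen K
#'   is in attribute `"chosen_k"`.
#' @export
select_k <- function(fits, override = NULL) {
  if (!length(fits)) stopf("empty fit list")
  tab <- data.frame(
    K = vapply(fits, `[[`, integer(1), "K"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic")
  )
  tab <- tab[order(tab$K), ]
  chosen <- if (!is.null(override)) override else
    tab$K[which.min(tab$bic)]    # which.min takes the first (smallest K) tie
  attr(tab, "chosen_k") <- chosen
  tab
}

#' Label mixture components rising / falling / non-transitional
#'
#' Per component, the contrast `delta` = mean fitted value over epoch-3
#' sample ages minus mean fitted value over epoch-1 sample ages; rising if
#' `delta > threshold`, falling if `delta < -threshold`, else
#' non-transitional.
#'
#' @param fit A `trajectory_fit` (its `ages` must align with
#'   `sample_table`).
#' @param sample_table Sample table for the samples used in the fit.
#' @param threshold Contrast threshold in normalized units (default 0.5).
#' @return The fit with added `labels` (length K) and `label_delta`.
#' @export
label_components <- function(fit, sample_table, threshold = 0.5) {
  check_sample_table(sample_table, cols = "epoch")
  if (nrow(sample_table) != length(fit$ages))
    stopf("sample table must align with the ages used in the fit")
  e1 <- sample_table$epoch == 1L
  e3 <- sample_table$epoch == 3L
  if (!any(e1) || !any(e3)) stopf("missing epoch-1 or epoch-3 samples")
  curves <- fitted_curves(fit, fit$ages)
  delta <- colMeans(curves[e3, , drop = FALSE]) -
    colMeans(curves[e1, , drop = FALSE])
  fit$labels <- ifelse(delta > threshold, "rising",
                       ifelse(delta < -threshold, "falling",
                              "non_transitional"))
  fit$label_delta <- delta
  fit
}

#' Hard-assign genes to mixture components
#'
#' Hard label = argmax responsibility; exact ties are broken toward
#' non-transitional, then falling, then rising (requires labeled
#' components; unlabeled fits break ties toward the lower component index).
#'
#' @param fit A `trajectory_fit`, ideally after [label_components()].
#' @return data.frame with `gene_id`, `component`, `label` (if available)
#'   and `max_resp`.
#' @export
assign_genes <- function(fit) {
  resp <- fit$resp
  pref <- if (!is.null(fit$labels)) {
    order_rank <- match(fit$labels,
                        c("non_transitional", "falling", "rising"))
    order_rank
  } else seq_len(fit$K)
  comp <- apply(resp, 1L, function(r) {
    top <- which(r >= max(r) - 1e-12)
    top[which.min(pref[top])]
  })
  data.frame(
    gene_id = fit$gene_ids %||% seq_len(nrow(resp)),
    component = comp,
    label = if (!is.null(fit$labels)) fit$labels[comp] else NA_character_,
    max_resp = resp[cbind(seq_len(nrow(resp)), comp)],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit developmental trajectories on a cohort
#'
#' Convenience wrapper: IQR-normalizes log2CPM, excludes epoch-0 samples
#' (very few samples bias the curve estimates near the origin), fits the
#' mixture on `log2(age_days)`, labels components by the epoch-3 versus
#' epoch-1 contrast and hard-assigns genes.
#'
#' @param log2cpm Genes x samples matrix.
#' @param sample_table Aligned sample table.
#' @param K Components requested (default 3).
#' @param exclude_epoch0 Drop epoch-0 samples before fitting (default TRUE).
#' @param ... Passed to [fit_mixture()].
#' @return List with `fit` (labeled `trajectory_fit`) and `assignments`.
#' @export
fit_trajectories <- function(log2cpm, sample_table, K = 3L,
                             exclude_epoch0 = TRUE, ...) {
  check_sample_table(sample_table)
  keep <- if (exclude_epoch0) sample_table$epoch != 0L else
    rep(TRUE, nrow(sample_table))
  st <- sample_table[keep, , drop = FALSE]
  norm <- iqr_normalize(log2cpm[, keep, drop = FALSE])
  fit <- fit_mixture(norm, log2(st$age_days), K = K, ...)
  fit <- label_components(fit, st)
  list(fit = fit, assignments = assign_genes(fit))
}
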