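# Shared fixture builders (all generated in code, fixed seeds)

# small cohort with planted eQTLs for scan/classification tests
small_cohort <- function(n_genes = 200L, n_variants = 1500L, n_eqtl = 0L,
                         beta = 0.8, seed = 101L, ...) {
  simulate_cohort(n_genes = n_genes, n_variants = n_variants,
                  n_eqtl = n_eqtl, beta = beta, seed = seed, ...)
}

# sample table with a handful of samples per period (fast)
small_samples <- function(n_each = 3L, seed = 5L) {
  simulate_samples(n_per_period = rep(n_each, 12L), seed = seed)
}

# clean normalized trajectory mixture matrix: known groups, no count layer
mixture_matrix <- function(G = 300L, S = 100L, sep = 2, sigma = 0.5,
                           seed = 11L) {
  set.seed(seed)
  ages <- seq(4.8, 12.9, length.out = S)
  u <- (ages - mean(ages)) / sd(ages)
  curves <- cbind(rising = sep * u, falling = -sep * u, flat = 0 * u)
  grp <- sample(colnames(curves), G, replace = TRUE)
  x <- t(curves)[grp, , drop = FALSE] + matrix(rnorm(G * S, 0, sigma), G, S)
  rownames(x) <- sprintf("g%03d", seq_len(G))
  list(x = x, ages = ages, group = grp, curves = curves)
}

# exhaustive Benjamini-Hochberg step-up oracle (independent of bh_fdr)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# closed-form OLS via normal equations (independent of the scan path)
ols_oracle <- function(y, X) {
  xtx <- t(X) %*% X
  coefs <- solve(xtx, t(X) %*% y)
  fit <- X %*% coefs
  rss <- sum((y - fit)^2)
  df <- nrow(X) - ncol(X)
  vcov <- solve(xtx) * rss / df
  se <- sqrt(diag(vcov))
  tstat <- coefs / se
  list(beta = as.vector(coefs), se = se,
       p = 2 * pt(-abs(tstat), df), df = df)
}
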