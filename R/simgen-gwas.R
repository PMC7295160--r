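# Synthetic GWAS summary statistics -------------------------------------------

#' Simulate GWAS summary statistics
#'
#' Non-causal variants receive Z scores from the standard normal; causal
#' variants receive `Z ~ Normal(mu, 1)` with `mu = effect_sd * sqrt(n_gwas)`
#' (the non-centrality of a Wald test of a standardized per-allele effect of
#' size `effect_sd` at sample size `n_gwas`), with a random sign per variant.
#' Betas and standard errors are reported on the standardized-trait scale
#' (`se = 1 / sqrt(n_gwas)`, `beta = z * se`); p-values are two-sided normal.
#'
#' @param variants Variant table from [simulate_genotypes()].
#' @param causal_set Character vector of causal variant ids (subset of
#'   `variants$variant_id`).
#' @param effect_sd Standardized causal effect size (0 = global null).
#' @param n_gwas GWAS sample size.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `variant_id`, `chrom`, `pos`, `beta`,
#'   `se`, `z`, `p`, `n`.
#' @export
simulate_gwas <- function(variants, causal_set = character(), effect_sd = 0,
                          n_gwas = 1e5, seed = 1L) {
  if (!all(causal_set %in% variants$variant_id))
    stopf("causal_set contains variants absent from the variant table")
  set.seed(seed)
  m <- nrow(variants)
  z <- rnorm(m)
  if (length(causal_set) && effect_sd > 0) {
    idx <- match(causal_set, variants$variant_id)
    mu <- effect_sd * sqrt(n_gwas)
    z[idx] <- sample(c(-1, 1), length(idx), replace = TRUE) *
      rnorm(length(idx), mu, 1)
  }
  se <- 1 / sqrt(n_gwas)
  data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
             pos = variants$pos, beta = z * se, se = se, z = z,
             p = 2 * pnorm(-abs(z)), n = n_gwas,
             stringsAsFactors = FALSE)
}
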