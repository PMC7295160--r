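# Five-hypothesis colocalization posteriors ----------------------------------

# log approximate Bayes factor per SNP: with V = se^2 and prior effect
# variance W, log ABF = 0.5 log(V / (V + W)) + z^2 W / (2 (V + W))
log_abf <- function(beta, se, W) {
  if (any(se <= 0)) stopf("standard errors must be positive")
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + z2 * W / (2 * (V + W))
}

#' Colocalization of a GWAS signal and an eQTL signal at one locus
#'
#' Single-causal-variant Bayesian colocalization over five hypotheses:
#' H0 no association, H1 GWAS association only, H2 eQTL association only,
#' H3 both traits associated at distinct variants, H4 both associated at a
#' shared variant.  Per SNP and trait a log approximate Bayes factor is
#' computed from (beta, se) (or from z and n, with `se = 1/sqrt(n)`);
#' hypothesis weights are prior-scaled sums over SNP configurations,
#' evaluated with log-sum-exp throughout, and normalized to posterior
#' probabilities PP0..PP4.  A posterior probability of H4 of at least 0.8
#' is conventionally taken as strong evidence of colocalization.
#'
#' @param gwas,eqtl data.frames over the same SNPs (same order or shared
#'   `variant_id`) with columns `beta` and `se`, or `z` and `n`.
#' @param p1,p2,p12 Prior probabilities that a SNP is causal for the GWAS
#'   trait only, the eQTL only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param W Prior effect variance (default `0.15^2`, the quantitative-trait
#'   convention).
#' @return List with `pp` (named vector PP0..PP4), `labf_gwas`,
#'   `labf_eqtl`, `n_snps`.
#' @export
coloc_abf <- function(gwas, eqtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      W = 0.15^2) {
  if ("variant_id" %in% names(gwas) && "variant_id" %in% names(eqtl)) {
    if (!setequal(gwas$variant_id, eqtl$variant_id))
      stopf("GWAS and eQTL SNP lists do not match")
    eqtl <- eqtl[match(gwas$variant_id, eqtl$variant_id), , drop = FALSE]
  } else if (nrow(gwas) != nrow(eqtl)) {
    stopf("GWAS and eQTL SNP lists do not match")
  }
  get_labf <- function(d) {
    if (all(c("beta", "se") %in% names(d))) log_abf(d$beta, d$se, W)
    else if (all(c("z", "n") %in% names(d)))
      log_abf(d$z / sqrt(d$n), 1 / sqrt(d$n), W)
    else stopf("need columns beta+se or z+n")
  }
  la <- get_labf(gwas)
  lb <- get_labf(eqtl)
  m <- length(la)

  lsa <- logsumexp(la)
  lsb <- logsumexp(lb)
  lsab <- logsumexp(la + lb)
  lh0 <- 0
  lh1 <- log(p1) + lsa
  lh2 <- log(p2) + lsb
  lh4 <- log(p12) + lsab
  # sum over i != j of ABF_gwas,i * ABF_eqtl,j = (sum_i)(sum_j) - sum_ii
  d <- lsab - (lsa + lsb)
  lh3 <- if (m > 1 && d < 0)
    log(p1) + log(p2) + lsa + lsb + log1p(-exp(d)) else -Inf
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  list(pp = pp, labf_gwas = la, labf_eqtl = lb, n_snps = m)
}

#' Fisher exact gene-set test against an expressed-gene background
#'
#' Builds the 2x2 overlap table of a query gene set and a trait-associated
#' gene set within the expressed-gene universe and applies Fisher's exact
#' test.  Trait genes outside the background are dropped with a warning.
#' The adjusted p-value is `min(1, p * n_comparisons)` for Bonferroni, or
#' should be computed across the family for BH (pass the family's p-values
#' to [bh_fdr()] in that case).
#'
#' @param query_set,trait_set Character vectors of gene ids.
#' @param background Character vector: the expressed-gene universe.
#' @param n_comparisons Family size for Bonferroni correction (default 1).
#' @return List with `table` (2x2), `odds_ratio` (sample odds ratio
#'   `ad/bc`), `p`, `p_adjusted`, `n_comparisons`.
#' @export
gene_set_fet <- function(query_set, trait_set, background,
                         n_comparisons = 1L) {
  query_set <- intersect(unique(query_set), background)
  outside <- setdiff(unique(trait_set), background)
  if (length(outside))
    warning(sprintf("%d trait genes outside the background dropped",
                    length(outside)), call. = FALSE)
  trait_set <- intersect(unique(trait_set), background)
  a <- length(intersect(query_set, trait_set))
  b <- length(setdiff(query_set, trait_set))
  cc <- length(setdiff(trait_set, query_set))
  d <- length(background) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2L, 2L,
                dimnames = list(c("query", "not_query"),
                                c("trait", "not_trait")))
  ft <- fisher.test(tab)
  list(table = tab,
       odds_ratio = (a * d) / (b * cc),
       p = ft$p.value,
       p_adjusted = min(1, ft$p.value * n_comparisons),
       n_comparisons = n_comparisons)
}
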