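# Exact Hardy-Weinberg equilibrium test (Wigginton-style enumeration) --------

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test of Hardy-Weinberg proportions given the observed
#' allele counts, enumerating the heterozygote distribution.  The p-value is
#' the probability mass of heterozygote counts with probability no larger
#' than the observed one; with `midp = TRUE` half the observed configuration's
#' probability is subtracted (mid-p correction).  Vectorized over variants.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote); equal-length vectors.
#' @param midp Use the mid-p correction (default TRUE).
#' @return Numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb, midp = TRUE) {
  stopifnot(length(n_aa) == length(n_ab), length(n_ab) == length(n_bb))
  mapply(hwe_exact_one, n_aa, n_ab, n_bb, MoreArgs = list(midp = midp))
}

hwe_exact_one <- function(n_aa, n_ab, n_bb, midp = TRUE) {
  if (min(n_aa, n_ab, n_bb) < 0) stopf("genotype counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_rare <- 2L * min(n_aa, n_bb) + n_ab    # minor allele count
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)
  # unnormalized log-probabilities of each heterozygote count
  hom_r <- (n_rare - hets) / 2L            # rare homozygotes
  hom_c <- n - hets - hom_r                # common homozygotes
  logp <- lgamma(n + 1) - lgamma(hets + 1) - lgamma(hom_r + 1) -
    lgamma(hom_c + 1) + hets * log(2)
  p <- exp(logp - logsumexp(logp))
  obs <- which(hets == n_ab)
  pv <- sum(p[p <= p[obs] * (1 + 1e-12)])
  if (midp) pv <- pv - p[obs] / 2
  min(max(pv, .Machine$double.xmin), 1)
}
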