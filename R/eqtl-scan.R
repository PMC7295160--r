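# Cis-eQTL detection: variant filtering, pair enumeration, linear scans ------

#' Filter variants for eQTL analysis
#'
#' Keeps a variant iff its minor allele frequency is at least `maf_min` in
#' both the prenatal (periods 1-6) and postnatal (periods 8-12) sample
#' subsets, and the exact Hardy-Weinberg test p-value over all samples is at
#' least `hwe_p_min`.
#'
#' @param variants Variant table (with `variant_id`).
#' @param dosage Variants x samples dosage matrix (0/1/2).
#' @param sample_table Aligned sample table.
#' @param maf_min MAF threshold (default 0.05).
#' @param hwe_p_min Hardy-Weinberg p-value threshold (default 1e-12).
#' @return Variant table subset passing the filters.
#' @export
filter_variants <- function(variants, dosage, sample_table, maf_min = 0.05,
                            hwe_p_min = 1e-12) {
  check_sample_table(sample_table)
  pre <- sample_table$stage == "prenatal"
  post <- sample_table$stage == "postnatal"
  if (sum(pre) < 2 || sum(post) < 2)
    stopf("prenatal and postnatal subsets each need at least 2 samples")
  maf_of <- function(m) {
    f <- rowMeans(m) / 2
    pmin(f, 1 - f)
  }
  maf_pre <- maf_of(dosage[, pre, drop = FALSE])
  maf_post <- maf_of(dosage[, post, drop = FALSE])
  n_alt <- rowSums(dosage == 2L)
  n_het <- rowSums(dosage == 1L)
  n_ref <- ncol(dosage) - n_alt - n_het
  hwe <- hwe_exact_test(n_ref, n_het, n_alt)
  keep <- maf_pre >= maf_min & maf_post >= maf_min & hwe >= hwe_p_min
  variants[keep, , drop = FALSE]
}

#' Enumerate cis gene-variant pairs
#'
#' A pair (gene, variant) is cis iff they share a chromosome and the variant
#' position (0-based) satisfies
#' `gene_start - window <= pos < gene_end + window`, i.e. the window is
#' measured from the gene boundaries.
#'
#' @param variants Variant table with `variant_id`, `chrom`, `pos`.
#' @param gene_annotation Gene table with `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param window Cis window in bp (default 1e6).
#' @return data.frame with columns `gene_id`, `variant_id`.
#' @export
cis_pairs <- function(variants, gene_annotation, window = 1e6) {
  if (!nrow(variants) || !nrow(gene_annotation))
    return(data.frame(gene_id = character(), variant_id = character(),
                      stringsAsFactors = FALSE))
  genes <- GenomicRanges::GRanges(
    gene_annotation$chrom,
    IRanges::IRanges(start = pmax(gene_annotation$start + 1 - window, 1),
                     end = gene_annotation$end + window))
  snps <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(snps, genes)
  data.frame(
    gene_id = gene_annotation$gene_id[S4Vectors::subjectHits(hits)],
    variant_id = variants$variant_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
}

# covariate design: period (categorical) + sex + 5 ancestry PCs; errors on
# rank deficiency listing the aliased columns
eqtl_design <- function(sample_table, n_pcs = 5L) {
  pcs <- ancestry_pc_cols(sample_table, n_pcs)
  d <- data.frame(period = factor(sample_table$period),
                  sex = factor(sample_table$sex))
  d <- cbind(d, sample_table[pcs])
  # single-level factors are constants absorbed by the intercept
  keep <- vapply(d, function(col) !is.factor(col) || nlevels(col) >= 2L,
                 logical(1))
  d <- d[keep]
  X <- if (ncol(d)) model.matrix(~ ., data = d) else
    matrix(1, nrow(sample_table), 1, dimnames = list(NULL, "(Intercept)"))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stopf("rank-deficient covariate design; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }
  X
}

cut_samples <- function(sample_table, cut) {
  switch(cut,
         complete = rep(TRUE, nrow(sample_table)),
         prenatal = sample_table$stage == "prenatal",
         postnatal = sample_table$stage == "postnatal",
         stopf("cut must be 'complete', 'prenatal' or 'postnatal'"))
}

#' Cis-eQTL linear-model scan for one sample cut
#'
#' For each gene-variant pair, ordinary least squares of adjusted expression
#' on alternate-allele dosage with developmental period (categorical), sex
#' and the first five ancestry principal components as covariates, on one of
#' three sample cuts: `complete` (all samples), `prenatal` (periods 1-6) or
#' `postnatal` (periods 8-12).  Computed by residualizing both expression
#' and dosage on the covariate design (Frisch-Waugh-Lovell), which matches
#' full-design OLS exactly.  Pairs whose dosage is constant within the cut
#' receive missing statistics.
#'
#' @param expr Genes x samples matrix of (adjusted) expression.
#' @param dosage Variants x samples dosage matrix.
#' @param sample_table Aligned sample table with ancestry PC columns.
#' @param pairs data.frame with `gene_id`, `variant_id` (see [cis_pairs()]).
#' @param cut One of "complete", "prenatal", "postnatal".
#' @param n_pcs Ancestry PCs used as covariates (default 5).
#' @return data.frame with `gene_id`, `variant_id`, `beta`, `se`, `p`,
#'   `fdr` (Benjamini-Hochberg within this cut, over non-missing pairs),
#'   `n`.
#' @export
eqtl_scan <- function(expr, dosage, sample_table, pairs,
                      cut = c("complete", "prenatal", "postnatal"),
                      n_pcs = 5L) {
  cut <- match.arg(cut)
  keep <- cut_samples(sample_table, cut)
  st <- sample_table[keep, , drop = FALSE]
  X <- eqtl_design(st, n_pcs)
  n <- nrow(st)
  df <- n - ncol(X) - 1L
  if (df < 1) stopf("cut '%s' leaves no residual degrees of freedom", cut)

  gi <- match(pairs$gene_id, rownames(expr))
  vi <- match(pairs$variant_id, rownames(dosage))
  if (anyNA(gi)) stopf("pairs name genes absent from the expression matrix")
  if (anyNA(vi)) stopf("pairs name variants absent from the dosage matrix")

  qr_x <- qr(X)
  re <- t(qr.resid(qr_x, t(expr[, keep, drop = FALSE])))    # genes x n
  rg <- t(qr.resid(qr_x, t(dosage[, keep, drop = FALSE])))  # variants x n

  ss_e <- rowSums(re^2)
  ss_g <- rowSums(rg^2)
  const <- apply(dosage[, keep, drop = FALSE], 1L,
                 function(d) max(d) == min(d))

  np <- nrow(pairs)
  beta <- se <- pval <- rep(NA_real_, np)
  chunk <- 200000L
  for (start in seq(1L, np, by = chunk)) {
    idx <- start:min(start + chunk - 1L, np)
    g <- gi[idx]; v <- vi[idx]
    cross <- rowSums(re[g, , drop = FALSE] * rg[v, , drop = FALSE])
    sg <- ss_g[v]
    ok <- !const[v] & sg > 1e-12
    b <- cross / sg
    rss <- ss_e[g] - b^2 * sg
    s <- sqrt(pmax(rss, 0) / df / sg)
    b[!ok] <- NA; s[!ok] <- NA
    beta[idx] <- b
    se[idx] <- s
    pval[idx] <- 2 * pt(-abs(b / s), df)
  }
  out <- data.frame(gene_id = pairs$gene_id, variant_id = pairs$variant_id,
                    beta = beta, se = se, p = pval, fdr = NA_real_, n = n,
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_fdr(out$p[ok])
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1), computed over the
#' supplied family (each analysis cut separately in the scan).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Signed distance from transcription start site to variant
#'
#' Positive distances are downstream of the TSS in the gene's direction of
#' transcription; negative distances are upstream.  For + strand genes this
#' is `pos - tss`; for - strand genes `tss - pos`.
#'
#' @param variant One-row (or vectorized) variant table with `chrom`, `pos`.
#' @param gene Gene annotation rows with `chrom`, `tss`, `strand`, aligned
#'   with `variant`.
#' @return Integer vector of signed distances in bp.
#' @export
tss_distance <- function(variant, gene) {
  if (any(variant$chrom != gene$chrom))
    stopf("variant and gene on different chromosomes")
  ifelse(gene$strand == "+", variant$pos - gene$tss, gene$tss - variant$pos)
}
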