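# Genomic-control lambda from distant gene-variant pairs ----------------------

CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)   # 0.4549364...

#' Genomic-control lambda from a vector of p-values
#'
#' `lambda = median(qchisq(p, 1, lower = FALSE)) / 0.4549364`; values near 1
#' indicate a well-calibrated test.
#'
#' @param p Numeric vector of p-values.
#' @return Scalar lambda.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stopf("no p-values supplied")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / CHISQ1_MEDIAN
}

# enumerate, per chromosome, how many variants are 10-100 Mb from each
# gene's TSS, and provide uniform sampling over the implied pair universe
distant_pair_index <- function(variants, gene_annotation, min_dist,
                               max_dist) {
  idx <- list()
  for (chr in unique(gene_annotation$chrom)) {
    g <- gene_annotation[gene_annotation$chrom == chr, , drop = FALSE]
    v <- variants[variants$chrom == chr, , drop = FALSE]
    if (!nrow(v) || !nrow(g)) next
    pos <- sort(v$pos)
    ord <- order(v$pos)
    # counts of variants in [tss-max, tss-min] and [tss+min, tss+max]
    lo1 <- findInterval(g$tss - max_dist - 1, pos)
    hi1 <- findInterval(g$tss - min_dist, pos)
    lo2 <- findInterval(g$tss + min_dist - 1, pos)
    hi2 <- findInterval(g$tss + max_dist, pos)
    n_left <- hi1 - lo1
    n_right <- hi2 - lo2
    idx[[chr]] <- list(genes = g$gene_id, variant_ids = v$variant_id[ord],
                       lo1 = lo1, n_left = n_left, lo2 = lo2,
                       n_right = n_right, total = n_left + n_right)
  }
  idx
}

sample_distant_pairs <- function(index, n_pairs) {
  per_gene <- unlist(lapply(index, `[[`, "total"), use.names = FALSE)
  total <- sum(per_gene)
  if (total < n_pairs)
    stopf("only %d eligible distant gene-variant pairs (< %d requested)",
          total, n_pairs)
  draw <- sort(sample.int(total, n_pairs))
  gene_id <- character(n_pairs)
  variant_id <- character(n_pairs)
  offset <- 0L
  k <- 1L
  for (chr in names(index)) {
    ci <- index[[chr]]
    cum <- cumsum(ci$total)
    chr_total <- sum(ci$total)
    while (k <= n_pairs && draw[k] <= offset + chr_total) {
      local <- draw[k] - offset
      gpos <- findInterval(local - 1L, cum) + 1L
      within <- local - c(0L, cum)[gpos]
      gene_id[k] <- ci$genes[gpos]
      vi <- if (within <= ci$n_left[gpos]) ci$lo1[gpos] + within else
        ci$lo2[gpos] + (within - ci$n_left[gpos])
      variant_id[k] <- ci$variant_ids[vi]
      k <- k + 1L
    }
    offset <- offset + chr_total
  }
  data.frame(gene_id = gene_id, variant_id = variant_id,
             stringsAsFactors = FALSE)
}

#' Genomic-control validation of the eQTL scan
#'
#' Repeatedly samples `n_pairs` gene-variant pairs on the same chromosome
#' whose TSS-to-variant distance lies in `[min_dist, max_dist]` (distant
#' pairs are unlikely to carry true cis regulatory signal), runs the
#' association scan on them, and computes the genomic-control lambda per
#' repetition.
#'
#' @param expr Genes x samples matrix of adjusted expression.
#' @param dosage Variants x samples dosage matrix.
#' @param sample_table Aligned sample table.
#' @param variants Variant table.
#' @param gene_annotation Gene annotation table.
#' @param cut Sample cut for the scan (default "complete").
#' @param n_pairs Pairs per repetition (default 500).
#' @param n_reps Repetitions (default 100).
#' @param min_dist,max_dist Distance band in bp (default 10-100 Mb).
#' @param seed Integer RNG seed.
#' @return List with `lambdas` (length `n_reps`) and `median_lambda`.
#' @export
genomic_control <- function(expr, dosage, sample_table, variants,
                            gene_annotation, cut = "complete",
                            n_pairs = 500L, n_reps = 100L, min_dist = 1e7,
                            max_dist = 1e8, seed = 1L) {
  gene_annotation <- gene_annotation[
    gene_annotation$gene_id %in% rownames(expr), , drop = FALSE]
  variants <- variants[
    variants$variant_id %in% rownames(dosage), , drop = FALSE]
  index <- distant_pair_index(variants, gene_annotation, min_dist, max_dist)
  set.seed(seed)
  lambdas <- vapply(seq_len(n_reps), function(r) {
    pairs <- sample_distant_pairs(index, n_pairs)
    res <- eqtl_scan(expr[unique(pairs$gene_id), , drop = FALSE],
                     dosage[unique(pairs$variant_id), , drop = FALSE],
                     sample_table, pairs, cut = cut)
    lambda_gc(res$p)
  }, numeric(1))
  list(lambdas = lambdas, median_lambda = median(lambdas))
}
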