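# GWAS integration: LD handling, matched-permutation enrichment ---------------

#' Pairwise LD (r-squared) table from dosages
#'
#' Computes squared Pearson correlations between dosage rows for all variant
#' pairs on the same chromosome within `max_dist` bp.
#'
#' @param dosage Variants x samples dosage matrix.
#' @param variants Variant table aligned with `dosage` rows.
#' @param max_dist Maximum pair distance in bp (default 1 Mb).
#' @return data.frame with columns `a`, `b` (variant ids) and `r2`.
#' @export
ld_table <- function(dosage, variants, max_dist = 1e6) {
  stopifnot(nrow(dosage) == nrow(variants))
  out <- list()
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    idx <- idx[order(variants$pos[idx])]
    pos <- variants$pos[idx]
    for (i in seq_along(idx)) {
      j <- i + 1L
      js <- integer(0)
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist) {
        js <- c(js, j)
        j <- j + 1L
      }
      if (!length(js)) next
      x <- dosage[idx[i], ]
      if (stats::sd(x) == 0) next
      ys <- dosage[idx[js], , drop = FALSE]
      sds <- apply(ys, 1L, stats::sd)
      ok <- sds > 0
      if (!any(ok)) next
      r <- as.vector(stats::cor(x, t(ys[ok, , drop = FALSE])))
      out[[length(out) + 1L]] <- data.frame(
        a = variants$variant_id[idx[i]],
        b = variants$variant_id[idx[js][ok]],
        r2 = r^2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), r2 = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# symmetric lookup of best proxies: for each id in `ids`, the candidate in
# `universe` with the highest r2 above the threshold
best_proxy <- function(ids, universe, ld, r2_min) {
  ld2 <- rbind(ld, data.frame(a = ld$b, b = ld$a, r2 = ld$r2))
  ld2 <- ld2[ld2$a %in% ids & ld2$b %in% universe & ld2$r2 > r2_min, ,
             drop = FALSE]
  ld2 <- ld2[order(ld2$a, -ld2$r2, ld2$b), ]
  ld2[!duplicated(ld2$a), ]
}

#' Match GWAS SNPs to the eQTL-tested variant universe
#'
#' A GWAS SNP is kept directly if itself tested; otherwise its best proxy
#' with `r2 > r2_min` among tested variants is substituted; otherwise it is
#' dropped (the count of dropped SNPs is attached as an attribute).
#'
#' @param gwas_snps Character vector of GWAS SNP ids.
#' @param tested_variants Character vector of eQTL-tested variant ids.
#' @param ld LD table from [ld_table()].
#' @param r2_min Proxy threshold (default 0.8).
#' @return data.frame with `snp`, `matched`, `type` ("direct"/"proxy");
#'   attribute `"n_dropped"`.
#' @export
match_to_tested <- function(gwas_snps, tested_variants, ld, r2_min = 0.8) {
  direct <- gwas_snps %in% tested_variants
  res <- data.frame(snp = gwas_snps,
                    matched = ifelse(direct, gwas_snps, NA_character_),
                    type = ifelse(direct, "direct", NA_character_),
                    stringsAsFactors = FALSE)
  need <- res$snp[!direct]
  if (length(need)) {
    px <- best_proxy(need, tested_variants, ld, r2_min)
    hit <- match(res$snp, px$a)
    use <- !direct & !is.na(hit)
    res$matched[use] <- px$b[hit[use]]
    res$type[use] <- "proxy"
  }
  dropped <- sum(is.na(res$matched))
  res <- res[!is.na(res$matched), , drop = FALSE]
  attr(res, "n_dropped") <- dropped
  res
}

#' LD pruning supervised by GWAS p-value
#'
#' Greedy: SNPs are processed in ascending GWAS p-value (ties broken by
#' position, then id); a SNP is kept unless it has `r2 > r2_max` with an
#' already-kept SNP within `window` bp on the same chromosome.  This
#' preferentially retains the most phenotype-associated SNP of each LD
#' clump.
#'
#' @param snps Character vector of SNP ids.
#' @param gwas_p Named (or aligned) vector of GWAS p-values for `snps`.
#' @param variants Variant table supplying `chrom` and `pos`.
#' @param ld LD table from [ld_table()].
#' @param r2_max Pruning threshold (default 0.7).
#' @param window Sliding window in bp (default 500 kb).
#' @return Character vector of retained SNP ids.
#' @export
supervised_prune <- function(snps, gwas_p, variants, ld, r2_max = 0.7,
                             window = 5e5) {
  if (length(gwas_p) != length(snps) || anyNA(gwas_p))
    stopf("every SNP needs a GWAS p-value")
  vi <- match(snps, variants$variant_id)
  if (anyNA(vi)) stopf("SNPs absent from the variant table")
  chrom <- variants$chrom[vi]
  pos <- variants$pos[vi]
  ord <- order(gwas_p, pos, snps)
  ld2 <- rbind(ld, data.frame(a = ld$b, b = ld$a, r2 = ld$r2))
  ld2 <- ld2[ld2$r2 > r2_max & ld2$a %in% snps & ld2$b %in% snps, ,
             drop = FALSE]
  partners <- split(ld2$b, ld2$a)
  kept <- character(0)
  kept_chrom <- character(0)
  kept_pos <- numeric(0)
  for (i in ord) {
    id <- snps[i]
    close <- kept_chrom == chrom[i] & abs(kept_pos - pos[i]) <= window
    high_ld <- any(kept[close] %in% partners[[id]])
    if (!high_ld) {
      kept <- c(kept, id)
      kept_chrom <- c(kept_chrom, chrom[i])
      kept_pos <- c(kept_pos, pos[i])
    }
  }
  kept
}

#' Bin variants by MAF decile and gene-density decile
#'
#' Deciles are computed over the supplied tested-variant universe after
#' removing variants inside `exclude` regions (e.g. an HLA-like interval).
#' Gene density is the number of genes whose cis window (gene boundaries
#' +/- `window`) contains the variant.  If fewer than 10 distinct quantile
#' boundaries exist the bins are coarser, with a warning.
#'
#' @param variants Variant table with `chrom`, `pos` and a `maf` column (or
#'   `maf_pre`/`maf_post`, in which case the minimum is used).
#' @param gene_annotation Gene table.
#' @param window Cis window in bp (default 1e6).
#' @param exclude Optional data.frame of regions (`chrom`, `start`, `end`,
#'   0-based half-open) removed from the universe.
#' @return `variants` (minus exclusions) with `maf_bin`, `density_bin` and
#'   `bin` columns appended.
#' @export
bin_variants <- function(variants, gene_annotation, window = 1e6,
                         exclude = NULL) {
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- rep(FALSE, nrow(variants))
    for (k in seq_len(nrow(exclude))) {
      drop <- drop | (variants$chrom == exclude$chrom[k] &
                        variants$pos >= exclude$start[k] &
                        variants$pos < exclude$end[k])
    }
    variants <- variants[!drop, , drop = FALSE]
  }
  maf <- if ("maf" %in% names(variants)) variants$maf else
    pmin(variants$maf_pre, variants$maf_post)

  gene_win <- GenomicRanges::GRanges(
    gene_annotation$chrom,
    IRanges::IRanges(start = pmax(gene_annotation$start + 1 - window, 1),
                     end = gene_annotation$end + window))
  snps <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos + 1, width = 1))
  density <- GenomicRanges::countOverlaps(snps, gene_win)

  decile <- function(x, label) {
    br <- unique(quantile(x, probs = seq(0, 1, 0.1), names = FALSE))
    if (length(br) < 11L)
      warning(sprintf("fewer than 10 distinct %s deciles; using %d bins",
                      label, length(br) - 1L), call. = FALSE)
    if (length(br) < 2L) return(rep(1L, length(x)))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  variants$maf_bin <- decile(maf, "MAF")
  variants$density_bin <- decile(density, "gene-density")
  variants$gene_density <- density
  variants$bin <- paste(variants$maf_bin, variants$density_bin, sep = "_")
  variants
}

#' MAF/gene-density matched permutation enrichment
#'
#' Tests whether a GWAS-associated SNP set is enriched for eQTLs relative to
#' null sets matched on MAF decile and gene-density decile.  Per
#' permutation, each GWAS SNP is replaced by a uniform draw from its
#' (MAF, density) bin excluding itself (draws are independent across SNPs,
#' with replacement).  The fold statistic is the observed eQTL proportion
#' divided by the mean null proportion; the empirical p-value uses the
#' add-one rule `(r + 1) / (n_perm + 1)` with r the number of null folds at
#' least as extreme (>=) as the observed fold.
#'
#' @param gwas_set Character vector of (pruned, matched) GWAS SNP ids.
#' @param eqtl_set Character vector of eQTL variant ids.
#' @param binned Output of [bin_variants()] covering the tested universe.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer RNG seed.
#' @return List with `observed`, `null_mean`, `fold`, `p`, `n_perm`,
#'   `n_gwas_snps`.
#' @export
permutation_enrichment <- function(gwas_set, eqtl_set, binned,
                                   n_perm = 10000L, seed = 1L) {
  idx <- match(gwas_set, binned$variant_id)
  if (anyNA(idx)) stopf("GWAS SNPs absent from the binned universe")
  is_eqtl <- binned$variant_id %in% eqtl_set
  observed <- mean(is_eqtl[idx])

  bins <- split(seq_len(nrow(binned)), binned$bin)
  set.seed(seed)
  n_snp <- length(idx)
  null_mat <- matrix(0L, n_snp, n_perm)
  for (k in seq_len(n_snp)) {
    cand <- setdiff(bins[[binned$bin[idx[k]]]], idx[k])
    if (!length(cand))
      stopf("no matched candidates in the bin of SNP %s", gwas_set[k])
    draw <- cand[sample.int(length(cand), n_perm, replace = TRUE)]
    null_mat[k, ] <- as.integer(is_eqtl[draw])
  }
  null_prop <- colMeans(null_mat)
  null_mean <- mean(null_prop)
  fold <- observed / null_mean
  null_fold <- null_prop / null_mean
  r <- sum(null_fold >= fold)
  list(observed = observed, null_mean = null_mean, fold = fold,
       p = (r + 1) / (n_perm + 1), n_perm = n_perm, n_gwas_snps = n_snp)
}
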