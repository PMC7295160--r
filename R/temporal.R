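# Temporal-predominance classification of eQTLs -------------------------------

#' Combine per-cut scan results into one record table
#'
#' Merges the complete, prenatal and postnatal scan outputs on
#' (gene, variant), suffixing the statistic columns per cut, and optionally
#' attaches the signed TSS distance.
#'
#' @param complete,prenatal,postnatal Outputs of [eqtl_scan()] for the three
#'   cuts on the same pair list.
#' @param variants,gene_annotation Optional tables; when both are given a
#'   `tss_dist` column is added.
#' @return data.frame with `gene_id`, `variant_id`, and per-cut columns
#'   `beta_*`, `se_*`, `p_*`, `fdr_*`, `n_*`.
#' @export
combine_cuts <- function(complete, prenatal, postnatal, variants = NULL,
                         gene_annotation = NULL) {
  key <- paste(complete$gene_id, complete$variant_id)
  if (!identical(key, paste(prenatal$gene_id, prenatal$variant_id)) ||
      !identical(key, paste(postnatal$gene_id, postnatal$variant_id)))
    stopf("scan outputs must cover the same pairs in the same order")
  out <- data.frame(gene_id = complete$gene_id,
                    variant_id = complete$variant_id,
                    stringsAsFactors = FALSE)
  for (cut in c("complete", "prenatal", "postnatal")) {
    tab <- switch(cut, complete = complete, prenatal = prenatal,
                  postnatal = postnatal)
    for (col in c("beta", "se", "p", "fdr", "n"))
      out[[paste(col, cut, sep = "_")]] <- tab[[col]]
  }
  if (!is.null(variants) && !is.null(gene_annotation)) {
    v <- variants[match(out$variant_id, variants$variant_id), ]
    g <- gene_annotation[match(out$gene_id, gene_annotation$gene_id), ]
    out$tss_dist <- tss_distance(v, g)
  }
  out
}

#' Z-test comparing prenatal and postnatal effect sizes
#'
#' `z = (beta_pre - beta_post) / sqrt(se_pre^2 + se_post^2)`, with two-sided
#' normal p-value `2 * pnorm(-|z|)`.
#'
#' @param beta_pre,se_pre Prenatal-cut effect and standard error.
#' @param beta_post,se_post Postnatal-cut effect and standard error.
#' @return data.frame with columns `z` and `p`.
#' @export
z_test <- function(beta_pre, se_pre, beta_post, se_post) {
  if (any(se_pre <= 0, na.rm = TRUE) || any(se_post <= 0, na.rm = TRUE))
    stopf("standard errors must be positive")
  z <- (beta_pre - beta_post) / sqrt(se_pre^2 + se_post^2)
  data.frame(z = z, p = 2 * pnorm(-abs(z)))
}

#' Select the top variant per eGene
#'
#' Among each gene's pairs with FDR <= `fdr_max` in at least one cut, picks
#' the pair whose smallest FDR-significant p-value (over cuts where that
#' pair is significant) is smallest; exact ties are broken by smaller
#' absolute TSS distance, then lexicographic variant id.  Genes with no
#' significant pair are absent from the output.
#'
#' @param records Output of [combine_cuts()] (needs `tss_dist` for the tie
#'   break; missing distances are treated as infinite).
#' @param fdr_max FDR significance threshold (default 0.05).
#' @return Subset of `records`, one row per eGene, with columns `best_p`
#'   and `best_cut` appended.
#' @export
select_top <- function(records, fdr_max = 0.05) {
  cuts <- c("complete", "prenatal", "postnatal")
  fdr <- as.matrix(records[paste0("fdr_", cuts)])
  pmat <- as.matrix(records[paste0("p_", cuts)])
  sig <- !is.na(fdr) & fdr <= fdr_max
  pmat[!sig] <- NA
  any_sig <- rowSums(sig) > 0
  rec <- records[any_sig, , drop = FALSE]
  pmat <- pmat[any_sig, , drop = FALSE]
  rec$best_p <- suppressWarnings(apply(pmat, 1L, min, na.rm = TRUE))
  rec$best_cut <- cuts[max.col(-replace(pmat, is.na(pmat), Inf),
                               ties.method = "first")]
  tssd <- if ("tss_dist" %in% names(rec)) abs(rec$tss_dist) else
    rep(Inf, nrow(rec))
  ord <- order(rec$gene_id, rec$best_p, tssd, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]
  rec[!duplicated(rec$gene_id), , drop = FALSE]
}

# classification of one set of pairs given precomputed z FDR
classify_rows <- function(rec, z, z_fdr, fdr_max = 0.05, p_max = 0.05) {
  same_sign <- sign(rec$beta_prenatal) == sign(rec$beta_postnatal)
  constant <- !is.na(rec$fdr_complete) & rec$fdr_complete <= fdr_max &
    same_sign & rec$p_prenatal <= p_max & rec$p_postnatal <= p_max
  pre_pred <- !constant &
    !is.na(rec$fdr_prenatal) & rec$fdr_prenatal <= fdr_max &
    rec$p_postnatal > p_max & z_fdr <= fdr_max
  post_pred <- !constant & !pre_pred &
    !is.na(rec$fdr_postnatal) & rec$fdr_postnatal <= fdr_max &
    rec$p_prenatal > p_max & z_fdr <= fdr_max
  category <- ifelse(constant, "constant",
              ifelse(pre_pred, "prenatal_predominant",
              ifelse(post_pred, "postnatal_predominant",
              ifelse(rec$beta_prenatal > rec$beta_postnatal,
                     "prenatal_trending", "postnatal_trending"))))
  category
}

#' Classify top gene-variant pairs into five temporal categories
#'
#' Rules, evaluated in order on each gene's top pair:
#' * constant: complete-cut FDR <= 0.05, same direction of effect and
#'   unadjusted p <= 0.05 in both the prenatal and postnatal cuts;
#' * prenatal-predominant: prenatal FDR <= 0.05, postnatal unadjusted
#'   p > 0.05, and pre/post Z-test FDR-adjusted p <= 0.05;
#' * postnatal-predominant: the mirror image;
#' * otherwise prenatal-trending if `beta_pre > beta_post`, else
#'   postnatal-trending (exact ties to postnatal-trending).
#'
#' The Z-test FDR is Benjamini-Hochberg over the top pairs only (the
#' minimal coherent family).
#'
#' @param top Output of [select_top()].
#' @param fdr_max,p_max Thresholds (defaults 0.05).
#' @return `top` with columns `z`, `z_p`, `z_fdr`, `category` appended.
#' @export
classify_temporal <- function(top, fdr_max = 0.05, p_max = 0.05) {
  needed <- c("beta_prenatal", "se_prenatal", "beta_postnatal",
              "se_postnatal", "p_prenatal", "p_postnatal", "fdr_complete",
              "fdr_prenatal", "fdr_postnatal")
  if (anyNA(top[needed]))
    stopf("missing per-cut statistics for one or more top pairs")
  zt <- z_test(top$beta_prenatal, top$se_prenatal, top$beta_postnatal,
               top$se_postnatal)
  top$z <- zt$z
  top$z_p <- zt$p
  top$z_fdr <- bh_fdr(zt$p)
  top$category <- classify_rows(top, top$z, top$z_fdr, fdr_max, p_max)
  top
}

#' Propagate eGene categories to all significant eQTLs
#'
#' Every FDR-significant gene-variant pair inherits the temporal category of
#' its gene's top pair; pairs of genes with no classified top pair are
#' omitted.
#'
#' @param records Output of [combine_cuts()].
#' @param top_classified Output of [classify_temporal()].
#' @param fdr_max Significance threshold (default 0.05).
#' @return Significant pairs with a `category` column.
#' @export
propagate_categories <- function(records, top_classified, fdr_max = 0.05) {
  cuts <- paste0("fdr_", c("complete", "prenatal", "postnatal"))
  fdr <- as.matrix(records[cuts])
  sig <- rowSums(!is.na(fdr) & fdr <= fdr_max) > 0
  out <- records[sig, , drop = FALSE]
  out$category <- top_classified$category[
    match(out$gene_id, top_classified$gene_id)]
  out[!is.na(out$category), , drop = FALSE]
}

#' Alternative eGene category-assignment schemes
#'
#' Compares the top-variant eGene classification against three alternatives:
#' (1) "majority": each eGene takes the most common individually assigned
#' category of its significant eQTLs, ties resolved in the order constant,
#' prenatal-predominant, postnatal-predominant, prenatal-trending,
#' postnatal-trending; (2) "second": the category of the gene's
#' second-most-significant pair (genes with a single significant pair are
#' reported separately); (3) "individual": every significant eQTL classified
#' on its own.  For each scheme a concordance table gives, per top-variant
#' category, the percentage assigned to each category.
#'
#' @param records Output of [combine_cuts()].
#' @param top_classified Output of [classify_temporal()].
#' @param fdr_max Significance threshold (default 0.05).
#' @return List with `individual` (per-eQTL table), `majority`, `second`
#'   (per-eGene tables; `second` has an attribute `"single_pair_genes"`),
#'   and `concordance` (a list of percentage matrices keyed by scheme).
#' @export
alternative_assignments <- function(records, top_classified,
                                    fdr_max = 0.05) {
  cuts <- paste0("fdr_", c("complete", "prenatal", "postnatal"))
  fdr <- as.matrix(records[cuts])
  sig_rows <- rowSums(!is.na(fdr) & fdr <= fdr_max) > 0
  sig <- records[sig_rows, , drop = FALSE]
  sig <- sig[stats::complete.cases(
    sig[c("beta_prenatal", "se_prenatal", "beta_postnatal",
          "se_postnatal")]), , drop = FALSE]
  zt <- z_test(sig$beta_prenatal, sig$se_prenatal, sig$beta_postnatal,
               sig$se_postnatal)
  z_fdr <- bh_fdr(zt$p)
  sig$category <- classify_rows(sig, zt$z, z_fdr, fdr_max)

  cat_order <- c("constant", "prenatal_predominant", "postnatal_predominant",
                 "prenatal_trending", "postnatal_trending")

  # (1) majority with the stated tie order
  majority <- vapply(split(sig$category, sig$gene_id), function(cc) {
    counts <- table(factor(cc, levels = cat_order))
    cat_order[which.max(counts)]
  }, character(1))
  majority <- data.frame(gene_id = names(majority), category = majority,
                         row.names = NULL, stringsAsFactors = FALSE)

  # (2) second most significant pair per gene
  pmin_cut <- suppressWarnings(apply(
    as.matrix(sig[paste0("p_", c("complete", "prenatal", "postnatal"))]),
    1L, min, na.rm = TRUE))
  second <- do.call(rbind, lapply(split(seq_len(nrow(sig)), sig$gene_id),
    function(idx) {
      if (length(idx) < 2L) return(NULL)
      second_idx <- idx[order(pmin_cut[idx])][2L]
      data.frame(gene_id = sig$gene_id[second_idx],
                 category = sig$category[second_idx],
                 stringsAsFactors = FALSE)
    }))
  rownames(second) <- NULL
  single <- setdiff(unique(sig$gene_id), second$gene_id)
  attr(second, "single_pair_genes") <- single

  top_cat <- setNames(top_classified$category, top_classified$gene_id)
  conc <- function(alt, by_gene = TRUE) {
    ref <- top_cat[alt$gene_id]
    tab <- table(factor(ref, levels = cat_order),
                 factor(alt$category, levels = cat_order))
    prop <- prop.table(tab, margin = 1L) * 100
    prop[is.nan(prop)] <- 0
    prop
  }
  list(individual = sig[c("gene_id", "variant_id", "category")],
       majority = majority, second = second,
       concordance = list(
         majority = conc(majority),
         second = conc(second),
         individual = conc(sig[c("gene_id", "category")])))
}

#' Differential expression variance between prenatal and postnatal stages
#'
#' Within each stage separately, residualizes each gene's expression on
#' period (categorical), sex and five ancestry principal components, then
#' compares residual variances with an F test:
#' `F = var_pre / var_post` on `(n_pre - k_pre, n_post - k_post)` degrees of
#' freedom, two-sided p by doubling the smaller tail, Benjamini-Hochberg
#' over genes, and a direction call at `fdr_max`.
#'
#' @param expr Genes x samples matrix (log2CPM).
#' @param sample_table Aligned sample table with ancestry PCs.
#' @param n_pcs Ancestry PCs used (default 5).
#' @param fdr_max Direction-call threshold (default 0.05).
#' @return data.frame with `gene_id`, `var_pre`, `var_post`, `f`, `df_pre`,
#'   `df_post`, `p`, `fdr`, `direction`.
#' @export
variance_f_test <- function(expr, sample_table, n_pcs = 5L,
                            fdr_max = 0.05) {
  check_sample_table(sample_table)
  resid_var <- function(stage) {
    keep <- sample_table$stage == stage
    st <- sample_table[keep, , drop = FALSE]
    X <- eqtl_design(st, n_pcs)
    df <- sum(keep) - ncol(X)
    if (df <= 0) stopf("stage '%s' has no residual degrees of freedom",
                       stage)
    r <- t(qr.resid(qr(X), t(expr[, keep, drop = FALSE])))
    list(v = rowSums(r^2) / df, df = df)
  }
  pre <- resid_var("prenatal")
  post <- resid_var("postnatal")
  f <- pre$v / post$v
  p <- 2 * pmin(pf(f, pre$df, post$df, lower.tail = FALSE),
                pf(f, pre$df, post$df))
  p <- pmin(p, 1)
  fdr <- bh_fdr(p)
  data.frame(
    gene_id = rownames(expr) %||% seq_len(nrow(expr)),
    var_pre = pre$v, var_post = post$v, f = f,
    df_pre = pre$df, df_post = post$df, p = p, fdr = fdr,
    direction = ifelse(fdr <= fdr_max,
                       ifelse(f > 1, "greater_prenatal", "greater_postnatal"),
                       "ns"),
    row.names = NULL, stringsAsFactors = FALSE)
}
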