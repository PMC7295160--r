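# End-to-end synthetic cohort -------------------------------------------------

#' Simulate a complete developmental eQTL cohort
#'
#' Convenience wrapper chaining the generator stages: samples, gene
#' annotation, genotypes, and trajectory-structured expression with
#' optionally planted eQTL effects.  Defaults mirror the study layout the
#' downstream cuts assume: 176 samples (112 prenatal, 4 transitional, 60
#' postnatal) and variants with allele frequency in `[0.05, 0.5]` in
#' Hardy-Weinberg equilibrium.
#'
#' When `n_eqtl > 0`, planted effects are assigned to distinct random genes
#' and a cis variant of each, in three equal parts: constant
#' (`beta_pre = beta_post = beta`), prenatal-predominant
#' (`beta_pre = beta, beta_post = 0`) and postnatal-predominant
#' (`beta_pre = 0, beta_post = beta`).
#'
#' @param n_genes,n_variants Numbers of genes and variants.
#' @param n_per_period Cohort layout (default [default_n_per_period()]).
#' @param traj Trajectory spec (default [trajectory_spec()]).
#' @param n_eqtl Number of planted eQTLs (default 0).
#' @param beta Planted effect size per alternate allele (log2 units).
#' @param min_maf Minimum generating allele frequency for planted variants.
#' @param n_chrom,chrom_length Chromosome layout.
#' @param library_size Reads per sample.
#' @param seed Integer RNG seed.
#' @return List with `samples`, `genes`, `genotypes`, `counts`, `group`
#'   (generating trajectory groups), and `eqtl` (the planted [eqtl_spec()]
#'   with a `type` column, or NULL).
#' @export
simulate_cohort <- function(n_genes = 2000L, n_variants = 20000L,
                            n_per_period = default_n_per_period(),
                            traj = trajectory_spec(), n_eqtl = 0L,
                            beta = 0.8, min_maf = 0.05, n_chrom = 4L,
                            chrom_length = 2e8, library_size = 3e7,
                            seed = 1L) {
  samples <- simulate_samples(n_per_period = n_per_period, seed = seed)
  genes <- simulate_genes(n_genes, n_chrom = n_chrom,
                          chrom_length = chrom_length, seed = seed + 1L)
  genotypes <- simulate_genotypes(n_variants, samples,
                                  maf_range = c(max(min_maf, 0.05), 0.5),
                                  n_chrom = n_chrom,
                                  chrom_length = chrom_length,
                                  seed = seed + 2L)
  eq <- NULL
  if (n_eqtl > 0) {
    set.seed(seed + 3L)
    pairs <- cis_pairs(genotypes$variants, genes)
    ok_v <- genotypes$variants$variant_id[genotypes$variants$af >= min_maf]
    pairs <- pairs[pairs$variant_id %in% ok_v, , drop = FALSE]
    genes_avail <- unique(pairs$gene_id)
    if (length(genes_avail) < n_eqtl)
      stopf("only %d genes have an eligible cis variant (< %d requested)",
            length(genes_avail), n_eqtl)
    pick_genes <- sample(genes_avail, n_eqtl)
    pick_var <- vapply(pick_genes, function(g) {
      cand <- pairs$variant_id[pairs$gene_id == g]
      cand[sample.int(length(cand), 1L)]
    }, character(1))
    type <- rep_len(c("constant", "prenatal_predominant",
                      "postnatal_predominant"), n_eqtl)
    eq <- eqtl_spec(
      gene_id = pick_genes, variant_id = pick_var,
      beta_pre = ifelse(type == "postnatal_predominant", 0, beta),
      beta_post = ifelse(type == "prenatal_predominant", 0, beta),
      gene_annotation = genes, variants = genotypes$variants)
    eq$type <- type
  }
  expr <- simulate_expression(samples, genes, traj, genotypes = genotypes,
                              eqtl = eq, library_size = library_size,
                              seed = seed + 4L)
  list(samples = samples, genes = genes, genotypes = genotypes,
       counts = expr$counts, group = expr$group, eqtl = eq)
}

#' Run the three-cut eQTL scan on a cohort
#'
#' Filters variants, enumerates cis pairs, runs the complete, prenatal and
#' postnatal scans and combines them into one record table with TSS
#' distances.
#'
#' @param expr Adjusted genes x samples expression matrix.
#' @param cohort Output of [simulate_cohort()] (or a list with the same
#'   `samples`, `genes`, `genotypes` components).
#' @param window Cis window in bp (default 1e6).
#' @param maf_min,hwe_p_min Variant filters (defaults 0.05 and 1e-12).
#' @return Output of [combine_cuts()].
#' @export
run_eqtl_cuts <- function(expr, cohort, window = 1e6, maf_min = 0.05,
                          hwe_p_min = 1e-12) {
  vars <- filter_variants(cohort$genotypes$variants,
                          cohort$genotypes$dosage, cohort$samples,
                          maf_min = maf_min, hwe_p_min = hwe_p_min)
  genes <- cohort$genes[cohort$genes$gene_id %in% rownames(expr), ,
                        drop = FALSE]
  pairs <- cis_pairs(vars, genes, window = window)
  scans <- lapply(c("complete", "prenatal", "postnatal"), function(cut)
    eqtl_scan(expr, cohort$genotypes$dosage, cohort$samples, pairs,
              cut = cut))
  combine_cuts(scans[[1]], scans[[2]], scans[[3]],
               variants = vars, gene_annotation = genes)
}
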