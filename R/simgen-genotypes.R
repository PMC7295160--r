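# Synthetic gene annotation and genotypes ------------------------------------

#' Simulate a gene annotation table
#'
#' Places genes uniformly on a set of synthetic chromosomes.  Coordinates are
#' 0-based half-open; the transcription start site is `start` for + strand
#' genes and `end - 1` for - strand genes.  Protein-coding genes receive a
#' loss-of-function-intolerance (pLI) score drawn from a U-shaped Beta
#' distribution; noncoding genes have missing pLI.
#'
#' @param n_genes Number of genes.
#' @param n_chrom Number of chromosomes (default 4).
#' @param chrom_length Chromosome length in bp (default 2e8, long enough for
#'   10-100 Mb distant-pair sampling).
#' @param gene_length Range of gene lengths in bp.
#' @param prop_coding Proportion of protein-coding genes.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `biotype`, `pli`.
#' @export
simulate_genes <- function(n_genes, n_chrom = 4L, chrom_length = 2e8,
                           gene_length = c(5e3, 2e5), prop_coding = 0.685,
                           seed = 1L) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  set.seed(seed)
  chrom <- paste0("chr", sort(rep_len(seq_len(n_chrom), n_genes)))
  len <- round(runif(n_genes, gene_length[1], gene_length[2]))
  start <- floor(runif(n_genes, 0, chrom_length - len))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  coding <- runif(n_genes) < prop_coding
  ann <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n_genes)),
    chrom = chrom,
    start = start,
    end = start + len,
    strand = strand,
    biotype = ifelse(coding, "protein_coding", "noncoding"),
    pli = ifelse(coding, stats::rbeta(n_genes, 0.2, 0.2), NA_real_),
    stringsAsFactors = FALSE
  )
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  ann[order(ann$chrom, ann$start), ]
}

# Latent Gaussian correlation giving haplotype-indicator correlation r_target
# at allele frequency p: solves P(Z1<q, Z2<q; rho) = p^2 + r*p*(1-p) by
# numerical integration of the bivariate normal orthant.
copula_rho <- function(r_target, p) {
  if (r_target <= 0) return(0)
  q <- qnorm(p)
  orthant <- function(rho) {
    f <- function(z) pnorm((q - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
    integrate(f, -Inf, q)$value
  }
  target <- p^2 + r_target * p * (1 - p)
  stats::uniroot(function(rho) orthant(rho) - target,
                 interval = c(1e-6, 1 - 1e-6), tol = 1e-8)$root
}

#' Simulate biallelic genotypes in Hardy-Weinberg equilibrium
#'
#' Draws per-variant allele frequencies uniformly in `maf_range` and
#' genotypes as the sum of two haplotype indicators obtained by thresholding
#' latent Gaussians, so each variant is in Hardy-Weinberg equilibrium.
#' Consecutive variants on the same chromosome are grouped into blocks of
#' `block_size`; within a block the latent Gaussians are equicorrelated with
#' a correlation solved numerically so that pairwise genotype r-squared is
#' approximately `within_block_r2`.  Realized minor-allele frequencies in the
#' prenatal and postnatal sample subsets and an exact (mid-p) Hardy-Weinberg
#' test p-value are recorded per variant.
#'
#' @param n_variants Number of variants.
#' @param sample_table Sample table from [simulate_samples()].
#' @param maf_range Allele-frequency sampling range, a subset of
#'   `[0.01, 0.5]`.
#' @param block_size Number of consecutive variants per LD block (default 1,
#'   i.e. independent variants).
#' @param within_block_r2 Target pairwise genotype r-squared within a block.
#' @param n_chrom,chrom_length Chromosome layout (must match the gene
#'   annotation when used together).
#' @param seed Integer RNG seed.
#' @return A list with `variants` (data.frame: `variant_id`, `chrom`, `pos`
#'   0-based, `ref`, `alt`, `af`, `maf_pre`, `maf_post`, `hwe_p`, `block`)
#'   and `dosage` (variants x samples integer matrix with entries 0/1/2).
#' @export
simulate_genotypes <- function(n_variants, sample_table,
                               maf_range = c(0.05, 0.5),
                               block_size = 1L, within_block_r2 = 0,
                               n_chrom = 4L, chrom_length = 2e8,
                               seed = 1L) {
  check_sample_table(sample_table)
  n <- nrow(sample_table)
  if (n < 2) stopf("need at least 2 samples to simulate genotypes")
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stopf("maf_range must be an ordered subset of [0.01, 0.5]")
  if (block_size < 1) stopf("block_size must be >= 1")

  set.seed(seed)
  chrom <- paste0("chr", sort(rep_len(seq_len(n_chrom), n_variants)))
  pos <- unlist(lapply(split(seq_len(n_variants), chrom), function(idx) {
    sort(sample.int(chrom_length, length(idx)))
  }), use.names = FALSE)
  chrom <- sort(chrom)   # split() ordering above is by sorted chrom name
  af <- runif(n_variants, maf_range[1], maf_range[2])

  # block index: consecutive variants within a chromosome
  block <- unlist(lapply(split(seq_len(n_variants), chrom), function(idx) {
    ceiling(seq_along(idx) / block_size)
  }), use.names = FALSE)
  block_id <- paste(chrom, block, sep = "_")

  rho <- if (block_size > 1L && within_block_r2 > 0)
    copula_rho(sqrt(within_block_r2), mean(af)) else 0

  dosage <- matrix(0L, n_variants, n)
  for (h in 1:2) {
    e <- matrix(rnorm(n_variants * n), n_variants, n)
    if (rho > 0) {
      shared <- matrix(rnorm(length(unique(block_id)) * n), ncol = n,
                       dimnames = list(unique(block_id), NULL))
      z <- sqrt(rho) * shared[block_id, , drop = FALSE] + sqrt(1 - rho) * e
    } else z <- e
    dosage <- dosage + (z < qnorm(af))
  }
  storage.mode(dosage) <- "integer"

  ref_alt <- matrix(replicate(n_variants,
                              sample(c("A", "C", "G", "T"), 2L)), nrow = 2L)
  pre <- sample_table$stage == "prenatal"
  post <- sample_table$stage == "postnatal"
  maf_of <- function(m) {
    f <- rowMeans(m) / 2
    pmin(f, 1 - f)
  }
  n_alt <- rowSums(dosage == 2L)
  n_het <- rowSums(dosage == 1L)
  n_ref <- n - n_alt - n_het

  variants <- data.frame(
    variant_id = sprintf("V%06d", seq_len(n_variants)),
    chrom = chrom,
    pos = pos,
    ref = ref_alt[1, ],
    alt = ref_alt[2, ],
    af = af,
    maf_pre = if (any(pre)) maf_of(dosage[, pre, drop = FALSE]) else NA_real_,
    maf_post = if (any(post)) maf_of(dosage[, post, drop = FALSE]) else NA_real_,
    hwe_p = hwe_exact_test(n_ref, n_het, n_alt),
    block = block_id,
    stringsAsFactors = FALSE
  )
  rownames(dosage) <- variants$variant_id
  colnames(dosage) <- sample_table$sample_id
  list(variants = variants, dosage = dosage)
}
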