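# Trajectory-structured expression with planted eQTL effects ------------------

#' Specify a mixture of polynomial expression trajectories
#'
#' Defines the generative model for gene-level log2 expression across
#' development: each gene belongs to one of K groups, each group has a
#' polynomial mean trajectory (degree <= 4) on transformed age, and Gaussian
#' noise is added on the log2 scale.  The age transform is
#' `u = (log2(age_days) - age_center) / age_scale`, which keeps prenatal and
#' postnatal ranges on a comparable footing.
#'
#' The default is the three-group structure used throughout the package:
#' "rising" genes (higher postnatal expression), "falling" genes (higher
#' prenatal expression) and "flat" genes, with mixing proportions
#' 0.29 / 0.22 / 0.49 and slopes chosen so the epoch-3 minus epoch-1 deltas
#' are roughly +2 / -1 / 0 log2 units.
#'
#' @param coef K x (degree+1) matrix of polynomial coefficients on the
#'   transformed age `u` (column j is the coefficient of `u^(j-1)`); row
#'   names are group labels.
#' @param mixing Mixing proportions (must sum to 1).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param offset_sd Standard deviation of per-gene baseline offsets
#'   (between-gene expression-level spread).
#' @param age_center,age_scale Parameters of the age transform.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(coef = NULL,
                            mixing = c(rising = 0.29, falling = 0.22,
                                       flat = 0.49),
                            noise_sd = 0.5, offset_sd = 2,
                            age_center = 8, age_scale = 2) {
  if (is.null(coef)) {
    coef <- rbind(rising  = c(0,  0.80, 0, 0, 0),
                  falling = c(0, -0.45, 0, 0, 0),
                  flat    = c(0,  0.00, 0, 0, 0))
  }
  coef <- as.matrix(coef)
  if (ncol(coef) > 5L) stopf("trajectory polynomials must have degree <= 4")
  if (nrow(coef) != length(mixing))
    stopf("coef rows and mixing proportions must agree")
  if (abs(sum(mixing) - 1) > 1e-8) stopf("mixing proportions must sum to 1")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (is.null(rownames(coef))) rownames(coef) <- names(mixing)
  structure(list(coef = coef, mixing = mixing, noise_sd = noise_sd,
                 offset_sd = offset_sd, age_center = age_center,
                 age_scale = age_scale),
            class = "trajectory_spec")
}

#' Transform post-conception age for trajectory polynomials
#'
#' @param age_days Age in post-conception days.
#' @param spec A [trajectory_spec()].
#' @return Transformed age `u`.
#' @export
transform_age <- function(age_days, spec) {
  (log2(age_days) - spec$age_center) / spec$age_scale
}

#' Specify planted cis-eQTL effects
#'
#' Each row plants an additive effect of a variant's alternate-allele dosage
#' on its target gene's log2 expression: `beta_pre` per allele in prenatal
#' samples, `beta_post` in postnatal samples (transitional samples receive
#' the mean of the two).  When annotation and variants are supplied, every
#' planted variant must lie within the cis window of its target gene.
#'
#' @param gene_id,variant_id Character vectors naming target genes/variants.
#' @param beta_pre,beta_post Effects per alternate allele on log2 expression.
#' @param gene_annotation,variants Optional tables used to validate the cis
#'   constraint.
#' @param window Cis window in bp from gene boundaries (default 1e6).
#' @return data.frame of class `eqtl_spec`.
#' @export
eqtl_spec <- function(gene_id, variant_id, beta_pre, beta_post,
                      gene_annotation = NULL, variants = NULL,
                      window = 1e6) {
  spec <- data.frame(gene_id = gene_id, variant_id = variant_id,
                     beta_pre = beta_pre, beta_post = beta_post,
                     stringsAsFactors = FALSE)
  if (!is.null(gene_annotation) && !is.null(variants)) {
    g <- gene_annotation[match(spec$gene_id, gene_annotation$gene_id), ]
    v <- variants[match(spec$variant_id, variants$variant_id), ]
    if (anyNA(g$gene_id)) stopf("eqtl_spec names genes absent from annotation")
    if (anyNA(v$variant_id)) stopf("eqtl_spec names unknown variants")
    ok <- g$chrom == v$chrom & v$pos >= g$start - window &
      v$pos < g$end + window
    if (!all(ok))
      stopf("planted variants outside the %g bp cis window: %s", window,
            paste(spec$variant_id[!ok], collapse = ", "))
  }
  class(spec) <- c("eqtl_spec", "data.frame")
  spec
}

#' Simulate a gene x sample read-count matrix
#'
#' Generates per-gene mean log2 expression as group polynomial trajectory
#' (on transformed age) plus a per-gene baseline offset, planted eQTL dosage
#' effects, an optional additive sex effect, and Gaussian noise.  The log2
#' means are interpreted as relative expression: per sample, target CPM
#' values are renormalized to sum to one million (CPM is compositional) and
#' inverted against `library_size` to integer read counts.
#'
#' @param sample_table Sample table from [simulate_samples()].
#' @param gene_annotation Gene table from [simulate_genes()].
#' @param traj A [trajectory_spec()].
#' @param genotypes Output of [simulate_genotypes()]; required when `eqtl`
#'   is supplied.
#' @param eqtl Optional [eqtl_spec()] of planted effects.
#' @param library_size Target reads per sample (default 3e7).
#' @param sex_effect Additive log2 shift applied to male samples (default 0).
#' @param baseline Global baseline log2 level; default `log2(1e6 / n_genes)`
#'   so that an all-flat matrix is compositionally self-consistent.
#' @param seed Integer RNG seed.
#' @return A list with `counts` (integer genes x samples matrix), `group`
#'   (generating group per gene), `offset` (per-gene baseline offsets) and
#'   `mean_log2` (the noiseless generative log2 means).
#' @export
simulate_expression <- function(sample_table, gene_annotation, traj,
                                genotypes = NULL, eqtl = NULL,
                                library_size = 3e7, sex_effect = 0,
                                baseline = NULL, seed = 1L) {
  check_sample_table(sample_table)
  stopifnot(inherits(traj, "trajectory_spec"))
  n_genes <- nrow(gene_annotation)
  n <- nrow(sample_table)
  if (is.null(baseline)) baseline <- log2(1e6 / n_genes)

  set.seed(seed)
  grp <- sample(rownames(traj$coef), n_genes, replace = TRUE,
                prob = traj$mixing)
  u <- transform_age(sample_table$age_days, traj)
  basis <- outer(u, 0:(ncol(traj$coef) - 1L), `^`)           # samples x deg+1
  curves <- basis %*% t(traj$coef)                           # samples x K
  offset <- rnorm(n_genes, 0, traj$offset_sd)

  mean_log2 <- matrix(baseline, n_genes, n) + offset +
    t(curves)[grp, , drop = FALSE]
  if (sex_effect != 0)
    mean_log2 <- mean_log2 +
      matrix(sex_effect * (sample_table$sex == "male"),
             n_genes, n, byrow = TRUE)

  if (!is.null(eqtl)) {
    if (is.null(genotypes)) stopf("planting eQTLs requires genotypes")
    gi <- match(eqtl$gene_id, gene_annotation$gene_id)
    vi <- match(eqtl$variant_id, rownames(genotypes$dosage))
    if (anyNA(gi)) stopf("eqtl spec names genes absent from the annotation")
    if (anyNA(vi)) stopf("eqtl spec names variants absent from the genotypes")
    stage_beta <- cbind(prenatal = eqtl$beta_pre,
                        transitional = (eqtl$beta_pre + eqtl$beta_post) / 2,
                        postnatal = eqtl$beta_post)
    stage_idx <- match(sample_table$stage,
                       c("prenatal", "transitional", "postnatal"))
    for (k in seq_len(nrow(eqtl))) {
      mean_log2[gi[k], ] <- mean_log2[gi[k], ] +
        genotypes$dosage[vi[k], ] * stage_beta[k, stage_idx]
    }
  }

  x <- mean_log2
  if (traj$noise_sd > 0)
    x <- x + matrix(rnorm(n_genes * n, 0, traj$noise_sd), n_genes, n)

  cpm <- 2^x
  cpm <- sweep(cpm, 2L, colSums(cpm) / 1e6, `/`)   # compositional closure
  counts <- round(cpm * (library_size / 1e6))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_annotation$gene_id, sample_table$sample_id)

  list(counts = counts, group = setNames(grp, gene_annotation$gene_id),
       offset = offset, mean_log2 = mean_log2)
}
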