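# Variant filtering, cis pairs, association scan, FDR, genomic control

test_that("exact HWE test matches a permutation oracle at small n", {
  # oracle: empirical distribution of heterozygote counts under random
  # pairing of the observed alleles
  perm_hwe <- function(n_aa, n_ab, n_bb, B = 80000L) {
    alleles <- rep(c(0L, 1L), c(2 * n_aa + n_ab, 2 * n_bb + n_ab))
    obs_het <- n_ab
    set.seed(99)
    hets <- replicate(B, {
      a <- sample(alleles)
      sum(a[c(TRUE, FALSE)] != a[c(FALSE, TRUE)])
    })
    tab <- table(hets) / B
    p_obs <- tab[as.character(obs_het)]
    sum(tab[tab <= p_obs + 1e-9]) - 0.5 * p_obs   # mid-p
  }
  for (cfg in list(c(4, 2, 4), c(7, 1, 2), c(3, 6, 1))) {
    expect_lt(abs(hwe_exact_test(cfg[1], cfg[2], cfg[3]) -
                    perm_hwe(cfg[1], cfg[2], cfg[3])), 0.01)
  }
  # strong disequilibrium is detected
  expect_lt(hwe_exact_test(50, 0, 50), 1e-12)
})

test_that("variant filter enforces subset MAFs and HWE", {
  st <- simulate_samples(seed = 70L)
  pre <- st$stage == "prenatal"; post <- st$stage == "postnatal"
  n <- nrow(st)
  mk <- function(maf_pre, maf_post) {
    d <- integer(n)
    d[pre] <- rbinom(sum(pre), 2, maf_pre)
    d[post] <- rbinom(sum(post), 2, maf_post)
    d
  }
  set.seed(71)
  dos <- rbind(ok = mk(0.3, 0.3), low_post = mk(0.06, 0.005),
               mono = rep(0L, n))
  # force exact subset frequencies for the borderline variant
  dos["low_post", post] <- rep(c(1L, 0L), c(4L, sum(post) - 4L)) # maf 0.033
  vars <- data.frame(variant_id = rownames(dos), chrom = "chr1",
                     pos = c(100L, 200L, 300L))
  kept <- filter_variants(vars, dos, st)
  expect_equal(kept$variant_id, "ok")
  expect_error(filter_variants(vars, dos[, 1:3], st[1:3, ]), "samples")
})

test_that("cis windows are half-open from the gene boundaries", {
  genes <- data.frame(gene_id = "g", chrom = "chr1",
                      start = 1000000L, end = 1010000L)
  vars <- data.frame(variant_id = c("in_edge", "out_edge", "body", "far"),
                     chrom = "chr1",
                     pos = c(2009999L, 2010000L, 1005000L, 5e7))
  pairs <- cis_pairs(vars, genes, window = 1e6)
  expect_setequal(pairs$variant_id, c("in_edge", "body"))
  # lower boundary: start - window included
  vars2 <- data.frame(variant_id = c("at_low", "below"), chrom = "chr1",
                      pos = c(0L, -1L))
  genes2 <- data.frame(gene_id = "g", chrom = "chr1", start = 1000000L,
                       end = 1010000L)
  expect_equal(cis_pairs(vars2, genes2, window = 1e6)$variant_id, "at_low")
})

test_that("scan statistics equal closed-form OLS on random designs", {
  set.seed(80)
  st <- simulate_samples(seed = 80L)
  n <- nrow(st)
  for (rep in 1:50) {
    expr <- matrix(rnorm(n), 1, n, dimnames = list("g", st$sample_id))
    dos <- matrix(rbinom(n, 2, runif(1, 0.1, 0.5)), 1, n,
                  dimnames = list("v", st$sample_id))
    cut <- sample(c("complete", "prenatal", "postnatal"), 1)
    res <- eqtl_scan(expr, dos, st,
                     data.frame(gene_id = "g", variant_id = "v"),
                     cut = cut)
    keep <- switch(cut, complete = rep(TRUE, n),
                   prenatal = st$stage == "prenatal",
                   postnatal = st$stage == "postnatal")
    sti <- st[keep, ]
    X <- cbind(dos[1, keep],
               model.matrix(~ factor(period) + sex + pc1 + pc2 + pc3 +
                              pc4 + pc5, sti))
    oracle <- ols_oracle(expr[1, keep], X)
    expect_equal(res$beta, oracle$beta[1], tolerance = 1e-8)
    expect_equal(res$se, unname(oracle$se[1]), tolerance = 1e-8)
    expect_equal(res$p, unname(oracle$p[1]), tolerance = 1e-8)
    expect_equal(res$n, sum(keep))
  }
})

test_that("scan is equivariant to allele flips and drops constant dosages", {
  co <- small_cohort(n_genes = 30L, n_variants = 2000L, seed = 81L)
  l2 <- compute_log2cpm(co$counts)
  pairs <- head(cis_pairs(co$genotypes$variants, co$genes), 20L)
  r1 <- eqtl_scan(l2, co$genotypes$dosage, co$samples, pairs, "complete")
  r2 <- eqtl_scan(l2, 2L - co$genotypes$dosage, co$samples, pairs,
                  "complete")
  expect_equal(r1$beta, -r2$beta, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  # constant dosage -> missing statistics, excluded from FDR
  dos <- co$genotypes$dosage
  dos[pairs$variant_id[1], ] <- 1L
  r3 <- eqtl_scan(l2, dos, co$samples, pairs, "complete")
  expect_true(is.na(r3$beta[1]) && is.na(r3$fdr[1]))
  expect_false(anyNA(r3$fdr[-1]))
})

test_that("BH adjustment matches exhaustive step-up on all orderings", {
  base_p <- c(0.003, 0.04, 0.19, 0.25, 0.78, 0.99)
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  for (i in seq_len(nrow(perms))) {
    p <- base_p[as.integer(perms[i, ])]
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  # adjusted values are monotone in the raw p-values
  set.seed(5)
  p <- runif(50)
  expect_true(all(diff(bh_fdr(sort(p))) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("TSS distances are signed by strand", {
  gplus <- data.frame(chrom = "chr1", tss = 100L, strand = "+")
  gminus <- data.frame(chrom = "chr1", tss = 100L, strand = "-")
  v <- data.frame(chrom = "chr1", pos = 150L)
  expect_equal(tss_distance(v, gplus), 50L)
  expect_equal(tss_distance(v, gminus), -50L)
  expect_equal(tss_distance(data.frame(chrom = "chr1", pos = 100L), gplus),
               0L)
  expect_error(tss_distance(data.frame(chrom = "chr2", pos = 1L), gplus),
               "chromosome")
})

test_that("lambda is 1 at p = 0.5 and follows the quantile arithmetic", {
  expect_equal(lambda_gc(rep(0.5, 11)), 1, tolerance = 1e-9)
  # all p = 0.05: qchisq(0.95, 1) / chi2 median = 3.8415 / 0.45494
  expect_equal(lambda_gc(rep(0.05, 11)), 8.444, tolerance = 1e-3)
})

test_that("distant-pair lambda is calibrated on a null cohort", {
  co <- small_cohort(n_genes = 400L, n_variants = 4000L, seed = 83L)
  l2 <- compute_log2cpm(co$counts)
  adj <- adjust_expression(l2, co$samples, n_hidden = 5L)
  gc <- genomic_control(adj, co$genotypes$dosage, co$samples,
                        co$genotypes$variants, co$genes, n_reps = 25L,
                        seed = 84L)
  expect_length(gc$lambdas, 25L)
  expect_true(all(gc$lambdas > 0))
  expect_gt(gc$median_lambda, 0.9)
  expect_lt(gc$median_lambda, 1.1)
  expect_error(
    genomic_control(adj, co$genotypes$dosage, co$samples,
                    co$genotypes$variants, co$genes,
                    min_dist = 2.5e8, max_dist = 3e8, seed = 1L),
    "eligible")
})
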