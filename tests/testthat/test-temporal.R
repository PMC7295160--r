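# Temporal-predominance classification and differential variance

# build a one-row record with the given statistics
rec_row <- function(gene = "g1", variant = "v1",
                    beta = c(1, 1, 1), se = c(0.1, 0.1, 0.1),
                    p = c(0.01, 0.01, 0.01), fdr = p, tss = 100L) {
  cuts <- c("complete", "prenatal", "postnatal")
  out <- data.frame(gene_id = gene, variant_id = variant,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cuts)) {
    out[[paste0("beta_", cuts[i])]] <- beta[i]
    out[[paste0("se_", cuts[i])]] <- se[i]
    out[[paste0("p_", cuts[i])]] <- p[i]
    out[[paste0("fdr_", cuts[i])]] <- fdr[i]
    out[[paste0("n_", cuts[i])]] <- 100L
  }
  out$tss_dist <- tss
  out
}

test_that("Z-test contrast matches normal-tail arithmetic", {
  zt <- z_test(1, 1, 1, 1)
  expect_equal(zt$z, 0)
  expect_equal(zt$p, 1)
  zt2 <- z_test(1.0, 0.3, 0.2, 0.4)
  expect_equal(zt2$z, 1.6)                       # 0.8 / sqrt(0.09 + 0.16)
  expect_equal(zt2$p, 0.1096, tolerance = 1e-4)  # 2 * pnorm(-1.6)
  zt3 <- z_test(0.2, 0.4, 1.0, 0.3)
  expect_equal(zt3$z, -zt2$z)
  expect_equal(zt3$p, zt2$p)
  expect_error(z_test(1, 0, 1, 1), "positive")
})

test_that("top-variant selection uses smallest significant p then TSS", {
  recs <- rbind(
    rec_row("g1", "v1", p = c(1e-8, 0.5, 0.5), fdr = c(0.01, 0.9, 0.9)),
    rec_row("g1", "v2", p = c(1e-5, 0.5, 0.5), fdr = c(0.02, 0.9, 0.9)),
    # significant only in the prenatal cut: competes with its prenatal p
    rec_row("g2", "v3", p = c(0.2, 1e-6, 0.4), fdr = c(0.6, 0.01, 0.8)),
    # g3: exact tie in p -> smaller |tss| wins
    rec_row("g3", "v4", p = c(1e-4, 0.5, 0.5), fdr = c(0.03, 1, 1),
            tss = -500L),
    rec_row("g3", "v5", p = c(1e-4, 0.5, 0.5), fdr = c(0.03, 1, 1),
            tss = 900L),
    # g4: nothing significant -> absent
    rec_row("g4", "v6", p = c(0.2, 0.3, 0.4), fdr = c(0.5, 0.6, 0.7)))
  top <- select_top(recs)
  expect_equal(top$variant_id[top$gene_id == "g1"], "v1")
  expect_equal(top$variant_id[top$gene_id == "g2"], "v3")
  expect_equal(top$best_cut[top$gene_id == "g2"], "prenatal")
  expect_equal(top$variant_id[top$gene_id == "g3"], "v4")
  expect_false("g4" %in% top$gene_id)
})

test_that("classification rules assign the five categories in order", {
  top <- rbind(
    # complete FDR 0.01, both cuts nominal p <= 0.05, same sign
    rec_row("const", "v1", beta = c(1, 1.1, 0.9),
            p = c(0.001, 0.01, 0.03), fdr = c(0.01, 0.04, 0.09)),
    # prenatal FDR 0.02, postnatal p 0.4, strong Z contrast
    rec_row("pre", "v2", beta = c(0.5, 1.2, 0.01), se = c(0.1, 0.1, 0.1),
            p = c(0.2, 0.001, 0.4), fdr = c(0.5, 0.02, 0.9)),
    # mirror image
    rec_row("post", "v3", beta = c(0.5, 0.01, 1.2), se = c(0.1, 0.1, 0.1),
            p = c(0.2, 0.4, 0.001), fdr = c(0.5, 0.9, 0.02)),
    # prenatal significant but weak contrast -> trending by sign
    rec_row("pretrend", "v4", beta = c(0.5, 0.6, 0.4), se = c(1, 4, 4),
            p = c(0.2, 0.01, 0.4), fdr = c(0.5, 0.02, 0.9)))
  cls <- classify_temporal(top)
  got <- setNames(cls$category, cls$gene_id)
  expect_equal(got[["const"]], "constant")
  expect_equal(got[["pre"]], "prenatal_predominant")
  expect_equal(got[["post"]], "postnatal_predominant")
  expect_equal(got[["pretrend"]], "prenatal_trending")
  # exact beta tie falls to postnatal_trending
  tie <- rec_row("tie", "v5", beta = c(0.5, 0.7, 0.7), se = c(1, 4, 4),
                 p = c(0.2, 0.01, 0.4), fdr = c(0.5, 0.02, 0.9))
  expect_equal(classify_temporal(tie)$category, "postnatal_trending")
  expect_error(classify_temporal(transform(top, se_prenatal = NA)),
               "missing")
})

test_that("the five categories partition fuzzed significant pairs", {
  set.seed(17)
  cats <- c("constant", "prenatal_predominant", "postnatal_predominant",
            "prenatal_trending", "postnatal_trending")
  for (rep in 1:20) {
    n <- 40L
    recs <- do.call(rbind, lapply(seq_len(n), function(i)
      rec_row(paste0("g", i), paste0("v", i),
              beta = rnorm(3), se = runif(3, 0.05, 0.5),
              p = runif(3), fdr = runif(3))))
    top <- select_top(recs)
    if (!nrow(top)) next
    cls <- classify_temporal(top)
    expect_true(all(cls$category %in% cats))
    expect_false(anyNA(cls$category))
    # primary categories are mutually exclusive regardless of rule order
    const <- cls$fdr_complete <= 0.05 &
      sign(cls$beta_prenatal) == sign(cls$beta_postnatal) &
      cls$p_prenatal <= 0.05 & cls$p_postnatal <= 0.05
    pre <- cls$fdr_prenatal <= 0.05 & cls$p_postnatal > 0.05 &
      cls$z_fdr <= 0.05
    post <- cls$fdr_postnatal <= 0.05 & cls$p_prenatal > 0.05 &
      cls$z_fdr <= 0.05
    expect_false(any(const & pre) || any(const & post) || any(pre & post))
  }
})

test_that("categories propagate from the top variant to all pairs", {
  recs <- do.call(rbind, lapply(1:12, function(i)
    rec_row("g1", paste0("v", i), p = c(1e-4 * i, 0.01, 0.02),
            fdr = c(0.04, 0.04, 0.04))))
  recs <- rbind(recs, rec_row("g2", "w1", p = c(0.9, 0.9, 0.9),
                              fdr = c(0.99, 0.99, 0.99)))
  top <- classify_temporal(select_top(recs))
  prop <- propagate_categories(recs, top)
  expect_equal(nrow(prop), 12L)
  expect_equal(unique(prop$category), top$category[top$gene_id == "g1"])
  expect_false("g2" %in% prop$gene_id)
})

test_that("alternative assignment schemes follow the stated tie rules", {
  # g1: three significant pairs, individually constant x2 + prenatal x1
  recs <- rbind(
    rec_row("g1", "v1", beta = c(1, 1, 1), p = c(0.001, 0.01, 0.03),
            fdr = c(0.01, 0.04, 0.05)),
    rec_row("g1", "v2", beta = c(1, 1, 1), p = c(0.002, 0.01, 0.03),
            fdr = c(0.01, 0.04, 0.05)),
    rec_row("g1", "v3", beta = c(0.5, 1.2, 0.01), se = c(0.1, 0.1, 0.1),
            p = c(0.2, 0.001, 0.4), fdr = c(0.5, 0.02, 0.9)),
    # g2: single significant pair -> skipped by the second-variant scheme
    rec_row("g2", "v4", beta = c(1, 1, 1), p = c(0.001, 0.01, 0.03),
            fdr = c(0.01, 0.04, 0.05)))
  top <- classify_temporal(select_top(recs))
  alt <- alternative_assignments(recs, top)
  expect_equal(alt$majority$category[alt$majority$gene_id == "g1"],
               "constant")
  expect_false("g2" %in% alt$second$gene_id)
  expect_true("g2" %in% attr(alt$second, "single_pair_genes"))
  # 2-2 tie resolves to constant (first in the stated order)
  recs2 <- rbind(recs[recs$gene_id == "g1", ][1:2, ],
                 rec_row("g1", "v5", beta = c(0.5, 1.2, 0.01),
                         se = c(0.1, 0.1, 0.1), p = c(0.2, 0.001, 0.4),
                         fdr = c(0.5, 0.02, 0.9)),
                 rec_row("g1", "v6", beta = c(0.5, 1.2, 0.01),
                         se = c(0.1, 0.1, 0.1), p = c(0.2, 0.001, 0.4),
                         fdr = c(0.5, 0.02, 0.9)))
  top2 <- classify_temporal(select_top(recs2))
  alt2 <- alternative_assignments(recs2, top2)
  expect_equal(alt2$majority$category, "constant")
  # concordance rows are percentages summing to 100 for observed categories
  rs <- rowSums(alt$concordance$individual)
  expect_true(all(rs[rs > 0] - 100 < 1e-9))
})

test_that("differential-variance F test detects planted heteroscedasticity", {
  st <- simulate_samples(seed = 90L)
  n <- nrow(st)
  pre <- st$stage == "prenatal"
  set.seed(91)
  G <- 120L
  x <- matrix(rnorm(G * n), G, n,
              dimnames = list(sprintf("g%03d", 1:G), st$sample_id))
  hetero <- 1:30
  x[hetero, pre] <- x[hetero, pre] * 2      # 4x prenatal variance
  res <- variance_f_test(x, st)
  expect_gte(mean(res$direction[hetero] == "greater_prenatal"), 0.9)
  # null genes rarely called, F near 1 on average
  expect_lte(mean(res$direction[-hetero] != "ns"), 0.05)
  expect_equal(median(res$f[-hetero]), 1, tolerance = 0.25)
  # two-sidedness: swapping the stage labels inverts F, p is unchanged
  st_swap <- st
  st_swap$stage <- c(prenatal = "postnatal", postnatal = "prenatal",
                     transitional = "transitional")[st$stage]
  res_swap <- variance_f_test(x, st_swap)
  expect_equal(res_swap$f, 1 / res$f, tolerance = 1e-10)
  expect_equal(res_swap$p, res$p, tolerance = 1e-10)
  # a stage with no residual degrees of freedom errors
  tiny <- st[c(which(pre)[1:3], which(!pre & st$stage == "postnatal")), ]
  expect_error(variance_f_test(x[, tiny$sample_id], tiny),
               "degrees|rank-deficient")
})
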