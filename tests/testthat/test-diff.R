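test_that("two-sided Fisher p matches exhaustive enumeration on fixtures", {
  ## degenerate margins
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 5, 5), 1)
  ## frozen enumeration values
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(3, 7, 6, 4), 68332 / 184756,
               tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tb <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    p_ours <- fisher_exact_two_sided(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    p_ref <- stats::fisher.test(tb)$p.value
    expect_equal(p_ours, min(p_ref, 1), tolerance = 1e-9)
  }
})

test_that("the UP-direction p never increases as the UP cell grows", {
  set.seed(7)
  for (i in 1:50) {
    b <- rpois(1, 30) + 1L
    c_ <- rpois(1, 10) + 1L
    d <- rpois(1, 30) + 1L
    prev <- NULL
    for (a in 0:40) {
      p <- fisher_exact_two_sided(a, b, c_, d, alternative = "greater")
      if (!is.null(prev)) expect_lte(p, prev + 1e-12)
      prev <- p
    }
  }
  ## one-sided tails agree with stats::fisher.test
  expect_equal(fisher_exact_two_sided(8, 2, 3, 9, alternative = "greater"),
               stats::fisher.test(matrix(c(8, 3, 2, 9), 2),
                                  alternative = "greater")$p.value,
               tolerance = 1e-10)
  expect_equal(fisher_exact_two_sided(8, 2, 3, 9, alternative = "less"),
               stats::fisher.test(matrix(c(8, 3, 2, 9), 2),
                                  alternative = "less")$p.value,
               tolerance = 1e-10)
})

test_that("gene classification builds the uaRNA-vs-sense table and calls", {
  cfg <- stats_config()
  counts <- data.frame(
    gene_id = c("up", "flat", "none"),
    ua_mut = c(40L, 10L, 0L), sense_mut = c(100L, 100L, 50L),
    ua_ctl = c(10L, 10L, 0L), sense_ctl = c(100L, 100L, 50L)
  )
  res <- classify_genes(counts, "mut", "ctl", cfg)
  expect_equal(res$odds_ratio[1], 4)
  expect_lt(res$p[1], 0.05)
  expect_equal(res$call[1], "UP")
  expect_equal(res$p[2], 1)
  expect_equal(res$call[2], "NC")
  ## no uaRNA reads anywhere: nothing to test
  expect_equal(res$p[3], 1)
  expect_equal(res$call[3], "NC")
  expect_error(classify_genes(counts, "mut", "missing"), "missing")
})

test_that("swapping sample roles maps UP and DN onto each other", {
  set.seed(5)
  counts <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    ua_a = rpois(200, 15), sense_a = rpois(200, 150),
    ua_b = rpois(200, c(rep(60, 30), rep(15, 170))),
    sense_b = rpois(200, 150)
  )
  fwd <- classify_genes(counts, "a", "b")
  rev <- classify_genes(counts, "b", "a")
  expect_equal(fwd$p, rev$p)
  map <- c(UP = "DN", DN = "UP", NC = "NC")
  expect_equal(rev$call, unname(map[fwd$call]))
})

test_that("the chi-squared tail matches the erfc closed form", {
  chi2 <- c(0, 0.5, 1, 7.3, 36, 13.2352941, 100)
  expect_equal(chisq_tail_p(chi2), chisq_tail_oracle(chi2),
               tolerance = 1e-12)
})

test_that("global enrichment counts calls and tests UP:DN against 50:50", {
  mk <- function(up, dn, nc = 10) data.frame(
    gene_id = sprintf("g%d", seq_len(up + dn + nc)),
    call = c(rep("UP", up), rep("DN", dn), rep("NC", nc))
  )
  e <- global_enrichment(mk(50, 50))
  expect_equal(e$chi2, 0)
  expect_equal(e$p_chi2, 1)
  expect_equal(e$ratio, 1)

  e <- global_enrichment(mk(80, 20))
  expect_equal(e$chi2, 36)
  expect_equal(e$p_chi2, 1.973175e-09, tolerance = 1e-6)

  e <- global_enrichment(mk(16, 1))
  expect_equal(e$chi2, 225 / 17, tolerance = 1e-12)
  expect_equal(e$p_chi2, 2.747268e-04, tolerance = 1e-6)

  e <- global_enrichment(mk(10, 0))
  expect_equal(e$ratio, Inf)
  expect_equal(e$chi2, 10)

  e <- global_enrichment(mk(0, 0))
  expect_true(e$degenerate)
  expect_equal(e$p_chi2, 1)
})

test_that("expression-change scatter reports pseudocounted log2 ratios", {
  cfg <- stats_config(pseudocount = 1e-9)
  totals <- c(t = 1e6, r = 1e6)
  counts <- data.frame(
    gene_id = c("gA", "gB"),
    ua_t = c(8L, 5L), sense_t = c(10L, 5L),
    ua_r = c(4L, 5L), sense_r = c(10L, 5L)
  )
  counts <- rpm_normalize(counts, totals)
  res <- classify_genes(counts, "t", "r", cfg)
  res$call[1] <- "UP"  # force the flag for the fixture
  sc <- change_scatter(counts, res, "t", "r", totals, cfg)
  expect_equal(sc$log2_ua_change[1], 1, tolerance = 1e-6)
  expect_equal(sc$log2_sense_change[1], 0, tolerance = 1e-6)
  expect_true(sc$significant[1])
  expect_equal(sc$log2_ua_change[2], 0, tolerance = 1e-6)
  expect_false(sc$significant[2])

  ## pseudocount keeps zero-RPM genes finite
  z <- rpm_normalize(data.frame(gene_id = "z", ua_t = 0L, sense_t = 0L,
                                ua_r = 7L, sense_r = 7L), totals)
  zres <- classify_genes(z, "t", "r", stats_config())
  zsc <- change_scatter(z, zres, "t", "r", totals, stats_config())
  expect_true(all(is.finite(c(zsc$log2_ua_change, zsc$log2_sense_change))))
})

test_that("CDF curves are empirical CDFs with the combined-read filter", {
  totals <- c(t = 1e6, r = 1e6)
  counts <- data.frame(
    gene_id = c("g1", "g2", "g3", "thin", "noua"),
    ua_t = c(10L, 20L, 40L, 9L, 0L), sense_t = c(500L, 500L, 500L, 500L, 500L),
    ua_r = c(20L, 20L, 20L, 10L, 0L), sense_r = c(500L, 500L, 500L, 500L, 500L)
  )
  counts <- rpm_normalize(counts, totals)
  res <- classify_genes(counts, "t", "r")
  cdf <- cdf_curves(counts, res, "t", "r", totals,
                    stats_config(pseudocount = 1e-9))
  ua <- cdf[cdf$category == "uaRNA", ]
  ## gene "thin" has 19 combined uaRNA reads -> excluded at threshold 20
  expect_setequal(ua$gene_id, c("g1", "g2", "g3"))
  expect_equal(ua$cdf, c(1 / 3, 2 / 3, 1))
  expect_equal(ua$log2fc, c(-1, 0, 1), tolerance = 1e-6)
  expect_true(!is.unsorted(ua$log2fc))
  ## exactly 20 combined reads is included
  counts$ua_t[4] <- 10L
  cdf2 <- cdf_curves(counts, classify_genes(counts, "t", "r"), "t", "r",
                     totals, stats_config(pseudocount = 1e-9))
  expect_true("thin" %in% cdf2$gene_id[cdf2$category == "uaRNA"])
})

test_that("a planted uaRNA increase right-shifts the uaRNA CDF curve", {
  sim <- small_sim()
  lens <- fasta_lengths(sim$genome)
  idx <- build_region_index(extend_three_prime(sim$genes, lens), lens)
  p <- call_pass(sim$reads, sim$genome)
  totals <- table(p$sample)
  counts <- rpm_normalize(
    build_count_table(assign_reads(p, idx), sim$genes),
    c(test = totals[["test"]], ref = totals[["ref"]])
  )
  res <- classify_genes(counts, "test", "ref")
  cdf <- suppressWarnings(cdf_curves(
    counts, res, "test", "ref",
    c(test = totals[["test"]], ref = totals[["ref"]])))
  med <- tapply(cdf$log2fc, cdf$category, stats::median)
  expect_gt(med[["uaRNA"]], med[["sense_all"]])
})
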