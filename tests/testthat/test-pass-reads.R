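# Tail-matching rule fixtures on a toy genome. Genome is all-C filler with
# specific bases written in (1-based positions in the constructor).

test_that("non-templated tails make a read PASS; templated ones do not", {
  g <- toy_genome(chr1 = list(len = 300, "151" = "GCTA"))
  ## tail entirely non-genomic: 4 As vs reference GCTA
  p <- call_pass(read_row("r1", "chr1", "+", 100L, 150L, "AAAA"), g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pa_site, 149L)
  expect_equal(p$nongenomic_a, 4L)

  ## fully templated tail: reference continues AAT
  g2 <- toy_genome(chr1 = list(len = 300, "151" = "AAT"))
  expect_equal(nrow(call_pass(read_row("r2", "chr1", "+", 100L, 150L, "AA"), g2)), 0L)

  ## a single non-genomic A is below the threshold
  g3 <- toy_genome(chr1 = list(len = 300, "151" = "G"))
  expect_equal(nrow(call_pass(read_row("r3", "chr1", "+", 100L, 150L, "A"), g3)), 0L)

  ## empty tail is never PASS
  expect_equal(nrow(call_pass(read_row("r4", "chr1", "+", 100L, 150L, ""), g)), 0L)
})

test_that("templated prefix advances the poly(A) site", {
  ## reference continues AAG; tail AAAA -> k = 2, 2 non-genomic As
  g <- toy_genome(chr1 = list(len = 300, "151" = "AAG"))
  p <- call_pass(read_row("r1", "chr1", "+", 100L, 150L, "AAAA"), g)
  expect_equal(p$pa_site, 151L)
  expect_equal(p$nongenomic_a, 2L)
})

test_that("minus-strand reads use the reverse-complemented continuation", {
  ## upstream genomic TAGC at 0-based 46..49 -> continuation revcomp = GCTA
  g <- toy_genome(chr1 = list(len = 300, "47" = "TAGC"))
  expect_equal(nrow(call_pass(
    read_row("r1", "chr1", "-", 50L, 100L, "GCTA"), g)), 0L)  # templated
  p <- call_pass(read_row("r2", "chr1", "-", 50L, 100L, "AAAA"), g)
  expect_equal(p$pa_site, 50L)
  expect_equal(p$nongenomic_a, 4L)

  ## templated prefix on minus strand: genomic ...TT at 48..49 -> cont. AA
  g2 <- toy_genome(chr1 = list(len = 300, "49" = "TT"))
  p2 <- call_pass(read_row("r3", "chr1", "-", 50L, 100L, "AAAA"), g2)
  expect_equal(p2$pa_site, 48L)
  expect_equal(p2$nongenomic_a, 2L)
})

test_that("exhausted reference counts remaining tail bases as non-genomic", {
  g <- toy_genome(chr1 = list(len = 200))
  p <- call_pass(read_row("r1", "chr1", "+", 150L, 200L, "AAAA"), g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$nongenomic_a, 4L)
})

test_that("N never counts as A and never matches the reference", {
  g <- toy_genome(chr1 = list(len = 300, "151" = "NAAA"))
  ## N in tail vs N in reference: no match, so whole tail is non-genomic;
  ## 3 As out of 4 bases -> purity 0.75 fails the default 0.8 threshold
  expect_equal(nrow(call_pass(
    read_row("r1", "chr1", "+", 100L, 150L, "NAAA"), g)), 0L)
  p <- call_pass(read_row("r1", "chr1", "+", 100L, 150L, "NAAA"), g,
                 min_a_fraction = 0.7)
  expect_equal(nrow(p), 1L)
  expect_equal(p$nongenomic_a, 3L)
})

test_that("low-purity soft clips are rejected despite non-genomic As", {
  g <- toy_genome(chr1 = list(len = 300, "151" = "GGGG"))
  expect_equal(nrow(call_pass(
    read_row("r1", "chr1", "+", 100L, 150L, "AAGG"), g)), 0L)
  expect_equal(nrow(call_pass(
    read_row("r1", "chr1", "+", 100L, 150L, "AAGG"), g,
    min_a_fraction = 0.5)), 1L)
})

test_that("PASS calling recovers exactly the truth labels on clean reads", {
  sim <- small_sim()
  p <- call_pass(sim$reads, sim$genome)
  truth <- sim$truth_reads
  called <- truth$read_id %in% p$read_id
  expect_equal(sum(called & !truth$pass), 0L)   # specificity = 1
  expect_equal(sum(!called & truth$pass), 0L)   # sensitivity = 1
  ## inferred poly(A) sites equal the designated cleavage positions
  m <- match(p$read_id, truth$read_id)
  expect_equal(p$pa_site, truth$pa_site[m])
})

test_that("PASS set is invariant under dataset-wide strand mirroring", {
  sim <- small_sim()
  lens <- fasta_lengths(sim$genome)
  p <- call_pass(sim$reads, sim$genome)
  pm <- call_pass(mirror_reads(sim$reads, lens), mirror_genome(sim$genome))
  expect_setequal(p$read_id, pm$read_id)
  m <- match(p$read_id, pm$read_id)
  expect_equal(pm$pa_site[m], as.integer(lens[p$chrom]) - 1L - p$pa_site)
  expect_equal(pm$nongenomic_a[m], p$nongenomic_a)
})

test_that("site clustering merges within the window and conserves reads", {
  pass <- data.frame(
    read_id = sprintf("r%d", 1:8), chrom = "chr1", strand = "+",
    pa_site = c(rep(100L, 5), rep(110L, 3)), nongenomic_a = 2L,
    sample = c(rep("A", 4), rep("B", 4)), stringsAsFactors = FALSE
  )
  cl <- cluster_sites(pass, window = 24)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$position, 100L)
  expect_equal(cl$total, 8L)
  expect_equal(cl$count_A, 4L)
  expect_equal(cl$count_B, 4L)

  ## separation beyond the window keeps sites apart
  pass$pa_site <- c(rep(100L, 5), rep(200L, 3))
  expect_equal(cluster_sites(pass, window = 24)$position, c(100L, 200L))

  ## single site unchanged
  one <- cluster_sites(pass[1, ], window = 24)
  expect_equal(one$position, 100L)
  expect_equal(one$total, 1L)
})

test_that("cluster representatives break count ties to the 5'-most member", {
  mk <- function(strand) data.frame(
    read_id = sprintf("r%d", 1:4), chrom = "chr1", strand = strand,
    pa_site = c(100L, 100L, 110L, 110L), nongenomic_a = 2L,
    stringsAsFactors = FALSE
  )
  expect_equal(cluster_sites(mk("+"))$position, 100L)
  expect_equal(cluster_sites(mk("-"))$position, 110L)
})

test_that("clustering is independent of input order and conserves totals", {
  sim <- small_sim()
  p <- call_pass(sim$reads, sim$genome)
  set.seed(1)
  cl1 <- cluster_sites(p)
  cl2 <- cluster_sites(p[sample(nrow(p)), ])
  expect_identical(cl1, cl2)
  expect_equal(sum(cl1$total), nrow(p))
  expect_equal(sum(cl1$count_test), sum(p$sample == "test"))
})

test_that("the PASS report tallies inputs, PASS reads and their fraction", {
  g <- toy_genome(chr1 = list(len = 300, "151" = "GCTA"))
  reads <- rbind(
    read_row(sprintf("p%d", 1:4), "chr1", "+", 100L, 150L, "AAAA", "S1"),
    read_row(sprintf("n%d", 1:6), "chr1", "+", 100L, 150L, "", "S1")
  )
  rep1 <- pass_report(reads, call_pass(reads, g))
  expect_equal(rep1$n_input, 10L)
  expect_equal(rep1$n_pass, 4L)
  expect_equal(rep1$pass_fraction, 0.4)

  empty <- pass_report(reads[0, ], call_pass(reads[0, ], g), samples = "S1")
  expect_equal(empty$n_input, 0L)
  expect_true(is.na(empty$pass_fraction))
})

test_that("simulated libraries reproduce the planted PASS fraction", {
  sim <- small_sim()
  rep <- pass_report(sim$reads, call_pass(sim$reads, sim$genome))
  truth_frac <- tapply(sim$truth_reads$pass, sim$truth_reads$sample, mean)
  expect_equal(rep$pass_fraction, as.numeric(truth_frac[rep$sample]))
})
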