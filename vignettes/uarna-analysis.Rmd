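---
title: "Quantifying upstream antisense RNA regulation from 3'-end sequencing"
author: "uaRNAdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying upstream antisense RNA regulation from 3'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaRNAdiff)
```

## The biological question

Most active promoters in vertebrate cells initiate transcription in both
directions. The upstream antisense transcripts (uaRNAs, also called
PROMPTs) are short, polyadenylated, and normally degraded quickly by the
nuclear exosome, so their steady-state levels are low. When surveillance or
turnover is perturbed — for instance by mutations in the RNA polymerase II
C-terminal domain — uaRNAs accumulate, and the imbalance is visible
genome-wide as an excess of genes whose uaRNA level rises *relative to the
same gene's sense mRNA*.

3'-end sequencing protocols such as 3'READS capture the 3' terminus of
poly(A)+ RNA, so each usable read marks one cleavage/polyadenylation event.
This package implements the downstream analysis of such data: from aligned
reads to poly(A)-site-supporting (PASS) reads, strand-aware sense/uaRNA
assignment, per-gene differential tests between two conditions, a global
enrichment summary, and descriptive poly(A)-site and TSS profiles. It does
not perform alignment or any wet-lab step.

## PASS reads: separating poly(A) tails from templated sequence

A 3'-end read typically ends in a stretch of As from the poly(A) tail that
the aligner soft-clips. Genomic A-runs can mimic a tail, so evidence for a
genuine cleavage site requires *non-genomic* As. `call_pass()` implements
this with a deterministic, strand-symmetric rule:

1. Take the 3' soft clip in read orientation (`tail_seq`).
2. Compute the longest prefix of the tail that matches the reference
   continuation downstream of the alignment, base for base
   (reverse-complemented for minus-strand reads). `N` never matches and
   never counts as A; where the chromosome ends mid-comparison, the
   remaining bases count as non-genomic.
3. The remainder of the tail is non-genomic. A read is PASS when the
   non-genomic part contains at least `min_nongenomic_a` As (default 2)
   *and* the A-fraction of the whole tail is at least `min_a_fraction`
   (default 0.8). The purity condition discards soft clips that are adapter
   remnants or mismatch artifacts rather than poly(A) tails.
4. The poly(A) site is the last aligned base advanced past the templated
   prefix; templated As belong to the transcript, so the inferred cleavage
   position moves with them.

```{r pass-example}
genome <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 150)))
reads <- data.frame(read_id = "r1", chrom = "chr1", strand = "+",
                    aln_start = 50L, aln_end = 100L, tail_seq = "AAAA")
call_pass(reads, genome)
```

PASS read 3' ends are then grouped into poly(A) sites by `cluster_sites()`
using single-linkage clustering within 24 bp (configurable; the choice is
recorded in the pipeline's config echo). The representative position is the
member with the highest pooled count, ties resolved to the strand-aware
5'-most member, and per-sample counts are conserved exactly.

## Gene territories and the uaRNA window

Gene models come from BED or GTF annotation (`load_gene_models()`);
transcripts of a gene are merged to the gene's maximal span, since the
analysis operates at gene level. Two strand-aware region sets drive
assignment:

* **Sense region** — the gene span extended 3' by 4 kb
  (`extend_three_prime()`), *only if* no other same-strand gene overlaps
  the would-be extension; the extension is all-or-nothing and clipped at
  chromosome ends. The extension captures cleavage sites downstream of
  annotated 3' ends.
* **uaRNA window** — the 2 kb immediately upstream of the TSS on the
  opposite strand (`build_region_index()`), half-open at the TSS.

Each PASS read is assigned by its inferred poly(A) site
(`assign_reads()`): a read in exactly one sense region on its strand is
*sense* for that gene; in more than one, *ambiguous* (excluded from all
counts and reported); otherwise, if it falls in a uaRNA window and is not
sense-assignable to any gene, it is *uaRNA* — when windows overlap, the
gene with the nearest TSS wins, ties to the smallest `gene_id`. Everything
else is *unassigned*. Sense assignment strictly precedes uaRNA, which
encodes the requirement that uaRNA reads must not be attributable to any
annotated gene as sense reads. The four categories partition each
library's PASS reads exactly — the pipeline report asserts this.

Three choices here were genuinely open and are configurable:

* assignment uses the read's 3' end (the poly(A) site), not any-overlap,
  because the analysis is anchored on cleavage positions;
* the 4-kb extension counts as gene territory when testing the uaRNA
  exclusion — a cleavage site downstream of a gene is sense evidence;
* the TSS coordinate itself is excluded from the window (half-open).

## Differential testing

For two libraries (test and reference), each gene's uaRNA reads are pooled
and compared with its pooled sense reads in a 2x2 table
`[[ua_test, sense_test], [ua_ref, sense_ref]]`, tested with a two-sided
Fisher exact test (`fisher_exact_two_sided()`). The two-sided p uses the
probability-mass method: the total hypergeometric probability of tables
(same margins) no more likely than the observed one, with a relative
tolerance of 1e-7 absorbing floating-point ties. Genes with p below
`alpha` (default 0.05) are called UP or DN according to the direction of
the uaRNA:sense shift; genes with no uaRNA reads in either library are NC
with p = 1. The odds ratio `(ua_t * sense_r) / (sense_t * ua_r)` is
reported; with a zero cell the call direction comes from the sample
proportions while the p-value remains exact. No multiple-testing
correction is applied to the headline counts, matching the p < 0.05
selection convention of this analysis style; the per-gene table makes it
trivial to add one.

The global summary (`global_enrichment()`) counts UP and DN genes and
tests their ratio against a 50:50 expectation with a one-degree-of-freedom
chi-squared goodness-of-fit without continuity correction,
`chi2 = (n_up - n_dn)^2 / (n_up + n_dn)`. Under the null of symmetric
regulation this is the natural test for a directional excess; the model
assumption is recorded in the pipeline's summary JSON.

Expression changes for scatter and CDF displays use
`log2((rpm_test + pc) / (rpm_ref + pc))`, where RPM is reads per million
*total PASS reads* of the library and the pseudocount `pc` is 0.5 reads
converted to each library's RPM scale. CDF curves
(`cdf_curves()`) are restricted to genes with at least 20 reads in the two
samples combined (per plotted category), which makes them insensitive to
the pseudocount; the curves cover uaRNAs, all sense transcripts, and sense
transcripts split by their gene's uaRNA status (UP, detected-but-NC, none
detected).

## Profiles

* `tss_distance_histogram()` bins uaRNA poly(A) sites by distance upstream
  of the host TSS (strand-aware, half-open bins).
* `nucleotide_profile()` reports per-offset A/C/G/T frequencies on the
  transcribed strand around poly(A) sites (offset 0 = cleavage site);
  out-of-chromosome offsets are dropped per site with adjusted
  denominators, so frequencies always sum to 1. A poly(A) signal such as
  AATAAA appears ~20-30 nt upstream of offset 0.
* `tss_metagene()` aggregates uaRNA read 3' ends per base over the 2 kb
  upstream of TSSs for all genes with uaRNA detected in any sample,
  converts to RPM per base, and smooths with lowess (tricube-weighted
  local linear regression; fraction 0.3, 0 robustness iterations,
  interpolation disabled). Local linear smoothing reproduces constants and
  straight lines exactly, which the tests exploit as an oracle.

## The synthetic-data generator

Raw sequencing data for this kind of study is rarely redistributable, so
the package ships a seeded generator (`simulate_dataset()`) that emulates
the statistical structure the analysis assumes, with full truth labels:

* uniform-base toy genome (default 4 chromosomes x 3.4 Mb, sized to pack
  250 genes per chromosome at the worst-case footprint);
* non-overlapping genes with >= 8 kb intergenic gaps — larger than the
  4-kb extension plus 2-kb window, so simulated territories never collide
  and truth assignment is unambiguous;
* per-gene sense expression drawn log-normally (sdlog 1, a typical spread
  for detected genes); half the genes have detectable uaRNA at a baseline
  uaRNA:sense ratio of 0.1, reflecting the low abundance of these
  transcripts;
* planted effects multiply the uaRNA:sense ratio of chosen genes by a
  configurable fold (default 4) in the test library;
* reads end at 1-3 designated sense poly(A) sites near each gene's 3' end
  and 1-2 antisense sites placed uniformly within the 2-kb upstream
  window; counts are Poisson (negative binomial optional), default
  2e5 reads per library — a desk-scale stand-in for the millions of reads
  of a real study;
* 25% of reads carry degenerate tails (empty, fully templated, or a single
  A) and are PASS-negative by construction; 5% come from spurious sites
  placed uniformly over the genome;
* AATAAA is written at transcript offsets -25..-20 of every designated
  site, and the two reference bases downstream of each site are forced to
  non-A so that truth PASS labels admit no templated-A ambiguity
  (`templated_a_frac` re-introduces ambiguity deliberately). Site
  placement keeps these sequence edits from colliding.

What the generator does **not** model: sequencing errors and quality
scores, alignment ambiguity and multimapping, PCR duplicates, internal
priming on genomic A-stretches, isoform structure, replicate-level
biological variability (libraries are pooled per condition, as the pooled
2x2 test assumes), and realistic base composition. Passing tests therefore
demonstrate the correctness of the *computational* pipeline under its
stated assumptions — not robustness to artifacts a real library would add
upstream of it.

## Validation summary

The test suite validates, among other properties:

* the Fisher p-value against an independent log-factorial enumeration
  oracle over every 2x2 table with N <= 120 plus random larger tables
  (agreement within 1e-10), and against `stats::fisher.test`;
* the 1-df chi-squared tail against the closed form
  `p = erfc(sqrt(chi2 / 2))` to 1e-12 relative accuracy;
* calibration on a null simulation (1,000 genes, 2e5 reads/library): the
  fraction of genes called at alpha 0.05 stays below 0.06 — the exact test
  is conservative at these counts;
* recovery of a planted effect (100 UP genes at fold 4, 6 DN): UP/DN
  ratio >= 8, global chi-squared p < 1e-10, recall of planted UP genes
  >= 0.8, false calls among null genes <= 0.06;
* exact PASS sensitivity and specificity against truth labels, exact
  read-partition conservation, planted-motif recovery in nucleotide
  profiles, and invariance of every count, call and summary under
  reverse-complement mirroring of the whole dataset.

These problem sizes (1,000 genes, 2e5 reads per library) are the package's
validation scale; all thresholds above are asserted in
`tests/testthat/test-acceptance.R`.

## Known limitations

* The pooled 2x2 Fisher test treats reads as independent; overdispersion
  between biological replicates is not modelled (the generator's
  negative-binomial option exists precisely to probe this sensitivity).
* Ambiguous reads (sense-assignable to several overlapping same-strand
  genes) are excluded rather than fractionally allocated.
* uaRNA windows of closely spaced divergent genes can overlap; nearest-TSS
  assignment is a heuristic there.
* The chi-squared enrichment test conditions on the UP/DN calls; it does
  not propagate per-gene uncertainty.
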