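# uaRNAdiff

Differential analysis of upstream antisense RNAs (uaRNAs / PROMPTs) from
strand-specific 3'-end sequencing data such as 3'READS.

Active promoters transcribe divergently: short, polyadenylated upstream
antisense RNAs are produced from the region just upstream of a gene's
transcription start site (TSS) and are normally degraded rapidly. Whether a
perturbation (for instance a mutation in the RNA polymerase II machinery)
causes uaRNAs to accumulate is visible in 3'-end sequencing as a shift in
the balance of uaRNA reads versus sense reads at each gene. `uaRNAdiff`
implements that analysis end to end for computational biologists working
with aligned 3'-end reads:

* **PASS reads** — a read supports a poly(A) site when its 3' soft clip
  carries ≥ 2 *non-genomic* As, i.e. As left over after removing the
  longest prefix of the tail that matches the reference continuation
  (strand-aware). The poly(A) site is the last aligned base advanced past
  the templated prefix.
* **Assignment** — a gene's sense region is its span extended 3' by 4 kb
  when no same-strand gene intrudes; its uaRNA window is the 2 kb upstream
  of the TSS on the opposite strand. A PASS read is *sense* if its
  poly(A) site falls in exactly one sense region on its strand, and
  *uaRNA* only if it falls in a window and is sense-assignable nowhere.
* **Per-gene test** — pooled counts form the 2x2 table
  `[[ua_test, sense_test], [ua_ref, sense_ref]]`, tested with a two-sided
  Fisher exact test (probability-mass method); genes with p < 0.05 are
  called UP or DN by the direction of the uaRNA:sense shift.
* **Global enrichment** — the UP:DN ratio with a 1-df chi-squared
  goodness-of-fit against 50:50: `chi2 = (n_up − n_dn)² / (n_up + n_dn)`.
* **Profiles** — distance-from-TSS histograms of uaRNA poly(A) sites,
  nucleotide composition around poly(A) sites (AATAAA visible upstream of
  the cleavage site), and a lowess-smoothed antisense TSS metagene in
  reads per million (RPM) per base.
* **Simulator** — a seeded generator of toy genomes, annotations and
  two-condition read sets with truth labels, used throughout the tests.

## Worked example

Simulate a small two-condition experiment with 10 genes planted to gain
uaRNA signal (fourfold) and 2 to lose it, then run the pipeline:

```r
library(uaRNAdiff)

cfg <- sim_config(seed = 42, n_chroms = 2, chrom_len = 450000, n_genes = 60,
                  reads_per_lib = 50000, n_up = 10, n_dn = 2)
sim <- simulate_dataset(cfg)
run <- run_pipeline(pipeline_config(
  sim$genome, sim$genes, sim$reads,
  sample_test = "test", sample_ref = "ref"))
print(run)
#> uaRNA pipeline run
#>   genes: 60
#>   sample n_input n_pass pass_fraction
#> 1    ref   49839  37413     0.7506772
#> 2   test   49686  37228     0.7492654
#>   sample sense uaRNA ambiguous unassigned total
#> 1    ref 34000  1558         0       1855 37413
#> 2   test 32677  2766         0       1785 37228
#> uaRNA regulation enrichment
#>   UP: 10  DN: 1  UP/DN: 10
#>   chi-squared (1 df): 7.364, p = 0.006656
```

Reading the report: ~75% of simulated reads carry a genuine non-templated
poly(A) tail and become PASS reads; each library's PASS reads are
partitioned exactly into sense, uaRNA, ambiguous and unassigned. Ten genes
are called UP versus one DN — the planted excess — giving a UP/DN ratio of
10 with chi-squared p ≈ 0.007. Per-gene detail lives in `run$results`:

```r
head(run$results[order(run$results$p), ], 4)
#>    gene_id ua_test sense_test ua_ref sense_ref odds_ratio            p call
#> 55   g0055     553       1332    138      1377   4.142626 4.727251e-51   UP
#> 33   g0033     460       1222    124      1206   3.661106 2.033294e-37   UP
#> 37   g0037     145        333     37       349   4.107215 2.942895e-14   UP
#> 2    g0002     114        335     22       321   4.965265 3.023145e-13   UP
```

The odds ratio near 4 for the top genes recovers the planted fourfold
change. With `out_dir` set, the pipeline also writes count tables, per-gene
results, site tables, profile data, a summary JSON and a config echo. Real
data enters the same way: a FASTA genome, BED/GTF annotation, and per-sample
SAM/BAM files or plain aligned-read tables
(`read_id, chrom, strand, aln_start, aln_end, tail_seq`). A command-line
wrapper for the simulate/run steps is installed at
`inst/scripts/uarna_pipeline.R`.

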