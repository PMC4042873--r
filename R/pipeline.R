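## End-to-end orchestration: annotation -> extension -> index -> PASS ->
## clustering -> assignment -> counting -> differential tests -> enrichment
## -> profiles, with config validation, stage-tagged errors and
## machine-readable outputs.

#' Pipeline configuration
#'
#' Inputs may be file paths (FASTA genome, BED/GTF annotation, TSV/SAM read
#' tables) or in-memory objects (a [Biostrings::DNAStringSet], a gene-model
#' `data.frame`, a named list of aligned-read `data.frame`s).
#'
#' @param genome Genome FASTA path or `DNAStringSet`.
#' @param annotation Annotation path or gene-model `data.frame`.
#' @param reads Named list (by sample) of aligned-read paths or
#'   `data.frame`s, or a single `data.frame` with a `sample` column.
#' @param sample_test,sample_ref Sample roles for the differential test.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @param extension 3' extension in bp (default 4000).
#' @param ua_window uaRNA window in bp (default 2000).
#' @param min_nongenomic_a Minimum non-genomic As for a PASS read
#'   (default 2).
#' @param min_a_fraction Minimum tail A-fraction (default 0.8).
#' @param cluster_window Poly(A)-site clustering window in bp (default 24).
#' @param alpha Fisher selection threshold (default 0.05).
#' @param min_reads_cdf Combined-read filter for CDF curves (default 20).
#' @param pseudocount Pseudocount in reads for log2 ratios (default 0.5).
#' @param metagene_span Metagene span upstream of the TSS (default 2000).
#' @param profile_flank Nucleotide-profile flank (default 50).
#' @param hist_bin Distance-histogram bin width (default 100).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(genome, annotation, reads,
                            sample_test, sample_ref, out_dir = NULL,
                            extension = 4000L, ua_window = 2000L,
                            min_nongenomic_a = 2L, min_a_fraction = 0.8,
                            cluster_window = 24L, alpha = 0.05,
                            min_reads_cdf = 20L, pseudocount = 0.5,
                            metagene_span = 2000L, profile_flank = 50L,
                            hist_bin = 100L) {
  structure(as.list(environment()), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg A [pipeline_config()].
#' @return A character vector of issues, named by the offending key; empty
#'   when the configuration is runnable.
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  add <- function(key, msg) {
    issues[[key]] <<- msg
  }
  num_pos <- function(key, strict = TRUE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (strict && v <= 0) || (!strict && v < 0)) {
      add(key, paste0(key, " must be a ", if (strict) "positive" else
        "non-negative", " number"))
    }
  }
  if (!is.numeric(cfg$alpha) || is.na(cfg$alpha) ||
      cfg$alpha <= 0 || cfg$alpha >= 1) {
    add("alpha", "alpha must be in (0, 1)")
  }
  num_pos("ua_window")
  num_pos("cluster_window")
  num_pos("min_a_fraction")
  num_pos("pseudocount")
  num_pos("metagene_span")
  num_pos("profile_flank")
  num_pos("hist_bin")
  num_pos("extension", strict = FALSE)
  num_pos("min_reads_cdf", strict = FALSE)
  if (!is.numeric(cfg$min_nongenomic_a) || cfg$min_nongenomic_a < 1) {
    add("min_nongenomic_a", "min_nongenomic_a must be >= 1")
  }
  for (key in c("sample_test", "sample_ref")) {
    if (!is.character(cfg[[key]]) || length(cfg[[key]]) != 1 ||
        is.na(cfg[[key]]) || !nzchar(cfg[[key]])) {
      add(key, paste0(key, " must be a non-empty sample name"))
    }
  }
  if (identical(cfg$sample_test, cfg$sample_ref)) {
    add("sample_ref", "sample_test and sample_ref must differ")
  }
  for (key in c("genome", "annotation")) {
    if (is.character(cfg[[key]]) && !file.exists(cfg[[key]])) {
      add(key, paste0(key, " path does not exist: ", cfg[[key]]))
    }
  }
  if (is.list(cfg$reads) && !is.data.frame(cfg$reads)) {
    for (s in names(cfg$reads)) {
      if (is.character(cfg$reads[[s]]) && !file.exists(cfg$reads[[s]])) {
        add(paste0("reads.", s),
            paste0("reads path for sample ", s, " does not exist"))
      }
    }
  }
  issues
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full uaRNA analysis pipeline
#'
#' Executes every stage in order and (when `out_dir` is set) writes the
#' count table, per-gene results, scatter and CDF data, site tables,
#' profiles, an enrichment/run-report JSON and a verbatim config echo.
#' Re-running with identical configuration and inputs reproduces identical
#' outputs: the analysis stages draw no random numbers.
#'
#' @param cfg A [pipeline_config()].
#' @return A run report list (class `uarna_run`) with per-stage tallies,
#'   the `enrichment_summary`, and all stage outputs.
#' @export
run_pipeline <- function(cfg) {
  issues <- validate_config(cfg)
  if (length(issues)) {
    stop("[config] invalid configuration:\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  }

  genome <- .stage("genome", .load_genome(cfg$genome))
  lens <- fasta_lengths(genome)

  genes <- .stage("annotation", {
    if (is.data.frame(cfg$annotation)) as_gene_models(cfg$annotation, lens)
    else load_gene_models(cfg$annotation, lens)
  })
  genes <- .stage("extend", extend_three_prime(genes, lens, cfg$extension))
  index <- .stage("index", build_region_index(genes, lens, cfg$ua_window))

  reads <- .stage("reads", {
    r <- cfg$reads
    if (is.data.frame(r)) {
      if (!"sample" %in% names(r)) r$sample <- "S1"
      r
    } else {
      parts <- lapply(names(r), function(s) {
        x <- r[[s]]
        if (is.character(x)) {
          x <- if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
            read_aligned_sam(x)
          } else {
            read_aligned_tsv(x)
          }
        }
        x$sample <- s
        x
      })
      do.call(rbind, c(parts, list(make.row.names = FALSE)))
    }
  })

  pass <- .stage("pass", call_pass(reads, genome, cfg$min_nongenomic_a,
                                   cfg$min_a_fraction))
  report_pass <- pass_report(reads, pass)
  totals <- stats::setNames(report_pass$n_pass, report_pass$sample)

  sites <- .stage("cluster", cluster_sites(pass, cfg$cluster_window))
  assigned <- .stage("assign", assign_reads(pass, index))
  tally <- assignment_tally(assigned)
  counts <- .stage("count", build_count_table(assigned, genes))
  counts <- .stage("rpm", rpm_normalize(counts, totals))

  scfg <- stats_config(cfg$alpha, cfg$min_reads_cdf, cfg$pseudocount)
  results <- .stage("diff", classify_genes(counts, cfg$sample_test,
                                           cfg$sample_ref, scfg))
  enrichment <- .stage("enrichment", global_enrichment(results))
  scatter <- .stage("scatter", change_scatter(counts, results,
                                              cfg$sample_test,
                                              cfg$sample_ref, totals, scfg))
  cdf <- .stage("cdf", cdf_curves(counts, results, cfg$sample_test,
                                  cfg$sample_ref, totals, scfg))

  hist <- .stage("profiles", tss_distance_histogram(sites, index,
                                                    cfg$ua_window,
                                                    cfg$hist_bin))
  ua_sites <- sites[.assign_positions(sites$chrom, sites$strand,
                                      sites$position,
                                      index)$category == "uaRNA", ,
                    drop = FALSE]
  ntp <- .stage("profiles", {
    if (nrow(ua_sites)) nucleotide_profile(ua_sites, genome,
                                           cfg$profile_flank) else NULL
  })
  metagene <- .stage("profiles", {
    if (any(assigned$category == "uaRNA")) {
      tss_metagene(assigned, index, totals, cfg$metagene_span)
    } else NULL
  })

  report <- structure(list(
    pass_report = report_pass,
    assignment_tally = tally,
    n_genes = nrow(genes),
    enrichment = enrichment,
    counts = counts,
    results = results,
    sites = sites,
    scatter = scatter,
    cdf = cdf,
    tss_histogram = hist,
    nucleotide_profile = ntp,
    metagene = metagene,
    config = cfg
  ), class = "uarna_run")

  if (!is.null(cfg$out_dir)) .stage("write", .write_outputs(report, cfg))
  report
}

.write_outputs <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  wt <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$counts, "gene_counts.tsv")
  wt(report$results, "gene_results.tsv")
  wt(report$scatter, "change_scatter.tsv")
  wt(report$cdf, "cdf_curves.tsv")
  wt(report$sites, "polya_sites.tsv")
  wt(report$pass_report, "pass_report.tsv")
  wt(report$assignment_tally, "assignment_tally.tsv")
  wt(report$tss_histogram, "tss_distance_histogram.tsv")
  if (!is.null(report$nucleotide_profile)) {
    wt(report$nucleotide_profile, "nucleotide_profile.tsv")
  }
  if (!is.null(report$metagene)) wt(report$metagene, "tss_metagene.tsv")
  e <- report$enrichment
  jsonlite::write_json(
    list(n_up = e$n_up, n_dn = e$n_dn, ratio = e$ratio, chi2 = e$chi2,
         p_chi2 = e$p_chi2,
         pass = stats::setNames(as.list(report$pass_report$n_pass),
                                report$pass_report$sample),
         chi2_model = "1-df goodness-of-fit, UP vs DN against 50:50, no continuity correction"),
    p("summary.json"), auto_unbox = TRUE, digits = NA
  )
  cfg_echo <- cfg
  for (k in c("genome", "annotation", "reads")) {
    if (!is.character(cfg_echo[[k]])) {
      cfg_echo[[k]] <- paste0("<in-memory ", class(cfg[[k]])[1], ">")
    }
  }
  jsonlite::write_json(cfg_echo, p("config_echo.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(NULL)
}

#' @export
print.uarna_run <- function(x, ...) {
  cat("uaRNA pipeline run\n")
  cat("  genes:", x$n_genes, "\n")
  print(x$pass_report)
  print(x$assignment_tally)
  print(x$enrichment)
  invisible(x)
}
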