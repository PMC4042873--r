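## Per-gene Fisher exact comparison of uaRNA vs sense reads between two
## samples, UP/DN classification, global enrichment, and expression-change
## summaries (scatter, CDF curves).

#' Statistical configuration
#'
#' @param alpha Per-gene significance level for the Fisher test (default
#'   0.05, the conventional selection threshold).
#' @param min_reads_cdf Minimum combined reads (both samples) for a gene to
#'   enter the CDF curves (default 20).
#' @param pseudocount Reads added per sample before log2 ratios, converted
#'   to the RPM scale of each library (default 0.5).
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, min_reads_cdf = 20L, pseudocount = 0.5) {
  stopifnot(alpha > 0, alpha < 1, min_reads_cdf >= 0, pseudocount > 0)
  structure(list(alpha = alpha, min_reads_cdf = as.integer(min_reads_cdf),
                 pseudocount = pseudocount),
            class = "stats_config")
}

## Two-sided p-values for every observable first cell given fixed margins.
## m, n2: row totals; k: first-column total. Probability-mass method: the
## p-value of observed a is the total hypergeometric mass of all tables (same
## margins) whose probability is <= that of a, with a small relative
## tolerance absorbing floating-point ties.
.fisher_pvals <- function(m, n2, k, tol = 1e-7) {
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  pmf <- stats::dhyper(lo:hi, m, n2, k)
  s <- sort(pmf)
  cs <- cumsum(s)
  pmin(cs[findInterval(pmf * (1 + tol), s)], 1)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by the probability-mass method: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (with relative
#' tolerance 1e-7 for floating-point ties). A table with an empty row or
#' column has p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @param alternative `"two.sided"` (default), or the one-sided tails
#'   `"greater"` / `"less"` on the first cell.
#' @return The p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (m == 0L || n2 == 0L || k == 0L || b + d == 0L) return(1)
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  switch(alternative,
    two.sided = .fisher_pvals(m, n2, k)[a - lo + 1L],
    greater = min(1, sum(stats::dhyper(a:hi, m, n2, k))),
    less = min(1, sum(stats::dhyper(lo:a, m, n2, k)))
  )
}

#' Classify per-gene uaRNA regulation between two samples
#'
#' For each gene, all uaRNA reads are compared to all sense reads between
#' the test and reference samples in a 2x2 table
#' `[[ua_test, sense_test], [ua_ref, sense_ref]]`. Genes with p below
#' `cfg$alpha` are called `UP` when the uaRNA:sense balance shifts up in the
#' test sample and `DN` when it shifts down; all other genes, including
#' genes with no uaRNA reads in either sample (p set to 1), are `NC`.
#'
#' The odds ratio is `(ua_test * sense_ref) / (sense_test * ua_ref)`; with a
#' zero cell the reported value may be 0, `Inf` or `NaN`, and the call
#' direction is taken from the sign of
#' `ua_test * sense_ref - ua_ref * sense_test`.
#'
#' @param counts Count table from [build_count_table()] (RPM columns are
#'   allowed and ignored).
#' @param test,ref Sample names for the test (e.g. mutant) and reference
#'   (e.g. control) roles.
#' @param cfg A [stats_config()].
#' @return A `data.frame` with `gene_id`, the four cell counts,
#'   `odds_ratio`, `p` and `call` (`UP`/`DN`/`NC`).
#' @export
classify_genes <- function(counts, test, ref, cfg = stats_config()) {
  for (col in c(paste0(c("ua_", "sense_"), test), paste0(c("ua_", "sense_"), ref))) {
    if (!col %in% names(counts)) stop("missing sample column: ", col)
  }
  ua_t <- counts[[paste0("ua_", test)]]
  se_t <- counts[[paste0("sense_", test)]]
  ua_r <- counts[[paste0("ua_", ref)]]
  se_r <- counts[[paste0("sense_", ref)]]

  p <- mapply(fisher_exact_two_sided, ua_t, se_t, ua_r, se_r)
  p[ua_t + ua_r == 0L] <- 1
  dir <- ua_t * se_r - ua_r * se_t
  call <- rep("NC", nrow(counts))
  call[p < cfg$alpha & dir > 0] <- "UP"
  call[p < cfg$alpha & dir < 0] <- "DN"
  data.frame(
    gene_id = counts$gene_id,
    ua_test = ua_t, sense_test = se_t, ua_ref = ua_r, sense_ref = se_r,
    odds_ratio = (ua_t * se_r) / (se_t * ua_r),
    p = p, call = call, stringsAsFactors = FALSE
  )
}

#' Upper-tail probability of a 1-df chi-squared statistic
#'
#' @param chi2 Non-negative statistic(s).
#' @return Upper-tail probabilities.
#' @export
chisq_tail_p <- function(chi2) {
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Global UP/DN enrichment summary
#'
#' Counts UP and DN genes, their ratio, and a 1-df chi-squared
#' goodness-of-fit statistic against an equal UP:DN expectation (no
#' continuity correction): `chi2 = (n_up - n_dn)^2 / (n_up + n_dn)`.
#'
#' @param results Output of [classify_genes()].
#' @return A list of class `enrichment_summary` with `n_up`, `n_dn`,
#'   `ratio` (`Inf` when `n_dn` is 0, `NaN` when both are 0), `chi2`,
#'   `p_chi2`, and `degenerate` (TRUE when no gene is UP or DN, in which
#'   case p is 1).
#' @export
global_enrichment <- function(results) {
  n_up <- sum(results$call == "UP")
  n_dn <- sum(results$call == "DN")
  degenerate <- n_up + n_dn == 0L
  chi2 <- if (degenerate) 0 else (n_up - n_dn)^2 / (n_up + n_dn)
  structure(
    list(n_up = n_up, n_dn = n_dn, ratio = n_up / n_dn,
         chi2 = chi2, p_chi2 = if (degenerate) 1 else chisq_tail_p(chi2),
         degenerate = degenerate),
    class = "enrichment_summary"
  )
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat("uaRNA regulation enrichment\n")
  cat(sprintf("  UP: %d  DN: %d  UP/DN: %.3g\n", x$n_up, x$n_dn, x$ratio))
  cat(sprintf("  chi-squared (1 df): %.4g, p = %.4g\n", x$chi2, x$p_chi2))
  invisible(x)
}

## Per-sample pseudocount on the RPM scale.
.pc_rpm <- function(cfg, totals, sample) cfg$pseudocount * 1e6 / totals[[sample]]

#' Per-gene uaRNA vs sense expression change (scatter data)
#'
#' log2 RPM ratios (test over reference, pseudocounted) for the uaRNA and
#' sense categories of every gene, with a significance flag from the
#' per-gene Fisher call.
#'
#' @param counts RPM-normalized count table (see [rpm_normalize()]).
#' @param results Output of [classify_genes()].
#' @param test,ref Sample names.
#' @param totals Named vector of total PASS reads per sample (pseudocount
#'   scale).
#' @param cfg A [stats_config()].
#' @return A `data.frame` with `gene_id`, `log2_ua_change`,
#'   `log2_sense_change`, `significant`.
#' @export
change_scatter <- function(counts, results, test, ref, totals,
                           cfg = stats_config()) {
  pc_t <- .pc_rpm(cfg, totals, test)
  pc_r <- .pc_rpm(cfg, totals, ref)
  data.frame(
    gene_id = counts$gene_id,
    log2_ua_change = log2((counts[[paste0("ua_rpm_", test)]] + pc_t) /
                          (counts[[paste0("ua_rpm_", ref)]] + pc_r)),
    log2_sense_change = log2((counts[[paste0("sense_rpm_", test)]] + pc_t) /
                             (counts[[paste0("sense_rpm_", ref)]] + pc_r)),
    significant = results$call[match(counts$gene_id, results$gene_id)] %in%
      c("UP", "DN"),
    stringsAsFactors = FALSE
  )
}

#' CDF curves of log2 expression change by transcript category
#'
#' Empirical cumulative distributions of log2 RPM change (test over
#' reference) for: uaRNAs; all sense transcripts; sense transcripts of genes
#' with UP uaRNAs; with non-regulated (detected, not UP/DN) uaRNAs; and with
#' no detectable uaRNAs. Only genes with at least `cfg$min_reads_cdf` reads
#' in the two samples combined (within the plotted category) are used.
#'
#' @inheritParams change_scatter
#' @return A `data.frame` with `category`, `gene_id`, `log2fc` and `cdf`
#'   (empirical CDF value at that gene, within category). Empty categories
#'   are omitted with a warning.
#' @export
cdf_curves <- function(counts, results, test, ref, totals,
                       cfg = stats_config()) {
  pc_t <- .pc_rpm(cfg, totals, test)
  pc_r <- .pc_rpm(cfg, totals, ref)
  res <- results[match(counts$gene_id, results$gene_id), ]
  ua_reads <- counts[[paste0("ua_", test)]] + counts[[paste0("ua_", ref)]]
  sense_reads <- counts[[paste0("sense_", test)]] + counts[[paste0("sense_", ref)]]
  ua_fc <- log2((counts[[paste0("ua_rpm_", test)]] + pc_t) /
                (counts[[paste0("ua_rpm_", ref)]] + pc_r))
  sense_fc <- log2((counts[[paste0("sense_rpm_", test)]] + pc_t) /
                   (counts[[paste0("sense_rpm_", ref)]] + pc_r))

  sel <- list(
    uaRNA = list(keep = ua_reads >= cfg$min_reads_cdf & ua_reads > 0L,
                 fc = ua_fc),
    sense_all = list(keep = sense_reads >= cfg$min_reads_cdf, fc = sense_fc),
    sense_ua_up = list(keep = sense_reads >= cfg$min_reads_cdf &
                         res$call == "UP", fc = sense_fc),
    sense_ua_nonregulated = list(keep = sense_reads >= cfg$min_reads_cdf &
                                   ua_reads > 0L & res$call == "NC",
                                 fc = sense_fc),
    sense_no_ua = list(keep = sense_reads >= cfg$min_reads_cdf &
                         ua_reads == 0L, fc = sense_fc)
  )
  out <- list()
  for (nm in names(sel)) {
    keep <- which(sel[[nm]]$keep)
    if (!length(keep)) {
      warning("empty CDF category omitted: ", nm)
      next
    }
    fc <- sel[[nm]]$fc[keep]
    o <- order(fc)
    out[[nm]] <- data.frame(
      category = nm, gene_id = counts$gene_id[keep][o], log2fc = fc[o],
      cdf = seq_along(o) / length(o), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
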