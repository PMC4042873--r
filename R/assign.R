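## Strand-aware assignment of PASS reads to genes (sense vs uaRNA) and
## per-gene count tables with RPM normalization.
##
## Assignment uses the read's inferred poly(A) site as the coordinate.
## Sense assignment strictly precedes uaRNA: a read whose 3' end falls in
## exactly one gene's (extended) sense region on the read's strand is sense
## for that gene; in more than one, it is ambiguous and excluded from
## counts. Only reads that are not sense-assignable anywhere may be uaRNA,
## and only when the 3' end lies in a uaRNA window on the read's strand
## (nearest TSS wins when windows overlap; ties go to the smallest gene_id).

## Shared point-assignment core: positions + strands -> category / gene_id.
.assign_positions <- function(chrom, strand, pos, index) {
  n <- length(pos)
  category <- rep("unassigned", n)
  gene_id <- rep(NA_character_, n)

  known <- chrom %in% names(index$genome_lengths)
  if (any(!known)) {
    warning("reads on chromosome(s) absent from the index left unassigned: ",
            paste(unique(chrom[!known]), collapse = ", "))
  }
  if (!any(known)) {
    return(data.frame(category = category, gene_id = gene_id,
                      stringsAsFactors = FALSE))
  }
  ki <- which(known)
  pts <- GenomicRanges::GRanges(
    chrom[ki], IRanges::IRanges(pos[ki] + 1L, width = 1L), strand = strand[ki]
  )
  suppressWarnings({
    ovs <- GenomicRanges::findOverlaps(pts, index$sense)
    ovu <- GenomicRanges::findOverlaps(pts, index$ua)
  })
  n_sense <- tabulate(queryHits(ovs), nbins = length(pts))

  one <- n_sense == 1L
  if (any(one)) {
    first <- ovs[!duplicated(queryHits(ovs))]
    qh <- queryHits(first)
    sel <- one[qh]
    category[ki[qh[sel]]] <- "sense"
    gene_id[ki[qh[sel]]] <- index$sense$gene_id[subjectHits(first)[sel]]
  }
  category[ki[n_sense > 1L]] <- "ambiguous"

  cand <- which(n_sense == 0L)
  if (length(cand) && length(ovu)) {
    keep <- queryHits(ovu) %in% cand
    q <- queryHits(ovu)[keep]
    s <- subjectHits(ovu)[keep]
    if (length(q)) {
      d <- abs(pos[ki[q]] - index$ua$tss[s])
      gid <- index$ua$gene_id[s]
      o <- order(q, d, gid)
      pick <- o[!duplicated(q[o])]
      category[ki[q[pick]]] <- "uaRNA"
      gene_id[ki[q[pick]]] <- gid[pick]
    }
  }
  data.frame(category = category, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Assign PASS reads to genes as sense or uaRNA
#'
#' @param pass PASS reads from [call_pass()].
#' @param index A `region_index` from [build_region_index()].
#' @return `pass` with added `category` (one of `sense`, `uaRNA`,
#'   `ambiguous`, `unassigned`) and `gene_id` (`NA` unless sense/uaRNA)
#'   columns; exactly one row per input read.
#' @export
assign_reads <- function(pass, index) {
  res <- .assign_positions(pass$chrom, pass$strand, pass$pa_site, index)
  pass$category <- res$category
  pass$gene_id <- res$gene_id
  pass
}

#' Per-gene, per-sample sense and uaRNA counts
#'
#' Genes without any assigned read are retained with zero counts, so the
#' table always covers the full annotation.
#'
#' @param assignments A data.frame from [assign_reads()] with a `sample`
#'   column, or a named list of per-sample data.frames.
#' @param genes Gene models (defines the row universe and order).
#' @return A `data.frame` with `gene_id` and `sense_<sample>` /
#'   `ua_<sample>` integer columns for every sample.
#' @export
build_count_table <- function(assignments, genes) {
  if (is.data.frame(assignments)) {
    if (!"sample" %in% names(assignments)) assignments$sample <- "S1"
    assignments <- split(assignments, assignments$sample)
  }
  if (anyDuplicated(names(assignments))) stop("duplicated sample names")
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (s in names(assignments)) {
    a <- assignments[[s]]
    f <- factor(a$gene_id, levels = genes$gene_id)
    out[[paste0("sense_", s)]] <-
      as.integer(table(f[a$category == "sense"]))
    out[[paste0("ua_", s)]] <-
      as.integer(table(f[a$category == "uaRNA"]))
  }
  out
}

#' Add reads-per-million (RPM) columns to a count table
#'
#' RPM = count x 10^6 / total PASS reads of the sample. The denominator is
#' the library's total PASS reads, not its assigned reads.
#'
#' @param counts Output of [build_count_table()].
#' @param totals Named numeric vector of total PASS reads per sample.
#' @return `counts` with added `sense_rpm_<sample>` / `ua_rpm_<sample>`.
#' @export
rpm_normalize <- function(counts, totals) {
  samples <- sub("^sense_", "",
                 grep("^sense_(?!rpm_)", names(counts), value = TRUE, perl = TRUE))
  for (s in samples) {
    if (!s %in% names(totals) || is.na(totals[[s]])) {
      stop("no PASS total for sample: ", s)
    }
    tot <- totals[[s]]
    if (tot <= 0) stop("total PASS reads must be > 0 for sample: ", s)
    counts[[paste0("sense_rpm_", s)]] <- counts[[paste0("sense_", s)]] * 1e6 / tot
    counts[[paste0("ua_rpm_", s)]] <- counts[[paste0("ua_", s)]] * 1e6 / tot
  }
  counts
}

#' Tally assignment categories per sample
#'
#' Convenience summary used by the pipeline report and the partition
#' invariant (sense + uaRNA + ambiguous + unassigned = total PASS reads).
#'
#' @param assignments As in [build_count_table()].
#' @return A `data.frame` with one row per sample and one column per
#'   category, plus `total`.
#' @export
assignment_tally <- function(assignments) {
  if (is.data.frame(assignments)) {
    if (!"sample" %in% names(assignments)) assignments$sample <- "S1"
    assignments <- split(assignments, assignments$sample)
  }
  cats <- c("sense", "uaRNA", "ambiguous", "unassigned")
  rows <- lapply(names(assignments), function(s) {
    a <- assignments[[s]]
    cnt <- vapply(cats, function(k) sum(a$category == k), integer(1))
    data.frame(sample = s, as.list(cnt), total = nrow(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
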