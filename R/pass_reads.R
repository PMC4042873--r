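## PASS read calling and poly(A)-site clustering.
##
## A 3'-end read supports a cleavage/polyadenylation site when its 3'
## soft-clipped tail carries at least two As that cannot be explained by the
## reference ("non-genomic As"). Non-genomic content is determined by the
## longest templated prefix: tail bases are compared base-for-base with the
## reference continuation downstream of the alignment (strand-aware,
## reverse-complemented for - reads); whatever follows the first mismatch is
## non-genomic. The poly(A) site is the last aligned base advanced past the
## templated prefix.

#' Read aligned 3'-end reads from the plain-text table dialect
#'
#' Columns: `read_id`, `chrom`, `strand`, `aln_start`, `aln_end` (0-based
#' half-open aligned block), `tail_seq` (3' soft-clip in read orientation,
#' possibly empty), and optionally `sample`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `data.frame` of aligned reads.
#' @export
read_aligned_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(tail_seq = "character"))
  need <- c("read_id", "chrom", "strand", "aln_start", "aln_end", "tail_seq")
  if (!all(need %in% names(df))) {
    stop("aligned-read table must have columns: ", paste(need, collapse = ", "))
  }
  df$tail_seq[is.na(df$tail_seq)] <- ""
  df
}

#' Read aligned 3'-end reads from a SAM/BAM file
#'
#' The 3' soft clip (in read orientation) is taken from the CIGAR: the
#' trailing `S` operation for forward-strand alignments, the leading `S`
#' operation (reverse-complemented) for reverse-strand alignments.
#'
#' @param path Path to a SAM (converted on the fly) or BAM file.
#' @param sample Optional sample name recorded in a `sample` column.
#' @return A `data.frame` in the same shape as [read_aligned_tsv()].
#' @export
read_aligned_sam <- function(path, sample = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "seq"))
  )
  cig <- GenomicAlignments::cigar(aln)
  left <- right <- integer(length(cig))
  hasl <- grepl("^\\d+S", cig)
  left[hasl] <- as.integer(sub("^(\\d+)S.*$", "\\1", cig[hasl]))
  hasr <- grepl("\\d+S$", cig)
  right[hasr] <- as.integer(sub("^.*?(\\d+)S$", "\\1", cig[hasr]))
  seqs <- as.character(mcols(aln)$seq)
  qlen <- nchar(seqs)
  minus <- as.character(GenomicAlignments::strand(aln)) == "-"
  tail <- character(length(aln))
  tail[!minus] <- substring(seqs[!minus], qlen[!minus] - right[!minus] + 1L)
  tail[!minus][right[!minus] == 0L] <- ""
  tail[minus] <- .revcomp(substring(seqs[minus], 1L, left[minus]))
  df <- data.frame(
    read_id = mcols(aln)$qname,
    chrom = as.character(GenomicAlignments::seqnames(aln)),
    strand = as.character(GenomicAlignments::strand(aln)),
    aln_start = GenomicAlignments::start(aln) - 1L,
    aln_end = GenomicAlignments::end(aln),
    tail_seq = tail,
    stringsAsFactors = FALSE
  )
  if (!is.null(sample)) df$sample <- sample
  df
}

#' Call poly(A)-site-supporting (PASS) reads
#'
#' A read is PASS when (a) its 3' tail carries at least `min_nongenomic_a`
#' As after removal of the longest reference-templated prefix and (b) the
#' A-fraction of the whole tail is at least `min_a_fraction` (guards against
#' non-poly(A) soft clips). `N` bases never count as A and never match the
#' reference. Where the reference is exhausted (chromosome edge), remaining
#' tail bases count as non-genomic.
#'
#' @param reads Aligned reads (see [read_aligned_tsv()]).
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param min_nongenomic_a Minimum non-genomic As (default 2).
#' @param min_a_fraction Minimum A-fraction of the tail (default 0.8).
#' @return A `data.frame` of PASS reads: `read_id`, `chrom`, `strand`,
#'   `pa_site` (0-based position of the inferred cleavage site, i.e. the
#'   last aligned base advanced past templated tail bases), `nongenomic_a`,
#'   plus `sample` if present in `reads`.
#' @export
call_pass <- function(reads, genome, min_nongenomic_a = 2L,
                      min_a_fraction = 0.8) {
  genome <- .load_genome(genome)
  n <- nrow(reads)
  tail <- toupper(as.character(reads$tail_seq))
  tail[is.na(tail)] <- ""
  tlen <- nchar(tail)
  if (any(grepl("[^ACGTN]", tail))) stop("tail_seq contains non-ACGTN characters")

  ref <- character(n)
  for (chr in unique(reads$chrom)) {
    ii <- which(reads$chrom == chr)
    if (!chr %in% names(genome)) {
      warning("chromosome absent from genome: ", chr,
              " (tails treated as fully non-genomic)")
      next
    }
    cs <- genome[[chr]]
    plus <- ii[reads$strand[ii] == "+"]
    minus <- ii[reads$strand[ii] == "-"]
    if (length(plus)) {
      ref[plus] <- .extract_ref(cs, reads$aln_end[plus] + 1L,
                                reads$aln_end[plus] + tlen[plus])
    }
    if (length(minus)) {
      ## transcript-direction continuation = revcomp of upstream genomic bases
      ref[minus] <- .revcomp(.extract_ref(cs, reads$aln_start[minus] - tlen[minus] + 1L,
                                          reads$aln_start[minus]))
    }
  }

  ## longest templated prefix length k, per read
  k <- integer(n)
  alive <- tlen > 0L
  for (j in seq_len(max(c(tlen, 0L)))) {
    tb <- substr(tail, j, j)
    rb <- substr(ref, j, j)
    m <- alive & tb != "" & rb != "" & tb == rb & tb != "N"
    k[m] <- j
    alive <- m
    if (!any(alive)) break
  }

  nong <- substring(tail, k + 1L)
  a_ng <- nchar(nong) - nchar(gsub("A", "", nong, fixed = TRUE))
  a_all <- tlen - nchar(gsub("A", "", tail, fixed = TRUE))
  is_pass <- tlen > 0L & a_ng >= min_nongenomic_a &
    (a_all / pmax(tlen, 1L)) >= min_a_fraction

  pa <- ifelse(reads$strand == "+", reads$aln_end - 1L + k, reads$aln_start - k)
  out <- data.frame(
    read_id = reads$read_id[is_pass],
    chrom = reads$chrom[is_pass],
    strand = reads$strand[is_pass],
    pa_site = as.integer(pa[is_pass]),
    nongenomic_a = as.integer(a_ng[is_pass]),
    stringsAsFactors = FALSE
  )
  if ("sample" %in% names(reads)) out$sample <- reads$sample[is_pass]
  out
}

#' Cluster PASS read 3' ends into poly(A) sites
#'
#' Single-linkage clustering of cleavage positions within `window` bp on the
#' same chromosome and strand. The representative position of a cluster is
#' the member with the highest pooled (all-sample) read count; ties go to the
#' 5'-most member (strand-aware). Per-sample counts are summed over members,
#' so total reads are conserved and the result is independent of input order.
#'
#' @param pass PASS reads from [call_pass()]; a missing `sample` column is
#'   treated as one sample `"S1"`.
#' @param window Maximum gap between neighbouring members in bp (default 24).
#' @return A `data.frame` with `chrom`, `strand`, `position`, one
#'   `count_<sample>` column per sample, and `total`.
#' @export
cluster_sites <- function(pass, window = 24L) {
  if (!"sample" %in% names(pass)) pass$sample <- "S1"
  samples <- sort(unique(pass$sample))

  ## unique positions, grouped by chrom+strand, single-linkage chained
  up <- unique(pass[, c("chrom", "strand", "pa_site")])
  up <- up[order(up$chrom, up$strand, up$pa_site), , drop = FALSE]
  n <- nrow(up)
  same_grp <- c(FALSE, up$chrom[-1] == up$chrom[-n] & up$strand[-1] == up$strand[-n])
  gap <- c(NA_integer_, diff(up$pa_site))
  up$cluster <- cumsum(!(same_grp & gap <= window))

  idx <- match(paste(pass$chrom, pass$strand, pass$pa_site),
               paste(up$chrom, up$strand, up$pa_site))
  cl_of_read <- up$cluster[idx]
  up$pooled <- tabulate(idx, nbins = n)

  ## representative: highest pooled count, ties to the strand-aware 5'-most
  pos5 <- ifelse(up$strand == "+", up$pa_site, -up$pa_site)
  o <- order(up$cluster, -up$pooled, pos5)
  rep_rows <- o[!duplicated(up$cluster[o])]
  res <- data.frame(
    chrom = up$chrom[rep_rows], strand = up$strand[rep_rows],
    position = up$pa_site[rep_rows], stringsAsFactors = FALSE
  )
  n_cl <- max(up$cluster)
  for (s in samples) {
    res[[paste0("count_", s)]] <-
      tabulate(cl_of_read[pass$sample == s], nbins = n_cl)[up$cluster[rep_rows]]
  }
  res$total <- tabulate(cl_of_read, nbins = n_cl)[up$cluster[rep_rows]]
  res <- res[order(res$chrom, res$strand, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-library PASS read tally
#'
#' @param reads Input aligned reads (with optional `sample` column).
#' @param pass The corresponding [call_pass()] output.
#' @param samples Optional explicit sample universe (so empty libraries
#'   still get a row); defaults to the samples seen in the data.
#' @return A `data.frame` with `sample`, `n_input`, `n_pass`,
#'   `pass_fraction` (`NA` for empty libraries).
#' @export
pass_report <- function(reads, pass, samples = NULL) {
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  if (!"sample" %in% names(pass)) pass$sample <- "S1"
  if (is.null(samples)) samples <- sort(unique(c(reads$sample, pass$sample)))
  n_in <- vapply(samples, function(s) sum(reads$sample == s), integer(1))
  n_pass <- vapply(samples, function(s) sum(pass$sample == s), integer(1))
  data.frame(
    sample = samples, n_input = n_in, n_pass = n_pass,
    pass_fraction = ifelse(n_in > 0, n_pass / n_in, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write PASS reads or poly(A) sites as BED6
#'
#' For PASS reads the score column is the non-genomic A count; for clustered
#' sites it is the pooled read count.
#'
#' @param x Output of [call_pass()] or [cluster_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(x, path) {
  if ("pa_site" %in% names(x)) {
    df <- data.frame(chrom = x$chrom, start = x$pa_site, end = x$pa_site + 1L,
                     name = x$read_id, score = x$nongenomic_a, strand = x$strand)
  } else {
    df <- data.frame(chrom = x$chrom, start = x$position, end = x$position + 1L,
                     name = paste0("pa_", seq_len(nrow(x))), score = x$total,
                     strand = x$strand)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
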