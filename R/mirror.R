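## Reverse-complement mirroring of a whole dataset. Used to verify strand
## symmetry: flipping every strand and mirroring every coordinate must leave
## all counts, calls and summaries identical.

#' Reverse-complement a genome
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @return The mirrored genome (same names).
#' @export
mirror_genome <- function(genome) {
  out <- Biostrings::reverseComplement(genome)
  names(out) <- names(genome)
  out
}

#' Mirror an annotation
#'
#' Maps each record `[start, end)` on chromosome of length L to
#' `[L - end, L - start)` and flips its strand. TSS and extension fields are
#' re-derived, so apply [extend_three_prime()] afterwards as usual.
#'
#' @param genes Gene models (or any table with `gene_id`, `chrom`,
#'   `strand`, `start`, `end`).
#' @param genome_lengths Named vector of chromosome lengths.
#' @return Mirrored gene models.
#' @export
mirror_annotation <- function(genes, genome_lengths) {
  L <- as.integer(genome_lengths[genes$chrom])
  df <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    strand = ifelse(genes$strand == "+", "-", "+"),
    start = L - genes$end, end = L - genes$start,
    stringsAsFactors = FALSE
  )
  as_gene_models(df, genome_lengths)
}

#' Mirror aligned reads
#'
#' Coordinates are mirrored, strands flipped; the tail sequence (read
#' orientation) is unchanged.
#'
#' @param reads Aligned-read `data.frame`.
#' @param genome_lengths Named vector of chromosome lengths.
#' @return Mirrored reads.
#' @export
mirror_reads <- function(reads, genome_lengths) {
  L <- as.integer(genome_lengths[reads$chrom])
  out <- reads
  out$strand <- ifelse(reads$strand == "+", "-", "+")
  out$aln_start <- L - reads$aln_end
  out$aln_end <- L - reads$aln_start
  out
}
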