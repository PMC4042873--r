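## Gene models, 3' extension, and the strand-aware region index.
##
## Coordinates are 0-based half-open everywhere inside the package. BED input
## is consumed as 0-based half-open and GTF as 1-based inclusive; both are
## converted on load. The TSS of a gene is `start` on the + strand and
## `end - 1` on the - strand.

#' Load gene models from a BED or GTF annotation
#'
#' Reads an annotation file, merges all records sharing a `gene_id` (BED name
#' column, GTF `gene_id` attribute) to the gene's maximal span, and derives
#' the strand-aware transcription start site. Records on chromosomes absent
#' from `genome_lengths` are dropped with a warning; records without a `+` or
#' `-` strand are an error.
#'
#' @param annotation Path to a BED (including BED12) or GTF file, or a
#'   data.frame with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @param genome_lengths Named vector of chromosome lengths (see
#'   [fasta_lengths()]).
#' @param format `"auto"` (by file extension), `"bed"` or `"gtf"`.
#' @return A `data.frame` of gene models with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `ext_start`, `ext_end`, ordered by
#'   (chrom, start, gene_id). `ext_start`/`ext_end` hold the extended span
#'   and equal the native span until [extend_three_prime()] is applied.
#' @export
load_gene_models <- function(annotation, genome_lengths,
                             format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (is.character(annotation)) {
    if (format == "auto") {
      format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", annotation, ignore.case = TRUE))
        "gtf" else "bed"
    }
    gr <- rtracklayer::import(annotation, format = format)
    gene_id <- if (format == "bed") gr$name else mcols(gr)$gene_id
    if (is.null(gene_id)) stop("annotation records carry no gene identifier")
    df <- data.frame(
      gene_id = as.character(gene_id),
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      strand  = as.character(GenomicRanges::strand(gr)),
      start   = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end     = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    df <- as.data.frame(annotation)[, c("gene_id", "chrom", "strand", "start", "end")]
  }
  as_gene_models(df, genome_lengths)
}

#' Build gene models from a raw record table
#'
#' Workhorse behind [load_gene_models()]; also used for in-memory annotations
#' such as the simulator's. Applies the transcript-merge rule, validates
#' records and derives TSS and (unextended) 3' boundaries.
#'
#' @inheritParams load_gene_models
#' @return See [load_gene_models()].
#' @export
as_gene_models <- function(annotation, genome_lengths) {
  df <- as.data.frame(annotation)
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("strand must be '+' or '-' (offending gene_id: ",
         paste(unique(df$gene_id[bad_strand]), collapse = ", "), ")")
  }
  if (any(df$start >= df$end)) {
    stop("gene records with start >= end: ",
         paste(unique(df$gene_id[df$start >= df$end]), collapse = ", "))
  }
  unknown <- !df$chrom %in% names(genome_lengths)
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " record(s) on unknown chromosome(s): ",
            paste(unique(df$chrom[unknown]), collapse = ", "))
    df <- df[!unknown, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable annotation records")

  ## Merge transcripts of a gene to the gene's maximal span.
  key <- df$gene_id
  chrom  <- tapply(df$chrom, key, function(x) unique(x))
  if (any(lengths(chrom) != 1L)) {
    stop("gene(s) annotated on multiple chromosomes: ",
         paste(names(chrom)[lengths(chrom) != 1L], collapse = ", "))
  }
  strand <- tapply(df$strand, key, function(x) unique(x))
  if (any(lengths(strand) != 1L)) {
    stop("gene(s) annotated on both strands: ",
         paste(names(strand)[lengths(strand) != 1L], collapse = ", "))
  }
  genes <- data.frame(
    gene_id = names(chrom),
    chrom   = unlist(chrom, use.names = FALSE),
    strand  = unlist(strand, use.names = FALSE),
    start   = as.integer(tapply(df$start, key, min)),
    end     = as.integer(tapply(df$end, key, max)),
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$ext_start <- genes$start
  genes$ext_end <- genes$end
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Extend gene 3' ends into downstream intergenic space
#'
#' Each gene's 3' boundary is pushed downstream by `extension` bp if and only
#' if no other gene on the same strand overlaps the would-be extension
#' interval; the extension is all-or-nothing. Extensions are clipped at
#' chromosome ends. The operation is idempotent: blocking is always evaluated
#' against native gene spans.
#'
#' @param genes Gene models from [load_gene_models()]/[as_gene_models()].
#' @param genome_lengths Named vector of chromosome lengths.
#' @param extension Extension length in bp (default 4000).
#' @return `genes` with `ext_start`/`ext_end` updated.
#' @export
extend_three_prime <- function(genes, genome_lengths, extension = 4000L) {
  stopifnot(extension >= 0)
  extension <- as.integer(extension)
  L <- as.integer(genome_lengths[genes$chrom])
  plus <- genes$strand == "+"

  ## Would-be extension interval, 0-based half-open, clipped at chrom bounds.
  ext_lo <- ifelse(plus, genes$end, pmax(genes$start - extension, 0L))
  ext_hi <- ifelse(plus, pmin(genes$end + extension, L), genes$start)

  native <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand
  )
  nonempty <- ext_hi > ext_lo
  extgr <- GenomicRanges::GRanges(
    genes$chrom[nonempty],
    IRanges::IRanges(ext_lo[nonempty] + 1L, ext_hi[nonempty]),
    strand = genes$strand[nonempty]
  )
  hits <- GenomicRanges::findOverlaps(extgr, native)
  hits <- hits[which(nonempty)[queryHits(hits)] != subjectHits(hits)]
  blocked <- logical(nrow(genes))
  blocked[which(nonempty)[unique(queryHits(hits))]] <- TRUE

  grant <- nonempty & !blocked
  genes$ext_start <- ifelse(!plus & grant, ext_lo, genes$start)
  genes$ext_end <- ifelse(plus & grant, ext_hi, genes$end)
  genes$ext_start <- as.integer(genes$ext_start)
  genes$ext_end <- as.integer(genes$ext_end)
  genes
}

#' Build the strand-aware sense-region / uaRNA-window index
#'
#' The sense region of a gene is its extended span on its own strand. The
#' uaRNA window of a gene covers `ua_window` bp immediately upstream of its
#' TSS on the opposite strand, half-open at the TSS (the TSS itself is
#' excluded) and clipped at chromosome edges: for a + strand gene with TSS t
#' the window is `[t - ua_window, t)` on `-`; for a - strand gene,
#' `[t + 1, t + 1 + ua_window)` on `+`.
#'
#' @param genes Extended gene models (see [extend_three_prime()]).
#' @param genome_lengths Named vector of chromosome lengths.
#' @param ua_window Window size in bp (default 2000).
#' @return A `region_index` list with `sense` and `ua` [GenomicRanges::GRanges]
#'   (1-based internally, `gene_id` and `tss` metadata), the gene table, and
#'   the configuration used.
#' @export
build_region_index <- function(genes, genome_lengths, ua_window = 2000L) {
  stopifnot(ua_window > 0)
  ua_window <- as.integer(ua_window)
  L <- as.integer(genome_lengths[genes$chrom])
  plus <- genes$strand == "+"

  sense <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$ext_start + 1L, genes$ext_end),
    strand = genes$strand, gene_id = genes$gene_id, tss = genes$tss
  )

  ua_lo <- ifelse(plus, pmax(genes$tss - ua_window, 0L), genes$tss + 1L)
  ua_hi <- ifelse(plus, genes$tss, pmin(genes$tss + 1L + ua_window, L))
  keep <- ua_hi > ua_lo
  ua <- GenomicRanges::GRanges(
    genes$chrom[keep], IRanges::IRanges(ua_lo[keep] + 1L, ua_hi[keep]),
    strand = ifelse(plus[keep], "-", "+"),
    gene_id = genes$gene_id[keep], tss = genes$tss[keep]
  )

  structure(
    list(sense = sense, ua = ua, genes = genes,
         ua_window = ua_window, genome_lengths = genome_lengths),
    class = "region_index"
  )
}

#' Write index regions as 6-column BED
#'
#' @param index A `region_index` from [build_region_index()].
#' @param path Output path.
#' @param what `"sense"`, `"ua"` or `"extension"` (the extended-only part of
#'   each sense region).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(index, path, what = c("sense", "ua", "extension")) {
  what <- match.arg(what)
  g <- index$genes
  df <- switch(what,
    sense = data.frame(chrom = g$chrom, start = g$ext_start, end = g$ext_end,
                       name = g$gene_id, score = 0L, strand = g$strand),
    extension = {
      plus <- g$strand == "+"
      ext <- data.frame(chrom = g$chrom,
                        start = ifelse(plus, g$end, g$ext_start),
                        end = ifelse(plus, g$ext_end, g$start),
                        name = g$gene_id, score = 0L, strand = g$strand)
      ext[ext$end > ext$start, , drop = FALSE]
    },
    ua = {
      ua <- index$ua
      data.frame(chrom = as.character(GenomicRanges::seqnames(ua)),
                 start = GenomicRanges::start(ua) - 1L,
                 end = GenomicRanges::end(ua),
                 name = ua$gene_id, score = 0L,
                 strand = as.character(GenomicRanges::strand(ua)))
    }
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
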