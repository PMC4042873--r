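# Programmatic fixtures shared across tests.

# A genome of repeated filler with specific bases written at given 1-based
# positions: toy_genome(chr1 = list(len = 300, "151" = "G", "152" = "C")).
toy_genome <- function(..., filler = "C") {
  spec <- list(...)
  seqs <- vapply(spec, function(s) {
    x <- rep(filler, s$len)
    for (nm in setdiff(names(s), "len")) {
      pos <- as.integer(nm)
      bases <- strsplit(s[[nm]], "")[[1]]
      x[pos + seq_along(bases) - 1L] <- bases
    }
    paste(x, collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(spec)
  g
}

# Aligned-read row builder.
read_row <- function(read_id, chrom, strand, aln_start, aln_end, tail_seq,
                     sample = NULL) {
  df <- data.frame(read_id = read_id, chrom = chrom, strand = strand,
                   aln_start = aln_start, aln_end = aln_end,
                   tail_seq = tail_seq, stringsAsFactors = FALSE)
  if (!is.null(sample)) df$sample <- sample
  df
}

# Gene-model table from vectors (0-based half-open), already validated.
gene_table <- function(gene_id, chrom, strand, start, end, lens) {
  as_gene_models(
    data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
               start = start, end = end, stringsAsFactors = FALSE),
    lens
  )
}

# Small simulated dataset used by several suites (seeded, cached per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_chroms = 2, chrom_len = 220000,
                        n_genes = 30, reads_per_lib = 20000,
                        n_up = 5, n_dn = 1)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
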