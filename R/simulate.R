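## Seeded simulator of a toy genome, annotation and two-condition 3'-end
## sequencing reads with truth labels.
##
## The generator emulates the statistical structure the analysis assumes:
## strand-specific reads whose 3' soft clips carry non-templated poly(A)
## tails, sense reads concentrated at designated poly(A) sites near gene 3'
## ends, antisense reads at designated sites within the 2-kb window upstream
## of TSSs, and two-condition counts with planted per-gene fold changes of
## the uaRNA:sense ratio. The reference bases immediately downstream of
## every designated cleavage site are forced to non-A so that truth PASS
## labels are unambiguous (configurable via `templated_a_frac`).

#' Simulation configuration
#'
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param n_genes Number of protein-coding genes.
#' @param gene_len_min,gene_len_max Gene length range in bp.
#' @param min_gap Minimum intergenic gap in bp. The default (8000) exceeds
#'   the 4-kb 3' extension plus the 2-kb uaRNA window, so simulated regions
#'   of neighbouring genes never collide.
#' @param gap_jitter Maximum random addition to the gap in bp.
#' @param expr_meanlog,expr_sdlog Log-normal per-gene sense expression
#'   parameters (natural-log scale).
#' @param ua_ratio Baseline uaRNA:sense read ratio for genes with
#'   detectable uaRNA, in (0, 1).
#' @param ua_detectable_frac Fraction of genes with detectable uaRNA.
#' @param n_up,n_dn Number of genes with a planted increase / decrease of
#'   the uaRNA:sense ratio in the test condition.
#' @param effect_fold Planted fold change (> 1) applied to the uaRNA:sense
#'   ratio of UP genes (and its reciprocal for DN genes) in the test
#'   condition.
#' @param reads_per_lib Expected total reads per library.
#' @param sample_test,sample_ref Library names for the two conditions.
#' @param nb_dispersion `NULL` for Poisson counts, or a negative-binomial
#'   dispersion (e.g. 0.1) for overdispersed counts.
#' @param frac_nonpass Fraction of reads without a usable poly(A) tail
#'   (empty, fully templated, or single-A soft clips).
#' @param frac_noise Fraction of reads from spurious cleavage sites placed
#'   uniformly over the genome.
#' @param read_len Aligned block length in bp.
#' @param tail_len_min,tail_len_max Poly(A) tail length range for
#'   PASS-destined reads.
#' @param polya_signal Hexamer planted upstream of every designated
#'   cleavage site (`NULL` to disable).
#' @param signal_offset Transcript-strand offset of the signal's first base
#'   relative to the cleavage site (default -25, i.e. AATAAA at -25..-20).
#' @param templated_a_frac Fraction of designated sites whose downstream
#'   reference bases are left untouched (possibly A), re-introducing
#'   templated-A ambiguity. Default 0.
#' @param n_sense_sites_max,n_ua_sites_max Maximum designated poly(A) sites
#'   per gene for the sense 3' end and the uaRNA window.
#' @param margin Chromosome-edge margin in bp kept free of genes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 4L, chrom_len = 3.4e6,
                       n_genes = 1000L, gene_len_min = 1000L,
                       gene_len_max = 3000L, min_gap = 8000L,
                       gap_jitter = 2000L, expr_meanlog = 0,
                       expr_sdlog = 1, ua_ratio = 0.1,
                       ua_detectable_frac = 0.5, n_up = 0L, n_dn = 0L,
                       effect_fold = 4, reads_per_lib = 2e5,
                       sample_test = "test", sample_ref = "ref",
                       nb_dispersion = NULL, frac_nonpass = 0.25,
                       frac_noise = 0.05, read_len = 50L,
                       tail_len_min = 8L, tail_len_max = 15L,
                       polya_signal = "AATAAA", signal_offset = -25L,
                       templated_a_frac = 0, n_sense_sites_max = 3L,
                       n_ua_sites_max = 2L, margin = 2100L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= 1, cfg$gene_len_min >= 200, cfg$gene_len_min <= cfg$gene_len_max,
    cfg$ua_ratio > 0, cfg$ua_ratio < 1,
    cfg$ua_detectable_frac >= 0, cfg$ua_detectable_frac <= 1,
    cfg$n_up >= 0, cfg$n_dn >= 0, cfg$effect_fold > 1,
    cfg$frac_nonpass >= 0, cfg$frac_nonpass <= 1,
    cfg$frac_noise >= 0, cfg$frac_noise <= 1,
    cfg$frac_nonpass + cfg$frac_noise < 1,
    cfg$templated_a_frac >= 0, cfg$templated_a_frac <= 1,
    cfg$tail_len_min >= 2, cfg$tail_len_min <= cfg$tail_len_max,
    cfg$sample_test != cfg$sample_ref
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a toy genome
#'
#' Chromosomes of i.i.d. uniform A/C/G/T bases. Cleavage-site-relative
#' sequence features (poly(A) signal, non-A downstream context) are written
#' in later by [simulate_reads()].
#'
#' @param cfg A [sim_config()].
#' @return A named [Biostrings::DNAStringSet] (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(cfg) {
  need <- 2 * cfg$margin +
    ceiling(cfg$n_genes / cfg$n_chroms) *
      (cfg$gene_len_max + cfg$min_gap + cfg$gap_jitter)
  if (need > cfg$chrom_len) {
    stop("chrom_len too small for n_genes with the configured gaps")
  }
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  genome
}

#' Simulate a gene annotation
#'
#' Genes are packed sequentially with random strands and gaps of at least
#' `min_gap` bp, then returned as gene models (see [as_gene_models()]).
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return Gene models `data.frame` (unextended).
#' @export
simulate_annotation <- function(cfg, genome) {
  set.seed(cfg$seed + 1L)
  lens <- fasta_lengths(genome)
  recs <- vector("list", cfg$n_genes)
  placed <- 0L
  for (chr in names(genome)) {
    pos <- cfg$margin
    repeat {
      if (placed >= cfg$n_genes) break
      gap <- cfg$min_gap + sample.int(cfg$gap_jitter + 1L, 1L) - 1L
      len <- sample(cfg$gene_len_min:cfg$gene_len_max, 1L)
      start <- pos + gap
      if (start + len > lens[[chr]] - cfg$margin) break
      placed <- placed + 1L
      recs[[placed]] <- data.frame(
        gene_id = placed, chrom = chr,
        strand = sample(c("+", "-"), 1L),
        start = start, end = start + len, stringsAsFactors = FALSE
      )
      pos <- start + len
    }
    if (placed >= cfg$n_genes) break
  }
  if (placed < cfg$n_genes) {
    stop("could not place ", cfg$n_genes, " genes; enlarge chrom_len/n_chroms")
  }
  df <- do.call(rbind, recs)
  df$gene_id <- sprintf("g%04d", seq_len(nrow(df)))
  as_gene_models(df, lens)
}

#' Plant a poly(A)-signal motif upstream of cleavage sites
#'
#' Writes `motif` on the transcribed strand of each site so that its first
#' base sits at transcript offset `offset` relative to the cleavage
#' position (offset 0). For - strand sites the reverse complement is
#' written at the mirrored genomic coordinates.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param sites `data.frame` with `chrom`, `strand`, `position` (0-based).
#' @param motif Motif string (default `"AATAAA"`).
#' @param offset Transcript-strand offset of the motif start (default -25).
#' @return The edited genome.
#' @export
plant_polya_signal <- function(genome, sites, motif = "AATAAA",
                               offset = -25L) {
  mb <- strsplit(motif, "")[[1]]
  mb_rc <- rev(strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif))), "")[[1]])
  ## genomic (1-based) positions and letters per site
  k <- length(mb)
  n <- nrow(sites)
  plus <- sites$strand == "+"
  pos_list <- letter_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sites$position[i]
    if (plus[i]) {
      pos_list[[i]] <- (p + offset):(p + offset + k - 1L) + 1L
      letter_list[[i]] <- mb
    } else {
      ## transcript offset -j maps to genomic p + j
      pos_list[[i]] <- (p - offset - k + 1L):(p - offset) + 1L
      letter_list[[i]] <- rev(vapply(mb, function(b) {
        chartr("ACGTN", "TGCAN", b)
      }, character(1)))
    }
  }
  .apply_edits(genome, sites$chrom, pos_list, letter_list)
}

## Apply per-site base edits (1-based positions); later sites win.
.apply_edits <- function(genome, chroms, pos_list, letter_list) {
  chrom_rep <- rep(chroms, lengths(pos_list))
  pos <- unlist(pos_list, use.names = FALSE)
  letters <- unlist(letter_list, use.names = FALSE)
  for (chr in unique(chrom_rep)) {
    ii <- which(chrom_rep == chr)
    L <- length(genome[[chr]])
    ok <- pos[ii] >= 1L & pos[ii] <= L
    ii <- ii[ok]
    ## keep the last edit at each position
    last <- rev(!duplicated(rev(pos[ii])))
    ii <- ii[last]
    genome[[chr]] <- Biostrings::replaceLetterAt(
      genome[[chr]], pos[ii], letters[ii]
    )
  }
  genome
}

## Force the two reference bases immediately downstream (transcript
## direction) of each site to non-A, removing templated-A ambiguity.
.force_clean_cleavage <- function(genome, sites) {
  n <- nrow(sites)
  plus <- sites$strand == "+"
  pos_list <- letter_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sites$position[i]
    if (plus[i]) {
      pos_list[[i]] <- c(p + 2L, p + 3L)       # 1-based p+1, p+2
      letter_list[[i]] <- c("G", "C")
    } else {
      pos_list[[i]] <- c(p, p - 1L)            # 1-based p-1, p-2
      letter_list[[i]] <- c("C", "G")          # complement to G, C
    }
  }
  .apply_edits(genome, sites$chrom, pos_list, letter_list)
}

#' Simulate two-condition 3'-end sequencing reads with truth labels
#'
#' Designates 1..`n_sense_sites_max` sense poly(A) sites near each gene's
#' native 3' end and 1..`n_ua_sites_max` antisense sites uniformly within
#' the 2-kb window upstream of its TSS, plants the configured cleavage-site
#' sequence context into the genome, draws per-gene/class/library counts
#' from the noise model with planted fold changes, and emits aligned reads
#' with poly(A) (PASS-destined) or degenerate (non-PASS-destined) tails,
#' plus uniformly placed spurious-site reads.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @param genes Output of [simulate_annotation()].
#' @return A list with `reads` (aligned-read `data.frame` with `sample`
#'   column), `truth_reads` (per-read true category, host gene and PASS
#'   label), `truth_genes` (per-gene regulation class, detectability and
#'   expected counts per library), `sites` (designated cleavage sites),
#'   and `genome` (the edited genome the reads are consistent with).
#' @export
simulate_reads <- function(cfg, genome, genes) {
  set.seed(cfg$seed + 2L)
  n <- nrow(genes)
  libs <- c(cfg$sample_test, cfg$sample_ref)

  ## --- per-gene generative parameters -----------------------------------
  w <- stats::rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  detectable <- stats::runif(n) < cfg$ua_detectable_frac
  if (cfg$n_up + cfg$n_dn > sum(detectable)) {
    stop("not enough uaRNA-detectable genes to plant ",
         cfg$n_up + cfg$n_dn, " effects")
  }
  class <- rep("null", n)
  planted <- sample(which(detectable), cfg$n_up + cfg$n_dn)
  class[planted[seq_len(cfg$n_up)]] <- "up"
  if (cfg$n_dn > 0) class[planted[cfg$n_up + seq_len(cfg$n_dn)]] <- "dn"

  r_ref <- ifelse(detectable, cfg$ua_ratio, 0)
  r_test <- r_ref *
    ifelse(class == "up", cfg$effect_fold,
           ifelse(class == "dn", 1 / cfg$effect_fold, 1))

  ## --- designated cleavage sites ----------------------------------------
  plus <- genes$strand == "+"
  sense_sites <- ua_sites <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- sample.int(cfg$n_sense_sites_max, 1L)
    off <- sample(seq(10L, 190L, by = 30L), ks)  # distinct, >=30 bp apart
    pa <- if (plus[i]) genes$end[i] - 1L - off else genes$start[i] + off
    sense_sites[[i]] <- data.frame(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      strand = genes$strand[i], position = pa, role = "sense",
      stringsAsFactors = FALSE
    )
    ku <- sample.int(cfg$n_ua_sites_max, 1L)
    ## keep >= 35 bp between sites so their planted sequence contexts
    ## (signal at -25..-20, non-A bases at +1..+2) never collide
    repeat {
      d <- sample(seq_len(2000L), ku)
      if (ku == 1L || min(dist(d)) >= 35) break
    }
    pa <- if (plus[i]) genes$tss[i] - d else genes$tss[i] + d
    ua_sites[[i]] <- data.frame(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      strand = if (plus[i]) "-" else "+", position = pa, role = "ua",
      stringsAsFactors = FALSE
    )
  }
  sites <- rbind(do.call(rbind, sense_sites), do.call(rbind, ua_sites))

  ## --- counts per gene / class / library --------------------------------
  draw <- function(mu) {
    if (is.null(cfg$nb_dispersion)) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  }
  assignable <- cfg$reads_per_lib * (1 - cfg$frac_nonpass - cfg$frac_noise)
  lam <- list()
  cnt <- list()
  for (lib in libs) {
    r <- if (lib == cfg$sample_test) r_test else r_ref
    intensity <- w * (1 + r)
    lam_sense <- assignable * w / sum(intensity)
    lam_ua <- assignable * w * r / sum(intensity)
    lam[[lib]] <- list(sense = lam_sense, ua = lam_ua)
    cnt[[lib]] <- list(sense = draw(lam_sense), ua = draw(lam_ua))
  }

  ## --- noise (spurious) sites -------------------------------------------
  lens <- fasta_lengths(genome)
  n_noise <- stats::setNames(
    stats::rpois(2, cfg$reads_per_lib * cfg$frac_noise), libs)
  noise_sites <- NULL
  if (sum(n_noise) > 0) {
    nn <- sum(n_noise)
    chr <- sample(names(genome), nn, replace = TRUE)
    pos <- as.integer(floor(stats::runif(nn, cfg$margin, lens[chr] - cfg$margin)))
    ## keep spurious sites away from gene-site edit footprints (opposite-strand
    ## footprints extend in opposite directions, so the radius must exceed
    ## the signal offset span on both sides: > 50 bp)
    for (ch in unique(chr)) {
      gp <- sort(sites$position[sites$chrom == ch])
      ii <- which(chr == ch)
      for (it in 1:25) {
        j <- findInterval(pos[ii], gp)
        d_lo <- ifelse(j >= 1L, pos[ii] - gp[pmax(j, 1L)], Inf)
        d_hi <- ifelse(j < length(gp), gp[pmin(j + 1L, length(gp))] - pos[ii], Inf)
        bad <- pmin(d_lo, d_hi) < 60
        if (!any(bad)) break
        pos[ii[bad]] <- as.integer(floor(stats::runif(
          sum(bad), cfg$margin, lens[ch] - cfg$margin)))
      }
    }
    noise_sites <- data.frame(
      gene_id = NA_character_, chrom = chr,
      strand = sample(c("+", "-"), nn, replace = TRUE),
      position = pos, role = "noise", stringsAsFactors = FALSE
    )
  }

  ## --- genome edits: motif first, clean cleavage context last -----------
  all_sites <- rbind(sites, noise_sites)
  if (!is.null(cfg$polya_signal)) {
    genome <- plant_polya_signal(genome, all_sites, cfg$polya_signal,
                                 cfg$signal_offset)
  }
  clean <- if (cfg$templated_a_frac > 0) {
    stats::runif(nrow(all_sites)) >= cfg$templated_a_frac
  } else rep(TRUE, nrow(all_sites))
  if (any(clean)) {
    genome <- .force_clean_cleavage(genome, all_sites[clean, , drop = FALSE])
  }

  ## --- emit reads --------------------------------------------------------
  n_sense_per_gene <- vapply(sense_sites, nrow, integer(1))
  n_ua_per_gene <- vapply(ua_sites, nrow, integer(1))
  sense_off <- cumsum(c(0L, n_sense_per_gene))[seq_len(n)]
  ua_off <- sum(n_sense_per_gene) + cumsum(c(0L, n_ua_per_gene))[seq_len(n)]
  out_reads <- out_truth <- list()
  for (lib in libs) {
    site_rows <- integer(0)   # row index into all_sites, one per read
    categ <- character(0)
    for (role in c("sense", "ua")) {
      holder <- if (role == "sense") sense_sites else ua_sites
      counts <- cnt[[lib]][[if (role == "sense") "sense" else "ua"]]
      k_per_gene <- if (role == "sense") n_sense_per_gene else n_ua_per_gene
      base_off <- if (role == "sense") sense_off else ua_off
      rows <- unlist(lapply(seq_len(n), function(i) {
        ni <- counts[i]
        if (ni == 0L) return(integer(0))
        k <- k_per_gene[i]
        alloc <- as.vector(stats::rmultinom(1L, ni, rep(1 / k, k)))
        base_off[i] + rep(seq_len(k), alloc)
      }), use.names = FALSE)
      site_rows <- c(site_rows, rows)
      categ <- c(categ, rep(if (role == "sense") "sense" else "uaRNA",
                            length(rows)))
    }
    ## non-PASS reads: sense sites, genes chosen proportional to expression
    n_np <- stats::rpois(1L, cfg$reads_per_lib * cfg$frac_nonpass)
    if (n_np > 0) {
      gidx <- sample.int(n, n_np, replace = TRUE, prob = w)
      ## uniform site choice within each sampled gene, vectorised
      rows <- sense_off[gidx] + 1L +
        as.integer(floor(stats::runif(n_np) * n_sense_per_gene[gidx]))
      site_rows <- c(site_rows, rows)
      categ <- c(categ, rep("sense", n_np))
    }
    ## noise reads: this library's block of noise sites
    if (n_noise[[lib]] > 0) {
      off0 <- nrow(sites) + if (lib == libs[1]) 0L else n_noise[[libs[1]]]
      rows <- off0 + seq_len(n_noise[[lib]])
      site_rows <- c(site_rows, rows)
      categ <- c(categ, rep("noise", n_noise[[lib]]))
    }
    pass_dest <- c(rep(TRUE, length(site_rows) - n_np - n_noise[[lib]]),
                   rep(FALSE, n_np), rep(TRUE, n_noise[[lib]]))

    ss <- all_sites[site_rows, , drop = FALSE]
    nr <- nrow(ss)
    splus <- ss$strand == "+"
    aln_start <- ifelse(splus, ss$position - cfg$read_len + 1L, ss$position)
    aln_end <- aln_start + cfg$read_len

    ## tails
    tail <- character(nr)
    is_pass <- pass_dest
    tail[is_pass] <- strrep("A", sample(
      cfg$tail_len_min:cfg$tail_len_max, sum(is_pass), replace = TRUE))
    npi <- which(!is_pass)
    if (length(npi)) {
      kind <- sample(c("empty", "templated", "shortA"), length(npi),
                     replace = TRUE, prob = c(0.5, 0.25, 0.25))
      tail[npi[kind == "empty"]] <- ""
      tail[npi[kind == "shortA"]] <- "A"
      ti <- npi[kind == "templated"]
      if (length(ti)) {
        tl <- sample(4:8, length(ti), replace = TRUE)
        tt <- character(length(ti))
        for (chr in unique(ss$chrom[ti])) {
          jj <- which(ss$chrom[ti] == chr)
          cs <- genome[[chr]]
          pl <- splus[ti][jj]
          tt[jj[pl]] <- .extract_ref(cs, ss$position[ti][jj[pl]] + 2L,
                                     ss$position[ti][jj[pl]] + 1L + tl[jj[pl]])
          tt[jj[!pl]] <- .revcomp(.extract_ref(
            cs, ss$position[ti][jj[!pl]] - tl[jj[!pl]] + 1L,
            ss$position[ti][jj[!pl]]))
        }
        tail[ti] <- tt
      }
    }

    ids <- sprintf("%s_%06d", lib, seq_len(nr))
    out_reads[[lib]] <- data.frame(
      read_id = ids, chrom = ss$chrom, strand = ss$strand,
      aln_start = as.integer(aln_start), aln_end = as.integer(aln_end),
      tail_seq = tail, sample = lib, stringsAsFactors = FALSE
    )
    out_truth[[lib]] <- data.frame(
      read_id = ids, sample = lib,
      category = ifelse(categ == "noise", "noise", categ),
      gene_id = ss$gene_id, pass = pass_dest,
      pa_site = ss$position, stringsAsFactors = FALSE
    )
  }

  truth_genes <- data.frame(
    gene_id = genes$gene_id, class = class, ua_detectable = detectable,
    expression_weight = w,
    exp_sense_test = lam[[cfg$sample_test]]$sense,
    exp_ua_test = lam[[cfg$sample_test]]$ua,
    exp_sense_ref = lam[[cfg$sample_ref]]$sense,
    exp_ua_ref = lam[[cfg$sample_ref]]$ua,
    stringsAsFactors = FALSE
  )
  list(
    reads = do.call(rbind, c(out_reads, list(make.row.names = FALSE))),
    truth_reads = do.call(rbind, c(out_truth, list(make.row.names = FALSE))),
    truth_genes = truth_genes,
    sites = all_sites,
    genome = genome
  )
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_genome()], [simulate_annotation()]
#' and [simulate_reads()].
#'
#' @param cfg A [sim_config()].
#' @return The [simulate_reads()] list plus `genes` and `config`.
#' @export
simulate_dataset <- function(cfg) {
  genome <- simulate_genome(cfg)
  genes <- simulate_annotation(cfg, genome)
  sim <- simulate_reads(cfg, genome, genes)
  sim$genes <- genes
  sim$config <- cfg
  sim
}

#' Write aligned reads as the plain-text table dialect
#'
#' @param reads Aligned-read `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param index Also write a samtools-style `.fai` index (default TRUE).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, index = TRUE) {
  Biostrings::writeXStringSet(genome, path)
  if (index) Rsamtools::indexFa(path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Single-block records spanning each gene.
#'
#' @param genes Gene models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed12 <- function(genes, path) {
  df <- data.frame(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0L, strand = genes$strand,
    thickStart = genes$start, thickEnd = genes$end, itemRgb = "0",
    blockCount = 1L, blockSizes = paste0(genes$end - genes$start, ","),
    blockStarts = "0,"
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write aligned reads as SAM
#'
#' Reconstructs each read's sequence from the genome (aligned block plus
#' soft-clipped tail) and writes plain-text SAM with soft-clip CIGARs, so
#' that simulated libraries can exercise the SAM input path.
#'
#' @param reads Aligned-read `data.frame`.
#' @param genome Named [Biostrings::DNAStringSet] consistent with `reads`.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, genome, path) {
  lens <- fasta_lengths(genome)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  block <- character(nrow(reads))
  for (chr in unique(reads$chrom)) {
    ii <- which(reads$chrom == chr)
    block[ii] <- .extract_ref(genome[[chr]], reads$aln_start[ii] + 1L,
                              reads$aln_end[ii])
  }
  minus <- reads$strand == "-"
  tl <- nchar(reads$tail_seq)
  mlen <- reads$aln_end - reads$aln_start
  cigar <- ifelse(tl > 0,
                  ifelse(minus, paste0(tl, "S", mlen, "M"),
                         paste0(mlen, "M", tl, "S")),
                  paste0(mlen, "M"))
  ## SAM stores the reference-strand sequence; for - reads the read is the
  ## reverse complement, so the tail appears reverse-complemented on the left
  seq <- ifelse(minus, paste0(.revcomp(reads$tail_seq), block),
                paste0(block, reads$tail_seq))
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                 reads$read_id, ifelse(minus, 16L, 0L), reads$chrom,
                 reads$aln_start + 1L, cigar, seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
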