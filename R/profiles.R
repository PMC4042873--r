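## Site-level descriptive profiles: distance-from-TSS histograms, nucleotide
## composition around poly(A) sites, and the TSS-proximal antisense metagene.

#' Distance-from-TSS histogram of uaRNA poly(A) sites
#'
#' Clustered poly(A) sites are assigned through the region index; sites
#' assigned as uaRNA are binned by their distance upstream of the host
#' gene's TSS (strand-aware: `tss - position` for + genes, `position - tss`
#' for - genes; always positive). Bins are half-open `[lo, hi)`; distances
#' of `max_dist` or more are excluded.
#'
#' @param sites Clustered sites from [cluster_sites()].
#' @param index A `region_index`.
#' @param max_dist Maximum distance in bp (default 2000, the uaRNA window).
#' @param bin Bin width in bp (default 100).
#' @return A `data.frame` with `bin_start`, `bin_end`, `count`.
#' @export
tss_distance_histogram <- function(sites, index, max_dist = 2000L, bin = 100L) {
  asg <- .assign_positions(sites$chrom, sites$strand, sites$position, index)
  ua <- which(asg$category == "uaRNA")
  g <- index$genes[match(asg$gene_id[ua], index$genes$gene_id), ]
  d <- ifelse(g$strand == "+", g$tss - sites$position[ua],
              sites$position[ua] - g$tss)
  d <- d[d >= 0 & d < max_dist]
  breaks <- seq(0L, max_dist, by = bin)
  idx <- findInterval(d, breaks)
  data.frame(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = tabulate(idx, nbins = length(breaks) - 1L)
  )
}

#' Nucleotide composition around poly(A) sites
#'
#' Per-offset A/C/G/T frequencies on the transcribed strand of each site
#' (reverse-complemented for - strand sites), with offset 0 at the cleavage
#' site. Offsets that fall outside a chromosome contribute nothing for that
#' site; denominators are adjusted per offset, so frequencies always sum to
#' 1 over A/C/G/T (N excluded and renormalized).
#'
#' @param sites A `data.frame` with `chrom`, `strand` and `position`
#'   (0-based), e.g. from [cluster_sites()].
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param flank Flank size in bp on each side (default 50).
#' @return A `data.frame` with `offset` (-flank..flank), frequency columns
#'   `A`, `C`, `G`, `T`, and `n` (sites contributing at that offset).
#' @export
nucleotide_profile <- function(sites, genome, flank = 50L) {
  genome <- .load_genome(genome)
  lens <- fasta_lengths(genome)
  w <- 2L * flank + 1L
  strs <- character(nrow(sites))
  for (chr in unique(sites$chrom)) {
    ii <- which(sites$chrom == chr)
    cs <- genome[[chr]]
    L <- lens[[chr]]
    s1 <- sites$position[ii] + 1L - flank   # 1-based window start
    e1 <- sites$position[ii] + 1L + flank
    body <- .extract_ref(cs, s1, e1)
    lp <- pmax(1L - s1, 0L)
    rp <- pmax(e1 - L, 0L)
    strs[ii] <- paste0(strrep("N", lp), body, strrep("N", rp))
  }
  minus <- sites$strand == "-"
  strs[minus] <- .revcomp(strs[minus])

  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(strs))
  bases <- c("A", "C", "G", "T")
  cnt <- matrix(0, nrow = 4, ncol = w, dimnames = list(bases, NULL))
  for (b in bases) if (b %in% rownames(cm)) cnt[b, ] <- cm[b, ]
  denom <- colSums(cnt)
  freq <- t(cnt) / ifelse(denom > 0, denom, NA_real_)
  data.frame(offset = seq(-flank, flank), freq, n = denom, row.names = NULL)
}

#' TSS-proximal antisense metagene profile
#'
#' Aggregates uaRNA-assigned PASS read 3' ends by distance upstream of the
#' host gene's TSS over all genes with uaRNA reads detected in any sample,
#' converts per-base counts to RPM (per million total PASS reads of each
#' sample), and smooths each sample's curve with lowess (tricube-weighted
#' local linear regression).
#'
#' @param assigned Assigned PASS reads from [assign_reads()] (with a
#'   `sample` column; a missing one is treated as a single sample).
#' @param index A `region_index`.
#' @param totals Named vector of total PASS reads per sample.
#' @param span Profile span upstream of the TSS in bp (default 2000).
#' @param smooth_f Lowess smoother span as a fraction of points
#'   (default 0.3).
#' @param smooth_iter Lowess robustness iterations (default 0).
#' @return A `data.frame` with `position` (-span..-1 relative to the TSS),
#'   `sample`, `rpm_raw`, `rpm_smooth`.
#' @export
tss_metagene <- function(assigned, index, totals, span = 2000L,
                         smooth_f = 0.3, smooth_iter = 0L) {
  if (!"sample" %in% names(assigned)) assigned$sample <- "S1"
  ua <- assigned[assigned$category == "uaRNA", , drop = FALSE]
  if (nrow(ua) == 0L) stop("no uaRNA-assigned reads; metagene undefined")
  g <- index$genes[match(ua$gene_id, index$genes$gene_id), ]
  d <- ifelse(g$strand == "+", g$tss - ua$pa_site, ua$pa_site - g$tss)
  keep <- d >= 1L & d <= span
  ua <- ua[keep, , drop = FALSE]
  d <- d[keep]

  out <- list()
  for (s in sort(unique(assigned$sample))) {
    cnt <- tabulate(d[ua$sample == s], nbins = span)
    rpm <- cnt * 1e6 / totals[[s]]
    x <- seq(-span, -1L)
    rpm <- rev(rpm)  # distance span..1 -> position -span..-1
    sm <- stats::lowess(x, rpm, f = smooth_f, iter = smooth_iter, delta = 0)
    out[[s]] <- data.frame(position = x, sample = s, rpm_raw = rpm,
                           rpm_smooth = sm$y, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
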