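# Metagene profiling: 10/50/40 bins over 5'UTR/CDS/3'UTR, mirroring the
# relative segment lengths of the human transcriptome.

METAGENE_BINS <- c(utr5 = 10L, cds = 50L, utr3 = 40L)

#' Assign a site to the longest isoform of its host gene
#'
#' @param site_chrom,site_pos,site_strand genomic site coordinates (0-based).
#' @param transcripts transcript catalog: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `length` (spliced length).
#' @return The chosen `transcript_id`, or `NA` (intergenic) when no transcript
#'   overlaps; ties on length break lexicographically by transcript id.
#' @export
assign_longest_isoform <- function(site_chrom, site_pos, site_strand,
                                   transcripts) {
  hit <- transcripts$chrom == site_chrom &
    transcripts$start <= site_pos & transcripts$end > site_pos &
    transcripts$strand == site_strand
  if (!any(hit)) return(NA_character_)
  cand <- transcripts[hit, ]
  cand <- cand[order(-cand$length, cand$transcript_id), ]
  cand$transcript_id[1]
}

#' Map a transcript offset to its metagene bin
#'
#' Bins 0-9 cover the 5'UTR, 10-59 the CDS, 60-99 the 3'UTR; within a region
#' the bin is `floor(relative_position * n_bins)` with the region-local
#' relative position in [0, 1), clamped to the region's last bin.
#'
#' @param tx_pos 0-based transcript offset of the site.
#' @param gene gene row with `cds_start`, `cds_end`, `tx_len`.
#' @return List with `region`, `bin` (0-99), `rel` (relative position) and
#'   `flagged` (TRUE when the containing region has zero length).
#' @export
site_to_bin <- function(tx_pos, gene) {
  stopifnot(tx_pos >= 0, tx_pos < gene$tx_len)
  if (is.na(gene$cds_start))
    stop("metagene bins are defined for mRNAs with an annotated CDS")
  bounds <- c(0L, gene$cds_start, gene$cds_end, gene$tx_len)
  regions <- c("5'UTR", "CDS", "3'UTR")
  base <- c(0L, 10L, 60L)
  nb <- c(10L, 50L, 40L)
  r <- findInterval(tx_pos, bounds[-4], rightmost.closed = FALSE)
  rlen <- bounds[r + 1L] - bounds[r]
  if (rlen == 0L) {
    return(list(region = regions[r], bin = base[r], rel = NA_real_,
                flagged = TRUE))
  }
  rel <- (tx_pos - bounds[r]) / rlen
  bin <- base[r] + min(nb[r] - 1L, floor(rel * nb[r]))
  list(region = regions[r], bin = as.integer(bin), rel = rel,
       flagged = FALSE)
}

# Vectorized bin assignment over a site table (gene_id, tx_pos).
assign_bins <- function(sites, genes) {
  gi <- match(sites$gene_id, genes$gene_id)
  out <- data.frame(site_id = sites$site_id, region = NA_character_,
                    bin = NA_integer_, rel = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(sites))) {
    g <- genes[gi[k], ]
    if (is.na(g$cds_start)) next  # ncRNA: no mRNA metagene structure
    b <- site_to_bin(sites$tx_pos[k], g)
    out$region[k] <- b$region; out$bin[k] <- b$bin; out$rel[k] <- b$rel
  }
  out
}

#' Metagene profile over the 100 bins
#'
#' Summarizes site counts per bin as fractions and fits a least-squares
#' polynomial smoothing curve (presentation only; raw fractions are the
#' canonical output and are unaffected by the smoothing degree).
#'
#' @param bins integer vector of bin indices (0-99).
#' @param degree polynomial degree of the smoothed curve.
#' @return List with `counts`, `fraction` (sums to 1) and `smooth` (fitted
#'   values, one per bin).
#' @export
metagene_profile <- function(bins, degree = 5L) {
  bins <- bins[!is.na(bins)]
  if (!length(bins)) stop("no assignable sites for the metagene profile")
  counts <- tabulate(bins + 1L, nbins = 100L)
  fraction <- counts / sum(counts)
  x <- 0:99
  fit <- stats::lm(fraction ~ stats::poly(x, degree))
  list(counts = counts, fraction = fraction,
       smooth = unname(stats::fitted(fit)), degree = degree)
}

#' Annotate the genic region of each site
#'
#' Every site gets exactly one label among 5'UTR, CDS, 3'UTR, ncRNA,
#' intergenic. When isoform annotations conflict the precedence is
#' CDS > UTR > ncRNA.
#'
#' @param sites site table with `gene_id`, `tx_pos` (NA gene = intergenic).
#' @param genes gene catalog.
#' @return Character vector of labels, one per site.
#' @export
annotate_genic_region <- function(sites, genes) {
  gi <- match(sites$gene_id, genes$gene_id)
  labs <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    if (is.na(gi[k])) { labs[k] <- "intergenic"; next }
    g <- genes[gi[k], ]
    if (is.na(g$cds_start)) { labs[k] <- "ncRNA"; next }
    p <- sites$tx_pos[k]
    labs[k] <- if (p < g$cds_start) "5'UTR"
      else if (p < g$cds_end) "CDS" else "3'UTR"
  }
  labs
}

#' CDS / 3'UTR site-count ratio
#'
#' @param labels genic-region labels (from [annotate_genic_region()]).
#' @return The ratio |CDS sites| / |3'UTR sites|; `NA` with a reason attribute
#'   when there are no 3'UTR sites.
#' @export
cds_utr3_ratio <- function(labels) {
  n_cds <- sum(labels == "CDS")
  n_utr3 <- sum(labels == "3'UTR")
  if (n_utr3 == 0) {
    out <- NA_real_
    attr(out, "reason") <- "undefined: no 3'UTR sites"
    return(out)
  }
  n_cds / n_utr3
}
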