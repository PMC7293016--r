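# Association of m6A with poly(A) cleavage sites: distance distributions,
# sub-motif usage at the cleavage position, PAS classification and
# nucleotide composition profiles.

#' Distribution of m6A sites around cleavage positions
#'
#' For each cleavage site, m6A sites on the same chromosome and strand within
#' +/-`window` nt are counted at signed transcript-orientation offsets
#' (downstream of the cut positive), aggregated over cleavage sites.
#'
#' @param sites m6A site table (`chrom`, `gpos`, `strand`).
#' @param cleavage cleavage-site table (`chrom`, `gpos`, `strand`).
#' @param window half-width W of the offset histogram (nt).
#' @return Integer vector of counts named by offset -W..W.
#' @export
distance_distribution <- function(sites, cleavage, window = 200L) {
  offs <- (-window):window
  counts <- stats::setNames(integer(length(offs)), offs)
  for (i in seq_len(nrow(cleavage))) {
    cl <- cleavage[i, ]
    sel <- sites$chrom == cl$chrom & sites$strand == cl$strand
    if (!any(sel)) next
    d <- sites$gpos[sel] - cl$gpos
    if (cl$strand == "-") d <- -d
    d <- d[abs(d) <= window]
    if (length(d))
      counts <- counts + tabulate(d + window + 1L, nbins = length(offs))
  }
  counts
}

#' Sub-motif usage at the cleavage position vs elsewhere in 3'UTRs
#'
#' Compares sub-motif proportions of m6A sites located exactly at a cleavage
#' position (offset 0) with those of the remaining 3'UTR sites, with a
#' chi-square test (suppressed below 5 offset-0 sites).
#'
#' @param sites site table with `submotif`, plus coordinates.
#' @param cleavage cleavage-site table.
#' @param utr3_labels genic-region labels for `sites` (only "3'UTR" sites
#'   enter the background group).
#' @return List with the two proportion vectors, group sizes, and `chisq`
#'   (htest or NULL when suppressed).
#' @export
submotif_at_cleavage <- function(sites, cleavage, utr3_labels) {
  key_cl <- paste(cleavage$chrom, cleavage$gpos, cleavage$strand)
  key_s <- paste(sites$chrom, sites$gpos, sites$strand)
  at0 <- key_s %in% key_cl
  bg <- !at0 & utr3_labels == "3'UTR"
  p0 <- submotif_proportions(sites$submotif[at0])
  pb <- submotif_proportions(sites$submotif[bg])
  test <- NULL
  if (sum(at0) >= 5) {
    tab <- rbind(table(factor(sites$submotif[at0], levels = SUBMOTIFS)),
                 table(factor(sites$submotif[bg], levels = SUBMOTIFS)))
    keep <- colSums(tab) > 0
    test <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))
  }
  list(at_cleavage = p0, utr3_background = pb,
       n_at_cleavage = sum(at0), n_background = sum(bg), chisq = test)
}

#' Classify the poly(A) signal of a cleavage site
#'
#' Scans the 40 nt upstream of the cleavage position on the sense strand:
#' AAUAAA takes precedence, then AUUAAA, then any hexamer from the variant
#' list ("other"); sites with none are the noncanonical class.
#'
#' @param cleavage cleavage-site table (`chrom`, `gpos`, `strand`).
#' @param genome named character vector of chromosome sequences.
#' @param variants "other"-class hexamer list (DNA alphabet).
#' @return Character vector of classes (AAUAAA, AUUAAA, other, none), with a
#'   `truncated` attribute flagging sites whose upstream window was cut by a
#'   contig edge.
#' @export
classify_pas <- function(cleavage, genome,
                         variants = pas_variant_hexamers()) {
  classes <- character(nrow(cleavage))
  trunc <- logical(nrow(cleavage))
  for (i in seq_len(nrow(cleavage))) {
    cl <- cleavage[i, ]
    chrom_seq <- genome[[cl$chrom]]
    clen <- nchar(chrom_seq)
    if (cl$strand == "+") {
      a <- cl$gpos - 40L + 1L; b <- cl$gpos  # 1-based window of 0-based pos-40..pos-1
      trunc[i] <- a < 1L
      win <- substr(chrom_seq, max(1L, a), max(0L, b))
    } else {
      a <- cl$gpos + 2L; b <- cl$gpos + 41L
      trunc[i] <- b > clen
      win <- revcomp(substr(chrom_seq, a, min(clen, b)))
    }
    classes[i] <-
      if (grepl(PAS_CANONICAL, win, fixed = TRUE)) "AAUAAA"
      else if (grepl(PAS_SECOND, win, fixed = TRUE)) "AUUAAA"
      else if (any(vapply(variants, grepl, logical(1), x = win,
                          fixed = TRUE))) "other"
      else "none"
  }
  attr(classes, "truncated") <- trunc
  classes
}

#' Nucleotide composition around cleavage sites
#'
#' Per PAS class, base frequencies at each position within +/-`flank` nt of
#' the cleavage position (sense strand; rows sum to 1), plus the 5-mer
#' context spanning 2 nt each side of position 0.
#'
#' @param cleavage cleavage-site table with a `pas_class` column.
#' @param genome named character vector of chromosome sequences.
#' @param flank half-width of the profile (nt).
#' @return Named list per class: `freq` ((2*flank+1) x 4 matrix) and
#'   `context` (character vector of central 5-mers).
#' @export
composition_profile <- function(cleavage, genome, flank = 50L) {
  classes <- unique(cleavage$pas_class)
  out <- list()
  for (cls in classes) {
    sub <- cleavage[cleavage$pas_class == cls, ]
    counts <- matrix(0L, 2L * flank + 1L, 4L,
                     dimnames = list(as.character((-flank):flank),
                                     c("A", "C", "G", "T")))
    contexts <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      cl <- sub[i, ]
      chrom_seq <- genome[[cl$chrom]]
      if (cl$strand == "+") {
        s <- substr(chrom_seq, cl$gpos - flank + 1L, cl$gpos + flank + 1L)
      } else {
        s <- revcomp(substr(chrom_seq, cl$gpos - flank + 1L,
                            cl$gpos + flank + 1L))
      }
      ch <- strsplit(s, "")[[1]]
      if (length(ch) != 2L * flank + 1L) next  # contig edge: skip
      ok <- ch %in% colnames(counts)
      counts[cbind(which(ok), match(ch[ok], colnames(counts)))] <-
        counts[cbind(which(ok), match(ch[ok], colnames(counts)))] + 1L
      contexts[i] <- substr(s, flank - 1L, flank + 3L)
    }
    rs <- rowSums(counts)
    freq <- counts / ifelse(rs == 0, 1, rs)
    out[[cls]] <- list(freq = freq, context = contexts[contexts != ""])
  }
  out
}
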