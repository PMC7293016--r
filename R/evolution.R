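# Cross-species constraint on m6A sites against matched control A sites:
# stratified control matching, the null distribution of conserved fractions,
# the constraint proportion, and phylostratigraphic site ages.

#' Decile (or n-tile) bin assignment
#' @param x numeric vector.
#' @param n number of bins.
#' @return Integer bin index 1..n from empirical quantiles of `x`.
#' @export
ntile_bins <- function(x, n = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n + 1L),
                               na.rm = TRUE))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# Stratum keys for conservation records: dN/dS decile x CDS-location bin x
# codon position for CDS sites; dN/dS decile x 3'UTR bin for 3'UTR sites.
# n_bins_cds must divide 20 (the native CDS bin resolution).
stratum_key <- function(records, dnds_bins, n_bins_cds = 20L) {
  cds_bin <- records$cds_bin %/% (20L %/% n_bins_cds)
  ifelse(records$region == "CDS",
         paste(dnds_bins, cds_bin, records$codon_pos, sep = ":"),
         paste(dnds_bins, records$region, records$utr3_bin, sep = ":"))
}

#' Draw one matched control set for a set of m6A sites
#'
#' Controls (A positions of non-m6A RRACH motifs) are matched to the m6A set
#' by stratum: dN/dS decile of the host gene, 20-bin CDS location and codon
#' position for CDS sites (3'UTR location bin for 3'UTR sites). For each m6A
#' site one control is drawn uniformly without replacement from its stratum.
#'
#' @param records conservation table containing both m6A and pool sites
#'   (`is_m6a`, `region`, `codon_pos`, `cds_bin`, `utr3_bin`, `dnds`).
#' @param n_bins_dnds number of dN/dS bins (deciles by default).
#' @param n_bins_cds CDS-location bins (20 by default; must divide 20 --
#'   coarsen when strata run empty).
#' @return Integer row indices into `records` of the matched control set
#'   (same size and stratum composition as the m6A set).
#' @export
match_controls <- function(records, n_bins_dnds = 10L, n_bins_cds = 20L) {
  dnds_bins <- ntile_bins(records$dnds, n_bins_dnds)
  key <- stratum_key(records, dnds_bins, n_bins_cds)
  m6a_keys <- key[records$is_m6a]
  need <- table(m6a_keys)
  pool_idx <- split(which(!records$is_m6a), key[!records$is_m6a])
  missing <- names(need)[!(names(need) %in% names(pool_idx)) |
                           unlist(lapply(names(need), function(k)
                             length(pool_idx[[k]] %||% integer(0)) <
                               need[[k]]))]
  if (length(missing))
    stop("strata without enough control sites: ",
         paste(missing, collapse = ", "),
         " (coarsen the dN/dS or location bins)")
  unlist(lapply(names(need), function(k) {
    p <- pool_idx[[k]]
    p[sample.int(length(p), need[[k]])]
  }), use.names = FALSE)
}

#' Fraction of sites conserved in a target species
#'
#' A site is conserved when its aligned base in the target species is A
#' (a substitution or gap is not conserved).
#'
#' @param records conservation table rows.
#' @param species target species name (column `base_<species>`).
#' @return The conserved fraction.
#' @export
conserved_fraction <- function(records, species) {
  col <- paste0("base_", species)
  if (!col %in% names(records)) stop("no alignment column for ", species)
  mean(records[[col]] == "A")
}

#' Null distribution of conserved fractions over matched control sets
#'
#' Resamples `n_sets` stratified control sets of the size of the m6A set and
#' records each set's conserved fraction. Within a stratum a set is drawn
#' without replacement, so the number of conserved controls per stratum is
#' hypergeometric; sets are drawn independently. The empirical p-value is the
#' right-tail fraction at or above the observed m6A conserved fraction, with
#' the +1 correction.
#'
#' @param records conservation table (m6A and pool).
#' @param species target species.
#' @param n_sets number of control sets (10000 as in the resampling design).
#' @param n_bins_dnds dN/dS bins for matching.
#' @param n_bins_cds CDS-location bins (must divide 20).
#' @return List of class `matched_null`: `observed`, `fractions`, `p`, `n`.
#' @export
null_distribution <- function(records, species, n_sets = 10000L,
                              n_bins_dnds = 10L, n_bins_cds = 20L) {
  col <- paste0("base_", species)
  conserved <- records[[col]] == "A"
  dnds_bins <- ntile_bins(records$dnds, n_bins_dnds)
  key <- stratum_key(records, dnds_bins, n_bins_cds)
  m6a <- records$is_m6a
  need <- table(key[m6a])
  n_m6a <- sum(m6a)
  observed <- mean(conserved[m6a])
  tot <- numeric(n_sets)
  for (k in names(need)) {
    pool <- which(!m6a & key == k)
    if (length(pool) < need[[k]])
      stop("strata without enough control sites: ", k)
    m1 <- sum(conserved[pool]); m2 <- length(pool) - m1
    tot <- tot + stats::rhyper(n_sets, m1, m2, need[[k]])
  }
  fractions <- tot / n_m6a
  p <- (sum(fractions >= observed) + 1) / (n_sets + 1)
  structure(list(observed = observed, fractions = fractions, p = p,
                 n = n_m6a, n_sets = n_sets), class = "matched_null")
}

#' @export
print.matched_null <- function(x, ...) {
  cat(sprintf(
    "Matched-control conservation test: observed %.3f vs null mean %.3f (n = %d sites, %d sets), right-tail p = %.4g\n",
    x$observed, mean(x$fractions), x$n, x$n_sets, x$p))
  invisible(x)
}

#' Proportion of sites under evolutionary constraint
#'
#' The relative deficit of the evolutionary rate at m6A sites against the
#' control rate: ((1 - f_m6a) - (1 - f_ctrl)) / (1 - f_ctrl), reported as an
#' unsigned percentage with the direction kept as an attribute (negative
#' direction = m6A sites more conserved than controls, i.e. constrained).
#'
#' @param f_m6a conserved fraction of m6A sites.
#' @param f_ctrl mean conserved fraction of control sites (must be < 1).
#' @return Percentage (numeric) with attribute `direction` in {-1, 0, 1}.
#' @export
constraint_proportion <- function(f_m6a, f_ctrl) {
  if (f_ctrl >= 1) stop("undefined: control sites fully conserved")
  v <- ((1 - f_m6a) - (1 - f_ctrl)) / (1 - f_ctrl)
  out <- abs(v) * 100
  attr(out, "direction") <- sign(v)
  out
}

#' Phylostratigraphic age of sites
#'
#' The age of a site is the rank of the most distantly related species in
#' which its aligned base is A; sites conserved nowhere get age 0
#' (lineage-specific).
#'
#' @param records conservation table rows.
#' @param panel species ordered by increasing divergence.
#' @return Integer vector of ages (0..length(panel)).
#' @export
site_age <- function(records, panel) {
  cols <- paste0("base_", panel)
  m <- as.matrix(records[, cols, drop = FALSE]) == "A"
  apply(m, 1, function(v) {
    w <- which(v)
    if (length(w)) max(w) else 0L
  })
}

#' Mean site age per 3'UTR location bin, m6A vs control
#'
#' @param records conservation table (3'UTR rows are used).
#' @param panel ordered species panel.
#' @param n_bins number of 3'UTR location bins.
#' @return Data frame: bin, mean age of m6A sites, mean age of controls.
#' @export
site_age_profile <- function(records, panel, n_bins = 10L) {
  utr <- records[records$region == "3'UTR", ]
  age <- site_age(utr, panel)
  out <- data.frame(bin = seq_len(n_bins) - 1L,
                    m6a = NA_real_, control = NA_real_)
  for (b in out$bin) {
    sel <- utr$utr3_bin == b
    out$m6a[out$bin == b] <- mean(age[sel & utr$is_m6a])
    out$control[out$bin == b] <- mean(age[sel & !utr$is_m6a])
  }
  out
}

#' Methylation level of strongly vs weakly constrained sites
#'
#' Splits sites of a region into top-quartile (strong constraint) and
#' bottom-quartile (weak constraint) by their nucleotide-level constraint
#' score (nearest-rank quartiles; groups disjoint) and compares their
#' winscores with a rank-sum test.
#'
#' @param score per-site constraint scores (rejected-substitution style).
#' @param winscore per-site methylation levels (peak winscores).
#' @param min_sites suppression threshold (result is NULL below it).
#' @return List with group medians, sizes and the Wilcoxon p-value, or NULL.
#' @export
constraint_vs_level <- function(score, winscore, min_sites = 8L) {
  keep <- is.finite(score) & is.finite(winscore)
  score <- score[keep]; winscore <- winscore[keep]
  n <- length(score)
  if (n < min_sites) return(NULL)
  o <- order(score)
  k <- floor(n / 4)
  low <- o[seq_len(k)]
  high <- o[seq.int(n - k + 1L, n)]
  wt <- stats::wilcox.test(winscore[high], winscore[low], exact = FALSE)
  list(median_high = stats::median(winscore[high]),
       median_low = stats::median(winscore[low]),
       n_high = length(high), n_low = length(low),
       p = wt$p.value)
}
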