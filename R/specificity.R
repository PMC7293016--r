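# Tissue-specificity of methylation: per-site winscore profiles across
# tissues, the tau index, and the tissue-sharing spectrum.

#' Per-sample winscores of sites from their best covering window
#'
#' For every site and sample, the winscore of the highest-scoring 100-nt
#' window covering the site position, computed in every sample regardless of
#' whether a peak was called there (tau needs a complete profile). Windows
#' not covering the site in a sample (e.g. an unexpressed gene) yield NA.
#'
#' @param sites site table (`gene_id`, `tx_pos`).
#' @param stats_by_sample named list of window-stat tables (one per sample).
#' @return Numeric matrix, sites x samples.
#' @export
site_sample_winscores <- function(sites, stats_by_sample) {
  m <- matrix(NA_real_, nrow(sites), length(stats_by_sample),
              dimnames = list(sites$site_id, names(stats_by_sample)))
  for (s in seq_along(stats_by_sample)) {
    st <- stats_by_sample[[s]]
    for (gid in unique(sites$gene_id)) {
      sg <- which(sites$gene_id == gid)
      wg <- st[st$gene_id == gid, ]
      if (nrow(wg) == 0) next
      for (k in sg) {
        cov <- wg$start <= sites$tx_pos[k] & wg$end > sites$tx_pos[k]
        if (any(cov)) m[k, s] <- max(wg$winscore[cov])
      }
    }
  }
  m
}

#' Average winscore per tissue (the tau input profile)
#'
#' Per site, the mean winscore over the replicates of each tissue, computed
#' in every tissue regardless of peak status; negative values are floored at
#' 0 so the profile behaves like a nonnegative expression vector. Missing
#' windows count as 0 with a flag.
#'
#' @param ws site x sample winscore matrix (from [site_sample_winscores()]).
#' @param design data frame with `sample_id`, `tissue`.
#' @return Site x tissue matrix of floored average winscores, with an
#'   `uncovered` attribute marking site/tissue pairs that had no window.
#' @export
tissue_winscore_matrix <- function(ws, design) {
  tissues <- unique(design$tissue)
  out <- matrix(0, nrow(ws), length(tissues),
                dimnames = list(rownames(ws), tissues))
  unc <- matrix(FALSE, nrow(ws), length(tissues),
                dimnames = dimnames(out))
  for (t in tissues) {
    cols <- design$sample_id[design$tissue == t]
    sub <- ws[, cols, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    unc[, t] <- !is.finite(mu)
    mu[!is.finite(mu)] <- 0
    out[, t] <- pmax(mu, 0)
  }
  attr(out, "uncovered") <- unc
  out
}

#' Tissue-specificity index tau
#'
#' \deqn{tau = \sum_{i=1}^{n} (1 - x_i / \max_i x_i) / (n - 1)}
#' computed on a nonnegative profile of average winscores; 0 for a uniform
#' profile, 1 for a one-tissue profile. An all-zero profile has no defined
#' tau and returns NA.
#'
#' @param x nonnegative numeric vector, one value per tissue (n >= 2).
#' @return tau between 0 and 1, or NA for an all-zero profile.
#' @examples
#' compute_tau(c(5, 5, 5, 5))  # 0
#' compute_tau(c(7, 0, 0, 0))  # 1
#' @export
compute_tau <- function(x) {
  if (length(x) < 2) stop("tau requires at least two tissues")
  if (any(x < 0)) stop("tau is defined for nonnegative profiles")
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Tau for every row of a tissue profile matrix
#' @param profile site x tissue matrix (nonnegative).
#' @return Numeric vector of tau values (NA for all-zero profiles).
#' @export
tau_profile <- function(profile) {
  apply(profile, 1, compute_tau)
}

#' Classify sites by tau
#'
#' Shared: tau < 0.15; tissue-specific: tau > 0.6 (strict inequalities);
#' everything from 0.15 to 0.6 inclusive is intermediate.
#'
#' @param tau numeric vector.
#' @return Character vector in {shared, intermediate, specific} (NA in, NA out).
#' @export
classify_sites <- function(tau) {
  ifelse(is.na(tau), NA_character_,
         ifelse(tau < 0.15, "shared",
                ifelse(tau > 0.6, "specific", "intermediate")))
}

#' Tissue-sharing spectrum
#'
#' Distribution of the number of tissues (k = 1..n) in whose consensus peaks
#' each site lies.
#'
#' @param meth_flags logical matrix, sites x tissues.
#' @return Integer vector of counts indexed by k = 1..n (sites methylated
#'   nowhere are not counted).
#' @export
sharing_spectrum <- function(meth_flags) {
  k <- rowSums(meth_flags)
  tabulate(k, nbins = ncol(meth_flags))
}

#' Ubiquitously expressed genes
#'
#' @param expr gene x tissue expression matrix (FPKM-like).
#' @param threshold strict lower bound required in every tissue (default 3).
#' @return Character vector of gene ids with expression > threshold in all
#'   tissues.
#' @export
ubiquitous_gene_filter <- function(expr, threshold = 3) {
  rownames(expr)[apply(expr, 1, function(v) all(v > threshold))]
}
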