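# RRACH sub-motif composition and the shuffling co-occurrence test for
# GGACH/AAACH segregation across peaks.

#' Classify an RRACH 5-mer into its sub-motif
#'
#' The four sub-motifs (GGACH, AGACH, GAACH, AAACH) resolve the two R
#' positions; the H position is ignored for classing.
#'
#' @param fivemer character vector of RRACH 5-mers.
#' @return Factor-free character vector of sub-motif classes.
#' @export
classify_submotif <- function(fivemer) {
  ok <- is_rrach(fivemer)
  if (!all(ok))
    stop("not RRACH: ", paste(unique(fivemer[!ok]), collapse = ", "))
  paste0(substr(fivemer, 1, 2), "ACH")
}

#' Per-sample sub-motif proportions
#' @param submotif character vector of sub-motif classes for one sample's sites.
#' @return Named numeric vector over the four classes, summing to 1.
#' @export
submotif_proportions <- function(submotif) {
  counts <- table(factor(submotif, levels = SUBMOTIFS))
  p <- as.numeric(counts) / sum(counts)
  stats::setNames(p, SUBMOTIFS)
}

#' Cross-tissue mean and variance of sub-motif proportions
#'
#' @param prop_by_tissue tissue x class matrix of proportions (tissue level =
#'   mean over its replicates).
#' @return Data frame with per-class mean and variance across tissues.
#' @export
submotif_variability <- function(prop_by_tissue) {
  stopifnot(nrow(prop_by_tissue) >= 2)
  data.frame(submotif = colnames(prop_by_tissue),
             mean = apply(prop_by_tissue, 2, mean),
             variance = apply(prop_by_tissue, 2, stats::var),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One random shuffle of sub-motif labels across peak slots
#'
#' Motif class labels are permuted uniformly at random over all motif
#' occurrence slots of a sample's peaks, with positions fixed: per-peak slot
#' counts and total per-class counts are both preserved.
#'
#' @param slots data frame with `peak_id` and `class` (one row per motif
#'   occurrence).
#' @return `slots` with the `class` column permuted.
#' @export
shuffle_submotifs <- function(slots) {
  stopifnot(nrow(slots) >= 2)
  slots$class <- slots$class[sample.int(nrow(slots))]
  slots
}

count_cooccurring <- function(peak_id, is_a, is_b) {
  pk <- factor(peak_id)
  m <- rowsum(cbind(a = as.integer(is_a), b = as.integer(is_b)), pk)
  sum(m[, 1] > 0 & m[, 2] > 0)
}

#' Shuffling test for sub-motif co-occurrence within peaks
#'
#' Tests whether peaks containing both of two sub-motifs (GGACH and AAACH by
#' default) are rarer than expected under random assignment of motif classes
#' to slots. The observed count is compared with `n_shuffles` label
#' permutations; both are mean-centred by dividing by the mean expected count
#' (M_expected); the empirical p-value is the left-tail fraction of the
#' expected distribution at or below the observed count, with the (b+1)/(m+1)
#' correction so p is never exactly 0.
#'
#' @param slots data frame with `peak_id`, `class` (one row per motif slot).
#' @param n_shuffles number of shuffles (10000 as in the test's definition).
#' @param classes the two sub-motif classes probed for co-occurrence.
#' @return List of class `shuffle_result`: `observed`, `expected` (vector),
#'   `m_expected`, `observed_norm`, `expected_norm`, `p`.
#' @export
cooccurrence_test <- function(slots, n_shuffles = 10000L,
                              classes = c("GGACH", "AAACH")) {
  stopifnot(nrow(slots) >= 2)
  is_a <- slots$class == classes[1]
  is_b <- slots$class == classes[2]
  if (!any(is_a) && !any(is_b))
    stop("no occurrences of either probed sub-motif")
  pk <- factor(slots$peak_id)
  ind <- cbind(a = as.integer(is_a), b = as.integer(is_b))
  obs_m <- rowsum(ind, pk)
  observed <- sum(obs_m[, 1] > 0 & obs_m[, 2] > 0)
  n <- nrow(slots)
  expected <- integer(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    m <- rowsum(ind[sample.int(n), , drop = FALSE], pk)
    expected[i] <- sum(m[, 1] > 0 & m[, 2] > 0)
  }
  m_exp <- mean(expected)
  p <- (sum(expected <= observed) + 1) / (n_shuffles + 1)
  res <- list(observed = observed, expected = expected, m_expected = m_exp,
              observed_norm = if (m_exp > 0) observed / m_exp else NA_real_,
              expected_norm = if (m_exp > 0) expected / m_exp else NULL,
              p = p, n_shuffles = n_shuffles)
  class(res) <- "shuffle_result"
  res
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat("Sub-motif co-occurrence shuffle test\n")
  cat(sprintf("  observed peaks with both: %d (normalized %.3f)\n",
              x$observed, x$observed_norm))
  cat(sprintf("  expected (mean of %d shuffles): %.2f\n",
              x$n_shuffles, x$m_expected))
  cat(sprintf("  empirical p (left tail): %.4g\n", x$p))
  invisible(x)
}
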