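#' Sliding-window winscore statistics for one gene and sample
#'
#' Scans the transcript with 100-nt sliding windows and computes the winscore
#' enrichment of IP over input coverage, each normalized by its gene median
#' coverage:
#' \deqn{winscore = log2((MeanWinIP/MedianGeneIP)/(MeanWinControl/MedianGeneControl))}
#' A pseudocount (default 1) is added to each of the four terms so the ratio
#' is defined on zero-coverage windows. The IP window RPKM and the input gene
#' RPKM used by the enrichment filters are attached.
#'
#' @param gene one gene row (needs `gene_id`, `tx_len`).
#' @param ip,input per-base coverage vectors over transcript coordinates.
#' @param ip_lib,input_lib library sizes (read counts) of the two tracks.
#' @param window window width in nt (100 as in the calling method).
#' @param step sliding step in nt (half-window by default).
#' @param pseudocount value added to mean and median coverages before the
#'   ratio; set to 0 for the exact scale-invariant statistic.
#' @return A data frame of windows (`start`, `end` transcript 0-based
#'   half-open, `winscore`, `ip_rpkm`, `input_gene_rpkm`), or an empty one
#'   with attribute `skip_reason` when the gene has no input coverage.
#'   A gene shorter than the window yields a single truncated window.
#' @export
compute_window_stats <- function(gene, ip, input, ip_lib, input_lib,
                                 window = 100L, step = 50L,
                                 pseudocount = 1) {
  L <- length(ip)
  stopifnot(length(input) == L, L == gene$tx_len)
  if (ip_lib <= 0 || input_lib <= 0) stop("library sizes must be positive")
  empty <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), winscore = numeric(0),
                      ip_rpkm = numeric(0), input_gene_rpkm = numeric(0))
  if (all(input == 0)) {
    attr(empty, "skip_reason") <- sprintf(
      "gene %s skipped: no input coverage", gene$gene_id)
    return(empty)
  }
  if (L <= window) {
    starts <- 0L
    ends <- L
  } else {
    starts <- seq.int(0L, L - window, by = step)
    if (starts[length(starts)] + window < L)
      starts <- c(starts, L - window)
    ends <- starts + window
  }
  cip <- c(0, cumsum(ip)); cin <- c(0, cumsum(input))
  wlen <- ends - starts
  mean_ip <- (cip[ends + 1L] - cip[starts + 1L]) / wlen
  mean_in <- (cin[ends + 1L] - cin[starts + 1L]) / wlen
  med_ip <- stats::median(ip)
  med_in <- stats::median(input)
  winscore <- log2(((mean_ip + pseudocount) / (med_ip + pseudocount)) /
                     ((mean_in + pseudocount) / (med_in + pseudocount)))
  ip_rpkm <- (cip[ends + 1L] - cip[starts + 1L]) * 1e9 / (wlen * ip_lib)
  gene_rpkm <- sum(input) * 1e9 / (L * input_lib)
  data.frame(gene_id = gene$gene_id, start = starts, end = ends,
             winscore = winscore, ip_rpkm = ip_rpkm,
             input_gene_rpkm = gene_rpkm, stringsAsFactors = FALSE)
}

# Window stats for every gene of one sample.
sample_window_stats <- function(genes, sample, window = 100L, step = 50L,
                                pseudocount = 1) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    out[[i]] <- compute_window_stats(g, sample$ip[[g$gene_id]],
                                     sample$input[[g$gene_id]],
                                     sample$ip_lib, sample$input_lib,
                                     window, step, pseudocount)
  }
  do.call(rbind, out)
}

#' Filter windows to the enriched set
#'
#' Keeps exactly the windows passing all three calling filters: IP window
#' RPKM >= 10, winscore >= 2, input gene RPKM >= 1 (all inclusive).
#'
#' @param stats window table from [compute_window_stats()].
#' @param min_winscore,min_ip_rpkm,min_gene_rpkm the three thresholds.
#' @return The subset of enriched windows.
#' @export
call_enriched_windows <- function(stats, min_winscore = 2,
                                  min_ip_rpkm = 10, min_gene_rpkm = 1) {
  stats[stats$winscore >= min_winscore &
          stats$ip_rpkm >= min_ip_rpkm &
          stats$input_gene_rpkm >= min_gene_rpkm, , drop = FALSE]
}

# Merge strictly overlapping intervals; returns merged intervals with the max
# score per merged run.
merge_windows <- function(start, end, score) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]; score <- score[o]
  ms <- me <- integer(0); sc <- numeric(0)
  for (i in seq_along(start)) {
    if (length(ms) && start[i] < me[length(me)]) {
      me[length(me)] <- max(me[length(me)], end[i])
      sc[length(sc)] <- max(sc[length(sc)], score[i])
    } else {
      ms <- c(ms, start[i]); me <- c(me, end[i]); sc <- c(sc, score[i])
    }
  }
  data.frame(start = ms, end = me, winscore = sc)
}

#' Replicate-consensus m6A peaks
#'
#' Per sample, overlapping enriched windows are merged into candidate peaks;
#' per tissue, overlapping candidates across samples are clustered and a
#' cluster is kept as a real peak when it is supported (winscore >= threshold)
#' in at least `min_support` samples of the tissue. Peak coordinates are the
#' union over supporting samples; the per-sample peak winscore is the max
#' member-window winscore.
#'
#' @param enriched_by_sample named list (per sample) of enriched window tables.
#' @param design data frame mapping `sample_id` to `tissue`.
#' @param min_support minimum supporting samples per tissue.
#' @return Peak table with one row per (gene, tissue, cluster) and one
#'   `ws_<sample>` column per sample of the tissue.
#' @export
consensus_peaks <- function(enriched_by_sample, design, min_support = 2L) {
  tissues <- unique(design$tissue)
  n_per <- table(design$tissue)
  if (any(n_per < min_support))
    stop("tissue(s) with fewer than ", min_support, " samples: ",
         paste(names(n_per)[n_per < min_support], collapse = ", "))
  peaks <- list()
  for (t in tissues) {
    samp <- design$sample_id[design$tissue == t]
    cand <- list()
    for (s in samp) {
      e <- enriched_by_sample[[s]]
      if (is.null(e) || nrow(e) == 0) next
      for (gid in unique(e$gene_id)) {
        eg <- e[e$gene_id == gid, ]
        m <- merge_windows(eg$start, eg$end, eg$winscore)
        m$gene_id <- gid; m$sample_id <- s
        cand[[length(cand) + 1L]] <- m
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    for (gid in unique(cand$gene_id)) {
      cg <- cand[cand$gene_id == gid, ]
      cg <- cg[order(cg$start, cg$end), ]
      comp <- integer(nrow(cg)); cur <- 0L; cur_end <- -1L
      for (i in seq_len(nrow(cg))) {
        if (cg$start[i] >= cur_end) cur <- cur + 1L
        comp[i] <- cur
        cur_end <- max(cur_end, cg$end[i])
      }
      for (k in unique(comp)) {
        ck <- cg[comp == k, ]
        support <- length(unique(ck$sample_id))
        if (support < min_support) next
        ws <- stats::setNames(rep(NA_real_, length(samp)),
                              paste0("ws_", samp))
        for (s in unique(ck$sample_id))
          ws[paste0("ws_", s)] <- max(ck$winscore[ck$sample_id == s])
        row <- data.frame(gene_id = gid, tissue = t,
                          start = min(ck$start), end = max(ck$end),
                          support = support,
                          winscore = max(ck$winscore),
                          stringsAsFactors = FALSE)
        for (nm in names(ws)) row[[nm]] <- ws[[nm]]
        peaks[[length(peaks) + 1L]] <- row
      }
    }
  }
  if (!length(peaks)) {
    return(data.frame(gene_id = character(0), tissue = character(0),
                      start = integer(0), end = integer(0),
                      support = integer(0), winscore = numeric(0)))
  }
  out <- do.call(rbind, lapply(peaks, function(r) {
    r[setdiff(unique(unlist(lapply(peaks, names))), names(r))] <- NA_real_
    r
  }))
  out$peak_id <- sprintf("p%05d", seq_len(nrow(out)))
  out[, c("peak_id", setdiff(names(out), "peak_id"))]
}

#' Infer single-nucleotide m6A sites from peaks
#'
#' Scans each peak's transcript-orientation sequence for RRACH motifs (the
#' 5-mer may extend up to 2 nt past the peak as long as the methylated A lies
#' inside) and emits one site per motif A. Sites are deduplicated genome-wide
#' by (chrom, position, strand); `meth_<tissue>` flags record the tissues in
#' whose consensus peaks the site lies.
#'
#' @param peaks peak table from [consensus_peaks()].
#' @param genome named character vector of chromosome sequences.
#' @param genes gene table.
#' @return Site table (`site_id`, coordinates, `tx_pos`, `motif`, `submotif`,
#'   per-tissue methylation flags).
#' @export
infer_sites <- function(peaks, genome, genes) {
  tissues <- unique(peaks$tissue)
  found <- list()
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    g <- genes[match(pk$gene_id, genes$gene_id), ]
    txseq <- gene_tx_seq(genome, g)
    a <- max(1L, pk$start - 2L + 1L)        # 1-based substr bounds
    b <- min(g$tx_len, pk$end + 2L)
    seg <- substr(txseq, a, b)
    apos <- scan_rrach(seg) + (a - 1L)       # back to 0-based tx offsets
    apos <- apos[apos >= pk$start & apos < pk$end]
    if (!length(apos)) next
    found[[length(found) + 1L]] <- data.frame(
      gene_id = pk$gene_id, tissue = pk$tissue, tx_pos = apos,
      motif = vapply(apos, function(p) tx_fivemer(txseq, p), character(1)),
      stringsAsFactors = FALSE)
  }
  if (!length(found)) {
    out <- data.frame(site_id = character(0), gene_id = character(0),
                      chrom = character(0), gpos = integer(0),
                      strand = character(0), tx_pos = integer(0),
                      motif = character(0), submotif = character(0))
    for (t in tissues) out[[paste0("meth_", t)]] <- logical(0)
    return(out)
  }
  hits <- do.call(rbind, found)
  key <- paste(hits$gene_id, hits$tx_pos)
  uniq <- hits[!duplicated(key), c("gene_id", "tx_pos", "motif")]
  gi <- match(uniq$gene_id, genes$gene_id)
  uniq$chrom <- genes$chrom[gi]
  uniq$strand <- genes$strand[gi]
  uniq$gpos <- as.integer(mapply(function(i, p) tx_to_genome(genes[i, ], p),
                                 gi, uniq$tx_pos))
  gkey <- paste(uniq$chrom, uniq$gpos, uniq$strand)
  uniq <- uniq[!duplicated(gkey), ]
  ukey <- paste(uniq$gene_id, uniq$tx_pos)
  for (t in tissues) {
    kt <- unique(paste(hits$gene_id, hits$tx_pos)[hits$tissue == t])
    uniq[[paste0("meth_", t)]] <- ukey %in% kt
  }
  uniq$submotif <- paste0(substr(uniq$motif, 1, 2), "ACH")
  uniq$site_id <- sprintf("m%05d", seq_len(nrow(uniq)))
  rownames(uniq) <- NULL
  uniq[, c("site_id", "gene_id", "chrom", "gpos", "strand", "tx_pos",
           "motif", "submotif", paste0("meth_", tissues))]
}

#' Normalize winscores on the top-50 peaks of each sample
#'
#' Controls for between-sample differences in RIP efficiency: per sample, the
#' mean winscore of its 50 highest-winscore peaks (all peaks if fewer) is
#' scaled to the cross-sample average of those means, and the same factor is
#' applied to all of the sample's winscores.
#'
#' @param peak_ws named list: per sample, the numeric vector of its peak
#'   winscores.
#' @param n_top number of top peaks defining the scaling (50).
#' @return List with `factors` (per-sample scale factors) and `normalized`
#'   (the rescaled winscore vectors).
#' @export
normalize_winscores_top50 <- function(peak_ws, n_top = 50L) {
  stopifnot(length(peak_ws) > 0, all(vapply(peak_ws, length, 1L) > 0))
  top_mean <- vapply(peak_ws, function(w) {
    mean(sort(w, decreasing = TRUE)[seq_len(min(n_top, length(w)))])
  }, numeric(1))
  target <- mean(top_mean)
  factors <- target / top_mean
  normalized <- Map(function(w, f) w * f, peak_ws, factors)
  list(factors = factors, normalized = normalized, target = target)
}

#' Run the full peak-calling stage on a simulated or loaded study
#'
#' @param study an `m6a_study` (or compatible list with `genes`, `samples`,
#'   `design`, `genome`).
#' @param window,step,pseudocount see [compute_window_stats()].
#' @param min_winscore,min_ip_rpkm,min_gene_rpkm see [call_enriched_windows()].
#' @param min_support see [consensus_peaks()].
#' @return List with per-sample `stats`, `enriched`, consensus `peaks` and
#'   inferred `sites`.
#' @export
call_peaks <- function(study, window = 100L, step = 50L, pseudocount = 1,
                       min_winscore = 2, min_ip_rpkm = 10,
                       min_gene_rpkm = 1, min_support = 2L) {
  stats <- lapply(study$samples, function(s)
    sample_window_stats(study$genes, s, window, step, pseudocount))
  names(stats) <- study$design$sample_id
  enriched <- lapply(stats, call_enriched_windows, min_winscore,
                     min_ip_rpkm, min_gene_rpkm)
  peaks <- consensus_peaks(enriched, study$design, min_support)
  sites <- infer_sites(peaks, study$genome, study$genes)
  list(stats = stats, enriched = enriched, peaks = peaks, sites = sites)
}
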