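# The winscore sliding-window peak caller, replicate consensus and RRACH
# site inference.

make_track <- function(ip, input) {
  gene <- data.frame(gene_id = "g1", tx_len = length(ip))
  list(gene = gene, ip = ip, input = input)
}

test_that("a 4-fold normalized IP ratio over a unit input ratio scores 2", {
  # window IP mean 399, gene IP median 99: (399+1)/(99+1) = 4 with the
  # default pseudocount; flat input gives a unit ratio -> winscore = log2(4)
  gene <- data.frame(gene_id = "g3", tx_len = 302L)
  ip <- c(rep(399, 100), rep(99, 202))
  st <- compute_window_stats(gene, ip, rep(37, 302), 1e6, 1e6,
                             window = 100, step = 101)
  expect_equal(st$winscore[1], 2)
})

test_that("identical IP and input tracks give winscore 0 everywhere", {
  gene <- data.frame(gene_id = "g1", tx_len = 500L)
  set.seed(1)
  v <- rpois(500, 20)
  st <- compute_window_stats(gene, v, v, 1e6, 1e6)
  expect_true(all(st$winscore == 0))
})

test_that("winscores agree with a hand-computed three-window table", {
  # 3 windows of 100 nt (step 100), toy coverage; oracle computed
  # independently from the formula with plain arithmetic
  gene <- data.frame(gene_id = "g1", tx_len = 300L)
  ip <- c(rep(8, 100), rep(40, 100), rep(2, 100))
  input <- c(rep(10, 100), rep(10, 100), rep(5, 100))
  st <- compute_window_stats(gene, ip, input, ip_lib = 2e6, input_lib = 1e6,
                             window = 100, step = 100, pseudocount = 1)
  med_ip <- median(ip); med_in <- median(input)
  oracle <- log2(((c(8, 40, 2) + 1) / (med_ip + 1)) /
                   ((c(10, 10, 5) + 1) / (med_in + 1)))
  expect_equal(st$winscore, oracle)
  expect_equal(st$ip_rpkm, c(8, 40, 2) * 100 * 1e9 / (100 * 2e6))
  expect_equal(st$input_gene_rpkm,
               rep(sum(input) * 1e9 / (300 * 1e6), 3))
})

test_that("degenerate genes are handled: short gene, zero input", {
  gene <- data.frame(gene_id = "g1", tx_len = 60L)
  st <- compute_window_stats(gene, rep(5, 60), rep(5, 60), 1e6, 1e6)
  expect_equal(nrow(st), 1)
  expect_equal(c(st$start, st$end), c(0, 60))
  gene2 <- data.frame(gene_id = "g2", tx_len = 200L)
  st2 <- compute_window_stats(gene2, rep(5, 200), rep(0, 200), 1e6, 1e6)
  expect_equal(nrow(st2), 0)
  expect_match(attr(st2, "skip_reason"), "no input coverage")
})

test_that("enrichment filters are inclusive and match a brute-force filter", {
  set.seed(42)
  stats <- data.frame(gene_id = "g", start = 0, end = 100,
                      winscore = c(1.99, 2.0, runif(50, 0, 4)),
                      ip_rpkm = c(50, 10.0, runif(50, 0, 30)),
                      input_gene_rpkm = c(5, 1.0, runif(50, 0, 3)))
  out <- call_enriched_windows(stats)
  expect_false(1.99 %in% out$winscore)       # strict on 1.99
  expect_true(any(out$winscore == 2 & out$ip_rpkm == 10))  # >= inclusive
  brute <- stats[sapply(seq_len(nrow(stats)), function(i)
    stats$winscore[i] >= 2 && stats$ip_rpkm[i] >= 10 &&
      stats$input_gene_rpkm[i] >= 1), ]
  expect_equal(out, brute)
})

test_that("consensus requires >= 2 supporting samples and unions coords", {
  design <- data.frame(sample_id = c("t_1", "t_2", "t_3"),
                       tissue = "t", stringsAsFactors = FALSE)
  win <- function(s, e, w = 3) data.frame(gene_id = "g1", start = s, end = e,
                                          winscore = w, ip_rpkm = 20,
                                          input_gene_rpkm = 2)
  # enriched in one sample only: no peak
  e1 <- list(t_1 = win(0, 100), t_2 = win(500, 600)[0, ], t_3 = win(0, 0)[0, ])
  expect_equal(nrow(consensus_peaks(e1, design)), 0)
  # enriched in 2 of 3 overlapping windows: peak, coords are the union
  e2 <- list(t_1 = win(0, 100), t_2 = win(50, 150), t_3 = win(0, 0)[0, ])
  pk <- consensus_peaks(e2, design)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(0, 150))
  expect_equal(pk$support, 2)
  # three mutually overlapping windows in one sample merge to one candidate
  e3 <- list(t_1 = rbind(win(0, 100), win(50, 150), win(100, 200)),
             t_2 = win(120, 220), t_3 = win(0, 0)[0, ])
  pk3 <- consensus_peaks(e3, design)
  expect_equal(nrow(pk3), 1)
  expect_equal(c(pk3$start, pk3$end), c(0, 220))
  # single-sample tissue is an error naming the tissue
  expect_error(consensus_peaks(e2, data.frame(sample_id = "x_1",
                                              tissue = "solo")),
               "solo")
})

test_that("peak sets are independent of gene and sample processing order", {
  study <- tiny_study()
  pk1 <- call_peaks(study)
  study_r <- study
  ord <- rev(seq_len(nrow(study$genes)))
  study_r$genes <- study$genes[ord, ]
  pk2 <- call_peaks(study_r)
  k1 <- with(pk1$peaks, sort(paste(gene_id, tissue, start, end)))
  k2 <- with(pk2$peaks, sort(paste(gene_id, tissue, start, end)))
  expect_identical(k1, k2)
})

test_that("site inference scans RRACH in transcript orientation", {
  genome <- c(chrT = paste0(strrep("T", 10), "GGACT", strrep("T", 10)))
  genes <- data.frame(gene_id = "g1", chrom = "chrT", start = 8L, end = 20L,
                      strand = "+", tx_len = 12L, stringsAsFactors = FALSE)
  peaks <- data.frame(peak_id = "p1", gene_id = "g1", tissue = "t",
                      start = 0L, end = 12L, stringsAsFactors = FALSE)
  s <- infer_sites(peaks, genome, genes)
  expect_equal(nrow(s), 1)
  expect_equal(s$motif, "GGACT")
  expect_equal(s$tx_pos, 4L)  # A of GGACT at transcript offset 4
  # no motif, no sites
  genome2 <- c(chrT = strrep("CCTCC", 5))
  genes2 <- transform(genes, start = 0L, end = 25L, tx_len = 25L)
  expect_equal(nrow(infer_sites(transform(peaks, end = 25L),
                                genome2, genes2)), 0)
})

test_that("minus-strand sites match a reverse-complement rescan oracle", {
  study <- tiny_study()
  pk <- tiny_peaks()
  minus <- pk$sites[pk$sites$strand == "-", ]
  expect_gt(nrow(minus), 0)
  for (i in seq_len(min(25, nrow(minus)))) {
    st <- minus[i, ]
    # oracle: take the genomic plus-strand 5-mer and reverse-complement it
    plus5 <- substr(study$genome[[st$chrom]], st$gpos - 1, st$gpos + 3)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus5)))
    expect_identical(rc, st$motif)
    expect_true(is_rrach(rc))
  }
})

test_that("top-50 normalization is a fixed point / removes known factors", {
  set.seed(7)
  base <- sort(runif(80, 2, 6), decreasing = TRUE)
  # identical samples: identity
  r0 <- normalize_winscores_top50(list(a = base, b = base))
  expect_equal(unname(r0$factors), c(1, 1))
  # one sample doubled: its top-50 mean equals the others after scaling
  r1 <- normalize_winscores_top50(list(a = base, b = 2 * base))
  m <- sapply(r1$normalized, function(w) mean(sort(w, TRUE)[1:50]))
  expect_equal(unname(m[1]), unname(m[2]))
  # construct-and-recover: factors proportional to 1, 2, 4
  r2 <- normalize_winscores_top50(list(a = base, b = 2 * base, c = 4 * base))
  f <- unname(r2$factors)
  expect_equal(f / f[1], c(1, 1 / 2, 1 / 4))
})

test_that("most planted methylated sites fall in a consensus peak", {
  study <- tiny_study()
  pk <- tiny_peaks()
  truth <- study$sites
  for (t in unique(study$design$tissue)) {
    tr <- truth[truth[[paste0("meth_", t)]], ]
    pkt <- pk$peaks[pk$peaks$tissue == t, ]
    inpk <- mapply(function(gid, p)
      any(pkt$gene_id == gid & pkt$start <= p & pkt$end > p),
      tr$gene_id, tr$tx_pos)
    expect_gt(mean(inpk), 0.85)
  }
})
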