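# SNP motif annotation, allele-specific methylation, DAF spectra and the
# Weir-Cockerham Fst estimator.

test_that("SNP motif annotation matches direct 5-mer construction", {
  # plus-strand gene with a GGACT motif at genomic 10..14 (A at 12)
  genome <- c(chrT = paste0("TTTTTTTTTT", "GGACT", "TTTTTTTTTT"))
  genes <- data.frame(gene_id = "g1", chrom = "chrT", start = 0L, end = 25L,
                      strand = "+", stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "s1", chrom = "chrT", gpos = 12L,
                      strand = "+", stringsAsFactors = FALSE)
  # C>T at the C of GGACT (position 13)
  snps <- data.frame(chrom = "chrT", pos = 13L, ref = "C", alt = "T",
                     aa = "T", gene_id = "g1", stringsAsFactors = FALSE)
  ann <- find_motif_snps(snps, genome, sites, genes)
  expect_equal(ann$motif_pos, "C")
  expect_equal(ann$m6a_allele, "C")
  expect_false(ann$ambiguous)
  expect_equal(ann$site_id_hit, "s1")
  # derived allele C creates the motif (ancestral T does not)
  expect_true(ann$creates_motif)
  # H-position SNP: position H, does not break RRAC, never creates it
  snps_h <- data.frame(chrom = "chrT", pos = 14L, ref = "T", alt = "G",
                       aa = "G", gene_id = "g1", stringsAsFactors = FALSE)
  ann_h <- find_motif_snps(snps_h, genome, sites, genes)
  expect_equal(ann_h$motif_pos, "H")
  expect_equal(ann_h$m6a_allele, "T")
  expect_false(isTRUE(ann_h$creates_motif))
})

test_that("annotation equals a brute-force rescan of both allele contexts", {
  study <- tiny_study()
  pk <- tiny_peaks()
  ann <- find_motif_snps(study$snps, study$genome, pk$sites, study$genes)
  sub <- ann[sample.int(nrow(ann), 60), ]
  for (i in seq_len(nrow(sub))) {
    s <- sub[i, ]
    g <- study$genes[match(s$gene_id, study$genes$gene_id), ]
    strand <- if (is.na(s$gene_id)) "+" else g$strand
    ctx <- substr(study$genome[[s$chrom]], s$pos - 3, s$pos + 5)
    if (strand == "-") ctx <- m6adyn:::revcomp(ctx)
    put <- function(allele) {
      ch <- strsplit(ctx, "")[[1]]
      ch[5] <- if (strand == "-") m6adyn:::COMP[[allele]] else allele
      paste(ch, collapse = "")
    }
    if (!is.na(s$aa)) {
      derived <- if (s$aa == s$ref) s$alt else s$ref
      ancestral <- if (s$aa == s$ref) s$ref else s$alt
      scan4 <- function(x) {
        any(vapply(1:6, function(j)
          grepl("^[AG][AG]AC$", substr(x, j, j + 3)) && j <= 5 && j + 3 >= 5,
          logical(1)))
      }
      expect_identical(s$creates_motif,
                       scan4(put(derived)) && !scan4(put(ancestral)),
                       info = s$snp_id)
    }
  }
})

test_that("allele ratios behave as planted across motif positions", {
  expect_equal(8 / 10, 0.8)  # ratio definition: m6A reads / total reads
  study <- tiny_study()
  art <- allele_ratio_test(study$pileups)
  rrac <- art[art$motif_pos %in% c("R1", "R2", "A", "C"), ]
  expect_true(all(rrac$p < 0.01))
  expect_true(all(rrac$median_diff > 0.1))
  h <- art[art$motif_pos == "H", ]
  expect_gt(h$p, 0.05)
  # identical compartments: p near 1
  set.seed(2)
  pile <- data.frame(snp_id = rep(sprintf("x%02d", 1:30), 2),
                     sample_id = "s", motif_pos = "A",
                     compartment = rep(c("IP", "input"), each = 30),
                     ratio = rep(round(runif(30), 3), 2))
  r0 <- allele_ratio_test(pile)
  expect_gt(r0$p, 0.5)
  # suppression below the heterozygote minimum
  r1 <- allele_ratio_test(pile[c(1:3, 31:33), ])
  expect_true(is.na(r1$p))
  expect_match(r1$note, "suppressed")
})

test_that("DAF honours the ancestral tag and is swap-invariant", {
  geno <- rbind(c(0L, 1L, 2L, 1L))  # alt dosages over 4 diploids
  expect_equal(derived_allele_frequency(geno, "A", "G", aa = "A"), 0.5)
  expect_equal(derived_allele_frequency(geno, "A", "G", aa = "G"), 0.5)
  geno2 <- rbind(c(2L, 2L, 1L, 1L))
  expect_equal(derived_allele_frequency(geno2, "A", "G", aa = "A"), 0.75)
  # swapping ref/alt (and dosages) leaves the DAF unchanged
  expect_equal(derived_allele_frequency(2L - geno2, "G", "A", aa = "A"),
               0.75)
  expect_true(is.na(derived_allele_frequency(geno, "A", "G", aa = NA)))
  expect_true(is.na(derived_allele_frequency(geno, "A", "G", aa = "C")))
  # 30 derived of 100 haplotypes
  g30 <- matrix(c(rep(1L, 30), rep(0L, 20)), nrow = 1)
  expect_equal(derived_allele_frequency(g30, "A", "G", aa = "A"), 0.3)
})

test_that("identical groups give a one-sided Mann-Whitney p near 1/2", {
  set.seed(7)
  x <- sim_daf(400)
  r <- daf_spectrum_test(x, list(self = x))
  expect_gt(r$p, 0.4)
  expect_lt(r$p, 0.6)
  # a planted right shift is detected
  r2 <- daf_spectrum_test(sim_daf(500, shift = 0.3), list(ctrl = sim_daf(500)))
  expect_lt(r2$p, 1e-6)
})

test_that("Weir-Cockerham theta matches the scalar oracle to 1e-10", {
  set.seed(11)
  for (i in 1:60) {
    r <- sample(2:4, 1)
    n <- sample(5:40, r, replace = TRUE)
    freqs <- runif(r, 0.05, 0.95)
    geno <- unlist(lapply(seq_len(r), function(k) rbinom(n[k], 2, freqs[k])))
    pops <- factor(rep(seq_len(r), n))
    if (sum(geno) %in% c(0, 2 * sum(n))) next  # monomorphic draw
    got <- weir_cockerham_fst(matrix(geno, nrow = 1), pops)
    expect_equal(got, wc_theta_oracle(geno, pops), tolerance = 1e-10)
  }
})

test_that("theta behaves at the identity and fixation limits", {
  set.seed(13)
  tg <- toy_genotypes(c(0.4, 0.4), 400)
  expect_lt(abs(weir_cockerham_fst(tg$geno, tg$pops)), 0.02)
  fixed <- list(geno = matrix(c(rep(2L, 300), rep(0L, 300)), nrow = 1),
                pops = factor(rep(1:2, each = 300)))
  expect_gt(weir_cockerham_fst(fixed$geno, fixed$pops), 0.99)
  mono <- matrix(rep(0L, 20), nrow = 1)
  expect_true(is.na(weir_cockerham_fst(mono, factor(rep(1:2, each = 10)))))
  expect_error(weir_cockerham_fst(matrix(0:1, 1), factor(c(1, 1))),
               "two populations")
})

test_that("the high-Fst filter is strict and equals a brute-force scan", {
  fst <- c(0.15, 0.16, NA, 0.9, -0.02, 0.1500001)
  got <- high_fst_filter(fst)
  expect_equal(got, c(2L, 4L, 6L))
  set.seed(17)
  v <- round(runif(200, 0, 0.3), 3)
  expect_equal(high_fst_filter(v),
               which(sapply(v, function(x) !is.na(x) && x > 0.15)))
})

test_that("neutral motif SNPs are no more differentiated than neutral SNPs", {
  cfg <- sim_config(seed = 19, n_genes = 15, selected_fraction = 0)
  study <- simulate_study(cfg)
  fst <- weir_cockerham_fst(study$genotypes, study$pops)
  grp <- study$snps$group
  n_motif <- sum(grp == "m6a_gain"); n_neutral <- sum(grp == "neutral")
  x <- sum(fst[grp == "m6a_gain"] > 0.15, na.rm = TRUE)
  y <- sum(fst[grp == "neutral"] > 0.15, na.rm = TRUE)
  if (x + y == 0) {
    expect_equal(x, y)  # no differentiated SNPs in either class
  } else {
    pt <- suppressWarnings(prop.test(c(x, y), c(n_motif, n_neutral)))
    expect_gt(pt$p.value, 0.01)
  }
})
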