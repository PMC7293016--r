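# The synthetic-study generator: determinism, planted-truth validity, and
# the statistical structure the downstream stages rely on.

test_that("config validation enforces segment lengths and probabilities", {
  cfg <- sim_config(seed = 1, n_genes = 10,
                    utr5_cds_utr3_lengths = c(200, 999, 801))
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(utr5_cds_utr3_lengths = c(200, 1001, 800)),
               "divisible by 3")
  expect_error(sim_config(utr5_cds_utr3_lengths = c(0, 999, 800)),
               "positive")
  expect_error(sim_config(enrichment_factor = 0.5), "enrichment_factor")
  expect_error(sim_config(tissue_specific_fraction = 1.2), "probability")
  expect_error(sim_config(tissue_names = c("a", "a")), "unique")
})

test_that("generated transcripts have the configured segment lengths", {
  cfg <- sim_config(seed = 7, n_genes = 10,
                    utr5_cds_utr3_lengths = c(200, 999, 801),
                    ncrna_fraction = 0)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$genes), 10)
  expect_true(all(gen$genes$tx_len == 2000))
  # CDS boundaries carry start/stop codons in transcript orientation
  for (i in 1:10) {
    g <- gen$genes[i, ]
    tx <- m6adyn:::gene_tx_seq(gen$genome, g)
    expect_equal(substr(tx, g$cds_start + 1, g$cds_start + 3), "ATG")
    expect_equal(substr(tx, g$cds_end - 2, g$cds_end), "TAA")
  }
})

test_that("the generator is bit-reproducible given (config, seed)", {
  cfg <- sim_config(seed = 11, n_genes = 8)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$genes, g2$genes)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$samples[[1]]$ip, s2$samples[[1]]$ip)
  expect_identical(s1$snps, s2$snps)
})

test_that("every planted site is an RRACH A on the emitted reference", {
  study <- tiny_study()
  for (i in seq_len(nrow(study$sites))) {
    st <- study$sites[i, ]
    g <- study$genes[match(st$gene_id, study$genes$gene_id), ]
    fm <- m6adyn:::tx_fivemer(m6adyn:::gene_tx_seq(study$genome, g),
                              st$tx_pos)
    expect_identical(fm, st$motif)
    expect_true(is_rrach(fm))
  }
  # RRACH motifs also occur outside planted sites (control pool exists)
  expect_gt(sum(!study$conservation$is_m6a), 0)
  # truth ids resolve across emitted tables
  expect_true(all(stats::na.omit(study$cleavage$m6a_site_id) %in%
                    study$sites$site_id))
  expect_true(all(study$conservation$site_id[study$conservation$is_m6a] %in%
                    study$sites$site_id))
  expect_true(all(study$selected_snps %in% study$snps$snp_id))
})

test_that("tissue_specific_fraction at its extremes is degenerate", {
  cfg1 <- sim_config(seed = 3, n_genes = 10, tissue_specific_fraction = 1)
  s1 <- plant_m6a_sites(generate_genome(cfg1), cfg1)$sites
  meth <- as.matrix(s1[, grep("^meth_", names(s1))])
  expect_true(all(rowSums(meth) == 1))
  cfg0 <- sim_config(seed = 3, n_genes = 10, tissue_specific_fraction = 0)
  s0 <- plant_m6a_sites(generate_genome(cfg0), cfg0)$sites
  meth0 <- as.matrix(s0[, grep("^meth_", names(s0))])
  expect_true(all(rowSums(meth0) == ncol(meth0)))
})

test_that("planted site counts follow the configured Poisson density", {
  # density 2/kb over 10 x 2 kb of transcript: count within the Poisson 99%
  # interval around 40 (oracle: qpois)
  cfg <- sim_config(seed = 5, n_genes = 10, site_density = 2,
                    utr5_cds_utr3_lengths = c(200, 999, 801),
                    ncrna_fraction = 0, stop_bias = 0)
  gen <- plant_m6a_sites(generate_genome(cfg), cfg)
  lam <- 2 * sum(gen$genes$tx_len) / 1000
  bounds <- qpois(c(0.005, 0.995), lam)
  n <- nrow(gen$sites)
  expect_gte(n, bounds[1] - 3)  # small loss to codon guards/min spacing
  expect_lte(n, bounds[2])
})

test_that("IP enrichment is tissue-faithful and null at enrichment 1", {
  study <- tiny_study()
  cfg <- study$config
  # a site methylated in exactly one tissue has a higher IP/input window
  # ratio there than in other tissues
  spec_sites <- study$sites[study$sites$specific, ]
  meth_cols <- paste0("meth_", cfg$tissue_names)
  ratios <- function(st, tissue) {
    samp <- study$design$sample_id[study$design$tissue == tissue]
    w <- max(1, st$tx_pos - 49):(st$tx_pos + 50)
    mean(sapply(samp, function(s) {
      g <- study$samples[[s]]
      sum(g$ip[[st$gene_id]][w]) / max(1, sum(g$input[[st$gene_id]][w]))
    }))
  }
  hits <- 0
  for (i in seq_len(min(20, nrow(spec_sites)))) {
    st <- spec_sites[i, ]
    on_t <- cfg$tissue_names[which(unlist(st[meth_cols]))]
    off_t <- setdiff(cfg$tissue_names, on_t)[1]
    if (ratios(st, on_t) > ratios(st, off_t)) hits <- hits + 1
  }
  expect_gte(hits / min(20, nrow(spec_sites)), 0.9)
  # enrichment_factor = 1: winscores are centred at zero
  cfg0 <- sim_config(seed = 9, n_genes = 10, enrichment_factor = 1,
                     tissue_names = c("a", "b"))
  s0 <- simulate_coverage(plant_m6a_sites(generate_genome(cfg0), cfg0), cfg0)
  st <- m6adyn:::sample_window_stats(s0$genes, s0$samples[[1]])
  expect_lt(abs(mean(st$winscore)), 0.05)
})

test_that("conservation probabilities drive the conserved-fraction gap", {
  study <- tiny_study()
  cons <- study$conservation
  f_m <- conserved_fraction(cons[cons$is_m6a, ], "mouse")
  f_c <- conserved_fraction(cons[!cons$is_m6a, ], "mouse")
  # binomial expectation oracle: gap approx 0.9 - 0.6 = 0.3
  se <- sqrt(0.9 * 0.1 / sum(cons$is_m6a) + 0.6 * 0.4 / sum(!cons$is_m6a))
  expect_lt(abs((f_m - f_c) - 0.3), 4 * se)
  # equal probabilities: constraint estimate near zero
  cfg <- sim_config(seed = 13, n_genes = 15, conservation_prob_m6a = 0.7,
                    conservation_prob_control = 0.7)
  s2 <- simulate_alignment_table(
    plant_cleavage_sites(plant_m6a_sites(generate_genome(cfg), cfg), cfg),
    cfg)
  c2 <- s2$conservation
  gap <- conserved_fraction(c2[c2$is_m6a, ], "mouse") -
    conserved_fraction(c2[!c2$is_m6a, ], "mouse")
  expect_lt(abs(gap), 0.05)
})

test_that("a single-species panel yields at most two site ages", {
  cfg <- sim_config(seed = 2, n_genes = 6, species_panel = "mouse")
  gen <- simulate_alignment_table(
    plant_cleavage_sites(plant_m6a_sites(generate_genome(cfg), cfg), cfg),
    cfg)
  ages <- site_age(gen$conservation, "mouse")
  expect_true(all(ages %in% c(0L, 1L)))
})

test_that("genotype truth: selected SNPs differentiated, neutral not", {
  study <- tiny_study()
  fst <- weir_cockerham_fst(study$genotypes, study$pops)
  sel <- study$snps$selected
  if (sum(sel) >= 5)
    expect_gt(mean(fst[sel] > 0.15, na.rm = TRUE), 0.8)
  expect_lt(mean(fst[study$snps$group == "neutral"] > 0.15, na.rm = TRUE),
            0.02)
  # identical haplotype pools: per-SNP Fst approx 0 on average
  expect_lt(abs(mean(fst[study$snps$group == "neutral"], na.rm = TRUE)),
            0.01)
})

test_that("written study files are consistent with in-memory truth", {
  study <- tiny_study()
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "reference.fa")))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_identical(as.character(seqs[["chrS"]]), unname(study$genome["chrS"]))
  genes <- read_gene_models(file.path(dir, "genes.gtf"))
  m <- match(study$genes$gene_id, genes$gene_id)
  expect_false(anyNA(m))
  expect_equal(genes$start[m], study$genes$start)
  expect_equal(genes$cds_start[m], study$genes$cds_start)
  cov <- read_bedgraph(file.path(dir, "cerebellum_1.ip.bedGraph"), genes)
  gid <- study$genes$gene_id[1]
  expect_equal(cov[[gid]], as.numeric(study$samples[["cerebellum_1"]]$ip[[gid]]))
  v <- read_vcf_file(file.path(dir, "snps.vcf"))
  expect_equal(v$snps$pos, study$snps$pos)
  expect_equal(unname(v$genotypes[5, ]), unname(study$genotypes[5, ]))
  expect_identical(is.na(v$snps$aa), is.na(study$snps$aa))
})
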