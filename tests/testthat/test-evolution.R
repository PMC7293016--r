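# Matched-control cross-species constraint, the constraint proportion, and
# phylostratigraphic site ages.

test_that("matched controls reproduce the m6A stratum composition", {
  set.seed(2)
  cons <- toy_conservation(n_m6a = 60, n_pool = 1200, p_m6a = 0.9,
                           p_ctrl = 0.6)
  idx <- match_controls(cons, n_bins_dnds = 3, n_bins_cds = 5)
  expect_equal(length(idx), 60)
  expect_false(any(cons$is_m6a[idx]))
  expect_equal(length(unique(idx)), 60)  # without replacement
  db <- ntile_bins(cons$dnds, 3)
  key <- m6adyn:::stratum_key(cons, db, 5)
  expect_equal(sort(table(key[cons$is_m6a])), sort(table(key[idx])))
  # dN/dS distribution of controls is indistinguishable from the m6A set
  suppressWarnings(ct <- chisq.test(table(
    group = rep(c("m6a", "ctrl"), each = 60),
    bin = c(db[cons$is_m6a], db[idx]))))
  expect_gt(ct$p.value, 0.01)
})

test_that("matching on the m6A set itself returns a permutation of it", {
  set.seed(4)
  cons <- toy_conservation(n_m6a = 30, n_pool = 0, p_m6a = 0.8, p_ctrl = 0.8)
  pool <- cons
  pool$is_m6a <- FALSE
  pool$aln_id <- paste0(pool$aln_id, "_ctrl")
  both <- rbind(cons, pool)
  idx <- match_controls(both, n_bins_dnds = 1, n_bins_cds = 1)
  # every matched control is the pool copy of some m6A record, used once
  expect_setequal(both$aln_id[idx], pool$aln_id)
})

test_that("empty strata raise an error naming them", {
  set.seed(6)
  cons <- toy_conservation(n_m6a = 20, n_pool = 5, p_m6a = 0.9, p_ctrl = 0.6)
  expect_error(match_controls(cons), "strata")
})

test_that("conserved fraction is a plain hand count over aligned bases", {
  df <- data.frame(base_mouse = c("A", "A", "C", "-", "A", "G", "A", "A",
                                  "A", "T"))
  expect_equal(conserved_fraction(df, "mouse"), 6 / 10)
  expect_equal(conserved_fraction(data.frame(base_mouse = rep("A", 4)),
                                  "mouse"), 1)
  expect_equal(conserved_fraction(data.frame(base_mouse = rep("-", 4)),
                                  "mouse"), 0)
  expect_error(conserved_fraction(df, "dog"), "no alignment column")
})

test_that("the null distribution detects planted constraint and stays
           calibrated when the m6A set is drawn from the pool", {
  set.seed(10)
  cons <- toy_conservation(n_m6a = 200, n_pool = 2000, p_m6a = 0.9,
                           p_ctrl = 0.6)
  nd <- null_distribution(cons, "mouse", n_sets = 2000, n_bins_dnds = 3,
                          n_bins_cds = 5)
  expect_lt(nd$p, 0.001)
  expect_equal(nd$n, 200)
  expect_equal(length(nd$fractions), 2000)
  # hypergeometric resampling agrees with explicit matched-set resampling
  explicit <- replicate(400, {
    idx <- match_controls(cons, n_bins_dnds = 3, n_bins_cds = 5)
    conserved_fraction(cons[idx, ], "mouse")
  })
  expect_lt(abs(mean(explicit) - mean(nd$fractions)), 0.015)
  expect_lt(abs(sd(explicit) - sd(nd$fractions)), 0.01)
  # anti-conserved planting pushes p toward 1
  anti <- toy_conservation(n_m6a = 150, n_pool = 1500, p_m6a = 0.4,
                           p_ctrl = 0.7)
  nd2 <- null_distribution(anti, "mouse", n_sets = 1000, n_bins_dnds = 3,
                           n_bins_cds = 5)
  expect_gt(nd2$p, 0.99)
})

test_that("constraint proportion equals its closed form", {
  # the worked third-codon estimate: fractions 0.644 vs 0.621 give 6%
  cp <- constraint_proportion(0.644, 0.621)
  expect_equal(round(as.numeric(cp)), 6)
  expect_equal(attr(cp, "direction"), -1)
  expect_equal(as.numeric(constraint_proportion(0.5, 0.5)), 0)
  expect_equal(as.numeric(constraint_proportion(1, 0.5)), 100)
  expect_error(constraint_proportion(0.8, 1), "undefined")
  # scale-free closed form on random inputs
  set.seed(3)
  for (i in 1:50) {
    f1 <- runif(1, 0, 0.99); f2 <- runif(1, 0, 0.99)
    expect_equal(as.numeric(constraint_proportion(f1, f2)),
                 abs(((1 - f1) - (1 - f2)) / (1 - f2)) * 100)
  }
})

test_that("site age is the most distant conserved species and is monotone", {
  panel <- c("chimp", "macaque", "mouse")
  rec <- data.frame(base_chimp = c("A", "A", "C", "C"),
                    base_macaque = c("A", "C", "C", "C"),
                    base_mouse = c("A", "A", "C", "C"))
  expect_equal(unname(site_age(rec, panel)), c(3L, 3L, 0L, 0L))
  expect_equal(unname(site_age(rec[2, ], panel[1:2])), 1L)
  # adding a more distant conserved species never decreases the age
  rec2 <- rec
  rec2$base_opossum <- c("A", "C", "A", "C")
  expect_true(all(site_age(rec2, c(panel, "opossum")) >=
                    site_age(rec, panel)))
})

test_that("m6A sites are older than controls in every 3'UTR bin when the
           conservation gap is planted", {
  study <- tiny_study()
  prof <- site_age_profile(study$conservation, study$config$species_panel)
  ok <- !is.na(prof$m6a) & !is.na(prof$control)
  expect_gt(sum(ok), 5)
  expect_true(all(prof$m6a[ok] > prof$control[ok]))
})

test_that("constraint-score quartiles couple to methylation level as planted", {
  # planted positive score-level coupling: strong, detectable split
  set.seed(5)
  z <- rnorm(400)
  r <- constraint_vs_level(z, 0.6 * z + rnorm(400, 0, 0.8))
  expect_gt(r$median_high, r$median_low)
  expect_lt(r$p, 1e-6)
  expect_equal(r$n_high, r$n_low)
  # independent scores: no signal
  r0 <- constraint_vs_level(rnorm(400), rnorm(400))
  expect_gt(r0$p, 0.001)
  expect_lt(abs(r0$median_high - r0$median_low), 0.5)
  # suppressed below the minimum group size
  expect_null(constraint_vs_level(rnorm(5), rnorm(5)))
  # on the synthetic study, the planted surrogate score still orders the
  # group medians (winscores at shared windows blur the magnitude)
  study <- tiny_study()
  pk <- tiny_peaks()
  m6a <- study$conservation[study$conservation$is_m6a, ]
  ws <- site_sample_winscores(
    data.frame(site_id = m6a$site_id, gene_id = m6a$gene_id,
               tx_pos = m6a$tx_pos), pk$stats)
  rs <- constraint_vs_level(m6a$rs_score, rowMeans(ws, na.rm = TRUE))
  expect_gt(rs$median_high, rs$median_low)
})
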