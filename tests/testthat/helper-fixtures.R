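# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# A small complete study exercised by most module tests.
tiny_study <- function() {
  memo("tiny_study", simulate_study(sim_config(seed = 1, n_genes = 20)))
}

tiny_peaks <- function() {
  memo("tiny_peaks", call_peaks(tiny_study()))
}

# The study at generator defaults, shared by the recovery criteria.
default_run <- function() {
  memo("default_run", {
    cfg <- sim_config(seed = 1)
    study <- simulate_study(cfg)
    list(config = cfg, study = study, pk = call_peaks(study))
  })
}

# A one-gene catalog for coordinate-level tests.
toy_gene <- function(tx_len = 300L, cds_start = 60L, cds_end = 240L,
                     strand = "+") {
  data.frame(gene_id = "gX", chrom = "chrT", start = 1000L,
             end = 1000L + tx_len, strand = strand,
             biotype = "protein_coding",
             utr5_len = cds_start, cds_len = cds_end - cds_start,
             utr3_len = tx_len - cds_end, tx_len = tx_len,
             cds_start = cds_start, cds_end = cds_end,
             stringsAsFactors = FALSE)
}

# Genotype matrix from per-population allele frequencies (diploids).
toy_genotypes <- function(freqs, n_ind_per_pop) {
  geno <- do.call(cbind, lapply(seq_along(freqs), function(p)
    matrix(stats::rbinom(n_ind_per_pop, 2L, freqs[p]), nrow = 1)))
  pops <- factor(rep(paste0("pop", seq_along(freqs)), each = n_ind_per_pop))
  list(geno = geno, pops = pops)
}

# Independent transcription of the Weir & Cockerham (1984) theta formulas,
# written scalar-by-scalar as the oracle for the vectorized estimator.
wc_theta_oracle <- function(geno, pops) {
  pops <- droplevels(as.factor(pops))
  r <- nlevels(pops)
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    g <- geno[pops == levels(pops)[k]]
    g <- g[!is.na(g)]
    n_i[k] <- length(g)
    p_i[k] <- sum(g) / (2 * length(g))
    h_i[k] <- mean(g == 1)
  }
  n_bar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_bar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / sum(n_i)
  a <- (n_bar / nc) * (s2 - (1 / (n_bar - 1)) *
                         (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
                            h_bar / 4))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) -
                                  ((r - 1) / r) * s2 -
                                  ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  a / (a + b + cc)
}

# Synthetic conservation-record table with explicit strata, for the
# matched-control machinery.
toy_conservation <- function(n_m6a, n_pool, p_m6a, p_ctrl,
                             n_genes = 20, panel = c("mouse")) {
  n <- n_m6a + n_pool
  gene <- sample(sprintf("g%02d", seq_len(n_genes)), n, replace = TRUE)
  dnds <- stats::setNames(stats::rgamma(n_genes, 2, 10),
                          sprintf("g%02d", seq_len(n_genes)))
  df <- data.frame(
    aln_id = sprintf("a%05d", seq_len(n)),
    gene_id = gene,
    is_m6a = rep(c(TRUE, FALSE), c(n_m6a, n_pool)),
    region = "CDS",
    codon_pos = sample(1:3, n, replace = TRUE),
    cds_bin = sample(0:19, n, replace = TRUE),
    utr3_bin = NA_integer_,
    dnds = unname(dnds[gene]),
    stringsAsFactors = FALSE)
  p <- ifelse(df$is_m6a, p_m6a, p_ctrl)
  for (sp in panel) {
    b <- ifelse(stats::rbinom(n, 1, p) == 1, "A",
                sample(c("C", "G", "T", "-"), n, replace = TRUE))
    df[[paste0("base_", sp)]] <- b
  }
  df
}
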