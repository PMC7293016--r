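#' Configuration for a synthetic m6A study
#'
#' Defines the miniature study the generator emits: an intronless genome with
#' one transcript per gene (5'UTR / CDS / 3'UTR of fixed lengths), planted
#' RRACH m6A sites with tissue-structured methylation, paired IP/input
#' coverage, poly(A) cleavage sites, a cross-species alignment table and
#' population genotypes, all with machine-readable ground truth.
#'
#' @param seed integer master seed; every artifact derives its own RNG stream
#'   from it.
#' @param n_genes number of protein-coding genes.
#' @param tissue_names unique tissue labels (>= 2 for specificity analyses).
#' @param replicates_per_tissue biological replicates per tissue.
#' @param utr5_cds_utr3_lengths nt lengths of the three mRNA segments; the CDS
#'   length must be a multiple of 3.
#' @param site_density expected planted m6A sites per kb of transcript.
#' @param enrichment_factor multiplicative IP enrichment within +/-50 nt of a
#'   methylated site (> 1); 8 by default so a fully enriched window reaches
#'   winscore >= 2 (a 4-fold normalized ratio) with margin.
#' @param depth mean input coverage per expressed base.
#' @param nb_size negative-binomial size (dispersion) of per-base coverage.
#' @param tissue_specific_fraction fraction of planted sites methylated in
#'   exactly one tissue; the rest are methylated in all tissues.
#' @param conservation_prob_m6a,conservation_prob_control per-species
#'   probability that the aligned base of an m6A (resp. control) site is A.
#' @param species_panel species ordered by increasing divergence from the
#'   focal genome.
#' @param n_populations,n_haplotypes_per_pop population sample structure for
#'   the genotype simulator (haplotypes per population must be even).
#' @param selected_fraction fraction of gain-of-motif SNPs given an elevated
#'   derived allele frequency and population differentiation.
#' @param daf_shift derived-allele-frequency shift applied to selected SNPs.
#' @param fst_delta half-spread of population allele frequencies at selected
#'   SNPs (creates high Fst).
#' @param n_control_snps SNPs placed in each control RRACH group (non-m6A
#'   3'UTR motifs; intergenic motifs).
#' @param n_neutral_snps motif-free neutral SNPs.
#' @param n_ratio_snps SNPs planted across the five RRACH motif positions of
#'   methylated sites for allele-specific methylation tests.
#' @param frac_missing_aa fraction of SNPs emitted without an ancestral-allele
#'   tag, to exercise the exclusion path.
#' @param ncrna_fraction noncoding genes added as a fraction of `n_genes`.
#' @param ncrna_length transcript length of noncoding genes.
#' @param intergenic_gap nt of intergenic sequence between genes.
#' @param cleavage_frac_canonical fraction of cleavage sites planted with an
#'   AATAAA poly(A) signal 21 nt upstream.
#' @param cleavage_frac_m6a fraction of cleavage sites with an m6A site planted
#'   at the cleavage position.
#' @param cleavage_c_downstream probability that a noncanonical cleavage site
#'   gets a C immediately downstream of the cut.
#' @param expr_sdlog log-sd of per-gene, per-tissue expression factors.
#' @param rip_eff_sdlog log-sd of per-sample RIP efficiency (what the top-50
#'   winscore normalization corrects).
#' @param level_sdlog log-sd of per-site methylation level multipliers.
#' @param stop_bias fraction of coding-gene sites drawn from a normal
#'   distribution centred on the stop codon (the rest are uniform).
#' @param stop_sd sd (nt) of the stop-codon-centred planting distribution.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20)
#' cfg$enrichment_factor
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       tissue_names = c("cerebellum", "heart", "liver"),
                       replicates_per_tissue = 3L,
                       utr5_cds_utr3_lengths = c(240L, 1200L, 960L),
                       site_density = 2,
                       enrichment_factor = 8,
                       depth = 30,
                       nb_size = 10,
                       tissue_specific_fraction = 0.4,
                       conservation_prob_m6a = 0.9,
                       conservation_prob_control = 0.6,
                       species_panel = c("chimp", "macaque", "mouse",
                                         "dog", "opossum"),
                       n_populations = 2L,
                       n_haplotypes_per_pop = 120L,
                       selected_fraction = 0.3,
                       daf_shift = 0.3,
                       fst_delta = 0.25,
                       n_control_snps = 400L,
                       n_neutral_snps = 800L,
                       n_ratio_snps = 150L,
                       frac_missing_aa = 0.05,
                       ncrna_fraction = 0.1,
                       ncrna_length = 800L,
                       intergenic_gap = 2000L,
                       cleavage_frac_canonical = 0.6,
                       cleavage_frac_m6a = 0.3,
                       cleavage_c_downstream = 0.7,
                       expr_sdlog = 0.5,
                       rip_eff_sdlog = 0.2,
                       level_sdlog = 0.25,
                       stop_bias = 0.7,
                       stop_sd = 150) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    tissue_names = as.character(tissue_names),
    replicates_per_tissue = as.integer(replicates_per_tissue),
    utr5_cds_utr3_lengths = as.integer(utr5_cds_utr3_lengths),
    site_density = site_density, enrichment_factor = enrichment_factor,
    depth = depth, nb_size = nb_size,
    tissue_specific_fraction = tissue_specific_fraction,
    conservation_prob_m6a = conservation_prob_m6a,
    conservation_prob_control = conservation_prob_control,
    species_panel = as.character(species_panel),
    n_populations = as.integer(n_populations),
    n_haplotypes_per_pop = as.integer(n_haplotypes_per_pop),
    selected_fraction = selected_fraction, daf_shift = daf_shift,
    fst_delta = fst_delta,
    n_control_snps = as.integer(n_control_snps),
    n_neutral_snps = as.integer(n_neutral_snps),
    n_ratio_snps = as.integer(n_ratio_snps),
    frac_missing_aa = frac_missing_aa,
    ncrna_fraction = ncrna_fraction, ncrna_length = as.integer(ncrna_length),
    intergenic_gap = as.integer(intergenic_gap),
    cleavage_frac_canonical = cleavage_frac_canonical,
    cleavage_frac_m6a = cleavage_frac_m6a,
    cleavage_c_downstream = cleavage_c_downstream,
    expr_sdlog = expr_sdlog, rip_eff_sdlog = rip_eff_sdlog,
    level_sdlog = level_sdlog, stop_bias = stop_bias, stop_sd = stop_sd
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  len <- cfg$utr5_cds_utr3_lengths
  if (length(len) != 3L || any(len <= 0L))
    stop("utr5_cds_utr3_lengths must be three positive nt lengths")
  if (len[2] %% 3L != 0L)
    stop("CDS length must be divisible by 3, got ", len[2])
  if (cfg$enrichment_factor < 1)
    stop("enrichment_factor must be >= 1 (1 = null, no IP enrichment)")
  probs <- c(cfg$tissue_specific_fraction, cfg$conservation_prob_m6a,
             cfg$conservation_prob_control, cfg$selected_fraction,
             cfg$frac_missing_aa, cfg$cleavage_frac_canonical,
             cfg$cleavage_frac_m6a, cfg$cleavage_c_downstream)
  if (any(probs < 0 | probs > 1))
    stop("all probability parameters must lie in [0, 1]")
  if (length(cfg$tissue_names) < 1L || anyDuplicated(cfg$tissue_names))
    stop("tissue_names must be non-empty and unique")
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$n_haplotypes_per_pop %% 2L != 0L)
    stop("n_haplotypes_per_pop must be even (diploid individuals)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic m6A study configuration\n")
  cat("  genes:", x$n_genes, "coding +",
      round(x$n_genes * x$ncrna_fraction), "noncoding\n")
  cat("  segments (5'UTR/CDS/3'UTR):",
      paste(x$utr5_cds_utr3_lengths, collapse = "/"), "nt\n")
  cat("  tissues:", paste(x$tissue_names, collapse = ", "),
      sprintf("(x%d replicates)\n", x$replicates_per_tissue))
  cat("  site density:", x$site_density, "/kb; IP enrichment:",
      x$enrichment_factor, "x; depth:", x$depth, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
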