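#' Simulate a complete miniature m6A study
#'
#' Runs the full generator chain: genome and gene models, planted m6A sites,
#' cleavage sites, IP/input coverage, the cross-species alignment table,
#' population genotypes and allele pileups. Every artifact draws from its own
#' RNG stream derived from `config$seed`, so the result is bit-reproducible
#' and adding artifacts never perturbs earlier ones.
#'
#' @param config a [sim_config()].
#' @return An object of class `m6a_study`: a list with `config`, `genome`,
#'   `genes`, `transcripts`, `sites`, `cleavage`, `design`, `samples`,
#'   `expression`, `conservation`, `snps`, `genotypes`, `pops`, `pileups`.
#' @examples
#' study <- simulate_study(sim_config(seed = 1, n_genes = 10))
#' nrow(study$sites)
#' @export
simulate_study <- function(config = sim_config()) {
  gen <- generate_genome(config)
  gen <- plant_m6a_sites(gen, config)
  gen <- plant_cleavage_sites(gen, config)
  gen <- simulate_coverage(gen, config)
  gen <- simulate_alignment_table(gen, config)
  gen <- simulate_genotypes(gen, config)
  gen <- simulate_allele_pileups(gen, config)
  gen$config <- config
  class(gen) <- "m6a_study"
  gen
}

#' @export
print.m6a_study <- function(x, ...) {
  cat("Synthetic m6A study:", nrow(x$genes), "genes,",
      nrow(x$sites), "planted sites,",
      nrow(x$design), "samples (",
      paste(unique(x$design$tissue), collapse = ", "), ")\n")
  cat("  cleavage sites:", nrow(x$cleavage),
      "| RRACH alignment records:", nrow(x$conservation),
      "| SNPs:", nrow(x$snps), "\n")
  invisible(x)
}
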