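#' Simulate paired IP/input coverage tracks for every sample
#'
#' Per-base coverage is drawn directly as negative-binomial counts (the
#' read-mapping stage is out of scope; peak calling consumes coverage). Input
#' coverage fluctuates around `depth` scaled by a lognormal per-gene,
#' per-tissue expression factor. IP coverage equals the input mean scaled by
#' `enrichment_factor * m_level` within +/-50 nt of every site methylated in
#' the sample's tissue (the 100-nt calling window), by 1 elsewhere, and by a
#' lognormal per-sample RIP efficiency throughout. Library sizes are the
#' summed coverage of each track.
#'
#' @param gen output of [plant_cleavage_sites()] (or [plant_m6a_sites()]).
#' @param config the same [sim_config()].
#' @return `gen` with `design` (sample/tissue table), `samples` (per sample:
#'   `ip` and `input` per-gene coverage lists, library sizes, RIP efficiency)
#'   and `expression` (gene x tissue expression factors) added.
#' @export
simulate_coverage <- function(gen, config) {
  genes <- gen$genes
  sites <- gen$sites
  tissues <- config$tissue_names
  reps <- config$replicates_per_tissue
  design <- data.frame(
    sample_id = paste(rep(tissues, each = reps), seq_len(reps), sep = "_"),
    tissue = rep(tissues, each = reps),
    replicate = rep(seq_len(reps), length(tissues)),
    stringsAsFactors = FALSE
  )
  with_stream(config$seed, "coverage", {
    expr <- matrix(stats::rlnorm(nrow(genes) * length(tissues),
                                 0, config$expr_sdlog),
                   nrow(genes), length(tissues),
                   dimnames = list(genes$gene_id, tissues))
    # per-gene multiplier profile of IP enrichment for each tissue
    mult_by_tissue <- lapply(tissues, function(t) {
      lapply(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        m <- rep(1, g$tx_len)
        sel <- sites$gene_id == g$gene_id & sites[[paste0("meth_", t)]]
        if (any(sel)) {
          for (j in which(sel)) {
            w <- max(1L, sites$tx_pos[j] - 50L + 1L):
              min(g$tx_len, sites$tx_pos[j] + 50L + 1L)
            e <- config$enrichment_factor * sites$m_level[j]
            m[w] <- pmax(m[w], e)
          }
        }
        m
      })
    })
    names(mult_by_tissue) <- tissues
    samples <- vector("list", nrow(design))
    names(samples) <- design$sample_id
    for (s in seq_len(nrow(design))) {
      t <- design$tissue[s]
      eff <- stats::rlnorm(1L, 0, config$rip_eff_sdlog)
      ip <- vector("list", nrow(genes)); input <- vector("list", nrow(genes))
      names(ip) <- genes$gene_id; names(input) <- genes$gene_id
      for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        mu <- config$depth * expr[i, t]
        input[[i]] <- stats::rnbinom(g$tx_len, mu = mu, size = config$nb_size)
        ip[[i]] <- stats::rnbinom(g$tx_len,
                                  mu = mu * eff * mult_by_tissue[[t]][[i]],
                                  size = config$nb_size)
      }
      samples[[s]] <- list(
        sample_id = design$sample_id[s], tissue = t,
        ip = ip, input = input,
        ip_lib = sum(vapply(ip, sum, numeric(1))),
        input_lib = sum(vapply(input, sum, numeric(1))),
        rip_efficiency = eff
      )
    }
    gen$design <- design
    gen$samples <- samples
    gen$expression <- expr
    gen
  })
}

#' Simulate a cross-species alignment table for all RRACH sites
#'
#' Every central A of an RRACH motif in a transcript (planted m6A site or
#' background control) gets an aligned-base call per species in the ordered
#' panel: the base is conserved (A) independently per species with probability
#' `conservation_prob_m6a` for m6A sites and `conservation_prob_control` for
#' controls; non-conserved calls are substitutions or gaps. Per-gene dN/dS is
#' gamma-distributed and shared by m6A and control sites of the gene. A
#' nucleotide-level constraint surrogate (`rs_score`, a rejected-substitution
#' style score) is emitted, correlated with conservation and, for m6A sites,
#' with the planted methylation level.
#'
#' @param gen output of [simulate_coverage()] (needs genome and sites).
#' @param config the same [sim_config()].
#' @return `gen` with a `conservation` data frame added: site coordinates,
#'   `is_m6a`, region, codon position, CDS (20) and 3'UTR (10) location bins,
#'   `dnds`, `rs_score` and one `base_<species>` column per panel species.
#' @export
simulate_alignment_table <- function(gen, config) {
  genes <- gen$genes
  sites <- gen$sites
  panel <- config$species_panel
  with_stream(config$seed, "alignment", {
    dnds <- stats::rgamma(nrow(genes), shape = 2, rate = 10)
    names(dnds) <- genes$gene_id
    rows <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      txseq <- gene_tx_seq(gen$genome, g)
      apos <- scan_rrach(txseq)
      if (length(apos) == 0L) next
      truth <- sites[sites$gene_id == g$gene_id, ]
      is_m6a <- apos %in% truth$tx_pos
      m_level <- rep(NA_real_, length(apos))
      site_id <- rep(NA_character_, length(apos))
      mi <- match(apos, truth$tx_pos)
      m_level[!is.na(mi)] <- truth$m_level[mi[!is.na(mi)]]
      site_id[!is.na(mi)] <- truth$site_id[mi[!is.na(mi)]]
      if (g$biotype == "protein_coding") {
        region <- ifelse(apos < g$cds_start, "5'UTR",
                         ifelse(apos < g$cds_end, "CDS", "3'UTR"))
        codon_pos <- ifelse(region == "CDS",
                            (apos - g$cds_start) %% 3L + 1L, NA_integer_)
        cds_bin <- ifelse(region == "CDS",
                          pmin(19L, (apos - g$cds_start) %/%
                                 ceiling(g$cds_len / 20)), NA_integer_)
        dist_stop <- apos - g$cds_end
        utr3_bin <- ifelse(region == "3'UTR",
                           pmin(9L, (apos - g$cds_end) %/%
                                  ceiling(g$utr3_len / 10)), NA_integer_)
      } else {
        region <- rep("ncRNA", length(apos))
        codon_pos <- rep(NA_integer_, length(apos))
        cds_bin <- rep(NA_integer_, length(apos))
        utr3_bin <- rep(NA_integer_, length(apos))
        dist_stop <- rep(NA_integer_, length(apos))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom,
        pos = vapply(apos, function(p) tx_to_genome(g, p), numeric(1)),
        strand = g$strand, tx_pos = apos, is_m6a = is_m6a,
        site_id = site_id, m_level = m_level,
        region = region, codon_pos = codon_pos, cds_bin = cds_bin,
        utr3_bin = utr3_bin, dist_to_stop = dist_stop,
        dnds = unname(dnds[g$gene_id]),
        row.names = NULL, stringsAsFactors = FALSE)
    }
    cons <- do.call(rbind, rows)
    cons$aln_id <- sprintf("a%06d", seq_len(nrow(cons)))
    p <- ifelse(cons$is_m6a, config$conservation_prob_m6a,
                config$conservation_prob_control)
    nonA <- c("C", "G", "T", "-")
    for (sp in panel) {
      conserved <- stats::rbinom(nrow(cons), 1L, p) == 1L
      base <- sample(nonA, nrow(cons), replace = TRUE,
                     prob = c(0.27, 0.27, 0.26, 0.2))
      base[conserved] <- "A"
      cons[[paste0("base_", sp)]] <- base
    }
    n_cons <- rowSums(cons[, paste0("base_", panel), drop = FALSE] == "A")
    cons$rs_score <- n_cons + stats::rnorm(nrow(cons), 0, 0.5) +
      ifelse(cons$is_m6a, 2 * log2(cons$m_level), 0)
    gen$conservation <- cons[, c("aln_id", setdiff(names(cons), "aln_id"))]
    gen
  })
}
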