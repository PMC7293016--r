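#' Draw derived allele frequencies from a neutral-like spectrum
#'
#' Frequencies follow the standard neutral site-frequency spectrum
#' (probability proportional to 1/i for i derived copies among `n_hap`
#' haplotypes), optionally right-shifted to emulate positive selection.
#'
#' @param n number of SNPs.
#' @param n_hap total haplotypes the spectrum is defined over.
#' @param shift additive frequency shift (capped below fixation).
#' @return Numeric vector of derived allele frequencies in (0, 1).
#' @export
sim_daf <- function(n, n_hap = 240L, shift = 0) {
  i <- sample.int(n_hap - 1L, n, replace = TRUE,
                  prob = 1 / seq_len(n_hap - 1L))
  pmin(i / n_hap + shift, 1 - 1 / n_hap)
}

# one SNP row constructor used by simulate_genotypes
snp_row <- function(id, chrom, pos, ref, alt, aa, group, motif_pos,
                    gene_id, region, strand) {
  data.frame(snp_id = id, chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = alt, aa = aa, group = group, motif_pos = motif_pos,
             gene_id = gene_id, region = region, strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate population genotypes around planted and control motifs
#'
#' Emits biallelic SNPs of five classes: gain-of-motif SNPs at planted 3'UTR /
#' ncRNA m6A sites (reference carries the motif A, the ancestral allele
#' disrupts it, so the derived allele creates the RRAC motif); matched control
#' SNPs at non-m6A RRACH motifs in 3'UTRs and at intergenic RRACH motifs;
#' motif-free neutral SNPs; and "ratio" SNPs spread over the five RRACH
#' positions of methylated sites for allele-specific methylation tests. A
#' `selected_fraction` of the gain-of-motif SNPs get a derived-allele
#' frequency shifted by `daf_shift` and population frequencies split by
#' `fst_delta` (high Fst); everything else is neutral. A small fraction of
#' SNPs lack the ancestral-allele tag.
#'
#' @param gen output of [simulate_alignment_table()].
#' @param config the same [sim_config()].
#' @return `gen` with `snps` (annotation truth), `genotypes` (SNP x individual
#'   matrix of alt-allele dosages), `pops` (individual -> population) and
#'   `selected_snps` added.
#' @export
simulate_genotypes <- function(gen, config) {
  genes <- gen$genes
  sites <- gen$sites
  cons <- gen$conservation
  with_stream(config$seed, "genotypes", {
    rows <- list()
    add <- function(r) rows[[length(rows) + 1L]] <<- r
    other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

    ## gain-of-motif SNPs: the A of planted 3'UTR / ncRNA m6A motifs
    gsel <- which(cons$is_m6a & cons$region %in% c("3'UTR", "ncRNA"))
    for (k in gsel) {
      anc <- sample(c("C", "G", "T"), 1L)
      g <- genes[match(cons$gene_id[k], genes$gene_id), ]
      ref <- if (g$strand == "+") "A" else COMP[["A"]]
      alt <- if (g$strand == "+") anc else COMP[[anc]]
      add(snp_row(NA, cons$chrom[k], cons$pos[k], ref, alt, alt, "m6a_gain",
                  "A", g$gene_id, cons$region[k], g$strand))
    }
    ## control SNPs at non-m6A 3'UTR RRACH motifs
    csel <- which(!cons$is_m6a & cons$region == "3'UTR")
    csel <- sample(csel, min(config$n_control_snps, length(csel)))
    for (k in csel) {
      anc <- sample(c("C", "G", "T"), 1L)
      g <- genes[match(cons$gene_id[k], genes$gene_id), ]
      ref <- if (g$strand == "+") "A" else COMP[["A"]]
      alt <- if (g$strand == "+") anc else COMP[[anc]]
      add(snp_row(NA, cons$chrom[k], cons$pos[k], ref, alt, alt, "ctrl_utr3",
                  "A", g$gene_id, "3'UTR", g$strand))
    }
    ## control SNPs at intergenic RRACH motifs (plus strand scan)
    chrom <- names(gen$genome)[1]
    occupied <- logical(nchar(gen$genome[[chrom]]))
    for (i in seq_len(nrow(genes)))
      occupied[(genes$start[i] + 1L):genes$end[i]] <- TRUE
    apos <- scan_rrach(gen$genome[[chrom]])  # 0-based central A, plus strand
    inter <- apos[!occupied[apos + 1L]]
    inter <- sample(inter, min(config$n_control_snps, length(inter)))
    for (p in inter) {
      anc <- sample(c("C", "G", "T"), 1L)
      add(snp_row(NA, chrom, p, "A", anc, anc, "ctrl_intergenic",
                  "A", NA_character_, "intergenic", "+"))
    }
    ## neutral motif-free SNPs at random intergenic positions
    free <- which(!occupied) - 1L
    free <- sample(free, min(config$n_neutral_snps, length(free)))
    for (p in free) {
      refb <- substr(gen$genome[[chrom]], p + 1L, p + 1L)
      if (refb == "N") next
      w <- substr(gen$genome[[chrom]], p - 3L, p + 5L)
      if (grepl(RRACH_RE, w)) next  # keep the neutral class motif-free
      alt <- sample(other_bases(refb), 1L)
      anc <- if (stats::runif(1) < 0.8) refb else alt
      add(snp_row(NA, chrom, p, refb, alt, anc, "neutral",
                  "none", NA_character_, "intergenic", "+"))
    }
    ## ratio SNPs across the five motif positions of methylated sites
    rsel <- sample(seq_len(nrow(sites)), min(config$n_ratio_snps, nrow(sites)))
    offs <- c(R1 = -2L, R2 = -1L, A = 0L, C = 1L, H = 2L)
    labs <- sample(names(offs), length(rsel), replace = TRUE)
    for (j in seq_along(rsel)) {
      st <- sites[rsel[j], ]
      g <- genes[match(st$gene_id, genes$gene_id), ]
      off <- offs[[labs[j]]]
      motif_base <- substr(st$motif, off + 3L, off + 3L)  # sense strand
      breaking <- switch(labs[j],
        R1 = , R2 = sample(c("C", "T"), 1L),
        A = sample(c("C", "G", "T"), 1L),
        C = sample(c("A", "G", "T"), 1L),
        H = "G")
      gpos <- tx_to_genome(g, st$tx_pos + off)
      ref <- if (g$strand == "+") motif_base else COMP[[motif_base]]
      alt <- if (g$strand == "+") breaking else COMP[[breaking]]
      add(snp_row(st$site_id, st$chrom, gpos, ref, alt,
                  sample(c(ref, alt), 1L), "ratio", labs[j],
                  st$gene_id, "site", g$strand))
    }

    snps <- do.call(rbind, rows)
    site_ref <- snps$snp_id  # ratio rows carried the site id here
    snps$site_id <- ifelse(snps$group == "ratio", site_ref, NA_character_)
    snps <- snps[!duplicated(paste(snps$chrom, snps$pos)), ]
    snps$snp_id <- sprintf("snp%05d", seq_len(nrow(snps)))

    ## frequencies
    H <- config$n_populations * config$n_haplotypes_per_pop
    daf <- sim_daf(nrow(snps), H)
    selected <- rep(FALSE, nrow(snps))
    gain <- which(snps$group == "m6a_gain")
    sel <- gain[stats::rbinom(length(gain), 1L, config$selected_fraction) == 1L]
    selected[sel] <- TRUE
    daf[sel] <- pmin(daf[sel] + config$daf_shift, 1 - 1 / H)
    pf <- matrix(daf, nrow(snps), config$n_populations)
    if (length(sel)) {
      pf[sel, 1] <- pmin(daf[sel] + config$fst_delta, 0.98)
      pf[sel, -1] <- pmax(daf[sel] - config$fst_delta, 0.02)
    }
    ## genotypes: derived-allele dosages per diploid individual, then
    ## converted to alt-allele dosage using the ancestral tag
    n_ind_pop <- config$n_haplotypes_per_pop %/% 2L
    n_ind <- n_ind_pop * config$n_populations
    pops <- factor(rep(paste0("pop", seq_len(config$n_populations)),
                       each = n_ind_pop))
    derived_dos <- matrix(0L, nrow(snps), n_ind)
    for (p in seq_len(config$n_populations)) {
      idx <- which(as.integer(pops) == p)
      derived_dos[, idx] <- stats::rbinom(nrow(snps) * length(idx), 2L,
                                          rep(pf[, p], length(idx)))
    }
    derived_is_alt <- ifelse(is.na(snps$aa), NA, snps$aa == snps$ref)
    geno <- derived_dos
    flip <- which(!is.na(derived_is_alt) & !derived_is_alt)
    geno[flip, ] <- 2L - derived_dos[flip, ]
    # for SNPs about to lose their AA tag, dosage orientation is arbitrary
    drop_aa <- stats::runif(nrow(snps)) < config$frac_missing_aa
    snps$aa[drop_aa] <- NA_character_
    snps$daf_true <- daf
    snps$selected <- selected
    rownames(geno) <- snps$snp_id
    gen$snps <- snps
    gen$genotypes <- geno
    gen$pops <- pops
    gen$selected_snps <- snps$snp_id[selected]
    gen
  })
}

#' Simulate IP/input allele pileups at heterozygous motif SNPs
#'
#' For every "ratio" SNP and sample, the individual is heterozygous with
#' probability 1/2; heterozygous SNPs yield read counts in both compartments.
#' The m6A (motif-matching) allele is drawn at frequency 0.5 in input reads
#' and, when the site is methylated in the sample's tissue and the SNP sits in
#' an RRAC position (not H), at `ip_ratio` in IP reads.
#'
#' @param gen output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @param mean_reads Poisson mean read depth per compartment.
#' @param ip_ratio IP m6A-allele ratio at methylation-affecting positions.
#' @return `gen` with a `pileups` data frame added (snp_id, sample_id,
#'   compartment, m6a_count, total).
#' @export
simulate_allele_pileups <- function(gen, config, mean_reads = 40,
                                    ip_ratio = 0.8) {
  snps <- gen$snps[gen$snps$group == "ratio", ]
  sites <- gen$sites
  with_stream(config$seed, "pileups", {
    rows <- list()
    for (i in seq_len(nrow(snps))) {
      st <- sites[match(snps$site_id[i], sites$site_id), ]
      for (s in gen$design$sample_id) {
        if (stats::runif(1) > 0.5) next  # homozygous in this individual
        tissue <- gen$design$tissue[gen$design$sample_id == s]
        meth <- isTRUE(st[[paste0("meth_", tissue)]])
        p_ip <- if (meth && snps$motif_pos[i] != "H") ip_ratio else 0.5
        for (comp in c("input", "IP")) {
          tot <- stats::rpois(1L, mean_reads) + 1L
          p <- if (comp == "IP") p_ip else 0.5
          rows[[length(rows) + 1L]] <- data.frame(
            snp_id = snps$snp_id[i], sample_id = s, compartment = comp,
            motif_pos = snps$motif_pos[i],
            m6a_count = stats::rbinom(1L, tot, p), total = tot,
            row.names = NULL, stringsAsFactors = FALSE)
        }
      }
    }
    gen$pileups <- do.call(rbind, rows)
    gen$pileups$ratio <- gen$pileups$m6a_count / gen$pileups$total
    gen
  })
}
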