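# Population-genetic selection scans on m6A motifs: SNP motif annotation,
# allele-specific methylation, DAF spectra and per-SNP Weir-Cockerham Fst.

MOTIF_POS_LABELS <- c("R1", "R2", "A", "C", "H")

# Sense-strand 5-mer windows containing a SNP, for one allele substituted in.
# context: 9-mer centred on the SNP (sense strand); allele: sense-strand base.
snp_windows <- function(context, allele) {
  ch <- strsplit(context, "")[[1]]
  ch[5] <- allele
  vapply(1:5, function(i) paste(ch[i:(i + 4)], collapse = ""), character(1))
}

#' Annotate SNPs relative to RRACH motifs
#'
#' For every biallelic SNP, determines (a) its position within a catalogued
#' m6A-site motif (R1/R2/A/C/H, transcript orientation) and which allele is
#' the m6A (motif-matching) allele, flagging SNPs where both alleles complete
#' a motif as ambiguous; and (b) whether the derived allele creates an RRAC
#' motif anywhere in its local context while the ancestral allele does not
#' (`creates_motif`). Alleles are complemented onto the sense strand of the
#' host gene (plus strand for intergenic SNPs).
#'
#' @param snps SNP table (`chrom`, `pos` 0-based, `ref`, `alt`, `aa`,
#'   optional `gene_id`).
#' @param genome named character vector of chromosome sequences.
#' @param sites m6A site catalog (`chrom`, `gpos`, `strand`, `site_id`).
#' @param genes gene table (for strand lookup).
#' @return `snps` with `motif_pos`, `m6a_allele` (sense strand), `ambiguous`,
#'   `site_id` and `creates_motif` columns added.
#' @export
find_motif_snps <- function(snps, genome, sites, genes) {
  n <- nrow(snps)
  motif_pos <- rep("none", n)
  m6a_allele <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)
  site_hit <- rep(NA_character_, n)
  creates <- rep(NA, n)
  gene_strand <- rep("+", n)
  if (!is.null(snps$gene_id)) {
    gi <- match(snps$gene_id, genes$gene_id)
    gene_strand[!is.na(gi)] <- genes$strand[gi[!is.na(gi)]]
  }
  site_key <- paste(sites$chrom, sites$gpos, sites$strand)
  for (i in seq_len(n)) {
    strand <- gene_strand[i]
    chrom_seq <- genome[[snps$chrom[i]]]
    gctx <- substr(chrom_seq, snps$pos[i] - 4L + 1L, snps$pos[i] + 4L + 1L)
    if (nchar(gctx) != 9L) next
    if (strand == "-") {
      ctx <- revcomp(gctx)
      ref <- COMP[[snps$ref[i]]]; alt <- COMP[[snps$alt[i]]]
    } else {
      ctx <- gctx
      ref <- snps$ref[i]; alt <- snps$alt[i]
    }
    w_ref <- snp_windows(ctx, ref)
    w_alt <- snp_windows(ctx, alt)
    ## (a) position within a catalogued site's motif
    for (off in -2:2) {
      a_gpos <- if (strand == "+") snps$pos[i] - off else snps$pos[i] + off
      k <- match(paste(snps$chrom[i], a_gpos, strand), site_key)
      if (!is.na(k)) {
        motif_pos[i] <- MOTIF_POS_LABELS[off + 3L]
        site_hit[i] <- sites$site_id[k]
        # the site's 5-mer is window starting at SNP offset -(off+2) from the
        # SNP, i.e. windows index 3 - off
        wi <- 3L - off
        ref_ok <- is_rrach(w_ref[wi]); alt_ok <- is_rrach(w_alt[wi])
        if (ref_ok && alt_ok) ambiguous[i] <- TRUE
        else if (ref_ok) m6a_allele[i] <- ref
        else if (alt_ok) m6a_allele[i] <- alt
        break
      }
    }
    ## (b) derived allele creates an RRAC motif
    if (!is.na(snps$aa[i])) {
      derived <- if (snps$aa[i] == snps$ref[i]) alt else ref
      ancestral <- if (snps$aa[i] == snps$ref[i]) ref else alt
      # RRAC 4-mers of the sense context that cover the SNP (index 5)
      rrac_covering <- function(allele) {
        ch <- strsplit(ctx, "")[[1]]
        ch[5] <- allele
        any(vapply(2:5, function(j)
          grepl("^[AG][AG]AC$", paste(ch[j:(j + 3)], collapse = "")),
          logical(1)))
      }
      creates[i] <- rrac_covering(derived) && !rrac_covering(ancestral)
    }
  }
  snps$motif_pos <- motif_pos
  snps$m6a_allele <- m6a_allele
  snps$ambiguous <- ambiguous
  snps$site_id_hit <- site_hit
  snps$creates_motif <- creates
  snps
}

#' Allele-specific methylation test per motif position
#'
#' Compares the m6A-allele read ratio (m6A-allele reads / total reads) between
#' IP and input compartments for heterozygous SNPs at each RRACH motif
#' position, with a two-sample Kolmogorov-Smirnov test and a directional
#' summary (median IP ratio - median input ratio). Positions with fewer than
#' `min_het` heterozygous observations are suppressed.
#'
#' @param pileups data frame: `snp_id`, `sample_id`, `compartment`
#'   ("IP"/"input"), `motif_pos`, `ratio` (or `m6a_count` and `total`).
#' @param min_het minimum heterozygous SNP-sample observations per position.
#' @return Data frame per motif position: n, KS statistic and p, median
#'   difference; suppressed positions carry NA and a reason.
#' @export
allele_ratio_test <- function(pileups, min_het = 5L) {
  if (is.null(pileups$ratio))
    pileups$ratio <- pileups$m6a_count / pileups$total
  out <- list()
  for (pos in intersect(MOTIF_POS_LABELS, unique(pileups$motif_pos))) {
    sub <- pileups[pileups$motif_pos == pos, ]
    ip <- sub$ratio[sub$compartment == "IP"]
    input <- sub$ratio[sub$compartment == "input"]
    n <- min(length(ip), length(input))
    if (n < min_het) {
      out[[pos]] <- data.frame(motif_pos = pos, n = n, ks_stat = NA_real_,
                               p = NA_real_, median_diff = NA_real_,
                               note = "suppressed: too few heterozygous SNPs",
                               stringsAsFactors = FALSE)
      next
    }
    ks <- suppressWarnings(stats::ks.test(ip, input))
    out[[pos]] <- data.frame(motif_pos = pos, n = n,
                             ks_stat = unname(ks$statistic), p = ks$p.value,
                             median_diff = stats::median(ip) -
                               stats::median(input),
                             note = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Derived allele frequencies from genotypes
#'
#' @param geno SNP x individual matrix of alt-allele dosages (0/1/2).
#' @param ref,alt,aa allele columns; SNPs with `aa` missing or not matching
#'   either allele return NA (excluded from DAF analyses and counted).
#' @return Numeric vector of derived allele frequencies.
#' @export
derived_allele_frequency <- function(geno, ref, alt, aa) {
  alt_freq <- rowMeans(geno, na.rm = TRUE) / 2
  ifelse(is.na(aa) | !(aa == ref | aa == alt), NA_real_,
         ifelse(aa == ref, alt_freq, 1 - alt_freq))
}

#' One-sided DAF spectrum comparison
#'
#' Tests whether the derived-allele-frequency distribution of gain-of-motif
#' SNPs is right-shifted relative to each control group, with a one-sided
#' Mann-Whitney U test (normal approximation with tie correction).
#'
#' @param daf_m6a DAF values of the m6A gain-of-motif group.
#' @param controls named list of control DAF vectors.
#' @return Data frame per control group: sizes, median difference, one-sided p.
#' @export
daf_spectrum_test <- function(daf_m6a, controls) {
  daf_m6a <- daf_m6a[!is.na(daf_m6a)]
  out <- lapply(names(controls), function(nm) {
    ctrl <- controls[[nm]][!is.na(controls[[nm]])]
    wt <- stats::wilcox.test(daf_m6a, ctrl, alternative = "greater",
                             exact = FALSE, correct = TRUE)
    data.frame(control = nm, n_m6a = length(daf_m6a), n_control = length(ctrl),
               median_m6a = stats::median(daf_m6a),
               median_control = stats::median(ctrl),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-SNP Weir-Cockerham Fst
#'
#' The Weir & Cockerham (1984) variance-components estimator theta computed
#' from genotypes, as population-genetics tools compute per-site Fst. Raw
#' estimates are reported (they may be negative); SNPs monomorphic across all
#' populations are undefined (NA).
#'
#' @param geno SNP x individual matrix of alt-allele dosages (0/1/2; NA
#'   allowed).
#' @param pops factor of population assignments (length = individuals; at
#'   least 2 populations with at least 1 genotype each).
#' @return Numeric vector of theta estimates, one per SNP.
#' @export
weir_cockerham_fst <- function(geno, pops) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  pops <- droplevels(as.factor(pops))
  r <- nlevels(pops)
  if (r < 2) stop("Fst requires at least two populations")
  idx <- split(seq_len(ncol(geno)), pops)
  n_i <- sapply(idx, function(j) rowSums(!is.na(geno[, j, drop = FALSE])))
  p_i <- sapply(idx, function(j)
    rowSums(geno[, j, drop = FALSE], na.rm = TRUE)) / (2 * n_i)
  h_i <- sapply(idx, function(j)
    rowSums(geno[, j, drop = FALSE] == 1L, na.rm = TRUE)) / n_i
  if (is.null(dim(n_i))) {
    n_i <- matrix(n_i, nrow = 1); p_i <- matrix(p_i, nrow = 1)
    h_i <- matrix(h_i, nrow = 1)
  }
  n_bar <- rowMeans(n_i)
  n_tot <- rowSums(n_i)
  nc <- (n_tot - rowSums(n_i^2) / n_tot) / (r - 1)
  p_bar <- rowSums(n_i * p_i) / n_tot
  s2 <- rowSums(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_i * h_i) / n_tot
  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) /
       (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  theta <- a / (a + b + cc)
  mono <- p_bar == 0 | p_bar == 1
  theta[mono] <- NA_real_
  unname(theta)
}

#' Highly differentiated SNPs
#'
#' @param fst per-SNP Fst estimates.
#' @param threshold strict lower bound (SNPs with Fst > threshold pass).
#' @return Integer indices of the differentiated SNPs.
#' @export
high_fst_filter <- function(fst, threshold = 0.15) {
  which(!is.na(fst) & fst > threshold)
}
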