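#' Generate a synthetic genome and gene models
#'
#' Emits one chromosome carrying intronless genes separated by intergenic
#' gaps. Each protein-coding gene has a 5'UTR, CDS and 3'UTR of the configured
#' lengths on a random strand, with ATG/TAA written at the CDS boundaries;
#' noncoding genes have no CDS. Random sequence guarantees RRACH motifs both
#' inside (after planting) and outside planted sites. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences), `genes` (one row per gene) and `transcripts` (one isoform per
#'   gene; columns `transcript_id`, `gene_id`, `length`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$utr5_cds_utr3_lengths
  with_stream(config$seed, "genome", {
    n_cod <- config$n_genes
    n_nc <- as.integer(round(n_cod * config$ncrna_fraction))
    gap <- config$intergenic_gap
    glen <- c(rep(sum(len), n_cod), rep(config$ncrna_length, n_nc))
    total <- n_cod + n_nc
    starts <- gap + cumsum(c(0L, glen[-total] + gap))
    chrom_len <- starts[total] + glen[total] + gap
    seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    genome <- c(chrS = paste(seq_chars, collapse = ""))
    strand <- sample(c("+", "-"), total, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(total)),
      chrom = "chrS",
      start = starts,
      end = starts + glen,
      strand = strand,
      biotype = c(rep("protein_coding", n_cod), rep("ncRNA", n_nc)),
      utr5_len = c(rep(len[1], n_cod), rep(NA_integer_, n_nc)),
      cds_len = c(rep(len[2], n_cod), rep(NA_integer_, n_nc)),
      utr3_len = c(rep(len[3], n_cod), rep(NA_integer_, n_nc)),
      tx_len = glen,
      cds_start = c(rep(len[1], n_cod), rep(NA_integer_, n_nc)),
      cds_end = c(rep(len[1] + len[2], n_cod), rep(NA_integer_, n_nc)),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n_cod)) {
      g <- genes[i, ]
      genome <- set_tx_seq(genome, g, g$cds_start, c("A", "T", "G"))
      genome <- set_tx_seq(genome, g, g$cds_end - 3L, c("T", "A", "A"))
    }
    transcripts <- data.frame(
      transcript_id = paste0(genes$gene_id, ".t1"),
      gene_id = genes$gene_id,
      length = genes$tx_len,
      stringsAsFactors = FALSE
    )
    list(genome = genome, genes = genes, transcripts = transcripts)
  })
}

# Planting distribution over transcript offsets of one coding gene:
# a stop-codon-centred normal component plus a uniform component.
sample_site_positions <- function(gene, n, config) {
  if (n == 0L) return(integer(0))
  from_stop <- stats::rbinom(n, 1L, if (is.na(gene$cds_end)) 0 else config$stop_bias)
  pos <- integer(n)
  k <- sum(from_stop == 1L)
  if (k > 0)
    pos[from_stop == 1L] <- as.integer(round(
      stats::rnorm(k, mean = gene$cds_end, sd = config$stop_sd)))
  if (k < n)
    pos[from_stop == 0L] <- as.integer(floor(
      stats::runif(n - k, min = 5, max = gene$tx_len - 5)))
  pmin(pmax(pos, 5L), gene$tx_len - 6L)
}

# Offsets whose 5-mer would overlap the start or stop codon are off limits.
codon_guard <- function(gene, pos) {
  if (is.na(gene$cds_start)) return(rep(TRUE, length(pos)))
  ok <- !(pos >= gene$cds_start - 2L & pos <= gene$cds_start + 4L) &
    !(pos >= gene$cds_end - 5L & pos <= gene$cds_end + 1L)
  ok
}

SUBMOTIFS <- c("GGACH", "AGACH", "GAACH", "AAACH")
SUBMOTIF_PROBS <- c(GGACH = 0.45, AGACH = 0.25, GAACH = 0.15, AAACH = 0.15)

make_motif <- function(class, h = NULL) {
  h <- h %||% sample(c("A", "C", "T"), 1L)
  c(substr(class, 1, 1), substr(class, 2, 2), "A", "C", h)
}

#' Plant m6A sites with tissue-structured methylation
#'
#' Draws a Poisson number of sites per gene (density `site_density`/kb),
#' concentrates coding-gene sites around the stop codon, writes an RRACH 5-mer
#' into the reference at each site (central A methylated, transcript
#' orientation) and assigns per-tissue methylation flags: a site is
#' tissue-specific (methylated in exactly one tissue) with probability
#' `tissue_specific_fraction`, otherwise methylated in all tissues. Each site
#' also carries a lognormal methylation-level multiplier used by the coverage
#' simulator.
#'
#' @param gen output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return `gen` with the genome edited in place and a `sites` truth
#'   data frame added (`meth_<tissue>` columns are the methylation flags).
#' @export
plant_m6a_sites <- function(gen, config) {
  genes <- gen$genes
  genome <- gen$genome
  tissues <- config$tissue_names
  with_stream(config$seed, "sites", {
    rows <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      n <- stats::rpois(1L, config$site_density * g$tx_len / 1000)
      pos <- sample_site_positions(g, n, config)
      pos <- sort(unique(pos[codon_guard(g, pos)]))
      if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 5L)]
      if (length(pos) == 0L) next
      cls <- sample(SUBMOTIFS, length(pos), replace = TRUE,
                    prob = SUBMOTIF_PROBS)
      motif <- character(length(pos))
      for (j in seq_along(pos)) {
        chars <- make_motif(cls[j])
        genome <- set_tx_seq(genome, g, pos[j] - 2L, chars)
        motif[j] <- paste(chars, collapse = "")
      }
      gpos <- vapply(pos, function(p) tx_to_genome(g, p), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, gpos = as.integer(gpos),
        strand = g$strand, tx_pos = pos, motif = motif, submotif = cls,
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
    if (is.null(sites)) stop("no sites planted; increase site_density")
    sites$site_id <- sprintf("s%05d", seq_len(nrow(sites)))
    specific <- stats::rbinom(nrow(sites), 1L,
                              config$tissue_specific_fraction) == 1L
    meth <- matrix(TRUE, nrow(sites), length(tissues),
                   dimnames = list(NULL, paste0("meth_", tissues)))
    if (any(specific)) {
      pick <- sample.int(length(tissues), sum(specific), replace = TRUE)
      meth[specific, ] <- FALSE
      meth[cbind(which(specific), pick)] <- TRUE
    }
    sites$specific <- specific
    sites$m_level <- stats::rlnorm(nrow(sites), 0, config$level_sdlog)
    sites <- cbind(sites, as.data.frame(meth))
    gen$genome <- genome
    gen$sites <- sites[, c("site_id", setdiff(names(sites), "site_id"))]
    gen
  })
}

PAS_CANONICAL <- "AATAAA"
PAS_SECOND <- "ATTAAA"

#' Common single-base AAUAAA variants used for the "other" canonical class
#' @return Character vector of hexamers (DNA alphabet).
#' @export
pas_variant_hexamers <- function() {
  c("AGTAAA", "TATAAA", "CATAAA", "GATAAA", "AATATA",
    "AATACA", "AATAGA", "AAAAAG", "ACTAAA", "AATGAA")
}

all_pas_hexamers <- function() c(PAS_CANONICAL, PAS_SECOND, pas_variant_hexamers())

# TRUE if the 40-nt window upstream of tx position pos contains any listed
# poly(A) hexamer.
has_pas_upstream <- function(txseq, pos) {
  win <- substr(txseq, max(1L, pos - 40L + 1L), pos)  # 1-based of 0-based pos-40..pos-1
  any(vapply(all_pas_hexamers(), function(h) grepl(h, win, fixed = TRUE),
             logical(1)))
}

#' Plant poly(A) cleavage sites (with optional PAS and m6A co-localization)
#'
#' One cleavage site per coding gene, placed in the 3'UTR. Canonical sites
#' (probability `cleavage_frac_canonical`) get AATAAA written 21 nt upstream;
#' noncanonical sites have all listed poly(A) hexamers scrubbed from the 40 nt
#' upstream and receive a C immediately downstream of the cut with probability
#' `cleavage_c_downstream`. A fraction `cleavage_frac_m6a` of cleavage sites
#' get an m6A site planted exactly at the cleavage position (AAACH-biased,
#' mirroring the sub-motif skew seen at cleavage positions); these are
#' appended to the site truth table.
#'
#' @param gen output of [plant_m6a_sites()].
#' @param config the same [sim_config()].
#' @return `gen` with a `cleavage` truth table added and genome/sites updated.
#' @export
plant_cleavage_sites <- function(gen, config) {
  genes <- gen$genes
  with_stream(config$seed, "cleavage", {
    genome <- gen$genome
    sites <- gen$sites
    tissues <- config$tissue_names
    rows <- list()
    extra <- list()
    for (i in which(genes$biotype == "protein_coding")) {
      g <- genes[i, ]
      site_pos <- sites$tx_pos[sites$gene_id == g$gene_id]
      pos <- NA_integer_
      for (try in 1:20) {
        cand <- as.integer(floor(stats::runif(1, g$cds_end + 45L, g$tx_len - 5L)))
        if (!any(abs(site_pos - cand) <= 47L)) { pos <- cand; break }
      }
      if (is.na(pos)) next
      canonical <- stats::rbinom(1L, 1L, config$cleavage_frac_canonical) == 1L
      with_m6a <- stats::rbinom(1L, 1L, config$cleavage_frac_m6a) == 1L
      if (canonical) {
        genome <- set_tx_seq(genome, g, pos - 21L,
                             strsplit(PAS_CANONICAL, "")[[1]])
      }
      m6a_id <- NA_character_
      if (with_m6a) {
        cls <- if (stats::runif(1) < 0.6) "AAACH" else
          sample(SUBMOTIFS, 1L, prob = SUBMOTIF_PROBS)
        h <- if (!canonical && stats::runif(1) < config$cleavage_c_downstream)
          "C" else NULL
        chars <- make_motif(cls, h)
        genome <- set_tx_seq(genome, g, pos - 2L, chars)
        m6a_id <- sprintf("s%05d", nrow(sites) + length(extra) + 1L)
        meth <- rep(TRUE, length(tissues))
        spec <- stats::rbinom(1L, 1L, config$tissue_specific_fraction) == 1L
        if (spec) {
          meth <- rep(FALSE, length(tissues))
          meth[sample.int(length(tissues), 1L)] <- TRUE
        }
        row <- data.frame(
          site_id = m6a_id, gene_id = g$gene_id, chrom = g$chrom,
          gpos = as.integer(tx_to_genome(g, pos)), strand = g$strand,
          tx_pos = pos, motif = paste(chars, collapse = ""), submotif = cls,
          specific = spec,
          m_level = stats::rlnorm(1L, 0, config$level_sdlog),
          row.names = NULL, stringsAsFactors = FALSE)
        for (k in seq_along(tissues)) row[[paste0("meth_", tissues[k])]] <- meth[k]
        extra[[length(extra) + 1L]] <- row
      } else if (!canonical &&
                 stats::runif(1) < config$cleavage_c_downstream) {
        genome <- set_tx_seq(genome, g, pos + 1L, "C")
      }
      if (!canonical) {
        # scrub accidental poly(A) hexamers from the upstream window, avoiding
        # bases of the planted motif (tx pos-2..pos+2)
        for (iter in 1:20) {
          txseq <- gene_tx_seq(genome, g)
          win0 <- pos - 40L  # 0-based first offset of the scan window
          win <- substr(txseq, win0 + 1L, pos)
          hit <- NA_integer_
          for (h in all_pas_hexamers()) {
            m <- regexpr(h, win, fixed = TRUE)
            if (m[1] != -1L) { hit <- win0 + as.integer(m) - 1L; break }
          }
          if (is.na(hit)) break
          cand <- hit + 0:5
          cand <- cand[cand < pos - 2L | cand > pos + 2L]
          repl <- sample(c("C", "G"), 1L)
          genome <- set_tx_seq(genome, g, cand[1], repl)
        }
        if (has_pas_upstream(gene_tx_seq(genome, g), pos)) next  # give up
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cleavage_id = sprintf("c%04d", length(rows) + 1L),
        gene_id = g$gene_id, chrom = g$chrom,
        gpos = as.integer(tx_to_genome(g, pos)), strand = g$strand,
        tx_pos = pos,
        pas_planted = if (canonical) "canonical" else "none",
        has_m6a = with_m6a, m6a_site_id = m6a_id,
        stringsAsFactors = FALSE)
    }
    if (length(extra)) sites <- rbind(sites, do.call(rbind, extra))
    gen$genome <- genome
    gen$sites <- sites
    gen$cleavage <- do.call(rbind, rows)
    gen
  })
}
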