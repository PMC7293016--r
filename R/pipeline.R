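# End-to-end orchestration: simulate (or load), call peaks, profile, test,
# with a reproducible manifest.

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in dependency order: simulation, peak calling and site
#' inference, metagene profiling, tissue specificity, sub-motif tests,
#' cleavage-site association, cross-species constraint and population
#' genetics. All outputs are written under `outdir` together with a manifest
#' (config hash, seed, per-file checksums); a rerun with an identical config
#' is bit-identical.
#'
#' @param config a [sim_config()] defining the study.
#' @param outdir output directory.
#' @param n_shuffles shuffles for the sub-motif co-occurrence test.
#' @param n_null_sets control sets for the conservation null distribution.
#' @param stages character vector of stages to run after simulation and peak
#'   calling (any of "metagene", "specificity", "motifs", "cleavage",
#'   "evolution", "popgen").
#' @param quiet suppress progress messages.
#' @return List of class `m6a_run` with per-stage results and the `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("m6adyn_"),
                         n_shuffles = 10000L, n_null_sets = 10000L,
                         stages = c("metagene", "specificity", "motifs",
                                    "cleavage", "evolution", "popgen"),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  say("stage simulate: %d genes, %d samples", config$n_genes,
      length(config$tissue_names) * config$replicates_per_tissue)
  study <- simulate_study(config)
  write_study(study, file.path(outdir, "inputs"))

  say("stage peakcall")
  pk <- call_peaks(study)
  res <- list(config = config, study = study, peaks = pk$peaks,
              sites = pk$sites)
  tsv <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(pk$peaks, "peaks.tsv")
  write_sites_bed(pk$sites, file.path(outdir, "sites.bed"))

  ws <- site_sample_winscores(pk$sites, pk$stats)
  norm <- normalize_winscores_top50(
    lapply(stats::setNames(nm = study$design$sample_id), function(s) {
      col <- paste0("ws_", s)
      v <- pk$peaks[[col]]
      v[!is.na(v)]
    }))
  res$normalization_factors <- norm$factors
  ws_norm <- sweep(ws, 2, norm$factors[colnames(ws)], `*`)
  utils::write.table(data.frame(site_id = rownames(ws), ws,
                                check.names = FALSE),
                     file.path(outdir, "site_winscores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if ("metagene" %in% stages) {
    say("stage metagene")
    bins <- assign_bins(pk$sites, study$genes)
    labels <- annotate_genic_region(pk$sites, study$genes)
    res$metagene <- metagene_profile(bins$bin)
    res$genic_regions <- table(labels)
    res$cds_utr3_ratio <- cds_utr3_ratio(labels)
    res$bins <- bins
    tsv(data.frame(bin = 0:99, count = res$metagene$counts,
                   fraction = res$metagene$fraction,
                   smooth = res$metagene$smooth), "metagene.tsv")
    tsv(data.frame(site_id = pk$sites$site_id, region = labels),
        "genic_regions.tsv")
  }

  if ("specificity" %in% stages) {
    say("stage specificity")
    prof <- tissue_winscore_matrix(ws_norm, study$design)
    tau <- tau_profile(prof)
    meth <- as.matrix(pk$sites[, paste0("meth_", unique(study$design$tissue)),
                               drop = FALSE])
    res$tau <- tau
    res$classification <- classify_sites(tau)
    res$sharing <- sharing_spectrum(meth)
    expr_fpkm <- gene_input_rpkm_matrix(study, pk$stats)
    res$ubiquitous_genes <- ubiquitous_gene_filter(expr_fpkm)
    tsv(data.frame(site_id = names(tau), tau = tau,
                   class = res$classification), "tau.tsv")
  }

  if ("motifs" %in% stages) {
    say("stage motifs")
    res$submotif <- submotif_stage(study, pk, n_shuffles)
  }

  if ("cleavage" %in% stages) {
    say("stage cleavage")
    cl <- study$cleavage
    cl$pas_class <- classify_pas(cl, study$genome)
    res$cleavage_pas <- cl
    res$cleavage_hist <- distance_distribution(pk$sites, cl)
    labels <- annotate_genic_region(pk$sites, study$genes)
    res$cleavage_submotif <- submotif_at_cleavage(pk$sites, cl, labels)
    res$cleavage_composition <- composition_profile(cl, study$genome)
    tsv(data.frame(offset = as.integer(names(res$cleavage_hist)),
                   count = res$cleavage_hist), "cleavage_hist.tsv")
  }

  if ("evolution" %in% stages) {
    say("stage evolution")
    cons <- study$conservation
    cds <- cons[cons$region == "CDS", ]
    target <- "mouse" %in% config$species_panel
    sp <- if (target) "mouse" else config$species_panel[1]
    # coarsen the matching bins until every m6A stratum has enough controls
    ladder <- list(c(10L, 20L), c(5L, 10L), c(3L, 5L), c(1L, 5L), c(1L, 1L))
    nd <- NULL
    for (nb in ladder) {
      nd <- tryCatch(with_stream(config$seed, "null",
                                 null_distribution(cds, sp,
                                                   n_sets = n_null_sets,
                                                   n_bins_dnds = nb[1],
                                                   n_bins_cds = nb[2])),
                     error = function(e) NULL)
      if (!is.null(nd)) { bins_used <- nb; break }
    }
    if (is.null(nd)) stop("evolution stage failed: control matching ",
                          "infeasible even with maximally coarse bins")
    res$matching_bins <- bins_used
    ctrl_idx <- with_stream(config$seed, "match",
                            match_controls(cds, n_bins_dnds = bins_used[1],
                                           n_bins_cds = bins_used[2]))
    f_ctrl <- conserved_fraction(cds[ctrl_idx, ], sp)
    res$conservation_null <- nd
    res$constraint_percent <- constraint_proportion(nd$observed,
                                                    mean(nd$fractions))
    res$age_profile <- site_age_profile(cons, config$species_panel)
    tsv(data.frame(fraction = nd$fractions), "conservation_null.tsv")
  }

  if ("popgen" %in% stages) {
    say("stage popgen")
    ann <- find_motif_snps(study$snps, study$genome, pk$sites, study$genes)
    daf <- derived_allele_frequency(study$genotypes, ann$ref, ann$alt, ann$aa)
    grp <- function(g) daf[ann$group == g & !is.na(daf)]
    res$daf_test <- daf_spectrum_test(
      grp("m6a_gain"),
      list(utr3_rrach = grp("ctrl_utr3"),
           intergenic_rrach = grp("ctrl_intergenic")))
    res$allele_ratio <- allele_ratio_test(study$pileups)
    fst <- weir_cockerham_fst(study$genotypes, study$pops)
    res$fst <- fst
    res$high_fst <- ann$snp_id[high_fst_filter(fst)]
    res$snp_annotation <- ann
    tsv(data.frame(snp_id = ann$snp_id, group = ann$group, daf = daf,
                   fst = fst), "popgen.tsv")
  }

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  cfg_file <- file.path(outdir, "config.txt")
  writeLines(utils::capture.output(utils::str(unclass(config))), cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("m6adyn")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checksums = tools::md5sum(files))
  res$manifest <- manifest
  writeLines(paste(names(manifest$checksums), manifest$checksums, sep = "\t"),
             file.path(outdir, "manifest.tsv"))
  class(res) <- "m6a_run"
  say("pipeline complete in %.1f s", manifest$elapsed_sec)
  res
}

# Tissue-level gene expression (input RPKM) matrix used by the ubiquitous
# gene filter.
gene_input_rpkm_matrix <- function(study, stats_by_sample) {
  tissues <- unique(study$design$tissue)
  m <- matrix(0, nrow(study$genes), length(tissues),
              dimnames = list(study$genes$gene_id, tissues))
  for (t in tissues) {
    cols <- study$design$sample_id[study$design$tissue == t]
    vals <- sapply(cols, function(s) {
      st <- stats_by_sample[[s]]
      v <- st$input_gene_rpkm[!duplicated(st$gene_id)]
      names(v) <- st$gene_id[!duplicated(st$gene_id)]
      v[rownames(m)]
    })
    vals[is.na(vals)] <- 0
    m[, t] <- rowMeans(vals)
  }
  m
}

# Per-sample sub-motif proportions and co-occurrence tests.
submotif_stage <- function(study, pk, n_shuffles) {
  design <- study$design
  tissues <- unique(design$tissue)
  props <- matrix(NA_real_, length(design$sample_id), 4,
                  dimnames = list(design$sample_id, SUBMOTIFS))
  tests <- list()
  for (s in design$sample_id) {
    t <- design$tissue[design$sample_id == s]
    col <- paste0("meth_", t)
    ssites <- pk$sites[pk$sites[[col]], ]
    if (nrow(ssites) == 0) next
    props[s, ] <- submotif_proportions(ssites$submotif)
    slots <- site_motif_slots(ssites, pk$peaks[pk$peaks$tissue == t, ])
    if (nrow(slots) >= 2)
      tests[[s]] <- with_stream(study$config$seed, paste0("shuffle_", s),
                                cooccurrence_test(slots, n_shuffles))
  }
  tissue_props <- t(sapply(tissues, function(t) {
    colMeans(props[design$sample_id[design$tissue == t], , drop = FALSE],
             na.rm = TRUE)
  }))
  list(sample_proportions = props, tissue_proportions = tissue_props,
       variability = submotif_variability(tissue_props),
       cooccurrence = tests)
}

#' Motif slots of sites within peaks (for the shuffling test)
#'
#' @param sites site table with `gene_id`, `tx_pos`, `submotif`.
#' @param peaks peak table of one tissue.
#' @return Data frame with `peak_id` and `class`, one row per motif
#'   occurrence inside a peak.
#' @export
site_motif_slots <- function(sites, peaks) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    sel <- sites$gene_id == pk$gene_id &
      sites$tx_pos >= pk$start & sites$tx_pos < pk$end
    if (!any(sel)) next
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = pk$peak_id, class = sites$submotif[sel],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(peak_id = character(0), class = character(0)))
  do.call(rbind, rows)
}

#' @export
print.m6a_run <- function(x, ...) {
  cat("m6adyn pipeline run\n")
  cat("  peaks:", nrow(x$peaks), "| sites:", nrow(x$sites), "\n")
  if (!is.null(x$tau))
    cat("  tau classes:", paste(names(table(x$classification)),
                                table(x$classification), collapse = ", "), "\n")
  if (!is.null(x$constraint_percent))
    cat(sprintf("  constraint: %.1f%% (conservation null p = %.3g)\n",
                x$constraint_percent, x$conservation_null$p))
  cat("  elapsed:", round(x$manifest$elapsed_sec, 1), "s\n")
  invisible(x)
}

#' Validate pipeline input files
#'
#' Light-weight format checks before a run: FASTA/GTF/BED/bedGraph/VCF
#' parseability, coordinate bounds and strand values. Problems are returned
#' as a report distinguishing fatal errors from warnings.
#'
#' @param fasta,gtf,bed,bedgraph,vcf optional file paths; NULL entries are
#'   skipped.
#' @return Data frame report (`file`, `level` in {ok, warning, fatal},
#'   `message`).
#' @export
validate_inputs <- function(fasta = NULL, gtf = NULL, bed = NULL,
                            bedgraph = NULL, vcf = NULL) {
  rep <- list()
  add <- function(f, level, msg) rep[[length(rep) + 1L]] <<-
    data.frame(file = f, level = level, message = msg,
               stringsAsFactors = FALSE)
  chroms <- NULL
  if (!is.null(fasta)) {
    if (!file.exists(fasta)) add(fasta, "fatal", "file not found")
    else {
      seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                       error = function(e) NULL)
      if (is.null(seqs)) add(fasta, "fatal", "FASTA parse error")
      else { chroms <- names(seqs); add(fasta, "ok", "parsed") }
    }
  }
  if (!is.null(bed)) {
    df <- tryCatch(utils::read.table(bed, sep = "\t"),
                   error = function(e) NULL)
    if (is.null(df)) add(bed, "fatal", "BED parse error")
    else if (any(df[[3]] < df[[2]]))
      add(bed, "fatal", "interval end < start")
    else add(bed, "ok", "parsed")
  }
  if (!is.null(bedgraph)) {
    df <- tryCatch(utils::read.table(bedgraph, sep = "\t", skip = 1),
                   error = function(e) NULL)
    if (is.null(df)) add(bedgraph, "fatal", "bedGraph parse error")
    else if (!is.null(chroms) && !all(df[[1]] %in% chroms))
      add(bedgraph, "fatal", "bedGraph chromosome absent from FASTA")
    else add(bedgraph, "ok", "parsed")
  }
  if (!is.null(gtf)) {
    ok <- tryCatch({rtracklayer::import(gtf, format = "gtf"); TRUE},
                   error = function(e) FALSE)
    add(gtf, if (ok) "ok" else "fatal",
        if (ok) "parsed" else "GTF parse error")
  }
  if (!is.null(vcf)) {
    v <- tryCatch(read_vcf_file(vcf), error = function(e) NULL)
    if (is.null(v)) add(vcf, "fatal", "VCF parse error")
    else {
      n_noaa <- sum(is.na(v$snps$aa))
      if (n_noaa > 0)
        add(vcf, "warning", sprintf(
          "%d record(s) without INFO/AA (excluded from DAF analyses)",
          n_noaa))
      add(vcf, "ok", "parsed")
    }
  }
  do.call(rbind, rep)
}
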