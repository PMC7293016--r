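# Readers and writers for the standard formats at the package boundary.
# Internal coordinates are 0-based half-open (BED native); GTF and VCF are
# converted on the way in/out.

#' Write study artifacts to standard-format files
#'
#' Emits reference FASTA, gene models (GTF and BED12), per-sample bedGraph
#' coverage (IP and input), cleavage-site BED, conservation TSV, VCF 4.2
#' genotypes, design/pileup/truth TSVs.
#'
#' @param study an [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @param stage_tag producer tag written as a header comment in TSV outputs.
#' @return Invisibly, the vector of written file paths.
#' @export
write_study <- function(study, dir, stage_tag = "m6adyn::write_study") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  p <- function(f) file.path(dir, f)
  ## FASTA
  seqs <- Biostrings::DNAStringSet(study$genome)
  Biostrings::writeXStringSet(seqs, p("reference.fa"))
  paths <- c(paths, p("reference.fa"))
  ## gene models
  write_gene_models_gtf(study$genes, p("genes.gtf"))
  write_gene_models_bed12(study$genes, p("genes.bed"))
  paths <- c(paths, p("genes.gtf"), p("genes.bed"))
  ## coverage
  for (s in study$samples) {
    for (comp in c("ip", "input")) {
      f <- p(sprintf("%s.%s.bedGraph", s$sample_id, comp))
      write_bedgraph_track(study$genes, s[[comp]], f)
      paths <- c(paths, f)
    }
  }
  ## cleavage sites as BED6
  cl <- study$cleavage
  write_bed6(data.frame(chrom = cl$chrom, start = cl$gpos,
                        end = cl$gpos + 1L, name = cl$cleavage_id,
                        score = 0L, strand = cl$strand),
             p("cleavage.bed"))
  paths <- c(paths, p("cleavage.bed"))
  ## tables
  tsv <- function(df, f) {
    con <- file(p(f), "w")
    writeLines(paste0("# producer: ", stage_tag), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <<- c(paths, p(f))
  }
  tsv(study$design, "design.tsv")
  tsv(study$sites, "truth_sites.tsv")
  tsv(study$cleavage, "truth_cleavage.tsv")
  tsv(study$conservation, "conservation.tsv")
  tsv(study$snps, "truth_snps.tsv")
  tsv(study$pileups, "pileups.tsv")
  write_vcf_file(study$snps, study$genotypes, study$pops, p("snps.vcf"))
  paths <- c(paths, p("snps.vcf"))
  utils::write.table(
    data.frame(individual = colnames_or_default(study$genotypes),
               population = as.character(study$pops)),
    p("populations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p("populations.tsv"))
  invisible(paths)
}

colnames_or_default <- function(m) {
  colnames(m) %||% sprintf("ind%03d", seq_len(ncol(m)))
}

write_gene_models_gtf <- function(genes, path) {
  rows <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id, g$gene_id)
    feat <- function(type, s0, e0) {
      sprintf("%s\tm6adyn\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s0 + 1L, e0, g$strand, attr0)
    }
    rows <- c(rows, feat("transcript", g$start, g$end),
              feat("exon", g$start, g$end))
    if (!is.na(g$cds_start)) {
      cs <- tx_to_genome(g, g$cds_start)
      ce <- tx_to_genome(g, g$cds_end - 1L)
      rows <- c(rows, feat("CDS", min(cs, ce), max(cs, ce) + 1L))
    }
  }
  writeLines(rows, path)
}

write_gene_models_bed12 <- function(genes, path) {
  cs <- ifelse(is.na(genes$cds_start), genes$start,
               pmin(mapply(tx_to_genome_v, split(genes, seq_len(nrow(genes))),
                           genes$cds_start),
                    mapply(tx_to_genome_v, split(genes, seq_len(nrow(genes))),
                           genes$cds_end - 1L)))
  ce <- ifelse(is.na(genes$cds_start), genes$start,
               pmax(mapply(tx_to_genome_v, split(genes, seq_len(nrow(genes))),
                           genes$cds_start),
                    mapply(tx_to_genome_v, split(genes, seq_len(nrow(genes))),
                           genes$cds_end - 1L)) + 1L)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                   genes$chrom, genes$start, genes$end,
                   paste0(genes$gene_id, ".t1"), genes$strand,
                   as.integer(cs), as.integer(ce),
                   genes$end - genes$start)
  writeLines(lines, path)
}

tx_to_genome_v <- function(gene, off) tx_to_genome(gene, off)

write_bedgraph_track <- function(genes, cov_by_gene, path) {
  gr <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- cov_by_gene[[g$gene_id]]
    if (is.null(v)) next
    if (g$strand == "-") v <- rev(v)  # genomic order
    r <- rle(v)
    ends <- g$start + cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    gr[[length(gr) + 1L]] <- data.frame(
      chrom = g$chrom, start = starts[keep], end = ends[keep],
      value = r$values[keep])
  }
  df <- do.call(rbind, gr)
  con <- file(path, "w")
  writeLines("track type=bedGraph", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
}

write_bed6 <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write called sites as BED6+ (tissue flags and motif as extra columns)
#' @param sites site table from [infer_sites()].
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  meth <- grep("^meth_", names(sites), value = TRUE)
  df <- data.frame(chrom = sites$chrom, start = sites$gpos,
                   end = sites$gpos + 1L, name = sites$site_id,
                   score = 0L, strand = sites$strand,
                   motif = sites$motif)
  for (m in meth) df[[m]] <- as.integer(sites[[m]])
  write_bed6(df, path)
}

write_vcf_file <- function(snps, genotypes, pops, path) {
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  inds <- colnames_or_default(genotypes)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L], nrow(genotypes))
  info <- ifelse(is.na(snps$aa), ".", paste0("AA=", snps$aa))
  lines <- paste(snps$chrom, snps$pos + 1L, snps$snp_id, snps$ref, snps$alt,
                 ".", "PASS", info, "GT", sep = "\t")
  body <- paste(lines, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  close(con)
}

#' Read gene models from a GTF file
#'
#' Reconstructs the intronless gene table (0-based half-open coordinates,
#' transcript-coordinate CDS bounds) from transcript/CDS features.
#'
#' @param path GTF path.
#' @return A gene data frame compatible with the analysis functions.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  tx <- df[df$type == "transcript", ]
  cds <- df[df$type == "CDS", ]
  genes <- data.frame(
    gene_id = tx$gene_id, chrom = as.character(tx$seqnames),
    start = tx$start - 1L, end = tx$end,
    strand = as.character(tx$strand),
    stringsAsFactors = FALSE)
  genes$tx_len <- genes$end - genes$start
  m <- match(genes$gene_id, cds$gene_id)
  genes$biotype <- ifelse(is.na(m), "ncRNA", "protein_coding")
  genes$cds_start <- NA_integer_; genes$cds_end <- NA_integer_
  ok <- !is.na(m)
  gs <- genes[ok, ]
  c1 <- ifelse(gs$strand == "+", cds$start[m[ok]] - 1L - gs$start,
               gs$end - cds$end[m[ok]])
  c2 <- ifelse(gs$strand == "+", cds$end[m[ok]] - gs$start,
               gs$end - (cds$start[m[ok]] - 1L))
  genes$cds_start[ok] <- as.integer(c1)
  genes$cds_end[ok] <- as.integer(c2)
  genes$utr5_len <- genes$cds_start
  genes$cds_len <- genes$cds_end - genes$cds_start
  genes$utr3_len <- genes$tx_len - genes$cds_end
  genes
}

#' Read a bedGraph coverage track into per-gene transcript coverage
#'
#' @param path bedGraph path.
#' @param genes gene table (as from [read_gene_models()]).
#' @return Named list of per-gene coverage vectors in transcript orientation.
#' @export
read_bedgraph <- function(path, genes) {
  df <- utils::read.table(path, sep = "\t", skip = 1,
                          col.names = c("chrom", "start", "end", "value"))
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- numeric(g$tx_len)
    sel <- df$chrom == g$chrom & df$end > g$start & df$start < g$end
    for (j in which(sel)) {
      a <- max(df$start[j], g$start) - g$start + 1L
      b <- min(df$end[j], g$end) - g$start
      v[a:b] <- df$value[j]
    }
    if (g$strand == "-") v <- rev(v)
    out[[i]] <- v
  }
  out
}

#' Read a VCF into the SNP table + genotype matrix the popgen stage consumes
#'
#' @param path VCF path (plain text, GT format, ancestral allele in INFO/AA).
#' @return List with `snps` (0-based positions, `aa` NA when the tag is
#'   absent) and `genotypes` (alt dosage matrix).
#' @export
read_vcf_file <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  aa <- sub(".*AA=([ACGTacgt]+).*", "\\1", fix$INFO)
  aa[!grepl("AA=", fix$INFO)] <- NA_character_
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  dos[is.na(gt)] <- NA_integer_
  snps <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS) - 1L,
                     ref = fix$REF, alt = fix$ALT, aa = toupper(aa),
                     stringsAsFactors = FALSE)
  list(snps = snps, genotypes = dos)
}
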