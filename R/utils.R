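# Internal helpers: derived RNG streams, coordinate maps, RRACH scanning.
# Internal coordinates are 0-based half-open throughout; 1-based only at
# format boundaries (GTF, VCF, substr indices).

#' Derive a deterministic child seed from a master seed and a key
#'
#' Each simulated artifact (genome, sites, coverage, ...) draws from its own
#' RNG stream keyed by name, so adding one artifact never perturbs the others.
#'
#' @param master integer master seed.
#' @param key character stream name.
#' @return An integer seed below 2^31.
#' @keywords internal
stream_seed <- function(master, key) {
  v <- utf8ToInt(key)
  h <- sum(v * seq_along(v)) %% 1000003L
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate expr under the derived stream, restoring the caller's RNG state.
with_stream <- function(master, key, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(master, key))
  expr
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(x) unname(rev(COMP[x]))

revcomp <- function(s) paste(revcomp_chars(strsplit(s, "")[[1]]), collapse = "")

# Map transcript offsets (0-based) to genomic positions (0-based) for an
# intronless gene row with fields start, end, strand.
tx_to_genome <- function(gene, off) {
  if (gene$strand == "+") gene$start + off else gene$end - 1L - off
}

genome_to_tx <- function(gene, gpos) {
  if (gene$strand == "+") gpos - gene$start else gene$end - 1L - gpos
}

# Extract the transcript-orientation sequence of a gene from a genome
# (named character vector of chromosome strings).
gene_tx_seq <- function(genome, gene) {
  s <- substr(genome[[gene$chrom]], gene$start + 1L, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}

# Write `chars` into the genome at transcript positions tx_pos..(tx_pos+len-1)
# of `gene`, complementing for minus-strand genes. Returns the genome.
set_tx_seq <- function(genome, gene, tx_pos, chars) {
  n <- length(chars)
  if (gene$strand == "+") {
    i1 <- gene$start + tx_pos + 1L
    substr(genome[[gene$chrom]], i1, i1 + n - 1L) <- paste(chars, collapse = "")
  } else {
    i1 <- gene$end - tx_pos - n + 1L
    substr(genome[[gene$chrom]], i1, i1 + n - 1L) <-
      paste(revcomp_chars(chars), collapse = "")
  }
  genome
}

RRACH_RE <- "[AG][AG]AC[ACT]"

#' Test whether 5-mers match the RRACH consensus
#'
#' R is A or G and H is A, C or T (U in RNA); the methylated base is the
#' central A.
#'
#' @param x character vector of 5-mers (DNA alphabet).
#' @return Logical vector.
#' @export
is_rrach <- function(x) {
  grepl(paste0("^", RRACH_RE, "$"), x)
}

# 0-based positions of the central A of every (possibly overlapping) RRACH
# occurrence in a sequence string.
scan_rrach <- function(s) {
  m <- gregexpr(paste0("(?=", RRACH_RE, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) + 1L  # match start (1-based) -> central A 0-based = start-1+2
}

# Extract the 5-mer around a transcript position (central A at tx_pos).
tx_fivemer <- function(txseq, tx_pos) {
  substr(txseq, tx_pos - 1L, tx_pos + 3L)  # 1-based substr of 0-based pos-2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
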