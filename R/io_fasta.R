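#' Load a reference genome from FASTA
#'
#' Reads the FASTA with Biostrings and caches each chromosome as a plain
#' character string for fast vectorized substring access during
#' trinucleotide-context extraction. Chromosome names are normalized (any
#' "chr" prefix stripped) to match variant records.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return a `genome_ref` object: list of per-chromosome sequence strings.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_mo("FASTA not found: %s", path)
  dss <- Biostrings::readDNAStringSet(path)
  nm <- normalize_chrom(sub("\\s.*$", "", names(dss)))
  seqs <- stats::setNames(as.character(dss), nm)
  structure(list(seq = seqs,
                 lengths = stats::setNames(nchar(seqs), nm)),
            class = "genome_ref")
}

#' Write a genome to FASTA
#' @param genome a `genome_ref` or named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  seqs <- if (inherits(genome, "genome_ref")) genome$seq else genome
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %d chromosome(s), %.2f Mb total\n",
              length(x$seq), sum(x$lengths) / 1e6))
  invisible(x)
}

## Vectorized base / context access (1-based, inclusive).
genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    s <- genome$seq[[chr]]
    if (is.null(s)) { out[idx] <- NA_character_; next }
    out[idx] <- substring(s, pos[idx], pos[idx])
  }
  out
}

genome_context <- function(genome, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    s <- genome$seq[[chr]]
    if (is.null(s)) next
    ok <- pos[idx] >= 2L & pos[idx] <= nchar(s) - 1L
    out[idx[ok]] <- substring(s, pos[idx][ok] - 1L, pos[idx][ok] + 1L)
  }
  out
}
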