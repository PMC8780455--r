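#' Read somatic SNVs from a VCF file
#'
#' Reads a VCF v4.x file (plain or bgzipped) and keeps only records that can
#' be represented as biallelic SNVs. Multi-allelic lines are split and each
#' single-base alternate allele kept as its own record; indels, MNVs and
#' symbolic alleles are dropped (the number dropped is reported as a message).
#' Duplicate (chrom, pos, ref, alt) records are collapsed. The FILTER column
#' is ignored: consensus somatic calls are assumed to be pre-filtered.
#'
#' @param path path to the VCF file.
#' @param sample_id,donor_id,label identity attached to the resulting object.
#' @return a [sample_variants()] object.
#' @export
read_vcf <- function(path, sample_id = basename(path), donor_id = sample_id,
                     label = NA_character_) {
  if (!file.exists(path)) stop_mo("VCF not found: %s", path)
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop_mo("unparseable VCF %s: %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix))) # single-record VCFs drop to vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) {
    warn_mo("VCF %s contains no records", path)
    return(sample_variants(sample_id, donor_id, label))
  }
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(as.character(fix[, "REF"]))
  alt <- toupper(as.character(fix[, "ALT"]))
  chr_prefix <- any(grepl("^chr", chrom))

  # split multi-allelic ALT fields into one candidate record per allele
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  cand <- data.frame(chrom = rep(chrom, n_alt), pos = rep(pos, n_alt),
                     ref = rep(ref, n_alt), alt = unlist(alt_list),
                     stringsAsFactors = FALSE)
  keep <- cand$ref %in% DNA_BASES & cand$alt %in% DNA_BASES & cand$alt != cand$ref
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message(sprintf("read_vcf: dropped %d non-SNV allele(s) in %s", n_dropped, path))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) warn_mo("VCF %s contains no SNVs", path)
  sample_variants(sample_id, donor_id, label, cand, chr_prefix = chr_prefix)
}

#' Write a sample's SNVs as a minimal VCF 4.2 file
#'
#' Emits a header with `##contig` lines and one body line per SNV. Chromosome
#' names are written with the "chr" prefix if the sample was read with one.
#' `read_vcf(write_vcf(s))` recovers the identical variant set.
#'
#' @param sample a [sample_variants()] object.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths; defaults to
#'   the chromosomes present in the sample with length `max(pos)`. Writing a
#'   variant on a chromosome absent from an explicitly supplied `contigs` is
#'   an error.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sample, path, contigs = NULL) {
  stopifnot(inherits(sample, "sample_variants"))
  v <- sample$variants
  if (is.null(contigs)) {
    contigs <- if (nrow(v)) vapply(split(v$pos, v$chrom), max, integer(1)) else integer()
  } else {
    names(contigs) <- normalize_chrom(names(contigs))
    missing_chr <- setdiff(unique(v$chrom), names(contigs))
    if (length(missing_chr))
      stop_mo("variants on chromosome(s) %s absent from declared contigs",
              paste(missing_chr, collapse = ", "))
  }
  pfx <- if (sample$chr_prefix) "chr" else ""
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=mutorigin"),
           sprintf("##contig=<ID=%s%s,length=%d>", pfx, names(contigs),
                   as.integer(contigs)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
                 collapse = "\t"))
  body <- if (nrow(v))
    sprintf("%s%s\t%d\t.\t%s\t%s\t.\t.\t.", pfx, v$chrom, v$pos, v$ref, v$alt)
  else character()
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_mo("cannot open %s for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
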