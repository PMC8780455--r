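#' Construct a per-sample set of somatic SNVs
#'
#' The central unit of the pipeline: one tumor sample's somatic single
#' nucleotide variants together with its donor identity and cancer-type label.
#' Donor identity is carried through downsampling and augmentation so that
#' cross-validation can keep all derivatives of one donor in one partition.
#'
#' @param sample_id sample identifier.
#' @param donor_id donor identifier; derivatives of a sample inherit it.
#' @param label cancer-type (cell-of-origin) label.
#' @param variants data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; only single-base A/C/G/T ref and alt with `alt != ref` are valid.
#' @param chr_prefix logical; whether chromosome names carried a "chr" prefix
#'   on input (restored on write).
#' @return an object of class `sample_variants`.
#' @export
sample_variants <- function(sample_id, donor_id = sample_id, label = NA_character_,
                            variants = empty_variant_frame(), chr_prefix = FALSE) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants)) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(variants)))
      stop_mo("variant frame must have columns %s", paste(need, collapse = ", "))
    variants <- variants[need]
    variants$chrom <- normalize_chrom(as.character(variants$chrom))
    variants$pos <- as.integer(variants$pos)
    variants$ref <- toupper(as.character(variants$ref))
    variants$alt <- toupper(as.character(variants$alt))
    bad <- !(variants$ref %in% DNA_BASES) | !(variants$alt %in% DNA_BASES) |
      variants$ref == variants$alt | is.na(variants$pos) | variants$pos < 1L
    if (any(bad))
      stop_mo("%d variant rows are not valid SNVs (single-base A/C/G/T, alt != ref, pos >= 1)",
              sum(bad))
    variants <- variants[!duplicated(variant_key(variants)), , drop = FALSE]
    variants <- variants[radix_order(variants$chrom, variants$pos,
                                     variants$ref, variants$alt), , drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(list(sample_id = sample_id, donor_id = donor_id, label = label,
                 variants = variants, chr_prefix = isTRUE(chr_prefix)),
            class = "sample_variants")
}

empty_variant_frame <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

## "chr1" and "1" refer to the same sequence internally; the prefix is an
## output cosmetic remembered per sample/reference.
normalize_chrom <- function(x) sub("^chr", "", x)

#' @export
print.sample_variants <- function(x, ...) {
  cat(sprintf("<sample_variants> %s (donor %s, label %s): %d SNVs\n",
              x$sample_id, x$donor_id, x$label, nrow(x$variants)))
  invisible(x)
}

#' Number of variants in a sample
#' @param sample a `sample_variants` object.
#' @return integer count.
#' @export
n_variants <- function(sample) nrow(sample$variants)
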