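## -------------------------------------------------------------------------
## Trinucleotide substitution classes (COSMIC-style, pyrimidine strand)
## -------------------------------------------------------------------------

#' The 96 trinucleotide substitution classes
#'
#' All single-base substitutions reported on the pyrimidine strand (ref C or
#' T; 6 substitution types) in their immediate 5'/3' context (4 x 4 flanks),
#' giving 96 classes. Names use the motif form, e.g. `"ACA>AGA"`. Ordering is
#' by substitution type (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then
#' 3' flank, alphabetically.
#'
#' @return character vector of 96 class names.
#' @export
trinucleotide_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1); alt <- substr(s, 3, 3)
    for (f5 in DNA_BASES) for (f3 in DNA_BASES)
      out <- c(out, sprintf("%s%s%s>%s%s%s", f5, ref, f3, f5, alt, f3))
  }
  out
}

## Complement lookup, vectorized over single bases.
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonicalize a stranded substitution to the pyrimidine strand
#'
#' A substitution observed with a purine reference base (A or G) is
#' reverse-complemented — context reversed and complemented, alternate allele
#' complemented — so that every substitution is reported with a C or T
#' reference, the convention under which exactly 96 classes exist.
#'
#' @param context character vector of trinucleotide contexts (ref base in the
#'   middle).
#' @param alt character vector of alternate alleles.
#' @return character vector of class names in `"ACA>AGA"` form.
#' @export
canonical_trinucleotide <- function(context, alt) {
  stopifnot(length(context) == length(alt))
  ref <- substr(context, 2, 2)
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    rc <- function(s) # reverse complement of trinucleotide strings
      paste0(COMP[substr(s, 3, 3)], COMP[substr(s, 2, 2)], COMP[substr(s, 1, 1)])
    context[flip] <- rc(context[flip])
    alt[flip] <- COMP[alt[flip]]
  }
  paste0(context, ">", substr(context, 1, 1), alt, substr(context, 3, 3))
}

#' Count trinucleotide substitution classes in a sample
#'
#' Maps every SNV to its pyrimidine-strand trinucleotide class using the
#' reference genome and returns counts over the 96 classes. Variants whose
#' reference base disagrees with the genome, or that lack a full flank
#' (position 1 or chromosome end, or unknown chromosome), are skipped and
#' reported via a message.
#'
#' @param sample a [sample_variants()] object.
#' @param genome a [read_genome()] object covering the sample's chromosomes.
#' @return named integer vector of length 96 (names from
#'   [trinucleotide_classes()]), with attribute `n_skipped`.
#' @export
trinucleotide_counts <- function(sample, genome) {
  classes <- trinucleotide_classes()
  v <- sample$variants
  counts <- stats::setNames(integer(96), classes)
  if (nrow(v) == 0L) { attr(counts, "n_skipped") <- 0L; return(counts) }
  ctx <- genome_context(genome, v$chrom, v$pos)
  ok <- !is.na(ctx) & !grepl("[^ACGT]", ctx)
  mismatch <- ok & substr(ctx, 2, 2) != v$ref
  ok <- ok & !mismatch
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    message(sprintf("trinucleotide_counts: skipped %d variant(s) in %s (%d ref-mismatch, %d missing context)",
                    n_skipped, sample$sample_id, sum(mismatch), sum(!ok) - sum(mismatch)))
  if (any(ok)) {
    cls <- canonical_trinucleotide(ctx[ok], v$alt[ok])
    tab <- table(factor(cls, levels = classes))
    counts[] <- as.integer(tab)
  }
  attr(counts, "n_skipped") <- n_skipped
  counts
}

## -------------------------------------------------------------------------
## Interval-based features: 1 Mb density bins and driver genes
## -------------------------------------------------------------------------

#' Genome-wide SNV density over 1 Mb bins
#'
#' Counts a sample's SNVs per bin (1-based inclusive boundaries), by binary
#' search on the sorted per-chromosome bin starts. Variants on chromosomes
#' absent from the manifest, or outside every bin, go to an `n_unbinned`
#' attribute rather than erroring.
#'
#' @param sample a [sample_variants()] object.
#' @param bins a [bin_index()].
#' @return integer vector of length `nrow(bins)`, named by bin, with
#'   attribute `n_unbinned`.
#' @export
bin_counts <- function(sample, bins) {
  stopifnot(inherits(bins, "bin_index"))
  v <- sample$variants
  counts <- stats::setNames(integer(nrow(bins)), bins$name)
  n_binned <- 0L
  if (nrow(v)) {
    for (chr in intersect(unique(v$chrom), unique(bins$chrom))) {
      brows <- which(bins$chrom == chr) # sorted by start by construction
      pos <- v$pos[v$chrom == chr]
      hit <- findInterval(pos, bins$start[brows])
      ok <- hit >= 1L & pos <= bins$end[brows][pmax(hit, 1L)]
      if (any(ok)) {
        tab <- tabulate(hit[ok], nbins = length(brows))
        counts[brows] <- counts[brows] + tab
        n_binned <- n_binned + sum(ok)
      }
    }
  }
  attr(counts, "n_unbinned") <- nrow(v) - n_binned
  counts
}

#' SNV density over driver-gene regions
#'
#' Counts a sample's SNVs per gene span (first-exon start to last-exon end,
#' 1-based inclusive), by binary search on the sorted per-chromosome variant
#' positions. A variant inside two overlapping gene spans increments both
#' genes, so the vector sum can exceed the variant count.
#'
#' @param sample a [sample_variants()] object.
#' @param genes a [gene_regions()] table.
#' @return integer vector of length `nrow(genes)`, named by gene.
#' @export
driver_counts <- function(sample, genes) {
  stopifnot(inherits(genes, "gene_regions"))
  v <- sample$variants
  counts <- stats::setNames(integer(nrow(genes)), genes$gene)
  if (nrow(v) == 0L || nrow(genes) == 0L) return(counts)
  for (chr in intersect(unique(genes$chrom), unique(v$chrom))) {
    pos <- sort(v$pos[v$chrom == chr])
    grows <- which(genes$chrom == chr)
    counts[grows] <- findInterval(genes$end[grows], pos) -
      findInterval(genes$start[grows] - 1L, pos)
  }
  counts
}

## -------------------------------------------------------------------------
## Cohort-level feature matrices
## -------------------------------------------------------------------------

#' Build the three per-sample feature matrices for a cohort
#'
#' Featurizes every sample with [bin_counts()], [trinucleotide_counts()] and
#' [driver_counts()]. Row order follows the input cohort; column (feature)
#' names are identical across samples by construction.
#'
#' @param cohort list of [sample_variants()] objects.
#' @param bins a [bin_index()].
#' @param genes a [gene_regions()] table.
#' @param genome a [read_genome()] object.
#' @return object of class `feature_matrix`: list with integer matrices
#'   `bins`, `tri`, `drivers` (samples x features), plus `sample_ids`,
#'   `donor_ids` and `labels` vectors aligned to the rows.
#' @export
build_feature_matrix <- function(cohort, bins, genes, genome) {
  n <- length(cohort)
  bm <- matrix(0L, n, nrow(bins), dimnames = list(NULL, bins$name))
  tm <- matrix(0L, n, 96L, dimnames = list(NULL, trinucleotide_classes()))
  dm <- matrix(0L, n, nrow(genes), dimnames = list(NULL, genes$gene))
  ids <- character(n); donors <- character(n); labels <- character(n)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    bm[i, ] <- bin_counts(s, bins)
    tm[i, ] <- trinucleotide_counts(s, genome)
    dm[i, ] <- driver_counts(s, genes)
    ids[i] <- s$sample_id; donors[i] <- s$donor_id; labels[i] <- s$label
  }
  structure(list(bins = bm, tri = tm, drivers = dm, sample_ids = ids,
                 donor_ids = donors, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples: %d bins + 96 trinucleotides + %d drivers\n",
              length(x$sample_ids), ncol(x$bins), ncol(x$drivers)))
  invisible(x)
}

#' Transform count features for model ingestion
#'
#' Raw counts span several orders of magnitude across mutation burdens;
#' `log1p` (the default) stabilizes training. `"total"` divides each row by
#' its sum (safe for all-zero rows); `"none"` passes raw counts through.
#'
#' @param fm a `feature_matrix`.
#' @param transform one of `"log1p"`, `"total"`, `"none"`.
#' @param feature_sets which blocks to return, in order.
#' @return named list of numeric matrices (one per feature set).
#' @export
prepare_features <- function(fm, transform = c("log1p", "total", "none"),
                             feature_sets = c("bins", "tri", "drivers")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fm, "feature_matrix"),
            all(feature_sets %in% c("bins", "tri", "drivers")))
  out <- lapply(fm[feature_sets], function(m) {
    m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
    switch(transform,
           log1p = log1p(m),
           total = m / pmax(rowSums(m), 1),
           none = m)
  })
  names(out) <- feature_sets
  out
}
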