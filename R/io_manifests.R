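#' Read a genome bin manifest
#'
#' Tab-separated file with columns `chrom`, `start`, `end` (1-based inclusive
#' in this project's dialect) and an optional `name`. Bins must be
#' non-overlapping within a chromosome; rows are sorted by (chromosome order
#' of first appearance, start).
#'
#' @param path path to the TSV file.
#' @param max_width maximum allowed bin width in bp (default 1e6).
#' @return a `bin_index` data frame with columns chrom/start/end/name.
#' @export
read_bin_manifest <- function(path, max_width = 1e6) {
  tab <- read_interval_tsv(path, what = "bin manifest")
  if (nrow(tab) == 0L) return(bin_index(tab))
  if (any(tab$end - tab$start + 1 > max_width))
    stop_mo("bin manifest %s contains bins wider than %g bp", path, max_width)
  bin_index(tab)
}

#' Construct/validate a bin index
#'
#' @param tab data frame with chrom/start/end and optional name.
#' @return validated `bin_index`.
#' @export
bin_index <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    tab <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE)
    return(structure(tab, class = c("bin_index", "data.frame")))
  }
  tab$chrom <- normalize_chrom(as.character(tab$chrom))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start < 1L | tab$start > tab$end)
  if (length(bad))
    stop_mo("invalid bin coordinates at row %d (start > end or start < 1)", bad[1])
  chrom_levels <- unique(tab$chrom)
  tab <- tab[order(match(tab$chrom, chrom_levels), tab$start), , drop = FALSE]
  by_chr <- split(seq_len(nrow(tab)), tab$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L) {
      s <- tab$start[idx]; e <- tab$end[idx]
      ov <- which(s[-1] <= e[-length(e)])
      if (length(ov))
        stop_mo("overlapping bins on chromosome %s near start %d",
                tab$chrom[idx[1]], s[ov[1] + 1L])
    }
  }
  if (is.null(tab$name))
    tab$name <- sprintf("%s:%d-%d", tab$chrom, tab$start, tab$end)
  rownames(tab) <- NULL
  structure(tab, class = c("bin_index", "data.frame"))
}

#' Read a driver-gene region table
#'
#' Tab-separated with columns `gene`, `chrom`, `start`, `end` (1-based
#' inclusive): each row spans a gene from the start of its first exon to the
#' end of its last exon. Gene symbols must be unique; regions may overlap.
#'
#' @param path path to the TSV file.
#' @return a `gene_regions` data frame.
#' @export
read_gene_regions <- function(path) {
  tab <- read_interval_tsv(path, what = "gene region table", gene_col = TRUE)
  gene_regions(tab)
}

#' Construct/validate a gene region table
#' @param tab data frame with gene/chrom/start/end.
#' @return validated `gene_regions`.
#' @export
gene_regions <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    tab <- data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(), stringsAsFactors = FALSE)
    return(structure(tab, class = c("gene_regions", "data.frame")))
  }
  tab$gene <- as.character(tab$gene)
  tab$chrom <- normalize_chrom(as.character(tab$chrom))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start < 1L | tab$start > tab$end)
  if (length(bad))
    stop_mo("invalid gene coordinates at row %d (start > end or start < 1)", bad[1])
  if (anyDuplicated(tab$gene))
    stop_mo("duplicate gene symbol: %s", tab$gene[duplicated(tab$gene)][1])
  rownames(tab) <- NULL
  structure(tab, class = c("gene_regions", "data.frame"))
}

#' Read a sample-to-label table
#'
#' Tab-separated with columns `sample_id`, `donor_id`, `label`; one row per
#' sample. Stratified splitting needs at least two samples per label, which
#' is warned about (not enforced) here.
#'
#' @param path path to the TSV file.
#' @return a `label_table` data frame.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0L) {
    warn_mo("label table %s is empty", path)
    tab <- data.frame(sample_id = character(), donor_id = character(),
                      label = character(), stringsAsFactors = FALSE)
    return(structure(tab, class = c("label_table", "data.frame")))
  }
  label_table(tab)
}

#' Construct/validate a label table
#' @param tab data frame with sample_id/donor_id/label.
#' @return validated `label_table`.
#' @export
label_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  need <- c("sample_id", "donor_id", "label")
  if (!all(need %in% names(tab)))
    stop_mo("label table needs columns %s", paste(need, collapse = ", "))
  tab <- tab[need]
  if (anyDuplicated(tab$sample_id))
    stop_mo("duplicate sample_id: %s", tab$sample_id[duplicated(tab$sample_id)][1])
  cnt <- table(tab$label)
  if (any(cnt < 2))
    warn_mo("label(s) with fewer than 2 samples: %s",
            paste(names(cnt)[cnt < 2], collapse = ", "))
  rownames(tab) <- NULL
  structure(tab, class = c("label_table", "data.frame"))
}

read_interval_tsv <- function(path, what, gene_col = FALSE) {
  if (!file.exists(path)) stop_mo("%s not found: %s", what, path)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) stop_mo("cannot parse %s %s: %s", what, path,
                                conditionMessage(e)))
  if (nrow(tab) == 0L) {
    warn_mo("%s %s is empty", what, path)
    return(tab)
  }
  need <- c(if (gene_col) "gene", "chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop_mo("%s %s needs columns %s", what, path, paste(need, collapse = ", "))
  tab
}

#' Write a bin or gene manifest as TSV
#' @param tab a `bin_index` or `gene_regions` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The GRCh37 1 Mb bin manifest
#'
#' Tiles the 22 GRCh37 autosomes with 1 Mb bins (the final bin of each
#' chromosome is partial), yielding the 2897-bin feature space used for
#' genome-wide SNV density. Chromosome lengths are shipped with the package.
#'
#' @return a `bin_index` with 2897 rows.
#' @export
grch37_bin_manifest <- function() {
  path <- system.file("extdata", "grch37_autosome_lengths.tsv",
                      package = "mutorigin", mustWork = TRUE)
  len <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tile_bins(stats::setNames(len$length, len$chrom), bin_size = 1e6)
}

#' Tile chromosomes into fixed-size bins
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 1e6); the last bin of each
#'   chromosome may be shorter.
#' @return a `bin_index`.
#' @export
tile_bins <- function(chrom_lengths, bin_size = 1e6) {
  pieces <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(1, len, by = bin_size)
    data.frame(chrom = chr, start = as.integer(starts),
               end = as.integer(pmin(starts + bin_size - 1, len)),
               stringsAsFactors = FALSE)
  })
  bin_index(do.call(rbind, pieces))
}
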