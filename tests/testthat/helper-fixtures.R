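## Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(.fixture_cache$tiny))
    .fixture_cache$tiny <- suppressMessages(
      make_fixture("tiny", dir = file.path(tempdir(), "mutorigin-tiny"),
                   seed = 101L))
  .fixture_cache$tiny
}

standard_fixture <- function(seed = 202L) {
  key <- paste0("std", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- suppressMessages(
      make_fixture("standard",
                   dir = file.path(tempdir(), paste0("mutorigin-std-", seed)),
                   seed = seed))
  .fixture_cache[[key]]
}

## Random valid SNV frame on a toy genome, for property tests.
random_variant_frame <- function(n, n_chrom = 3, chrom_len = 1e5) {
  chrom <- sample(paste0("C", seq_len(n_chrom)), n, replace = TRUE)
  pos <- sample.int(chrom_len, n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

## Independent brute-force canonicalizer for stranded trinucleotide
## substitutions: hand-coded complement table and explicit string reversal,
## sharing no code with the package implementation.
oracle_canonical <- function(context, alt) {
  comp <- function(b) c(A = "T", T = "A", C = "G", G = "C")[[b]]
  mapply(function(ctx, a) {
    chars <- strsplit(ctx, "")[[1]]
    if (chars[2] %in% c("A", "G")) {
      chars <- rev(vapply(chars, comp, character(1)))
      a <- comp(a)
    }
    paste0(paste(chars, collapse = ""), ">", chars[1], a, chars[3])
  }, context, alt, USE.NAMES = FALSE)
}
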