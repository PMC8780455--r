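#' Retention fractions and augmentation levels of the study design
#'
#' The canonical grid of retention fractions used to emulate liquid-biopsy
#' sparsity, and the grid of augmentation levels (subsamples generated per
#' training sample).
#' @name study_grids
NULL

#' @rdname study_grids
#' @export
retention_grid <- function() c(0.02, 0.05, 0.10, 0.25, 0.70, 1.00)

#' @rdname study_grids
#' @export
augmentation_grid <- function() c(10L, 20L, 30L, 40L, 50L)

#' Best augmentation level per retention fraction
#'
#' The augmentation level that maximized average accuracy at each retention
#' fraction in the original study design; used as the default pairing when
#' running integration experiments.
#' @return named integer vector keyed by retention fraction.
#' @export
best_augmentation <- function() {
  c("0.7" = 20L, "0.25" = 20L, "0.1" = 30L, "0.05" = 50L, "0.02" = 50L)
}

#' Randomly downsample a sample's SNVs
#'
#' Simulates the sparse mutation profile of circulating tumor DNA by keeping
#' a uniformly random subset of exactly `k = max(1, round(p * n))` SNVs,
#' sampled without replacement. Deterministic given `seed`. With
#' `mode = "bernoulli"` each variant is instead kept independently with
#' probability `p` (the retained count is then random).
#'
#' @param sample a [sample_variants()] object with at least one variant.
#' @param p retention fraction in (0, 1].
#' @param seed integer seed.
#' @param mode `"fixed"` (default; exact count) or `"bernoulli"`.
#' @param sample_id id for the derived sample (defaults to parent id).
#' @return a `sample_variants` whose variants are a subset of the parent's;
#'   donor id and label are inherited.
#' @export
downsample <- function(sample, p, seed, mode = c("fixed", "bernoulli"),
                       sample_id = sample$sample_id) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "sample_variants"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop_mo("retention fraction p must lie in (0, 1], got %s", format(p))
  n <- n_variants(sample)
  if (n < 1L) stop_mo("cannot downsample sample %s with no variants", sample$sample_id)
  keep <- with_seed(seed, {
    if (mode == "fixed") {
      k <- max(1L, as.integer(round(p * n)))
      sort(sample.int(n, k))
    } else {
      which(stats::runif(n) < p)
    }
  })
  out <- sample
  out$sample_id <- sample_id
  out$variants <- sample$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out
}

#' Augment a training set by repeated downsampling
#'
#' Generates `N` random subsamples at retention `p` from every training
#' sample, enlarging the training set `N`-fold. Each replicate's seed is
#' derived deterministically from `(seed, parent sample_id, replicate)`, so
#' adding or reordering parents never reshuffles existing replicates.
#' Augmentation is applied to training samples only; validation/test samples
#' should receive exactly one subsample each (see [run_experiment()]).
#'
#' @param train list of parent (full-profile) `sample_variants`.
#' @param N augmentation level: subsamples per parent (positive integer).
#' @param p retention fraction in (0, 1].
#' @param seed master integer seed.
#' @return list with one element per subsample; each element has fields
#'   `sample` (the subsample) and `provenance` (parent_sample_id, donor_id,
#'   replicate, p, seed).
#' @export
augment_training_set <- function(train, N, p, seed) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    stop_mo("augmentation level N must be a positive integer, got %s", format(N))
  N <- as.integer(N)
  out <- vector("list", length(train) * N)
  j <- 0L
  for (parent in train) {
    for (r in seq_len(N)) {
      child_seed <- derive_seed(seed, parent$sample_id, r)
      sub <- downsample(parent, p, child_seed,
                        sample_id = sprintf("%s.rep%02d", parent$sample_id, r))
      j <- j + 1L
      out[[j]] <- list(
        sample = sub,
        provenance = list(parent_sample_id = parent$sample_id,
                          donor_id = parent$donor_id, replicate = r,
                          p = p, seed = child_seed))
    }
  }
  out
}

#' Provenance table of an augmented set
#' @param augmented result of [augment_training_set()].
#' @return data frame with one row per subsample.
#' @export
augmentation_provenance <- function(augmented) {
  do.call(rbind, lapply(augmented, function(el) {
    data.frame(sample_id = el$sample$sample_id,
               parent_sample_id = el$provenance$parent_sample_id,
               donor_id = el$provenance$donor_id,
               replicate = el$provenance$replicate,
               p = el$provenance$p, seed = el$provenance$seed,
               stringsAsFactors = FALSE)
  }))
}
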