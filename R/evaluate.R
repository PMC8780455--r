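## -------------------------------------------------------------------------
## Donor-safe stratified shuffle-split cross-validation and metrics.
## -------------------------------------------------------------------------

## Largest-remainder allocation of n items to the given fractions.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified, donor-safe shuffle-split cross-validation partitions
#'
#' Draws `n_splits` independent random partitions of the parent samples into
#' train / validation / test sets. Within each split, every class is
#' allocated to the three fractions by largest-remainder rounding
#' (stratification), and all samples of one donor always land in the same
#' partition so that no donor can leak between train and test. Classes with
#' fewer than 3 samples are placed wholly in train with a warning.
#'
#' @param labels a [label_table()] of parent samples.
#' @param n_splits number of independent splits (default 3).
#' @param fractions length-3 numeric summing to 1: train, validation, test
#'   proportions (default 0.6 / 0.2 / 0.2).
#' @param seed integer seed; each split uses a derived sub-seed.
#' @return list of `cohort_split` objects, each with character vectors
#'   `train`, `val`, `test` of sample ids and a `split_index`.
#' @export
stratified_group_shuffle_split <- function(labels, n_splits = 3L,
                                           fractions = c(0.6, 0.2, 0.2),
                                           seed = 1L) {
  stopifnot(inherits(labels, "label_table") || is.data.frame(labels),
            length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  lapply(seq_len(n_splits), function(s) {
    split_seed <- derive_seed(seed, "split", s)
    parts <- with_seed(split_seed, {
      out <- list(train = character(), val = character(), test = character())
      for (cls in sort(unique(labels$label))) {
        rows <- labels[labels$label == cls, , drop = FALSE]
        if (nrow(rows) < 3) {
          warn_mo("class '%s' has %d sample(s): allocated wholly to train",
                  cls, nrow(rows))
          out$train <- c(out$train, rows$sample_id)
          next
        }
        targets <- largest_remainder(nrow(rows), fractions)
        donors <- unique(rows$donor_id)
        donors <- donors[sample.int(length(donors))]
        remaining <- targets
        for (d in donors) {
          ids <- rows$sample_id[rows$donor_id == d]
          # donor goes to the partition with the largest unfilled deficit;
          # ties favor train, then validation
          part <- which.max(remaining - c(0, 1e-9, 2e-9))
          out[[part]] <- c(out[[part]], ids)
          remaining[part] <- remaining[part] - length(ids)
        }
      }
      out
    })
    structure(list(train = parts$train, val = parts$val, test = parts$test,
                   split_index = s, seed = split_seed),
              class = "cohort_split")
  })
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> #%d: %d train / %d val / %d test\n",
              x$split_index, length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Assert that no donor appears in two partitions
#'
#' @param split a `cohort_split`.
#' @param labels the [label_table()] the split was drawn from.
#' @return `TRUE` invisibly; error if any donor spans partitions.
#' @export
assert_no_donor_leakage <- function(split, labels) {
  donor_of <- stats::setNames(labels$donor_id, labels$sample_id)
  d <- lapply(split[c("train", "val", "test")], function(ids)
    unique(donor_of[ids]))
  overlap <- c(intersect(d$train, d$val), intersect(d$train, d$test),
               intersect(d$val, d$test))
  if (length(overlap))
    stop_mo("donor leakage across partitions: %s",
            paste(unique(overlap), collapse = ", "))
  invisible(TRUE)
}

#' Classification metrics from predicted probabilities
#'
#' Computes the confusion matrix, per-class F1 (`2PR/(P+R)`, 0 where
#' `P + R = 0`), their unweighted (macro) mean, average accuracy (fraction of
#' correctly classified samples), and top-k accuracy — the fraction of
#' samples whose true class is among the k highest-probability predictions
#' (probability ties broken by ascending class index).
#'
#' @param y_true true class labels.
#' @param prob matrix of predicted class probabilities with one column per
#'   class; column names, if present, must match `class_names` order.
#' @param class_names class names aligned with the columns of `prob`.
#' @param k_list values of k for top-k accuracy.
#' @return object of class `metrics_report`: list with `accuracy`,
#'   `per_class_f1`, `macro_f1`, `top_k` (named vector), `confusion`
#'   (true x predicted matrix), `n`.
#' @export
score_predictions <- function(y_true, prob, class_names = colnames(prob),
                              k_list = c(1L, 2L, 3L)) {
  y_true <- as.character(y_true)
  stopifnot(is.matrix(prob), nrow(prob) == length(y_true),
            ncol(prob) == length(class_names))
  if (!all(y_true %in% class_names))
    stop_mo("true label(s) absent from class_names: %s",
            paste(setdiff(unique(y_true), class_names), collapse = ", "))
  n <- length(y_true)
  true_idx <- match(y_true, class_names)
  pred_idx <- max.col(prob, ties.method = "first")
  confusion <- table(factor(y_true, levels = class_names),
                     factor(class_names[pred_idx], levels = class_names))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  tp <- diag(confusion)
  prec_den <- colSums(confusion)
  rec_den <- rowSums(confusion)
  f1 <- ifelse(2 * tp + (prec_den - tp) + (rec_den - tp) == 0, 0,
               2 * tp / (prec_den + rec_den))
  names(f1) <- class_names
  rank_of_true <- vapply(seq_len(n), function(i) {
    ord <- order(-prob[i, ], seq_len(ncol(prob)))
    which(ord == true_idx[i])
  }, integer(1))
  top_k <- vapply(k_list, function(k) mean(rank_of_true <= k), numeric(1))
  names(top_k) <- paste0("top", k_list)
  structure(list(accuracy = mean(pred_idx == true_idx),
                 per_class_f1 = f1, macro_f1 = mean(f1),
                 top_k = top_k, confusion = confusion, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy %.3f  macro-F1 %.3f  [%s]\n",
              x$n, x$accuracy, x$macro_f1,
              paste(sprintf("%s %.3f", names(x$top_k), x$top_k), collapse = ", ")))
  invisible(x)
}

#' Paired t-test between two per-fold metric vectors
#'
#' Classical paired two-sided t-test on the fold-wise differences, used to
#' compare two experimental configurations evaluated on the same
#' cross-validation folds. Significance is flagged at p < 0.05. When every
#' difference is zero the comparison is degenerate: t is reported as NaN and
#' p as 1 with a warning; a non-zero but constant difference yields NaN/NaN.
#'
#' @param a,b equal-length (>= 2) numeric vectors paired by fold.
#' @return list with `t`, `df`, `p`, `mean_diff`, `significant`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    if (all(abs(d) < .Machine$double.eps^0.5)) {
      warn_mo("paired_ttest: all differences are zero; degenerate comparison")
      return(list(t = NaN, df = length(d) - 1L, p = 1, mean_diff = 0,
                  significant = FALSE))
    }
    warn_mo("paired_ttest: zero-variance non-zero differences; statistic undefined")
    return(list(t = NaN, df = length(d) - 1L, p = NaN, mean_diff = mean(d),
                significant = FALSE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), significant = tt$p.value < 0.05)
}
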