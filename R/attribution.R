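## -------------------------------------------------------------------------
## Integrated-gradients interpretation of the fitted classifiers.
## -------------------------------------------------------------------------

#' Integrated gradients attributions for samples
#'
#' For each sample the attribution of feature j is
#' `x_j * mean_m dF_c(alpha_m * x) / dx_j`, a midpoint Riemann approximation
#' of the path integral from the zero baseline to the input, where `F_c` is
#' the score of the sample's top predicted class `c`. By default the score
#' is the pre-softmax logit; `on = "prob"` uses the softmax probability.
#'
#' @param model a [coo_net()] fit.
#' @param x named list of feature matrices (or a single matrix) — typically
#'   one or more rows of the model's input space.
#' @param steps number of interpolation points (>= 1; default 50).
#' @param on `"logit"` (default) or `"prob"`.
#' @param target_class optional fixed class name; default is each sample's
#'   top predicted class.
#' @return list with `attributions` (named list of matrices, one per feature
#'   set, rows = samples) and `target_class` (character vector per sample).
#' @export
integrated_gradients <- function(model, x, steps = 50L,
                                 on = c("logit", "prob"), target_class = NULL) {
  on <- match.arg(on)
  stopifnot(steps >= 1)
  x <- check_newdata(model, x)
  n <- nrow(x[[1]])
  prob <- predict(model, x, type = "prob")
  ci <- if (is.null(target_class)) {
    max.col(prob, ties.method = "first")
  } else {
    rep_len(match(target_class, model$classes), n)
  }
  if (anyNA(ci)) stop_mo("unknown target class")
  acc <- lapply(x, function(m) matrix(0, nrow(m), ncol(m),
                                      dimnames = dimnames(m)))
  alphas <- (seq_len(steps) - 0.5) / steps
  for (a in alphas) {
    xa <- lapply(x, function(m) m * a)
    g <- input_gradients(model, xa, ci, on = on)
    if (!all(vapply(g, function(m) all(is.finite(m)), logical(1))))
      stop_mo("non-finite gradients encountered during integrated gradients")
    for (fs in names(acc)) acc[[fs]] <- acc[[fs]] + g[[fs]]
  }
  attributions <- lapply(names(acc), function(fs) x[[fs]] * acc[[fs]] / steps)
  names(attributions) <- names(acc)
  list(attributions = attributions, target_class = model$classes[ci])
}

#' Average per-sample attributions into a per-class matrix
#'
#' Arithmetic mean of attributions over the test samples of each class. When
#' a `split` factor is supplied the mean is taken within each split first
#' and the per-split class means are then averaged, so splits with unequal
#' test sizes weigh equally. Classes with no samples get a row of `NA` with
#' a warning.
#'
#' @param attr matrix of per-sample attributions (samples x features), e.g.
#'   one feature set from [integrated_gradients()] (or several columns bound
#'   together).
#' @param labels per-sample class labels.
#' @param fold optional per-sample split/fold identifier.
#' @param classes class set for the rows (default: sorted unique labels).
#' @return an `attribution_matrix`: numeric matrix (classes x features) with
#'   attribute `stage = "raw_mean"`.
#' @export
class_mean_attributions <- function(attr, labels, fold = NULL, classes = NULL) {
  stopifnot(is.matrix(attr), nrow(attr) == length(labels))
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  one_mean <- function(rows) {
    out <- matrix(NA_real_, length(classes), ncol(attr),
                  dimnames = list(classes, colnames(attr)))
    for (cls in classes) {
      idx <- rows[labels[rows] == cls]
      if (length(idx)) out[cls, ] <- colMeans(attr[idx, , drop = FALSE])
    }
    out
  }
  if (is.null(fold)) {
    m <- one_mean(seq_len(nrow(attr)))
  } else {
    stopifnot(length(fold) == nrow(attr))
    per_fold <- lapply(split(seq_len(nrow(attr)), fold), one_mean)
    m <- Reduce(`+`, lapply(per_fold, function(x) ifelse(is.na(x), 0, x))) /
      pmax(Reduce(`+`, lapply(per_fold, function(x) 1 * !is.na(x))), 1)
    all_na <- Reduce(`&`, lapply(per_fold, is.na))
    m[all_na] <- NA_real_
  }
  if (anyNA(m))
    warn_mo("class(es) with no samples: %s",
            paste(rownames(m)[apply(m, 1, anyNA)], collapse = ", "))
  structure(m, stage = "raw_mean", class = c("attribution_matrix", "matrix"))
}

#' Log-modulus transform
#'
#' Sign-preserving logarithm `L(f) = sign(f) * log(|f| + 1)` (natural log):
#' odd, continuous and monotone, with `L(0) = 0`. Applied to attribution
#' matrices before scaling so that large-magnitude features do not swamp the
#' color scale.
#'
#' @param x numeric vector/matrix (an `attribution_matrix` keeps its class,
#'   with stage updated to `"log_modulus"`).
#' @return transformed object of the same shape.
#' @export
log_modulus <- function(x) {
  out <- sign(x) * log1p(abs(x))
  if (inherits(x, "attribution_matrix")) {
    attributes(out) <- attributes(x)
    attr(out, "stage") <- "log_modulus"
  }
  out
}

#' Scale an attribution matrix to [-1, 1]
#'
#' Positive entries are divided by the matrix maximum and negative entries
#' by the magnitude of the matrix minimum, preserving sign, so the extremes
#' map to +1 and -1 and zeros stay zero. The scaling is applied to one
#' feature-type matrix at a time. `formula_literal = TRUE` instead divides
#' negatives by the (negative) minimum itself, which flips their sign.
#'
#' @param m numeric matrix (typically at the log-modulus stage).
#' @param formula_literal divide negatives by `f_min` rather than `|f_min|`.
#' @return scaled matrix with stage `"scaled"`; an all-zero (or all-NA)
#'   matrix is returned unchanged with a warning.
#' @export
scale_attributions <- function(m, formula_literal = FALSE) {
  vals <- m[is.finite(m)]
  if (!length(vals) || all(vals == 0)) {
    warn_mo("attribution matrix has no non-zero entries; returned unchanged")
    out <- m
  } else {
    out <- m
    pos <- is.finite(m) & m > 0
    neg <- is.finite(m) & m < 0
    if (any(pos)) out[pos] <- m[pos] / max(m[pos])
    if (any(neg)) {
      f_min <- min(m[neg])
      out[neg] <- if (formula_literal) m[neg] / f_min else m[neg] / abs(f_min)
    }
  }
  if (inherits(m, "attribution_matrix")) {
    attributes(out) <- attributes(m)
  }
  attr(out, "stage") <- "scaled"
  class(out) <- c("attribution_matrix", "matrix")
  out
}

#' Select top attributed features per class and take their union
#'
#' Within one feature-type matrix (raw-mean stage), ranks features per class
#' by absolute attribution, keeps the top `k` in each class, and returns the
#' union over classes. Features with zero attribution in every class are
#' excluded. The default per-type k values follow the study design: 1 bin,
#' 2 trinucleotides, 2 driver genes.
#'
#' @param m an `attribution_matrix` (classes x features).
#' @param k features kept per class (capped at the matrix width with a
#'   warning).
#' @return character vector: the union of top features, in column order.
#' @export
top_features <- function(m, k = 1L) {
  stopifnot(is.matrix(m))
  if (k > ncol(m)) {
    warn_mo("k = %d exceeds the %d available features; capped", k, ncol(m))
    k <- ncol(m)
  }
  nonzero <- colSums(abs(m) > 0, na.rm = TRUE) > 0
  sel <- character(0)
  for (cls in rownames(m)) {
    v <- abs(m[cls, ])
    v[!nonzero] <- -Inf
    ord <- order(-v, seq_along(v))
    keep <- ord[seq_len(k)]
    keep <- keep[is.finite(v[keep])]
    sel <- union(sel, colnames(m)[keep])
  }
  sel[order(match(sel, colnames(m)))]
}

#' Per-class display ordering of features
#'
#' For heatmap display each class's features are sorted by attribution in a
#' reference matrix (the full-data run), and sparse-data matrices reuse that
#' ordering so the same feature order appears in every panel of a feature
#' type.
#'
#' @param reference an `attribution_matrix` computed on the reference (full)
#'   data.
#' @param decreasing sort direction.
#' @return named list: one integer column-ordering vector per class.
#' @export
feature_display_order <- function(reference, decreasing = TRUE) {
  stopifnot(is.matrix(reference))
  lapply(stats::setNames(rownames(reference), rownames(reference)),
         function(cls) order(reference[cls, ], decreasing = decreasing,
                             na.last = TRUE))
}
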