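## -------------------------------------------------------------------------
## Gaussian-process Bayesian hyperparameter search (sequential model-based
## minimization with expected improvement), over mixed real / integer /
## categorical spaces.
## -------------------------------------------------------------------------

#' Define a hyperparameter search space
#'
#' Each dimension is a list created by [param_real()], [param_integer()] or
#' [param_categorical()]. The default space covers the tuned
#' hyperparameters of one network entry point: learning rate and L2 penalty
#' (log-uniform), dropout (uniform), hidden-layer count and width (integer)
#' and activation (categorical).
#'
#' @param ... named parameter definitions.
#' @return object of class `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  stopifnot(length(dims) >= 1, !is.null(names(dims)), all(nzchar(names(dims))))
  for (d in dims) stopifnot(d$type %in% c("real", "integer", "categorical"))
  structure(dims, class = "search_space")
}

#' @rdname search_space
#' @param lower,upper finite bounds (inclusive).
#' @param log sample/model this dimension on the log scale.
#' @export
param_real <- function(lower, upper, log = FALSE) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper,
            !log || lower > 0)
  list(type = "real", lower = lower, upper = upper, log = log)
}

#' @rdname search_space
#' @export
param_integer <- function(lower, upper) {
  stopifnot(is.finite(lower), is.finite(upper), lower <= upper)
  list(type = "integer", lower = as.integer(lower), upper = as.integer(upper))
}

#' @rdname search_space
#' @param choices non-empty vector of categorical values.
#' @export
param_categorical <- function(choices) {
  stopifnot(length(choices) >= 1)
  list(type = "categorical", choices = choices)
}

#' @rdname search_space
#' @export
default_search_space <- function() {
  search_space(
    learning_rate = param_real(1e-5, 1e-2, log = TRUE),
    l2 = param_real(1e-6, 1e-2, log = TRUE),
    dropout = param_real(0, 0.5),
    n_layers = param_integer(1, 4),
    n_nodes = param_integer(32, 512),
    activation = param_categorical(c("relu", "tanh", "elu", "sigmoid")))
}

## Unit-cube encoding: reals/integers scale to [0,1] (log scale where asked),
## categoricals expand to one-hot.
space_encode <- function(space, params) {
  enc <- numeric(0)
  for (nm in names(space)) {
    d <- space[[nm]]
    v <- params[[nm]]
    enc <- c(enc, switch(d$type,
      real = if (d$log) (log(v) - log(d$lower)) / (log(d$upper) - log(d$lower))
             else (v - d$lower) / (d$upper - d$lower),
      integer = if (d$upper > d$lower) (v - d$lower) / (d$upper - d$lower) else 0.5,
      categorical = as.numeric(d$choices == v)))
  }
  enc
}

## Map a unit-cube point (from the LHS / random design) to parameter values.
space_decode_unit <- function(space, u) {
  params <- list()
  j <- 0L
  for (nm in names(space)) {
    d <- space[[nm]]
    if (d$type == "categorical") {
      k <- length(d$choices)
      params[[nm]] <- d$choices[[which.max(u[j + seq_len(k)])]]
      j <- j + k
    } else {
      j <- j + 1L
      params[[nm]] <- switch(d$type,
        real = if (d$log) exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
               else d$lower + u[j] * (d$upper - d$lower),
        integer = as.integer(round(d$lower + u[j] * (d$upper - d$lower))))
    }
  }
  params
}

space_unit_dim <- function(space) {
  sum(vapply(space, function(d)
    if (d$type == "categorical") length(d$choices) else 1L, integer(1)))
}

random_params <- function(space, n) {
  lapply(seq_len(n), function(i)
    space_decode_unit(space, stats::runif(space_unit_dim(space))))
}

## GP with squared-exponential kernel on the encoded space; lengthscale and
## noise chosen by maximum marginal likelihood over a small grid, on
## standardized objective values.
gp_fit <- function(Xe, y) {
  ym <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  yz <- (y - ym) / ys
  D2 <- as.matrix(stats::dist(Xe))^2
  best <- NULL
  for (len in c(0.1, 0.2, 0.5, 1, 2)) {
    for (noise in c(1e-4, 1e-2, 1e-1)) {
      K <- exp(-D2 / (2 * len^2)) + diag(noise, nrow(Xe))
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), yz))
      ll <- -0.5 * sum(yz * alpha) - sum(log(diag(ch)))
      if (is.null(best) || ll > best$ll)
        best <- list(ll = ll, len = len, noise = noise, chol = ch, alpha = alpha)
    }
  }
  c(best, list(Xe = Xe, ym = ym, ys = ys))
}

gp_predict <- function(fit, Xnew) {
  D2 <- outer(rowSums(Xnew^2), rowSums(fit$Xe^2), "+") -
    2 * Xnew %*% t(fit$Xe)
  Ks <- exp(-pmax(D2, 0) / (2 * fit$len^2))
  mu <- as.numeric(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(Ks))
  var <- pmax(1 + fit$noise - colSums(v^2), 1e-12)
  list(mean = mu * fit$ys + fit$ym, sd = sqrt(var) * fit$ys)
}

expected_improvement <- function(mu, sd, ymin) {
  z <- (ymin - mu) / sd
  (ymin - mu) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Sequential Gaussian-process minimization
#'
#' Minimizes a black-box objective over a [search_space()]: an initial Latin
#' hypercube design is evaluated, then each further candidate maximizes
#' expected improvement under a Gaussian-process surrogate (squared
#' exponential kernel on the unit-cube encoding) over a random candidate
#' set. An objective that throws is recorded at the worst value seen so far
#' and the search continues. Deterministic given `seed`.
#'
#' @param space a [search_space()].
#' @param objective `function(params) -> finite scalar` to minimize (for
#'   hyperparameter tuning: the negated validation accuracy).
#' @param n_calls total number of objective evaluations (>= 10).
#' @param seed integer seed.
#' @param n_initial size of the initial random design (default
#'   `min(10, max(5, n_calls %/% 3))`).
#' @param n_candidates candidate points scored per GP iteration.
#' @return object of class `search_result`: `best_params`, `best_value`, and
#'   a `trace` data frame (iteration, value, and one column per parameter).
#' @export
bayes_search <- function(space, objective, n_calls, seed = 1L,
                         n_initial = NULL, n_candidates = 500L) {
  stopifnot(inherits(space, "search_space"), n_calls >= 10)
  n_initial <- n_initial %||% min(10L, max(5L, n_calls %/% 3L))
  n_initial <- min(n_initial, n_calls)
  with_seed(seed, {
    U <- lhs::randomLHS(n_initial, space_unit_dim(space))
    evaluated <- list()
    values <- numeric(0)
    encs <- NULL
    eval_one <- function(params) {
      val <- tryCatch(objective(params), error = function(e) {
        warn_mo("objective failed (%s); recording worst-seen value",
                conditionMessage(e))
        if (length(values)) max(values) else Inf
      })
      if (!is.finite(val)) val <- if (length(values)) max(values) else 1e10
      val
    }
    for (i in seq_len(n_calls)) {
      if (i <= n_initial) {
        params <- space_decode_unit(space, U[i, ])
      } else {
        fit <- gp_fit(encs, values)
        cand <- random_params(space, n_candidates)
        Xc <- do.call(rbind, lapply(cand, function(p) space_encode(space, p)))
        pr <- gp_predict(fit, Xc)
        ei <- expected_improvement(pr$mean, pr$sd, min(values))
        params <- cand[[which.max(ei)]]
      }
      val <- eval_one(params)
      evaluated[[i]] <- params
      values <- c(values, val)
      encs <- rbind(encs, space_encode(space, params))
    }
    best <- which.min(values)
    trace <- cbind(data.frame(iteration = seq_len(n_calls), value = values),
                   do.call(rbind, lapply(evaluated, function(p)
                     as.data.frame(p, stringsAsFactors = FALSE))))
    structure(list(best_params = evaluated[[best]], best_value = values[best],
                   trace = trace, seed = seed),
              class = "search_result")
  })
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d evaluations, best value %.5g\n",
              nrow(x$trace), x$best_value))
  cat("  best:", paste(names(x$best_params),
                       vapply(x$best_params, function(v) format(v, digits = 4),
                              character(1)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

params_to_hyperparams <- function(params) {
  do.call(hyperparams, params[intersect(names(params),
    c("learning_rate", "l2", "dropout", "n_layers", "n_nodes", "activation"))])
}

#' Tune hyperparameters per network entry point
#'
#' Runs one [bayes_search()] per entry point of the chosen architecture: a
#' single search for early integration; one per feature branch for
#' multi-branch; one per stage for consecutive integration. Entry points are
#' tuned sequentially — while entry point `i` is searched, already-tuned
#' entry points keep their best values and later ones their defaults.
#'
#' @param architecture `"early"`, `"multi_branch"` or `"consecutive"`.
#' @param n_entry_points number of entry points (number of feature sets for
#'   multi-branch/consecutive; forced to 1 for early).
#' @param objective_builder `function(hp_list) -> finite scalar` where
#'   `hp_list` is the full per-entry-point list of [hyperparams()]; returns
#'   the value to minimize.
#' @param space a [search_space()] used for every entry point.
#' @param n_calls evaluations per entry point. The default 25 is desk-scale;
#'   the full study design used 200.
#' @param seed integer seed.
#' @param feature_order passed through to the returned spec.
#' @return an [integration_spec()] with tuned hyperparameters and an
#'   attribute `"searches"` holding the per-entry-point `search_result`s.
#' @export
tune_per_entry_point <- function(architecture, n_entry_points, objective_builder,
                                 space = default_search_space(), n_calls = 25L,
                                 seed = 1L, feature_order = NULL) {
  architecture <- match.arg(architecture, c("early", "multi_branch", "consecutive"))
  n_entry <- if (architecture == "early") 1L else as.integer(n_entry_points)
  hp_list <- replicate(n_entry, hyperparams(), simplify = FALSE)
  searches <- vector("list", n_entry)
  for (e in seq_len(n_entry)) {
    obj <- function(params) {
      trial <- hp_list
      trial[[e]] <- params_to_hyperparams(params)
      objective_builder(trial)
    }
    res <- bayes_search(space, obj, n_calls, seed = derive_seed(seed, "entry", e))
    hp_list[[e]] <- params_to_hyperparams(res$best_params)
    searches[[e]] <- res
  }
  spec <- integration_spec(architecture, hp_list, feature_order)
  attr(spec, "searches") <- searches
  spec
}
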