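## -------------------------------------------------------------------------
## Feed-forward classifier with early / multi-branch / consecutive feature
## integration. Dense blocks are wired into a small DAG; forward, backprop
## and Adam are implemented directly on base-R matrices so that input
## gradients (needed for integrated gradients) are available exactly.
## -------------------------------------------------------------------------

ACTIVATIONS <- c("relu", "tanh", "sigmoid", "elu")

#' Hyperparameters of one dense stack
#'
#' One set of hyperparameters governs one entry point of the network: the
#' whole network for early integration, one feature branch for multi-branch,
#' one stage for consecutive integration.
#'
#' @param learning_rate positive Adam step size.
#' @param l2 non-negative L2 (weight decay) penalty on dense kernels
#'   (biases are not penalized).
#' @param dropout dropout rate in `[0, 1)`, applied after each hidden layer.
#' @param n_layers number of hidden dense layers (0 = passthrough).
#' @param n_nodes neurons per hidden layer.
#' @param activation one of `"relu"`, `"tanh"`, `"sigmoid"`, `"elu"`.
#' @return object of class `hyperparams`.
#' @export
hyperparams <- function(learning_rate = 1e-3, l2 = 1e-4, dropout = 0.1,
                        n_layers = 2L, n_nodes = 64L, activation = "relu") {
  stopifnot(learning_rate > 0, l2 >= 0, dropout >= 0, dropout < 1,
            n_layers >= 0, n_nodes >= 1)
  activation <- match.arg(activation, ACTIVATIONS)
  structure(list(learning_rate = learning_rate, l2 = l2, dropout = dropout,
                 n_layers = as.integer(n_layers), n_nodes = as.integer(n_nodes),
                 activation = activation),
            class = "hyperparams")
}

#' Training schedule
#'
#' Defaults follow the study design: Adam with batch size 32 for 50 epochs,
#' glorot-uniform weight initialization and zero biases.
#'
#' @param batch_size mini-batch size.
#' @param epochs number of passes over the training set (0 returns the
#'   initialized network untrained).
#' @param beta1,beta2,epsilon Adam moment/stability constants.
#' @return object of class `training_schedule`.
#' @export
training_schedule <- function(batch_size = 32L, epochs = 50L, beta1 = 0.9,
                              beta2 = 0.999, epsilon = 1e-8) {
  stopifnot(batch_size >= 1, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "training_schedule")
}

#' Integration architecture specification
#'
#' @param architecture `"early"` (all feature sets concatenated into one
#'   input), `"multi_branch"` (one dense stack per feature set, last layers
#'   concatenated before the softmax head) or `"consecutive"` (feature sets
#'   injected one after another: each stage's last layer is concatenated with
#'   the next raw feature set).
#' @param hyperparams a single [hyperparams()] (early) or a list with one set
#'   per entry point (multi-branch: per branch; consecutive: per stage).
#' @param feature_order order in which feature sets enter a consecutive
#'   network; ignored otherwise. `NULL` keeps the input order.
#' @return object of class `integration_spec`.
#' @export
integration_spec <- function(architecture = c("early", "multi_branch", "consecutive"),
                             hyperparams = NULL, feature_order = NULL) {
  architecture <- match.arg(architecture)
  if (inherits(hyperparams, "hyperparams")) hyperparams <- list(hyperparams)
  structure(list(architecture = architecture, hyperparams = hyperparams,
                 feature_order = feature_order),
            class = "integration_spec")
}

glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

act_fun <- function(z, name) {
  switch(name,
         relu = pmax(z, 0),
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         elu = ifelse(z > 0, z, exp(z) - 1),
         identity = z)
}

act_grad <- function(z, a, name) {
  switch(name,
         relu = (z > 0) * 1,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         elu = ifelse(z > 0, 1, a + 1),
         identity = array(1, dim(z)))
}

new_block <- function(inputs, in_dim, hp) {
  layers <- list()
  d <- in_dim
  if (hp$n_layers > 0) for (i in seq_len(hp$n_layers)) {
    layers[[i]] <- list(W = glorot_uniform(d, hp$n_nodes), b = numeric(hp$n_nodes))
    d <- hp$n_nodes
  }
  list(inputs = inputs, layers = layers, activation = hp$activation,
       dropout = hp$dropout, lr = hp$learning_rate, l2 = hp$l2,
       in_dim = in_dim, out_dim = d)
}

## Wire the block DAG for a given architecture. Blocks are created in
## topological order; each block's output feeds exactly one consumer.
build_network <- function(spec, input_dims, n_classes) {
  arch <- spec$architecture
  fs <- names(input_dims)
  hp <- spec$hyperparams
  n_entry <- switch(arch, early = 1L, multi_branch = length(fs),
                    consecutive = length(fs))
  if (is.null(hp)) hp <- replicate(n_entry, hyperparams(), simplify = FALSE)
  if (length(hp) != n_entry)
    stop_mo("architecture '%s' with %d feature set(s) needs %d hyperparameter set(s), got %d",
            arch, length(fs), n_entry, length(hp))
  blocks <- list()
  if (arch == "early") {
    blocks$b1 <- new_block(fs, sum(input_dims), hp[[1]])
    head_inputs <- "b1"
  } else if (arch == "multi_branch") {
    for (i in seq_along(fs))
      blocks[[paste0("b", i)]] <- new_block(fs[i], input_dims[[fs[i]]], hp[[i]])
    head_inputs <- paste0("b", seq_along(fs))
  } else {
    ord <- spec$feature_order %||% fs
    if (!setequal(ord, fs))
      stop_mo("feature_order must be a permutation of the feature sets (%s)",
              paste(fs, collapse = ", "))
    prev <- NULL
    for (i in seq_along(ord)) {
      ins <- c(prev, ord[i])
      in_dim <- sum(c(if (!is.null(prev)) blocks[[prev]]$out_dim,
                      input_dims[[ord[i]]]))
      blocks[[paste0("b", i)]] <- new_block(ins, in_dim, hp[[i]])
      prev <- paste0("b", i)
    }
    head_inputs <- prev
  }
  head_dim <- sum(vapply(head_inputs, function(b) blocks[[b]]$out_dim, numeric(1)))
  head <- list(inputs = head_inputs,
               W = glorot_uniform(head_dim, n_classes), b = numeric(n_classes),
               lr = mean(vapply(hp, `[[`, numeric(1), "learning_rate")),
               l2 = mean(vapply(hp, `[[`, numeric(1), "l2")))
  list(blocks = blocks, head = head)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Forward pass. X: named list of matrices. Returns block caches, logits,
## probabilities. Dropout masks (inverted dropout) are drawn only when
## training = TRUE; activations are cached pre-dropout for exact backprop.
net_forward <- function(net, X, training = FALSE) {
  outs <- X
  caches <- list()
  for (bn in names(net$blocks)) {
    blk <- net$blocks[[bn]]
    H <- do.call(cbind, unname(outs[blk$inputs]))
    cache <- list(Hin = list(), Z = list(), A = list(), mask = list())
    for (i in seq_along(blk$layers)) {
      cache$Hin[[i]] <- H
      Z <- sweep(H %*% blk$layers[[i]]$W, 2, blk$layers[[i]]$b, "+")
      A <- act_fun(Z, blk$activation)
      cache$Z[[i]] <- Z
      cache$A[[i]] <- A
      if (training && blk$dropout > 0) {
        mask <- matrix(stats::runif(length(A)) >= blk$dropout, nrow(A), ncol(A)) /
          (1 - blk$dropout)
        cache$mask[[i]] <- mask
        H <- A * mask
      } else {
        cache$mask[[i]] <- NULL
        H <- A
      }
    }
    cache$out <- H
    caches[[bn]] <- cache
    outs[[bn]] <- H
  }
  Hh <- do.call(cbind, unname(outs[net$head$inputs]))
  logits <- sweep(Hh %*% net$head$W, 2, net$head$b, "+")
  list(caches = caches, head_input = Hh, logits = logits,
       probs = softmax(logits))
}

## Split a gradient on a concatenated matrix back into its named sources and
## accumulate into `acc`.
route_gradient <- function(acc, dH, sources, dims) {
  off <- 0L
  for (s in sources) {
    d <- dims[[s]]
    g <- dH[, off + seq_len(d), drop = FALSE]
    acc[[s]] <- if (is.null(acc[[s]])) g else acc[[s]] + g
    off <- off + d
  }
  acc
}

## Backward pass from d(objective)/d(logits). Returns parameter gradients
## (same shape as the network) and, optionally, input gradients per feature
## set. L2 gradients are added to kernel gradients here.
net_backward <- function(net, fwd, X, dLogits, input_grads = FALSE) {
  dims <- c(lapply(X, ncol),
            lapply(net$blocks, function(b) b$out_dim))
  grads <- list(blocks = list(), head = NULL)
  gW <- crossprod(fwd$head_input, dLogits) + 2 * net$head$l2 * net$head$W
  gb <- colSums(dLogits)
  grads$head <- list(W = gW, b = gb)
  acc <- list()
  acc <- route_gradient(acc, dLogits %*% t(net$head$W), net$head$inputs, dims)
  for (bn in rev(names(net$blocks))) {
    blk <- net$blocks[[bn]]
    cache <- fwd$caches[[bn]]
    dOut <- acc[[bn]]
    if (is.null(dOut)) next
    layer_grads <- vector("list", length(blk$layers))
    if (length(blk$layers)) {
      dH <- dOut
      for (i in rev(seq_along(blk$layers))) {
        has_mask <- length(cache$mask) >= i && !is.null(cache$mask[[i]])
        dA <- if (has_mask) dH * cache$mask[[i]] else dH
        dZ <- dA * act_grad(cache$Z[[i]], cache$A[[i]], blk$activation)
        layer_grads[[i]] <- list(
          W = crossprod(cache$Hin[[i]], dZ) + 2 * blk$l2 * blk$layers[[i]]$W,
          b = colSums(dZ))
        dH <- dZ %*% t(blk$layers[[i]]$W)
      }
      dIn <- dH
    } else {
      dIn <- dOut
    }
    grads$blocks[[bn]] <- layer_grads
    acc <- route_gradient(acc, dIn, blk$inputs, dims)
  }
  out <- list(grads = grads)
  if (input_grads) out$input_grads <- acc[names(X)]
  out
}

## Adam state mirrors the parameter structure; moments start at scalar zero
## and take matrix shape on the first update.
adam_init <- function(net) {
  zero_state <- function(...) list(mW = 0, vW = 0, mb = 0, vb = 0)
  list(blocks = lapply(net$blocks, function(b) lapply(b$layers, zero_state)),
       head = zero_state(), t = 0L)
}

adam_update_param <- function(p, g, st, lr, sched, t) {
  bc1 <- 1 - sched$beta1^t
  bc2 <- 1 - sched$beta2^t
  mW <- st$mW * sched$beta1 + (1 - sched$beta1) * g$W
  vW <- st$vW * sched$beta2 + (1 - sched$beta2) * g$W^2
  mb <- st$mb * sched$beta1 + (1 - sched$beta1) * g$b
  vb <- st$vb * sched$beta2 + (1 - sched$beta2) * g$b^2
  p$W <- p$W - lr * (mW / bc1) / (sqrt(vW / bc2) + sched$epsilon)
  p$b <- p$b - lr * (mb / bc1) / (sqrt(vb / bc2) + sched$epsilon)
  list(param = p, state = list(mW = mW, vW = vW, mb = mb, vb = vb))
}

#' Fit a feature-integration classifier
#'
#' Trains a feed-forward softmax classifier on one or more feature matrices
#' using mini-batch Adam with categorical cross-entropy. Weights are
#' initialized glorot-uniform, biases at zero. The final-epoch weights are
#' returned (no early stopping); validation data, if given, is only used to
#' log per-epoch accuracy. Training is deterministic given `seed`.
#'
#' @param x named list of numeric matrices (samples x features), one per
#'   feature set, all with the same rows; a single matrix is accepted.
#' @param y class labels (character or factor), length `nrow`.
#' @param architecture,hyperparams,feature_order see [integration_spec()]; an
#'   `integration_spec` can be passed via `spec` instead.
#' @param spec optional [integration_spec()] overriding the three arguments.
#' @param x_val,y_val optional validation data in the same shape.
#' @param schedule a [training_schedule()].
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param classes optional fixed class-name vector (defaults to the sorted
#'   unique labels of `y`).
#' @param verbose print per-epoch progress.
#' @return an object of class `coo_net` with `predict`, `print`, `summary`
#'   and `plot` methods, holding the learned weights, class names and a
#'   per-epoch history (`loss`, `val_accuracy`).
#' @export
coo_net <- function(x, y, architecture = c("early", "multi_branch", "consecutive"),
                    hyperparams = NULL, feature_order = NULL, spec = NULL,
                    x_val = NULL, y_val = NULL, schedule = training_schedule(),
                    seed = 1L, classes = NULL, verbose = FALSE) {
  if (is.matrix(x)) x <- list(input = x)
  stopifnot(is.list(x), length(x) >= 1, !is.null(names(x)))
  if (is.null(spec))
    spec <- integration_spec(match.arg(architecture), hyperparams, feature_order)
  n <- nrow(x[[1]])
  stopifnot(all(vapply(x, nrow, integer(1)) == n), length(y) == n)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (!all(y %in% classes)) stop_mo("labels outside the class set")
  n_classes <- length(classes)
  if (n_classes < 2) stop_mo("need at least 2 classes")
  input_dims <- vapply(x, ncol, integer(1))

  with_seed(seed, {
    net <- build_network(spec, input_dims, n_classes)
    Y <- matrix(0, n, n_classes)
    Y[cbind(seq_len(n), match(y, classes))] <- 1
    st <- adam_init(net)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          val_accuracy = numeric())
    for (epoch in seq_len(schedule$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = schedule$batch_size)
      epoch_loss <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + schedule$batch_size - 1L, n)]
        Xb <- lapply(x, function(m) m[idx, , drop = FALSE])
        Yb <- Y[idx, , drop = FALSE]
        fwd <- net_forward(net, Xb, training = TRUE)
        p_true <- rowSums(fwd$probs * Yb)
        loss <- -mean(log(pmax(p_true, 1e-12)))
        if (!is.finite(loss))
          stop_mo("training diverged (non-finite loss) at epoch %d; consider a lower learning rate",
                  epoch)
        epoch_loss <- epoch_loss + loss * length(idx)
        dLogits <- (fwd$probs - Yb) / length(idx)
        bwd <- net_backward(net, fwd, Xb, dLogits)
        st$t <- st$t + 1L
        for (bn in names(net$blocks)) {
          blk <- net$blocks[[bn]]
          g <- bwd$grads$blocks[[bn]]
          if (is.null(g)) next
          for (i in seq_along(blk$layers)) {
            upd <- adam_update_param(blk$layers[[i]], g[[i]],
                                     st$blocks[[bn]][[i]],
                                     blk$lr, schedule, st$t)
            net$blocks[[bn]]$layers[[i]] <- upd$param
            st$blocks[[bn]][[i]] <- upd$state
          }
        }
        updh <- adam_update_param(net$head, bwd$grads$head,
                                  st$head, net$head$lr, schedule, st$t)
        net$head <- updh$param
        st$head <- updh$state
      }
      val_acc <- NA_real_
      if (!is.null(x_val)) {
        if (is.matrix(x_val)) x_val <- list(input = x_val)
        pv <- net_forward(net, x_val, training = FALSE)$probs
        pred <- classes[max.col(pv, ties.method = "first")]
        val_acc <- mean(pred == as.character(y_val))
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss / n,
                                           val_accuracy = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val_acc %s", epoch,
                        epoch_loss / n,
                        ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    structure(list(blocks = net$blocks, head = net$head, classes = classes,
                   feature_sets = names(x), input_dims = input_dims,
                   spec = spec, schedule = schedule, history = history,
                   seed = seed, n_train = n),
              class = "coo_net")
  })
}

as_net <- function(object) list(blocks = object$blocks, head = object$head)

check_newdata <- function(object, newdata) {
  if (is.matrix(newdata)) newdata <- stats::setNames(list(newdata),
                                                     object$feature_sets[1])
  missing_fs <- setdiff(object$feature_sets, names(newdata))
  if (length(missing_fs))
    stop_mo("newdata lacks feature set(s): %s", paste(missing_fs, collapse = ", "))
  newdata <- newdata[object$feature_sets]
  dims <- vapply(newdata, ncol, integer(1))
  if (!all(dims == object$input_dims))
    stop_mo("newdata widths (%s) do not match the model (%s)",
            paste(dims, collapse = ","), paste(object$input_dims, collapse = ","))
  newdata
}

#' Predict from a fitted integration classifier
#'
#' @param object a [coo_net()] fit.
#' @param newdata named list of feature matrices (or single matrix).
#' @param type `"prob"` for the softmax probability matrix (rows sum to 1),
#'   `"class"` for the top label, `"topk"` for a matrix whose rows are the
#'   `k` highest-probability class names in rank order (probability ties
#'   broken by ascending class index).
#' @param k number of ranked labels for `type = "topk"`.
#' @param ... unused.
#' @return matrix of probabilities, character vector, or n x k character
#'   matrix according to `type`.
#' @export
predict.coo_net <- function(object, newdata, type = c("prob", "class", "topk"),
                            k = 3L, ...) {
  type <- match.arg(type)
  newdata <- check_newdata(object, newdata)
  probs <- net_forward(as_net(object), newdata, training = FALSE)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  if (type == "class") return(object$classes[max.col(probs, ties.method = "first")])
  if (k < 1) stop_mo("k must be >= 1")
  k <- min(k, length(object$classes))
  t(apply(probs, 1, function(p)
    object$classes[order(-p, seq_along(p))[seq_len(k)]]))
}

#' Gradients of a class score with respect to the inputs
#'
#' Exact input gradients via backpropagation, per row of `newdata`.
#'
#' @param object a `coo_net` fit.
#' @param newdata named list of feature matrices (or single matrix).
#' @param class_index integer scalar or per-row vector: class whose score is
#'   differentiated.
#' @param on `"logit"` (pre-softmax score, default) or `"prob"` (softmax
#'   probability).
#' @return named list of gradient matrices, one per feature set.
#' @export
input_gradients <- function(object, newdata, class_index, on = c("logit", "prob")) {
  on <- match.arg(on)
  newdata <- check_newdata(object, newdata)
  net <- as_net(object)
  fwd <- net_forward(net, newdata, training = FALSE)
  n <- nrow(fwd$probs)
  ci <- rep_len(as.integer(class_index), n)
  dLogits <- matrix(0, n, length(object$classes))
  if (on == "logit") {
    dLogits[cbind(seq_len(n), ci)] <- 1
  } else {
    pc <- fwd$probs[cbind(seq_len(n), ci)]
    dLogits <- -fwd$probs * pc
    dLogits[cbind(seq_len(n), ci)] <- dLogits[cbind(seq_len(n), ci)] + pc
  }
  ## L2 terms must not leak into input gradients: zero the penalties first.
  net0 <- net
  net0$head$l2 <- 0
  for (bn in names(net0$blocks)) net0$blocks[[bn]]$l2 <- 0
  net_backward(net0, fwd, newdata, dLogits, input_grads = TRUE)$input_grads
}

#' @export
print.coo_net <- function(x, ...) {
  cat(sprintf("<coo_net> %s integration: %s -> %d classes\n",
              x$spec$architecture,
              paste(sprintf("%s(%d)", x$feature_sets, x$input_dims), collapse = " + "),
              length(x$classes)))
  cat(sprintf("  trained %d epochs on %d samples (batch %d, seed %d)\n",
              nrow(x$history), x$n_train, x$schedule$batch_size, x$seed))
  invisible(x)
}

#' @export
summary.coo_net <- function(object, ...) {
  cat(sprintf("Feed-forward cell-of-origin classifier (%s integration)\n",
              object$spec$architecture))
  for (bn in names(object$blocks)) {
    blk <- object$blocks[[bn]]
    cat(sprintf("  %s: inputs [%s], %d layer(s) x %s, activation %s, dropout %.2f, lr %.2g, l2 %.2g\n",
                bn, paste(blk$inputs, collapse = ", "), length(blk$layers),
                if (length(blk$layers)) ncol(blk$layers[[1]]$W) else blk$in_dim,
                blk$activation, blk$dropout, blk$lr, blk$l2))
  }
  cat(sprintf("  head: [%s] -> %d classes (softmax)\n",
              paste(object$head$inputs, collapse = ", "), length(object$classes)))
  if (nrow(object$history)) {
    last <- object$history[nrow(object$history), ]
    cat(sprintf("  final epoch %d: loss %.4f%s\n", last$epoch, last$loss,
                if (is.na(last$val_accuracy)) "" else
                  sprintf(", validation accuracy %.3f", last$val_accuracy)))
  }
  invisible(object)
}

#' Plot the training history of a fitted classifier
#' @param x a `coo_net` fit.
#' @param ... passed to [plot()].
#' @export
plot.coo_net <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history to plot"); return(invisible(x)) }
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (any(!is.na(h$val_accuracy))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_accuracy, type = "l", lty = 2, axes = FALSE,
                   xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation accuracy", side = 4, line = 2)
  }
  invisible(x)
}
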