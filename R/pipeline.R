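## -------------------------------------------------------------------------
## End-to-end experiment orchestration: split -> downsample/augment ->
## featurize -> (tune) -> train -> score -> attribute.
## -------------------------------------------------------------------------

#' Configure a sparsity/augmentation experiment
#'
#' @param cohort_dir directory holding `genome.fa`, `bins.tsv`, `genes.tsv`,
#'   `labels.tsv` and `vcf/<sample_id>.vcf` (as written by [make_fixture()]).
#' @param retention vector of retention fractions to run.
#' @param augmentation vector of augmentation levels; `1` is the
#'   unaugmented baseline (one subsample per training parent).
#' @param architecture,feature_order,hyperparams model wiring; see
#'   [integration_spec()]. `hyperparams = NULL` uses defaults or, when
#'   `hpo_calls > 0`, the tuned values.
#' @param feature_sets which feature types enter the model.
#' @param transform count transform fed to [prepare_features()].
#' @param n_splits shuffle-split rounds.
#' @param hpo_calls Bayesian-optimization budget per entry point (0 skips
#'   tuning). Tuning is re-run in each split on its own validation set.
#' @param schedule a [training_schedule()].
#' @param attribute compute integrated-gradients attribution matrices for
#'   the trained models (early integration only).
#' @param ig_steps interpolation steps for attribution.
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir optional directory for metrics, confusion matrices and the
#'   run manifest.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(cohort_dir, retention = c(1.0),
                              augmentation = c(1L), architecture = "early",
                              feature_order = NULL, hyperparams = NULL,
                              feature_sets = c("bins", "tri", "drivers"),
                              transform = "log1p", n_splits = 3L,
                              hpo_calls = 0L, schedule = training_schedule(),
                              attribute = FALSE, ig_steps = 50L, seed = 1L,
                              out_dir = NULL) {
  stopifnot(length(retention) >= 1, length(augmentation) >= 1,
            all(retention > 0 & retention <= 1), all(augmentation >= 1))
  if (!dir.exists(cohort_dir)) stop_mo("cohort_dir does not exist: %s", cohort_dir)
  structure(as.list(environment()), class = "experiment_config")
}

#' Load a cohort directory into memory
#'
#' Reads the labels, per-sample VCFs, manifests and genome written by
#' [make_fixture()] (or assembled by hand in the same layout). The result
#' can be passed to [run_experiment()] to avoid re-reading the same cohort
#' across repeated experiments.
#'
#' @param dir cohort directory.
#' @return list with `labels`, `samples`, `bins`, `genes`, `genome`.
#' @export
load_cohort <- function(dir) {
  labels <- read_labels(file.path(dir, "labels.tsv"))
  samples <- lapply(seq_len(nrow(labels)), function(i) {
    read_vcf(file.path(dir, "vcf", paste0(labels$sample_id[i], ".vcf")),
             sample_id = labels$sample_id[i], donor_id = labels$donor_id[i],
             label = labels$label[i])
  })
  names(samples) <- labels$sample_id
  list(labels = labels, samples = samples,
       bins = read_bin_manifest(file.path(dir, "bins.tsv")),
       genes = read_gene_regions(file.path(dir, "genes.tsv")),
       genome = read_genome(file.path(dir, "genome.fa")))
}

## One subsample per evaluation (val/test) parent; the derived seed depends
## on retention and split but NOT on the augmentation level, so different
## augmentation settings are compared on identical evaluation sets.
eval_subsample <- function(samples, ids, p, split_index, seed) {
  lapply(ids, function(sid) {
    if (p >= 1) samples[[sid]]
    else downsample(samples[[sid]], p,
                    derive_seed(seed, "eval", p, split_index, sid))
  })
}

#' Run the sparsity / augmentation / integration experiment grid
#'
#' For every (retention, augmentation) cell and every shuffle split: checks
#' the donor-leakage invariant, augments the training parents only,
#' downsamples validation/test parents once each, featurizes, optionally
#' tunes hyperparameters on the validation set, trains the classifier and
#' scores the test set. Cells with augmentation level 1 serve as
#' unaugmented baselines; augmented cells at the same retention are compared
#' to them with paired t-tests across splits.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-cell progress.
#' @param data optional pre-loaded cohort from [load_cohort()]; defaults to
#'   reading `config$cohort_dir`.
#' @return object of class `coo_experiment`: `summary` (one row per cell and
#'   split), `cells` (per-cell metrics, models' histories, comparisons),
#'   `comparisons` (paired t-tests vs baselines), `attributions` (per
#'   feature set, when requested) and `manifest` (seeds and checksums).
#' @export
run_experiment <- function(config, verbose = TRUE, data = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(data)) data <- load_cohort(config$cohort_dir)
  splits <- stratified_group_shuffle_split(data$labels, config$n_splits,
                                           seed = derive_seed(config$seed, "cv"))
  for (sp in splits) assert_no_donor_leakage(sp, data$labels)
  classes <- sort(unique(data$labels$label))

  featurize <- function(sample_list) {
    fm <- build_feature_matrix(sample_list, data$bins, data$genes, data$genome)
    list(x = prepare_features(fm, config$transform, config$feature_sets),
         y = fm$labels, ids = fm$sample_ids)
  }
  ## full (100%-retention) parent features are identical across splits and
  ## cells: featurize them once on first use
  full_cache <- new.env(parent = emptyenv())
  featurize_full <- function(ids) {
    if (is.null(full_cache$f)) full_cache$f <- featurize(data$samples)
    f <- full_cache$f
    idx <- match(ids, f$ids)
    list(x = lapply(f$x, function(m) m[idx, , drop = FALSE]),
         y = f$y[idx], ids = ids)
  }

  summary_rows <- list()
  cells <- list()
  attribution_acc <- list()
  for (p in config$retention) {
    for (N in config$augmentation) {
      cell_key <- sprintf("p%s_N%d", format(p), N)
      cell <- list(retention = p, augmentation = N, splits = list())
      for (sp in splits) {
        s <- sp$split_index
        train_parents <- data$samples[sp$train]
        if (p >= 1 && N == 1L) {
          tr <- featurize_full(sp$train)
        } else {
          aug <- augment_training_set(train_parents, N, p,
                                      derive_seed(config$seed, "aug", p, N, s))
          tr <- featurize(lapply(aug, `[[`, "sample"))
        }
        if (p >= 1) {
          va <- featurize_full(sp$val)
          te <- featurize_full(sp$test)
        } else {
          va <- featurize(eval_subsample(data$samples, sp$val, p, s, config$seed))
          te <- featurize(eval_subsample(data$samples, sp$test, p, s, config$seed))
        }

        hp <- config$hyperparams
        if (config$hpo_calls > 0) {
          n_entry <- if (config$architecture == "early") 1L
                     else length(config$feature_sets)
          tuned <- tune_per_entry_point(
            config$architecture, n_entry,
            objective_builder = function(hp_list) {
              fit <- coo_net(tr$x, tr$y, spec = integration_spec(
                               config$architecture, hp_list,
                               config$feature_order),
                             x_val = va$x, y_val = va$y,
                             schedule = config$schedule, classes = classes,
                             seed = derive_seed(config$seed, "hpo-fit", p, N, s))
              -utils::tail(fit$history$val_accuracy, 1)
            },
            n_calls = config$hpo_calls,
            seed = derive_seed(config$seed, "hpo", p, N, s),
            feature_order = config$feature_order)
          hp <- tuned$hyperparams
        }

        fit <- coo_net(tr$x, tr$y, spec = integration_spec(
                         config$architecture, hp, config$feature_order),
                       x_val = va$x, y_val = va$y, schedule = config$schedule,
                       classes = classes,
                       seed = derive_seed(config$seed, "fit", p, N, s))
        prob <- predict(fit, te$x, type = "prob")
        metrics <- score_predictions(te$y, prob, classes)
        cell$splits[[s]] <- list(metrics = metrics, history = fit$history,
                                 hyperparams = hp)
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          retention = p, augmentation = N, split = s,
          accuracy = metrics$accuracy, macro_f1 = metrics$macro_f1,
          top1 = metrics$top_k[["top1"]], top2 = metrics$top_k[["top2"]],
          top3 = metrics$top_k[["top3"]])

        if (isTRUE(config$attribute) && config$architecture == "early") {
          ig <- integrated_gradients(fit, te$x, steps = config$ig_steps)
          for (fs in names(ig$attributions)) {
            key <- paste(cell_key, fs, sep = ".")
            prev <- attribution_acc[[key]]
            attribution_acc[[key]] <- list(
              m = rbind(prev$m, ig$attributions[[fs]]),
              label = c(prev$label, te$y),
              fold = c(prev$fold, rep(s, length(te$y))))
          }
        }
        if (verbose)
          message(sprintf("[%s split %d] accuracy %.3f macro-F1 %.3f",
                          cell_key, s, metrics$accuracy, metrics$macro_f1))
      }
      cells[[cell_key]] <- cell
    }
  }
  summary <- do.call(rbind, summary_rows)

  comparisons <- list()
  for (p in config$retention) {
    base <- summary[summary$retention == p & summary$augmentation == 1L, ]
    if (!nrow(base)) next
    for (N in setdiff(config$augmentation, 1L)) {
      aug <- summary[summary$retention == p & summary$augmentation == N, ]
      if (!nrow(aug)) next
      key <- sprintf("p%s_N%d_vs_N1", format(p), N)
      comparisons[[key]] <- paired_ttest(aug$accuracy[order(aug$split)],
                                         base$accuracy[order(base$split)])
    }
  }

  attributions <- NULL
  if (length(attribution_acc)) {
    attributions <- lapply(attribution_acc, function(acc) {
      raw <- class_mean_attributions(acc$m, acc$label, fold = acc$fold,
                                     classes = classes)
      list(raw_mean = raw, log_modulus = log_modulus(raw),
           scaled = scale_attributions(log_modulus(raw)))
    })
  }

  result <- structure(list(config = config, splits = splits, cells = cells,
                           summary = summary, comparisons = comparisons,
                           attributions = attributions,
                           manifest = list(seed = config$seed,
                                           n_splits = config$n_splits,
                                           classes = classes)),
                      class = "coo_experiment")
  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

#' @export
print.coo_experiment <- function(x, ...) {
  cat("<coo_experiment>\n")
  agg <- stats::aggregate(accuracy ~ retention + augmentation, x$summary, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$summary, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (key in names(result$cells)) {
    cell <- result$cells[[key]]
    for (s in seq_along(cell$splits)) {
      cm <- cell$splits[[s]]$metrics$confusion
      utils::write.table(cm, file.path(out_dir,
                                       sprintf("confusion_%s_split%d.tsv", key, s)),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  if (length(result$comparisons))
    jsonlite::write_json(result$comparisons,
                         file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$attributions)) {
    for (key in names(result$attributions)) {
      for (stage in names(result$attributions[[key]])) {
        utils::write.table(result$attributions[[key]][[stage]],
                           file.path(out_dir, sprintf("attribution_%s_%s.tsv",
                                                      key, stage)),
                           sep = "\t", quote = FALSE, col.names = NA)
      }
    }
  }
  jsonlite::write_json(
    list(seed = result$manifest$seed, n_splits = result$manifest$n_splits,
         classes = result$manifest$classes,
         retention = result$config$retention,
         augmentation = result$config$augmentation,
         architecture = result$config$architecture),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
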