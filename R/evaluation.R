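# Repeated random k-fold cross-validation with confusion-matrix metrics.
#
# Default protocol: 20 independent random repartitions of the cohort into 5
# folds (fold sizes differing by at most one, larger folds first; on 59
# records that is {12, 12, 12, 12, 11}), giving 100 train/test experiments.
# Following the original protocol, the held-out fold serves both as the
# early-stopping set and as the reported test set — a known optimistic-bias
# design, reproduced deliberately; a three-way split mode is available.

#' Build a repeated cross-validation plan
#'
#' @param ids character vector of record ids.
#' @param n_folds number of folds (default 5).
#' @param n_repeats number of independent repartitions (default 20).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param stratify_by optional 0/1 labels (same order as `ids`) for
#'   class-stratified folds; default `NULL` = unstratified random
#'   partitions, matching the original protocol.
#' @return an object of class `cv_plan`: per repeat, a named integer vector
#'   mapping record id to fold index.
#' @export
make_cv_plan <- function(ids, n_folds = 5L, n_repeats = 20L, seed = 1L,
                         stratify_by = NULL) {
  n <- length(ids)
  if (n < n_folds)
    abort_contract(sprintf("need at least %d records for %d folds, got %d",
                           n_folds, n_folds, n))
  if (anyDuplicated(ids)) abort_contract("record ids must be unique")
  sizes <- rep(n %/% n_folds, n_folds) +
    as.integer(seq_len(n_folds) <= n %% n_folds)
  fold_of <- rep.int(seq_len(n_folds), sizes)
  assignments <- with_seed(seed, lapply(seq_len(n_repeats), function(rep_i) {
    f <- integer(n)
    if (is.null(stratify_by)) {
      f <- sample(fold_of) # uniform random partition with fixed fold sizes
    } else {
      for (cls in unique(stratify_by)) {
        idx <- which(stratify_by == cls)
        f[idx] <- (sample(seq_along(idx)) - 1L) %% n_folds + 1L
      }
    }
    names(f) <- ids
    f
  }))
  structure(
    list(n_records = n, n_folds = as.integer(n_folds),
         n_repeats = as.integer(n_repeats), seed = as.integer(seed),
         assignments = assignments),
    class = "cv_plan"
  )
}

#' Fold sizes of one repeat
#' @param plan a `cv_plan`.
#' @param repeat_i repeat index (default 1).
#' @return integer vector of fold sizes.
#' @export
fold_sizes <- function(plan, repeat_i = 1L) {
  as.integer(table(factor(plan$assignments[[repeat_i]],
                          levels = seq_len(plan$n_folds))))
}

#' Confusion-matrix metrics
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named list: `accuracy`, `sensitivity` (`TP/(TP+FN)`; `NA` when
#'   the fold holds no positives), `specificity` (`TN/(TN+FP)`; `NA` when
#'   no negatives). Undefined metrics are reported as missing, never as 0.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn >= 1) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp >= 1) tn / (tn + fp) else NA_real_
  )
}

split_xy <- function(features) {
  fcols <- setdiff(names(features), c("record_id", "label"))
  list(x = as.matrix(features[, fcols, drop = FALSE]),
       y = features$label, ids = features$record_id)
}

#' Run repeated cross-validation of the perceptron pipeline
#'
#' For every (repeat, fold) experiment: train on the remaining folds, use
#' the held-out fold for early stopping (`validation = "heldout"`, the
#' original single-split protocol) or an inner carve-out of the training
#' folds (`validation = "three-way"`), then score confusion counts on the
#' held-out fold. Per-experiment weight initialization uses an independent
#' child seed spawned from `master_seed`, so experiments are individually
#' re-runnable.
#'
#' @param features feature data.frame from [cohort_features()].
#' @param plan a [make_cv_plan()] covering exactly the feature record ids.
#' @param config a [train_config()].
#' @param master_seed master seed for per-experiment child seeds.
#' @param threshold decision threshold (default 0.5).
#' @param n_hidden hidden width (default twice the feature dimension).
#' @param validation `"heldout"` (default) or `"three-way"`.
#' @param val_fraction training fraction carved out for early stopping in
#'   three-way mode (default 0.2).
#' @param aggregate `"macro"` (default; unweighted mean of per-experiment
#'   metrics) or `"pooled"` (metrics of summed confusion counts).
#' @return an `eval_report`: `experiments` data.frame (repeat, fold, tp,
#'   tn, fp, fn, stop_epoch, accuracy, sensitivity, specificity),
#'   `aggregate` list, `n_experiments`, `config_hash`.
#' @export
run_cross_validation <- function(features, plan, config = train_config(),
                                 master_seed = 1L, threshold = 0.5,
                                 n_hidden = NULL,
                                 validation = c("heldout", "three-way"),
                                 val_fraction = 0.2,
                                 aggregate = c("macro", "pooled")) {
  validation <- match.arg(validation)
  aggregate <- match.arg(aggregate)
  d <- split_xy(features)
  if (!setequal(d$ids, names(plan$assignments[[1]])))
    abort_contract("cross-validation plan does not cover the feature record ids")
  n_in <- ncol(d$x)
  if (is.null(n_hidden)) n_hidden <- 2L * n_in
  n_exp <- plan$n_repeats * plan$n_folds
  child_seeds <- spawn_seeds(master_seed, 2L * n_exp)

  rows <- vector("list", n_exp)
  k <- 0L
  for (rep_i in seq_len(plan$n_repeats)) {
    folds <- plan$assignments[[rep_i]][d$ids]
    for (fold_i in seq_len(plan$n_folds)) {
      k <- k + 1L
      test <- which(folds == fold_i)
      train <- which(folds != fold_i)
      if (validation == "three-way") {
        n_val <- max(1L, round(val_fraction * length(train)))
        val_idx <- with_seed(child_seeds[n_exp + k],
                             sample(train, n_val))
        train <- setdiff(train, val_idx)
      } else {
        val_idx <- test
      }
      cfg_k <- config
      cfg_k$seed <- child_seeds[k]
      fit <- tryCatch(
        mlp_train(mlp_init(n_in, n_hidden, seed = cfg_k$seed),
                  d$x[train, , drop = FALSE], d$y[train],
                  d$x[val_idx, , drop = FALSE], d$y[val_idx], cfg_k),
        enose_divergence_error = function(e) e
      )
      if (inherits(fit, "error")) {
        rows[[k]] <- data.frame(repeat_i = rep_i, fold = fold_i,
                                tp = NA_integer_, tn = NA_integer_,
                                fp = NA_integer_, fn = NA_integer_,
                                stop_epoch = NA_integer_,
                                accuracy = NA_real_, sensitivity = NA_real_,
                                specificity = NA_real_,
                                error = conditionMessage(fit))
        next
      }
      pred <- mlp_classify(fit$model, d$x[test, , drop = FALSE], threshold)
      truth <- d$y[test]
      tp <- sum(pred == 1L & truth == 1L); tn <- sum(pred == 0L & truth == 0L)
      fp <- sum(pred == 1L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
      m <- confusion_metrics(tp, tn, fp, fn)
      rows[[k]] <- data.frame(repeat_i = rep_i, fold = fold_i, tp = tp,
                              tn = tn, fp = fp, fn = fn,
                              stop_epoch = fit$stop_epoch,
                              accuracy = m$accuracy,
                              sensitivity = m$sensitivity,
                              specificity = m$specificity,
                              error = NA_character_)
    }
  }
  experiments <- do.call(rbind, rows)
  agg <- if (aggregate == "macro") {
    list(accuracy = mean(experiments$accuracy, na.rm = TRUE),
         sensitivity = mean(experiments$sensitivity, na.rm = TRUE),
         specificity = mean(experiments$specificity, na.rm = TRUE))
  } else {
    with(experiments, confusion_metrics(sum(tp, na.rm = TRUE),
                                        sum(tn, na.rm = TRUE),
                                        sum(fp, na.rm = TRUE),
                                        sum(fn, na.rm = TRUE)))
  }
  structure(
    list(experiments = experiments, aggregate = agg, n_experiments = n_exp,
         aggregation = aggregate,
         config_hash = config_hash(list(plan$seed, config, master_seed,
                                        threshold, n_hidden, validation))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d experiments | accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (%s mean)\n",
    x$n_experiments, 100 * x$aggregate$accuracy,
    100 * x$aggregate$sensitivity, 100 * x$aggregate$specificity,
    x$aggregation))
  invisible(x)
}

#' Write an evaluation report (CSV of experiments + JSON summary)
#'
#' @param report an `eval_report`.
#' @param csv_path per-experiment CSV path.
#' @param json_path JSON summary path
#'   (`{accuracy, sensitivity, specificity, n_experiments, config_hash}`).
#' @return invisibly, the two paths.
#' @export
write_eval_report <- function(report, csv_path, json_path) {
  data.table::fwrite(report$experiments, csv_path)
  jsonlite::write_json(
    c(report$aggregate,
      list(n_experiments = report$n_experiments,
           config_hash = report$config_hash)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
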