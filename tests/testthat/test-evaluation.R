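# Repeated random 5-fold cross-validation and confusion metrics.

test_that("fold sizes differ by at most one, larger folds first", {
  ids59 <- sprintf("r%02d", 1:59)
  plan <- make_cv_plan(ids59, n_folds = 5L, n_repeats = 20L, seed = 4L)
  for (rep_i in seq_len(plan$n_repeats))
    expect_identical(fold_sizes(plan, rep_i), c(12L, 12L, 12L, 12L, 11L))
  expect_length(plan$assignments, 20L)

  plan10 <- make_cv_plan(sprintf("r%02d", 1:10), 5L, 1L, seed = 1L)
  expect_identical(fold_sizes(plan10), rep(2L, 5L))

  # fold-size multiset invariant to seed; every record in exactly one fold
  for (seed in c(2L, 77L, 1234L)) {
    p <- make_cv_plan(ids59, seed = seed, n_repeats = 2L)
    for (a in p$assignments) {
      expect_identical(sort(as.integer(table(a)), decreasing = TRUE),
                       c(12L, 12L, 12L, 12L, 11L))
      expect_setequal(names(a), ids59)
    }
  }
  expect_error(make_cv_plan(c("a", "b"), n_folds = 5L),
               class = "enose_contract_error")
})

test_that("confusion metrics follow their definitions, NA on empty classes", {
  expect_equal(confusion_metrics(1, 1, 0, 0),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_equal(confusion_metrics(0, 0, 1, 1),
               list(accuracy = 0, sensitivity = 0, specificity = 0))
  m <- confusion_metrics(3, 1, 1, 1)
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 1 / 2)
  expect_true(is.na(confusion_metrics(0, 3, 1, 0)$sensitivity))
  expect_true(is.na(confusion_metrics(2, 0, 0, 1)$specificity))
})

test_that("cross-validation reports one experiment per (repeat, fold) with exact counts", {
  co <- small_cohort(6L, 5L, effect = 1, seed = 31L)
  feats <- cohort_features(co)
  plan <- make_cv_plan(feats$record_id, n_folds = 5L, n_repeats = 2L,
                       seed = 6L)
  cfg <- train_config(max_epochs = 200L, min_epochs = 100L, patience = 100L,
                      eval_every = 20L)
  rep1 <- run_cross_validation(feats, plan, cfg, master_seed = 8L)

  expect_identical(nrow(rep1$experiments), 10L)
  expect_identical(rep1$n_experiments, 10L)
  with(rep1$experiments, {
    sizes <- tp + tn + fp + fn
    for (r in 1:2)
      expect_identical(as.integer(sizes[repeat_i == r]), fold_sizes(plan, r))
  })
  # macro aggregate equals the unweighted mean of per-experiment metrics
  expect_identical(rep1$aggregate$accuracy, mean(rep1$experiments$accuracy))
  expect_identical(rep1$aggregate$sensitivity,
                   mean(rep1$experiments$sensitivity, na.rm = TRUE))

  # bit-exact reproducibility under the same master seed
  rep2 <- run_cross_validation(feats, plan, cfg, master_seed = 8L)
  expect_identical(rep1$experiments, rep2$experiments)

  # pooled aggregation consistency
  rep3 <- run_cross_validation(feats, plan, cfg, master_seed = 8L,
                               aggregate = "pooled")
  expect_equal(rep3$aggregate$accuracy,
               with(rep1$experiments, sum(tp + tn) / sum(tp + tn + fp + fn)))

  path_csv <- withr::local_tempfile(fileext = ".csv")
  path_json <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep1, path_csv, path_json)
  summ <- jsonlite::read_json(path_json)
  expect_equal(summ$accuracy, rep1$aggregate$accuracy)
  expect_equal(summ$n_experiments, 10L)
})

test_that("the held-out fold never influences gradient updates", {
  co <- small_cohort(5L, 5L, effect = 0.5, seed = 12L)
  feats <- cohort_features(co)
  d <- enosepipe:::split_xy(feats)
  cfg <- train_config(max_epochs = 100L, min_epochs = 100L, patience = 1000L,
                      eval_every = 100L) # single evaluation at the last epoch
  init <- mlp_init(227L, 100L, seed = 3L)
  fit_a <- mlp_train(init, d$x[1:6, ], d$y[1:6], d$x[7:8, ], d$y[7:8], cfg)
  fit_b <- mlp_train(init, d$x[1:6, ], d$y[1:6], d$x[9:10, ], d$y[9:10], cfg)
  # final-epoch snapshots identical although validation sets differ
  expect_identical(fit_a$model, fit_b$model)
})

test_that("three-way split mode trains, validates and tests on disjoint sets", {
  co <- small_cohort(8L, 7L, effect = 1, seed = 19L)
  feats <- cohort_features(co)
  plan <- make_cv_plan(feats$record_id, n_folds = 5L, n_repeats = 1L,
                       seed = 2L)
  cfg <- train_config(max_epochs = 200L, min_epochs = 100L, patience = 100L,
                      eval_every = 20L)
  rep3 <- run_cross_validation(feats, plan, cfg, master_seed = 5L,
                               validation = "three-way")
  expect_identical(nrow(rep3$experiments), 5L)
  with(rep3$experiments, expect_identical(as.integer(tp + tn + fp + fn),
                                          fold_sizes(plan, 1L)))
})
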