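# From-scratch sigmoid perceptron: forward closed forms, gradient
# correctness, early stopping, determinism.

test_that("forward pass matches closed forms and the tie rule", {
  zero <- mlp_init(227L, 454L, seed = 1L)
  zero$W1[] <- 0; zero$b1[] <- 0; zero$W2[] <- 0; zero$b2 <- 0
  x <- rnorm(227)
  expect_identical(mlp_forward(zero, x), 0.5)
  expect_identical(mlp_classify(zero, x), 1L) # >= threshold convention

  sat <- zero
  sat$b2 <- 500
  expect_equal(mlp_forward(sat, x), 1.0, tolerance = 1e-12)
  expect_identical(mlp_classify(sat, x), 1L)

  expect_error(mlp_forward(zero, c(NA, rnorm(226))),
               class = "enose_contract_error")
  expect_error(mlp_forward(zero, rnorm(10)), class = "enose_contract_error")
})

test_that("vectorized forward agrees with a two-loop evaluator to 1e-12", {
  withr::with_seed(11L, {
    for (rep_i in 1:5) {
      n_in <- sample(3:12, 1); n_hid <- sample(2:9, 1)
      m <- mlp_init(n_in, n_hid, seed = rep_i)
      x <- rnorm(n_in, sd = 2)
      expect_equal(mlp_forward(m, x), forward_two_loop(m, x),
                   tolerance = 1e-12)
    }
  })
})

test_that("backprop gradients match central differences to 1e-6 for both losses", {
  withr::with_seed(4L, {
    n_in <- 10L; n_hid <- 4L; n <- 12L
    x <- matrix(rnorm(n * n_in), n)
    y <- rep(c(0, 1), length.out = n)
    for (loss in c("cross-entropy", "mse")) {
      m <- mlp_init(n_in, n_hid, seed = 8L)
      ga <- analytic_gradient(m, x, y, loss)
      gn <- numeric_gradient(flatten_params(m), x, y, n_in, n_hid, loss)
      rel <- sqrt(sum((ga - gn)^2)) / max(sqrt(sum(ga^2)), sqrt(sum(gn^2)))
      expect_lt(rel, 1e-6)
    }
  })
})

test_that("training is deterministic and full-batch loss is monotone at small lr", {
  withr::with_seed(2L, {
    x <- matrix(rnorm(20 * 6), 20)
    y <- as.numeric(x[, 1] + 0.5 * x[, 2] > 0)
  })
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 300L,
                      min_epochs = 300L, patience = 1000L, eval_every = 10L)
  f1 <- mlp_train(mlp_init(6L, 12L, seed = 3L), x, y, x, y, cfg)
  f2 <- mlp_train(mlp_init(6L, 12L, seed = 3L), x, y, x, y, cfg)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(diff(f1$trace$train_loss) <= 1e-12))
})

test_that("separable synthetic classes reach high held-out accuracy", {
  co <- small_cohort(8L, 8L, effect = 2, seed = 5L, noise_sd = 2,
                     subject_sd = 0.05, demographics = "balanced")
  feats <- cohort_features(co)
  d <- enosepipe:::split_xy(feats)
  train <- c(1:5, 9:13); val <- setdiff(1:16, train)
  fit <- mlp_train(mlp_init(227L, 454L, seed = 1L),
                   d$x[train, ], d$y[train], d$x[val, ], d$y[val],
                   train_config(max_epochs = 2000L, min_epochs = 200L,
                                patience = 200L, eval_every = 20L))
  acc <- mean(mlp_classify(fit$model, d$x[val, ]) == d$y[val])
  expect_gte(acc, 0.95)
  expect_lte(fit$stop_epoch, 8000L)
})

test_that("shuffled labels keep held-out accuracy at the permutation null", {
  co <- small_cohort(10L, 10L, effect = 1, seed = 6L,
                     demographics = "balanced")
  feats <- cohort_features(co)
  d <- enosepipe:::split_xy(feats)
  y_shuf <- withr::with_seed(9L, sample(d$y))
  train <- 1:12; val <- 13:20
  fit <- mlp_train(mlp_init(227L, 454L, seed = 2L),
                   d$x[train, ], y_shuf[train], d$x[val, ], y_shuf[val],
                   train_config(max_epochs = 600L, min_epochs = 600L,
                                patience = 1000L, eval_every = 200L))
  best_acc <- max(fit$trace$val_acc)
  p_maj <- max(mean(y_shuf[val]), 1 - mean(y_shuf[val]))
  band <- 1.96 * sqrt(p_maj * (1 - p_maj) / length(val))
  expect_lte(best_acc, p_maj + band + 0.25) # small-sample slack: 8 held out
  expect_gte(best_acc, p_maj - band - 0.25)
})

test_that("non-finite loss raises a divergence error naming epoch and rate", {
  x <- matrix(rnorm(10 * 4), 10)
  y <- rep(c(0, 1), 5)
  m <- mlp_init(4L, 3L, seed = 1L)
  m$W1[1, 1] <- NaN
  err <- tryCatch(
    mlp_train(m, x, y, x, y,
              train_config(max_epochs = 10L, min_epochs = 1L,
                           eval_every = 1L)),
    condition = function(e) e)
  expect_s3_class(err, "enose_divergence_error")
  expect_match(conditionMessage(err), "epoch")
})

test_that("models serialize to JSON and back without changing predictions", {
  m <- mlp_init(9L, 5L, seed = 44L)
  path <- withr::local_tempfile(fileext = ".json")
  mlp_save(m, path, extra = list(note = "unit"))
  back <- mlp_load(path)
  x <- matrix(rnorm(3 * 9), 3)
  expect_equal(mlp_forward(back, x), mlp_forward(m, x), tolerance = 1e-15)
  expect_identical(attr(back, "extra")$note, "unit")
})
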