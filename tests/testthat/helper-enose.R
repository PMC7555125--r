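# Shared fixtures and independent oracles, built in code at test time.

# Deterministic, noise-free configuration: every generated value follows the
# closed-form generative signal exactly.
clean_config <- function(...) {
  synth_config(n_cancer = 1L, n_control = 1L, noise_sd = 0,
               drift_per_cycle = 0, subject_sd = 0, seed = 42L, ...)
}

# Small stochastic cohort for pipeline-level tests.
small_cohort <- function(n1 = 6L, n0 = 5L, effect = 0.5, seed = 7L, ...) {
  generate_cohort(synth_config(n_cancer = n1, n_control = n0,
                               effect_size = effect, seed = seed, ...))
}

# Hand-built segmented record: cooling segments set directly, bypassing
# generation, for feature-level contract tests.
fake_segmented <- function(segments, label = 0L, age = 50, sex = "F",
                           smoking = "no") {
  n_cyc <- dim(segments)[2]
  cycles <- data.frame(cycle_index = seq_len(n_cyc),
                       heat_start = 45L + 270L * (seq_len(n_cyc) - 1L),
                       cool_start = 150L + 270L * (seq_len(n_cyc) - 1L),
                       cool_end = 315L + 270L * (seq_len(n_cyc) - 1L))
  structure(list(record_id = "fake", cycles = cycles,
                 cooling_segments = segments, age = age, sex = sex,
                 smoking = smoking, label = label),
            class = "segmented_record")
}

const_segments <- function(value = 1, n_cyc = 4L) {
  array(value, dim = c(14L, n_cyc, 165L),
        dimnames = list(sensor = enose_channel_names()[1:14],
                        cycle = NULL, sample = NULL))
}

# Independent two-loop forward oracle: no linear algebra shortcuts.
forward_two_loop <- function(model, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(model$n_hidden)
  for (j in seq_len(model$n_hidden)) {
    z <- model$b1[j]
    for (i in seq_len(model$n_in)) z <- z + model$W1[j, i] * x[i]
    h[j] <- sig(z)
  }
  z_out <- model$b2
  for (j in seq_len(model$n_hidden)) z_out <- z_out + model$W2[1, j] * h[j]
  sig(z_out)
}

# Loss of a parameter vector, for central-difference gradient checks.
flatten_params <- function(m) c(as.vector(m$W1), m$b1, as.vector(m$W2), m$b2)

unflatten_params <- function(theta, n_in, n_hidden) {
  i1 <- n_hidden * n_in
  structure(list(
    W1 = matrix(theta[1:i1], n_hidden, n_in),
    b1 = theta[(i1 + 1):(i1 + n_hidden)],
    W2 = matrix(theta[(i1 + n_hidden + 1):(i1 + 2 * n_hidden)], 1L, n_hidden),
    b2 = theta[i1 + 2 * n_hidden + 1],
    n_in = n_in, n_hidden = n_hidden), class = "mlp_model")
}

batch_loss <- function(theta, x, y, n_in, n_hidden, loss) {
  m <- unflatten_params(theta, n_in, n_hidden)
  p <- mlp_forward(m, x)
  if (loss == "cross-entropy") {
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(pc) + (1 - y) * log(1 - pc))
  } else {
    mean((p - y)^2)
  }
}

# Analytic full-batch gradient recovered from one gradient-descent step.
analytic_gradient <- function(model, x, y, loss) {
  lr <- 1e-3
  cfg <- train_config(learning_rate = lr, max_epochs = 1L, min_epochs = 1L,
                      patience = 10L, eval_every = 1L, loss = loss)
  fit <- mlp_train(model, x, y, x, y, cfg)
  (flatten_params(model) - flatten_params(fit$model)) / lr
}

numeric_gradient <- function(theta, x, y, n_in, n_hidden, loss, h = 1e-5) {
  g <- numeric(length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    g[k] <- (batch_loss(tp, x, y, n_in, n_hidden, loss) -
             batch_loss(tm, x, y, n_in, n_hidden, loss)) / (2 * h)
  }
  g
}

# Reduced-epoch training profile used for cohort-scale experiments in the
# suite; keeps the protocol's 500-epoch minimum before early stopping.
reduced_profile <- function(max_epochs = 1000L) {
  train_config(max_epochs = max_epochs, min_epochs = 500L, patience = 200L,
               eval_every = 20L)
}
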