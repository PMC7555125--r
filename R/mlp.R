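# One-hidden-layer sigmoid perceptron, written from scratch: 227 -> 454 -> 1
# with logistic activations on both layers, trained by full-batch gradient
# descent with backpropagation and early stopping on held-out accuracy.
# The hidden layer is fixed at twice the input dimension by default.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Signal a training-divergence error
#' @noRd
abort_divergence <- function(message, ...) {
  abort_enose(message, "enose_divergence_error", ...)
}

#' Initialize a perceptron model
#'
#' Weights are drawn uniformly in the Glorot bound
#' `+/- sqrt(6 / (fan_in + fan_out))` per layer; biases start at zero.
#'
#' @param n_in input dimension (default 227).
#' @param n_hidden hidden dimension (default `2 * n_in` = 454).
#' @param seed integer RNG seed for the draw.
#' @return an object of class `mlp_model`: `W1` (`n_hidden x n_in`), `b1`,
#'   `W2` (`1 x n_hidden`), `b2`.
#' @export
mlp_init <- function(n_in = 227L, n_hidden = 2L * n_in, seed = 1L) {
  lim1 <- sqrt(6 / (n_in + n_hidden))
  lim2 <- sqrt(6 / (n_hidden + 1))
  with_seed(seed, {
    structure(
      list(
        W1 = matrix(runif(n_hidden * n_in, -lim1, lim1), n_hidden, n_in),
        b1 = numeric(n_hidden),
        W2 = matrix(runif(n_hidden, -lim2, lim2), 1L, n_hidden),
        b2 = 0,
        n_in = as.integer(n_in), n_hidden = as.integer(n_hidden)
      ),
      class = "mlp_model"
    )
  })
}

#' Forward pass
#'
#' `sigma(W2 . sigma(W1 x + b1) + b2)` with the logistic sigmoid on both
#' layers; numerically stable over the full double range (saturates cleanly
#' to 0/1).
#'
#' @param model an `mlp_model`.
#' @param x numeric vector of length `n_in`, or a matrix with one row per
#'   observation.
#' @return vector of probabilities in `(0, 1)` (one per row).
#' @export
mlp_forward <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_in)
    abort_contract(sprintf("input has %d columns, model expects %d",
                           ncol(x), model$n_in))
  if (!all(is.finite(x))) abort_contract("input contains non-finite values")
  h <- sigmoid(sweep(x %*% t(model$W1), 2L, model$b1, "+"))
  as.vector(sigmoid(h %*% t(model$W2) + model$b2))
}

#' Classify with a decision threshold
#'
#' @param model an `mlp_model`.
#' @param x input vector or matrix.
#' @param threshold decision threshold (default 0.5); outputs `>=` the
#'   threshold map to class 1.
#' @return integer vector of 0/1 labels.
#' @export
mlp_classify <- function(model, x, threshold = 0.5) {
  as.integer(mlp_forward(model, x) >= threshold)
}

#' Training configuration
#'
#' @param learning_rate gradient-descent step size (default 0.05).
#' @param max_epochs hard epoch cap (default 8000).
#' @param min_epochs epochs before early stopping may trigger (default 500).
#' @param patience evaluations-without-improvement window, in epochs
#'   (default 200).
#' @param eval_every held-out evaluation cadence in epochs (default 10).
#' @param loss `"cross-entropy"` (default) or `"mse"`.
#' @param seed seed for weight initialization.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, max_epochs = 8000L,
                         min_epochs = 500L, patience = 200L,
                         eval_every = 10L, loss = c("cross-entropy", "mse"),
                         seed = 1L) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) abort_contract("learning_rate must be > 0")
  if (min_epochs > max_epochs)
    abort_contract("min_epochs must be <= max_epochs")
  structure(
    list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         min_epochs = as.integer(min_epochs), patience = as.integer(patience),
         eval_every = as.integer(eval_every), loss = loss,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

loss_value <- function(p, y, loss) {
  if (loss == "cross-entropy") {
    pc <- clamp(p, 1e-12, 1 - 1e-12)
    -mean(y * log(pc) + (1 - y) * log(1 - pc))
  } else {
    mean((p - y)^2)
  }
}

#' Train by full-batch backpropagation with early stopping
#'
#' Plain full-batch gradient descent on the chosen loss with 0/1 targets.
#' Every `eval_every` epochs the held-out accuracy is evaluated; training
#' stops at `max_epochs`, or once no held-out improvement has been seen for
#' `patience` epochs after `min_epochs`. The returned model is the
#' parameter snapshot at the best held-out accuracy (ties broken toward the
#' earliest epoch) — the operational form of stopping when training error
#' still falls but held-out error starts to rise.
#'
#' @param model an `mlp_model` (e.g. from [mlp_init()]).
#' @param x,y training inputs (matrix, rows = observations) and 0/1 labels.
#' @param x_val,y_val held-out set used for early stopping.
#' @param config a [train_config()].
#' @return list with `model` (best snapshot), `trace` (data.frame: epoch,
#'   train_loss, train_acc, val_acc), `best_epoch`, `stop_epoch`.
#' @export
mlp_train <- function(model, x, y, x_val, y_val, config = train_config()) {
  if (!nrow(x) || !nrow(x_val)) abort_contract("training and held-out sets must be non-empty")
  if (nrow(x) != length(y) || nrow(x_val) != length(y_val))
    abort_contract("label length must match input rows")
  W1 <- model$W1; b1 <- model$b1; W2 <- model$W2; b2 <- model$b2
  n <- nrow(x)
  lr <- config$learning_rate
  best <- list(acc = -Inf, epoch = 0L, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  trace <- vector("list", config$max_epochs %/% config$eval_every + 1L)
  t_i <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    h <- sigmoid(sweep(x %*% t(W1), 2L, b1, "+"))     # n x H
    p <- as.vector(sigmoid(h %*% t(W2) + b2))         # n
    delta_out <- if (config$loss == "cross-entropy") {
      (p - y) / n
    } else {
      2 * (p - y) * p * (1 - p) / n
    }
    dW2 <- crossprod(matrix(delta_out, ncol = 1L), h)  # 1 x H
    db2 <- sum(delta_out)
    delta_h <- (delta_out %o% as.vector(W2)) * h * (1 - h)  # n x H
    dW1 <- crossprod(delta_h, x)                       # H x n_in
    db1 <- colSums(delta_h)

    W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
    W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2

    if (epoch %% config$eval_every == 0L || epoch == config$max_epochs) {
      cur <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                  n_in = model$n_in, n_hidden = model$n_hidden)
      class(cur) <- "mlp_model"
      tr_loss <- loss_value(mlp_forward(cur, x), y, config$loss)
      if (!is.finite(tr_loss)) {
        abort_divergence(sprintf(
          "non-finite training loss at epoch %d (learning rate %g)",
          epoch, lr))
      }
      tr_acc <- mean(as.integer(mlp_forward(cur, x) >= 0.5) == y)
      va_acc <- mean(as.integer(mlp_forward(cur, x_val) >= 0.5) == y_val)
      t_i <- t_i + 1L
      trace[[t_i]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                 train_acc = tr_acc, val_acc = va_acc)
      if (va_acc > best$acc) {
        best <- list(acc = va_acc, epoch = epoch,
                     W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      }
      if (epoch >= config$min_epochs && epoch - best$epoch >= config$patience)
        break
    }
  }

  out <- structure(
    list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
         n_in = model$n_in, n_hidden = model$n_hidden),
    class = "mlp_model"
  )
  list(model = out, trace = do.call(rbind, trace[seq_len(t_i)]),
       best_epoch = best$epoch, stop_epoch = trace[[t_i]]$epoch)
}

#' Serialize / restore a model as JSON
#'
#' Stores shapes and parameters at full precision, plus any training trace
#' or configuration supplied.
#'
#' @param model an `mlp_model`.
#' @param path JSON file path.
#' @param extra optional named list (e.g. config, trace) stored alongside.
#' @return `mlp_load` returns the `mlp_model` (extras as attribute
#'   `"extra"`).
#' @export
mlp_save <- function(model, path, extra = NULL) {
  obj <- list(
    n_in = model$n_in, n_hidden = model$n_hidden,
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    extra = extra
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname mlp_save
#' @export
mlp_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(w, nr) {
    if (is.matrix(w)) w else matrix(unlist(w), nrow = nr, byrow = TRUE)
  }
  model <- structure(
    list(W1 = as_mat(obj$W1, obj$n_hidden),
         b1 = as.numeric(obj$b1),
         W2 = as_mat(obj$W2, 1L),
         b2 = as.numeric(obj$b2),
         n_in = as.integer(obj$n_in), n_hidden = as.integer(obj$n_hidden)),
    class = "mlp_model"
  )
  attr(model, "extra") <- obj$extra
  model
}
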