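# Calibration: sensor-wise train/test splitting and a small multilayer
# perceptron (9 inputs, two log-sigmoid hidden layers, linear output)
# trained by full-batch backpropagation on mean squared error, mapping the
# hybrid colour descriptor to pH.

#' MLP configuration
#'
#' @param hidden_sizes two positive hidden-layer widths.
#' @param max_iters iteration cap (default 10,000).
#' @param error_limit stop when training MSE (on z-scored targets' scale,
#'   i.e. raw pH units squared) falls below this.
#' @param learning_rate gradient step size.
#' @param momentum classical momentum coefficient.
#' @param seed weight-initialisation seed.
#' @export
mlp_config <- function(hidden_sizes = c(10L, 5L), max_iters = 10000L,
                       error_limit = 1e-6, learning_rate = 0.05,
                       momentum = 0.9, seed = 1L) {
  if (length(hidden_sizes) != 2L || any(hidden_sizes < 1L)) {
    stop("exactly two positive hidden layer sizes required")
  }
  if (error_limit <= 0) stop("error_limit must be > 0")
  list(hidden_sizes = as.integer(hidden_sizes), max_iters = as.integer(max_iters),
       error_limit = error_limit, learning_rate = learning_rate,
       momentum = momentum, seed = as.integer(seed))
}

logsig <- function(x) 1 / (1 + exp(-x))

#' Split a descriptor table by sensor identity
#'
#' Whole sensors are held out (default 2 of every 6) so the test set
#' simulates genuinely unseen devices; every sensor must carry all pH
#' levels.
#'
#' @param data data.frame with columns `sensor`, `ph` and descriptor
#'   columns.
#' @param n_test number of held-out sensors.
#' @param seed selection seed.
#' @return list `train`, `test`, `test_sensors`.
#' @export
split_dataset <- function(data, n_test = 2L, seed = 1L) {
  sensors <- unique(data$sensor)
  if (length(sensors) < 3L) stop("need at least 3 sensors")
  levels_per <- table(data$sensor, data$ph) > 0
  if (!all(levels_per)) stop("every sensor must have every pH level")
  set.seed(derive_subseed(seed, 2026L))
  test_sensors <- sort(sample(sensors, n_test))
  list(train = data[!data$sensor %in% test_sensors, , drop = FALSE],
       test = data[data$sensor %in% test_sensors, , drop = FALSE],
       test_sensors = test_sensors)
}

#' Train the calibration MLP
#'
#' Inputs are z-scored with training statistics (stored in the model);
#' weights follow scaled uniform initialisation; training is full-batch
#' gradient descent with momentum on the mean squared error, stopping at
#' `max_iters` or when the MSE drops below `error_limit`.
#'
#' @param x n x 9 descriptor matrix.
#' @param y length-n target values (pH).
#' @param config [mlp_config()].
#' @return object of class `calibration_model` with weights, biases,
#'   standardisation parameters and `training_history`.
#' @export
train_mlp <- function(x, y, config = mlp_config()) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nrow(x) == 0L) stop("empty training set")
  if (anyNA(x) || anyNA(y)) stop("NA in training data")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl < 1e-9] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  n_in <- ncol(z); h1 <- config$hidden_sizes[1]; h2 <- config$hidden_sizes[2]
  set.seed(derive_subseed(config$seed, 313L))
  rw <- function(nr, nc) matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  w1 <- rw(n_in, h1); b1 <- numeric(h1)
  w2 <- rw(h1, h2); b2 <- numeric(h2)
  w3 <- rw(h2, 1); b3 <- 0
  v <- list(w1 = 0 * w1, b1 = 0 * b1, w2 = 0 * w2, b2 = 0 * b2, w3 = 0 * w3, b3 = 0)
  n <- nrow(z)
  lr <- config$learning_rate; mom <- config$momentum
  mse <- NA_real_; prev_mse <- Inf; it_done <- 0L
  for (it in seq_len(config$max_iters)) {
    a1 <- logsig(sweep(z %*% w1, 2, b1, "+"))
    a2 <- logsig(sweep(a1 %*% w2, 2, b2, "+"))
    out <- drop(a2 %*% w3) + b3
    err <- out - y
    mse <- mean(err^2)
    it_done <- it
    if (!is.finite(mse)) stop("divergence: non-finite loss; lower the learning rate")
    if (mse < config$error_limit) break
    # bold-driver step control: back off (and drop momentum) when the
    # full-batch loss rises, so late-stage oscillation cannot stall descent
    if (mse > prev_mse) {
      lr <- lr * 0.7
      v <- lapply(v, function(m) m * 0)
    } else {
      lr <- min(lr * 1.01, config$learning_rate * 10)
    }
    prev_mse <- mse
    d_out <- matrix(2 * err / n, ncol = 1)
    g_w3 <- t(a2) %*% d_out; g_b3 <- sum(d_out)
    d2 <- (d_out %*% t(w3)) * a2 * (1 - a2)
    g_w2 <- t(a1) %*% d2; g_b2 <- colSums(d2)
    d1 <- (d2 %*% t(w2)) * a1 * (1 - a1)
    g_w1 <- t(z) %*% d1; g_b1 <- colSums(d1)
    v$w3 <- mom * v$w3 - lr * g_w3; w3 <- w3 + v$w3
    v$b3 <- mom * v$b3 - lr * g_b3; b3 <- b3 + v$b3
    v$w2 <- mom * v$w2 - lr * g_w2; w2 <- w2 + v$w2
    v$b2 <- mom * v$b2 - lr * g_b2; b2 <- b2 + v$b2
    v$w1 <- mom * v$w1 - lr * g_w1; w1 <- w1 + v$w1
    v$b1 <- mom * v$b1 - lr * g_b1; b1 <- b1 + v$b1
  }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, w3 = w3, b3 = b3,
                 centering = ctr, scaling = scl,
                 training_history = list(iterations = it_done, final_mse = mse),
                 config = config),
            class = "calibration_model")
}

#' Predict pH from descriptors
#'
#' Forward pass through the trained network.  Predictions outside the
#' plausible operating window `[2.5, 7.0]` are returned but flagged.
#'
#' @param model a `calibration_model`.
#' @param x length-9 descriptor or m x 9 matrix.
#' @return numeric predictions with attribute `out_of_range` (logical).
#' @export
predict_ph <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, 1)
  if (ncol(x) != length(model$centering)) stop("descriptor length mismatch")
  if (anyNA(x)) stop("NA in descriptor")
  z <- sweep(sweep(x, 2, model$centering), 2, model$scaling, "/")
  a1 <- logsig(sweep(z %*% model$w1, 2, model$b1, "+"))
  a2 <- logsig(sweep(a1 %*% model$w2, 2, model$b2, "+"))
  out <- drop(a2 %*% model$w3) + model$b3
  attr(out, "out_of_range") <- out < 2.5 | out > 7.0
  out
}

#' Evaluate predictions on a held-out set
#'
#' @param model a `calibration_model`.
#' @param x m x 9 descriptor matrix.
#' @param y true values.
#' @return list `rmse`, `r2`, `table` (true, predicted, residual), and
#'   `per_level` mean residual by true value.
#' @export
evaluate_mlp <- function(model, x, y) {
  if (length(y) == 0L) stop("empty test set")
  pred <- as.numeric(predict_ph(model, as.matrix(x)))
  resid <- pred - y
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  tab <- data.frame(true_ph = y, predicted_ph = pred, residual = resid)
  per_level <- stats::aggregate(residual ~ true_ph, tab, mean)
  list(rmse = sqrt(mean(resid^2)), r2 = r2, table = tab, per_level = per_level)
}

#' Serialise / restore a calibration model as JSON
#' @param model a `calibration_model`.
#' @param path JSON path.
#' @export
write_calibration_model <- function(model, path) {
  jsonlite::write_json(list(
    w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    w3 = as.numeric(model$w3), b3 = model$b3,
    centering = model$centering, scaling = model$scaling,
    training_history = model$training_history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w1 = as.matrix(j$w1), b1 = j$b1, w2 = as.matrix(j$w2),
                 b2 = j$b2, w3 = matrix(j$w3, ncol = 1), b3 = j$b3,
                 centering = j$centering, scaling = j$scaling,
                 training_history = j$training_history),
            class = "calibration_model")
}
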