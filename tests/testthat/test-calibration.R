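# Synthetic descriptor <-> pH dataset mimicking the simulator's monotone
# hue map: deterministic smooth features of pH plus optional noise.
descriptor_dataset <- function(n_sensors = 6L, ph_levels = holoquant:::PH_LEVELS,
                               noise_sd = 0, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_sensors)) {
    off <- rnorm(1, 0, 0.02)
    for (ph in ph_levels) {
      h <- ph_to_hue(ph)
      base <- c(cos(h * pi / 180), sin(h * pi / 180), h / 360,
                0.8, 0.5, 0.4, 60 - h / 10, 20 * cos(h * pi / 180),
                -30 * sin(h * pi / 180))
      rows[[length(rows) + 1L]] <- data.frame(
        sensor = s, ph = ph,
        t(base + off + rnorm(9, 0, noise_sd)))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:11] <- holoquant:::descriptor_cols()
  out
}

test_that("dataset splitting holds out whole sensors with all levels", {
  d <- descriptor_dataset()
  sp <- split_dataset(d, n_test = 2, seed = 3)
  expect_equal(nrow(sp$train), 44)  # 4 sensors x 11 levels
  expect_equal(nrow(sp$test), 22)   # 2 sensors x 11 levels
  expect_length(intersect(unique(sp$train$sensor), unique(sp$test$sensor)), 0)
  sp2 <- split_dataset(d, n_test = 2, seed = 3)
  expect_identical(sp$test_sensors, sp2$test_sensors)
  expect_error(split_dataset(d[d$sensor <= 2, ], seed = 1), "3 sensors")
  # missing level detection
  expect_error(split_dataset(d[-5, ], seed = 1), "every pH level")
})

test_that("the MLP represents constants and learns the noiseless map", {
  d <- descriptor_dataset(n_sensors = 4, noise_sd = 0, seed = 2)
  x <- as.matrix(d[, holoquant:::descriptor_cols()])
  m_const <- train_mlp(x, rep(4.2, nrow(x)), mlp_config(seed = 1))
  # the stopping rule is MSE < 1e-6, i.e. RMSE below 1e-3
  expect_lt(sqrt(mean((predict_ph(m_const, x) - 4.2)^2)), 1e-3)
  m <- train_mlp(x, d$ph, mlp_config(seed = 4))
  rmse <- sqrt(mean((predict_ph(m, x) - d$ph)^2))
  expect_lt(rmse, 0.05)
  # training point predicted back
  expect_lt(abs(predict_ph(m, x[7, ]) - d$ph[7]), 0.05)
})

test_that("training is deterministic and stops on the error limit", {
  d <- descriptor_dataset(n_sensors = 3, seed = 5)
  x <- as.matrix(d[, holoquant:::descriptor_cols()])
  m1 <- train_mlp(x, d$ph, mlp_config(seed = 11))
  m2 <- train_mlp(x, d$ph, mlp_config(seed = 11))
  expect_identical(m1$w1, m2$w1)
  expect_identical(m1$w3, m2$w3)
  loose <- train_mlp(x, d$ph, mlp_config(seed = 11, error_limit = 0.25))
  expect_lt(loose$training_history$iterations,
            m1$training_history$iterations)
  expect_lt(loose$training_history$final_mse, 0.25)
})

test_that("a linear target is matched almost perfectly", {
  set.seed(6)
  x <- matrix(runif(80 * 9), 80, 9)
  beta <- runif(9, -1, 1)
  y <- drop(x %*% beta) + 2
  m <- train_mlp(x, y, mlp_config(seed = 2))
  pred <- predict_ph(m, x)
  r2 <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  expect_gte(r2, 0.999)
})

test_that("prediction validates input and flags out-of-range values", {
  d <- descriptor_dataset(n_sensors = 3, seed = 7)
  x <- as.matrix(d[, holoquant:::descriptor_cols()])
  m <- train_mlp(x, d$ph, mlp_config(seed = 3, max_iters = 500))
  expect_error(predict_ph(m, x[1, 1:5]), "length")
  bad <- x[1, ]; bad[4] <- NA
  expect_error(predict_ph(m, bad), "NA")
  p <- predict_ph(m, x[1:5, ])
  expect_length(attr(p, "out_of_range"), 5)
})

test_that("training loss is nonincreasing for a small learning rate", {
  set.seed(8)
  x <- matrix(runif(30 * 9), 30, 9)
  y <- rowSums(x[, 1:3])
  losses <- vapply(c(5, 25, 125, 625), function(iters) {
    train_mlp(x, y, mlp_config(seed = 4, max_iters = iters,
                               learning_rate = 0.002,
                               momentum = 0))$training_history$final_mse
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("standardisation is internal: raw descriptors predict directly", {
  d <- descriptor_dataset(n_sensors = 3, seed = 9)
  x <- as.matrix(d[, holoquant:::descriptor_cols()])
  m <- train_mlp(x, d$ph, mlp_config(seed = 5, max_iters = 2000))
  # applying the stored standardisation by hand and bypassing it must agree
  z <- sweep(sweep(x, 2, m$centering), 2, m$scaling, "/")
  m_raw <- m; m_raw$centering <- rep(0, 9); m_raw$scaling <- rep(1, 9)
  expect_equal(as.numeric(predict_ph(m_raw, z)),
               as.numeric(predict_ph(m, x)), tolerance = 1e-12)
})

test_that("held-out sensors are predicted within tolerance on noisy data", {
  rmses <- vapply(1:5, function(seed) {
    d <- descriptor_dataset(noise_sd = 0.01, seed = seed)
    sp <- split_dataset(d, n_test = 2, seed = seed)
    m <- train_mlp(as.matrix(sp$train[, holoquant:::descriptor_cols()]),
                   sp$train$ph, mlp_config(seed = seed))
    evaluate_mlp(m, as.matrix(sp$test[, holoquant:::descriptor_cols()]),
                 sp$test$ph)$rmse
  }, numeric(1))
  expect_lte(mean(rmses), 0.15)
})

test_that("evaluation metrics behave at the extremes", {
  d <- descriptor_dataset(n_sensors = 3, seed = 10)
  x <- as.matrix(d[, holoquant:::descriptor_cols()])
  m <- train_mlp(x, d$ph, mlp_config(seed = 6))
  ev <- evaluate_mlp(m, x, d$ph)
  expect_lt(ev$rmse, 0.05)
  expect_gt(ev$r2, 0.99)
  expect_equal(nrow(ev$per_level), length(unique(d$ph)))
  # a constant predictor scores R^2 <= 0
  m_const <- train_mlp(x, rep(5, nrow(x)), mlp_config(seed = 1, max_iters = 200))
  expect_lte(evaluate_mlp(m_const, x, d$ph)$r2, 0)
})

test_that("calibration model survives a JSON round trip", {
  d <- descriptor_dataset(n_sensors = 3, seed = 12)
  x <- as.matrix(d[, holoquant:::descriptor_cols()])
  m <- train_mlp(x, d$ph, mlp_config(seed = 2, max_iters = 300))
  path <- file.path(tempdir(), "mlp_rt.json")
  write_calibration_model(m, path)
  back <- read_calibration_model(path)
  expect_equal(as.numeric(predict_ph(back, x)),
               as.numeric(predict_ph(m, x)), tolerance = 1e-9)
  unlink(path)
})
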