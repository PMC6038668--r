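test_that("lagged regressor construction enumerates windows most-recent-first", {
  reg <- build_regressors(c(1, 2, 3, 4), order = 2)
  expect_equal(reg$X, matrix(c(2, 3, 1, 2), nrow = 2))
  expect_equal(reg$target, c(3, 4))
  expect_error(build_regressors(c(1, 2, 3), order = 3),
               class = "gaitnarx_insufficient_data_error")
  regc <- build_regressors(rep(5, 10), order = 2)
  expect_true(all(regc$X == 5) && all(regc$target == 5))
})

test_that("ARX on a noiseless AR(1) recovers the coefficient exactly", {
  y <- numeric(200)
  y[1] <- 1
  for (t in 2:200) y[t] <- 0.5 * y[t - 1]
  m <- fit_arx(y, order_na = 1)
  expect_equal(m$a, -0.5, tolerance = 1e-8)
  expect_lt(m$train_meta$vn, 1e-16)
})

test_that("ARX on a noisy AR(1) matches the normal-equations oracle on the same draw", {
  set.seed(314)
  n <- 1000
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.9 * y[t - 1] + rnorm(1, 0, 0.01)
  m <- fit_arx(y, order_na = 1)
  oracle <- oracle_ar_ls(y, 1)
  expect_equal(m$a, oracle$a, tolerance = 1e-8)
  expect_equal(m$c0, oracle$c0, tolerance = 1e-8)
  expect_true(m$a > -0.93 && m$a < -0.87)
})

test_that("ARX equals the normal-equations oracle on random signals at higher order", {
  for (s in 1:5) {
    set.seed(700 + s)
    y <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), n = 400)) +
      rnorm(400, 0, 0.05)
    m <- fit_arx(y, order_na = 4)
    oracle <- oracle_ar_ls(y, 4)
    expect_equal(m$a, oracle$a, tolerance = 1e-8)
  }
})

test_that("degenerate training signals are refused", {
  expect_error(fit_arx(rep(3, 100), order_na = 2),
               class = "gaitnarx_degenerate_signal_error")
  expect_error(fit_narx(rep(3, 100), order_n = 2, r = 2, seed = 1),
               class = "gaitnarx_degenerate_signal_error")
})

test_that("NARX recovers a planted model's one-step map on held-out data", {
  planted <- planted_narx()
  y <- sim_planted(planted, 2500, noise_sd = 0.01, seed = 123)
  fit <- fit_narx(y[1:2000], order_n = 3, r = 2, seed = 5, max_iter = 2000)
  held <- y[2001:2500]
  pred <- predict_series(fit, held)
  rmse <- sqrt(mean((pred[-(1:3)] - held[-(1:3)])^2))
  expect_lte(rmse, 2 * 0.01)
})

test_that("NARX training is bit-reproducible at a fixed seed", {
  spec <- cohort_spec(n_subjects = 1, seed = 3)
  y <- magnitude_series(generate_normal(spec, 1, 1))
  f1 <- fit_narx(y, order_n = 5, r = 4, seed = 17, max_iter = 100)
  f2 <- fit_narx(y, order_n = 5, r = 4, seed = 17, max_iter = 100)
  expect_identical(f1, f2)
  f3 <- fit_narx(y, order_n = 5, r = 4, seed = 18, max_iter = 100)
  expect_false(identical(f1$alpha, f3$alpha))
})

test_that("trained NARX objective is no worse than the best ARX of the same order", {
  spec <- cohort_spec(seed = 9)
  y <- lapply(1:3, function(tr) magnitude_series(generate_normal(spec, 1, tr)))
  narx <- fit_narx(y, order_n = 10, r = 20, seed = 2)
  arx <- fit_arx(y, order_na = 10)
  expect_lte(narx$train_meta$vn, arx$train_meta$vn + 1e-3)
})

test_that("one-step prediction de-normalizes correctly and honours its contract", {
  # all-zero output weights: prediction is the de-normalized zero = the mean
  m <- mk_narx(alpha = c(0, 0), B = matrix(0, 3, 2), c0 = 0,
               norm_mu = 9.5, norm_sd = 2)
  expect_equal(predict_one_step(m, c(1, 2)), 9.5)
  # identity ARX (a1 = -1, c0 = 0) reproduces its input through the z-score
  arx <- structure(list(kind = "arx", order = 1L, a = -1, c0 = 0, fs = 10,
                        norm_mu = 3, norm_sd = 2,
                        train_meta = list(vn = 0, n_train = 0L)),
                   class = c("arx_model", "gait_model"))
  expect_equal(predict_one_step(arx, 5), 5)
  expect_error(predict_one_step(arx, c(5, 6)), class = "gaitnarx_contract_error")
  # planted noiseless trajectory predicts itself
  planted <- planted_narx()
  y <- planted_trajectory(planted, 100)
  preds <- predict_series(planted, y)
  expect_lt(max(abs(preds[-(1:3)] - y[-(1:3)])), 1e-6)
})

test_that("RMSE and FIT match the printed formulas on hand-worked examples", {
  r1 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r1$rmse, 0)
  expect_equal(r1$fit, 1)
  r2 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 5))
  expect_equal(r2$rmse, sqrt(4 / 3))
  r3 <- goodness_of_fit(c(0, 2), c(0, 0))
  expect_equal(r3$rmse, sqrt(2))
  expect_equal(r3$fit, 1 - sqrt(2))   # prediction-sd denominator is 1
  # degenerate: constant predictions
  r4 <- goodness_of_fit(c(1, 1, 1), c(1, 2, 3))
  expect_true(r4$degenerate)
  expect_true(is.na(r4$fit))
  expect_error(goodness_of_fit(1:3, 1:4), class = "gaitnarx_contract_error")
  expect_error(goodness_of_fit(1, 1), class = "gaitnarx_insufficient_data_error")
})

test_that("FIT is at most 1, equal to 1 iff RMSE is 0, on random sequences", {
  for (s in 1:50) {
    set.seed(s)
    pred <- rnorm(20); meas <- rnorm(20)
    rep_ <- goodness_of_fit(pred, meas)
    expect_lte(rep_$fit, 1)
    expect_identical(rep_$fit == 1, rep_$rmse == 0)
  }
})

test_that("added measurement noise degrades FIT monotonically (majority direction)", {
  planted <- planted_narx()
  y <- planted_trajectory(planted, 120)
  preds <- predict_series(planted, y)
  keep <- 4:120
  grid <- c(0, 0.1, 0.2, 0.5)
  drops <- 0L
  for (s in 1:20) {
    set.seed(2000 + s)
    noise <- rnorm(length(keep))
    fits <- vapply(grid, function(sd_) {
      goodness_of_fit(preds[keep], y[keep] + sd_ * noise)$fit
    }, numeric(1))
    drops <- drops + as.integer(all(diff(fits) <= 1e-12))
  }
  expect_gte(drops, 11)  # majority of seeds strictly non-increasing
})
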