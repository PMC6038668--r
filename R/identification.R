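## Output-only ARX / NARX identification of the normal-walk acceleration
## signal, plus the RMSE/FIT goodness-of-fit statistics used by the online
## detector.
##
## Both model classes regress the next sample of the (z-scored) scalar
## acceleration signal on its `order` most recent values:
##   ARX :  yhat(t) = c0 - sum_k a_k y(t-k)          (left-hand-side sign
##          convention of the linear difference equation, so the stored a_k
##          are the negated regression coefficients)
##   NARX:  yhat(t) = c0 + sum_i alpha_i sigmoid(beta_i . [w(t-1); 1])
##          with w(t-1) = (y(t-1), ..., y(t-order)).
## There is no exogenous input: walking is modelled as an autonomous
## quasi-periodic process observed through a single acceleration channel.

#' Build lagged regressors and targets from a scalar signal
#'
#' Row `k` of the regressor matrix is `(y(k-1), ..., y(k-order))` — most
#' recent sample first — paired with target `y(k)`, for every `k` from
#' `order + 1` to `length(y)`.
#'
#' @param y numeric vector, length greater than `order`.
#' @param order number of past samples in the regressor window.
#' @return A list with `X` (matrix, `length(y) - order` rows by `order`
#'   columns) and `target` (numeric vector of next-sample values).
#' @examples
#' build_regressors(c(1, 2, 3, 4), order = 2)
#' @export
build_regressors <- function(y, order) {
  y <- as.numeric(y)
  order <- as.integer(order)
  if (order < 1L)
    stop_gaitnarx("`order` must be >= 1", "gaitnarx_contract_error")
  n <- length(y)
  if (n <= order)
    stop_gaitnarx(sprintf(
      "need more than `order` = %d samples to build regressors, got %d",
      order, n), "gaitnarx_insufficient_data_error")
  m <- n - order
  X <- matrix(0, nrow = m, ncol = order)
  for (k in seq_len(order)) X[, k] <- y[(order - k + 1):(n - k)]
  list(X = X, target = y[(order + 1):n])
}

## Regressors over one or more independent segments (e.g. separate training
## trials): no lag window ever spans a segment boundary.
build_regressors_multi <- function(segments, order) {
  if (!is.list(segments)) segments <- list(segments)
  parts <- lapply(segments, build_regressors, order = order)
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       target = unlist(lapply(parts, `[[`, "target"), use.names = FALSE))
}

norm_stats <- function(y) {
  mu <- mean(y)
  s <- sd(y)          # sample sd of the pooled training signal
  if (!is.finite(s) || s <= 0 || s < 1e-12 * max(1, abs(mu)))
    stop_gaitnarx("degenerate (constant or zero-variance) training signal",
                  "gaitnarx_degenerate_signal_error")
  list(mu = mu, sd = s)
}

#' Fit a linear ARX (autoregressive) model of a walking signal
#'
#' Ordinary least squares on the lagged regressors of the z-scored signal.
#' With no exogenous input the model reduces to a pure autoregression; the
#' coefficient vector `a` is stored in the left-hand-side sign convention of
#' the linear difference equation, so one-step prediction is
#' `yhat(t) = c0 - sum_k a_k * y(t-k)` (on the z-scored scale).
#'
#' @param y numeric vector (or list of vectors, one per training trial) of
#'   the scalar acceleration signal.
#' @param order_na model order: number of past outputs (poles).
#' @param fs sampling frequency in Hz recorded in the model.
#' @return An object of class `arx_model` with fields `order`, `a`, `c0`,
#'   `fs`, `norm_mu`, `norm_sd`, and `train_meta` (residual-variance
#'   objective `vn`, training size).
#' @seealso [fit_narx()], [predict_one_step()]
#' @export
fit_arx <- function(y, order_na = 10L, fs = 10) {
  order_na <- as.integer(order_na)
  segs <- if (is.list(y)) lapply(y, as.numeric) else list(as.numeric(y))
  pooled <- unlist(segs, use.names = FALSE)
  if (length(pooled) <= order_na + 10L)
    stop_gaitnarx(sprintf(
      "need more than order + 10 = %d samples to fit an ARX model, got %d",
      order_na + 10L, length(pooled)), "gaitnarx_insufficient_data_error")
  ns <- norm_stats(pooled)
  zsegs <- lapply(segs, function(s) (s - ns$mu) / ns$sd)
  reg <- build_regressors_multi(zsegs, order_na)
  A <- cbind(1, reg$X)
  fit <- stats::lm.fit(A, reg$target)
  if (fit$rank < ncol(A))
    stop_gaitnarx("rank-deficient regressor matrix (degenerate signal)",
                  "gaitnarx_degenerate_signal_error")
  coefs <- fit$coefficients
  res <- fit$residuals
  structure(
    list(kind = "arx", order = order_na,
         a = -unname(coefs[-1]), c0 = unname(coefs[1]),
         fs = fs, norm_mu = ns$mu, norm_sd = ns$sd,
         train_meta = list(vn = mean(res^2), n_train = length(reg$target))),
    class = c("arx_model", "gait_model"))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## theta layout: [alpha (r), c0, vec(B)] with B an (order+1) x r matrix whose
## last row is the per-unit bias.
narx_unpack <- function(theta, order, r) {
  list(alpha = theta[seq_len(r)],
       c0 = theta[r + 1L],
       B = matrix(theta[-seq_len(r + 1L)], nrow = order + 1L, ncol = r))
}

narx_objective <- function(theta, Xa, target, order, r) {
  p <- narx_unpack(theta, order, r)
  f <- drop(sigmoid(Xa %*% p$B) %*% p$alpha) + p$c0
  mean((target - f)^2)
}

narx_gradient <- function(theta, Xa, target, order, r) {
  p <- narx_unpack(theta, order, r)
  S <- sigmoid(Xa %*% p$B)
  f <- drop(S %*% p$alpha) + p$c0
  e <- f - target
  m <- length(target)
  g_alpha <- 2 / m * drop(crossprod(S, e))
  g_c0 <- 2 / m * sum(e)
  D <- (e %o% p$alpha) * S * (1 - S)      # m x r back-propagated error
  g_B <- 2 / m * crossprod(Xa, D)
  c(g_alpha, g_c0, as.vector(g_B))
}

#' Fit a NARX model of a walking signal
#'
#' Identifies the nonlinear autoregressive model
#' `yhat(t) = c0 + sum_i alpha_i * sigmoid(beta_i . [w(t-1); 1])` on the
#' z-scored signal by minimizing the mean squared one-step prediction error
#' (the least-squares prediction-error criterion). The objective is
#' nonconvex, so the optimizer — analytic-gradient BFGS from seeded
#' small-weight initializations — keeps the best of `n_starts` deterministic
#' restarts; the fit is bit-reproducible given `(y, order_n, r, seed,
#' max_iter, n_starts)`.
#'
#' @param y numeric vector (or list of vectors, one per training trial) of
#'   the scalar acceleration signal.
#' @param order_n regressor length (number of past samples); default 10, the
#'   operating point used throughout the package.
#' @param r number of sigmoid basis functions; default 20.
#' @param seed integer seed for weight initialization.
#' @param max_iter BFGS iteration cap per restart.
#' @param n_starts number of seeded restarts (best objective kept).
#' @param fs sampling frequency in Hz recorded in the model.
#' @return An object of class `narx_model` with fields `order`, `r`,
#'   `alpha` (length `r`), `beta` (`(order+1) x r` matrix, bias last row),
#'   `c0`, `fs`, `norm_mu`, `norm_sd`, and `train_meta` (`seed`,
#'   `iterations`, final objective `vn`, `converged`, chosen start index).
#' @seealso [fit_arx()], [predict_one_step()], [classify_stream()]
#' @export
fit_narx <- function(y, order_n = 10L, r = 20L, seed = 1L, max_iter = 500L,
                     n_starts = 3L, fs = 10) {
  order_n <- as.integer(order_n); r <- as.integer(r)
  if (r < 1L) stop_gaitnarx("`r` must be >= 1", "gaitnarx_contract_error")
  segs <- if (is.list(y)) lapply(y, as.numeric) else list(as.numeric(y))
  pooled <- unlist(segs, use.names = FALSE)
  if (length(pooled) <= order_n + 20L)
    stop_gaitnarx(sprintf(
      "need more than order + 20 = %d samples to fit a NARX model, got %d",
      order_n + 20L, length(pooled)), "gaitnarx_insufficient_data_error")
  ns <- norm_stats(pooled)
  zsegs <- lapply(segs, function(s) (s - ns$mu) / ns$sd)
  reg <- build_regressors_multi(zsegs, order_n)
  Xa <- cbind(reg$X, 1)
  npar <- r + 1L + (order_n + 1L) * r

  best <- NULL
  for (start in seq_len(n_starts)) {
    theta0 <- with_seed(derive_seed(seed, 7919, start), {
      c(runif(r, -0.5, 0.5),                              # alpha
        0,                                                # c0
        runif((order_n + 1L) * r, -0.7, 0.7) / sqrt(order_n + 1L))
    })
    opt <- stats::optim(theta0, fn = narx_objective, gr = narx_gradient,
                        Xa = Xa, target = reg$target, order = order_n, r = r,
                        method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-8))
    if (!is.finite(opt$value))
      stop_gaitnarx(sprintf(
        "non-finite objective during NARX optimization (start %d after %d evaluations)",
        start, opt$counts[["function"]]), "gaitnarx_optimization_failure_error")
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$start <- start
    }
  }
  p <- narx_unpack(best$par, order_n, r)
  structure(
    list(kind = "narx", order = order_n, r = r,
         alpha = p$alpha, beta = p$B, c0 = p$c0, basis = "sigmoid",
         fs = fs, norm_mu = ns$mu, norm_sd = ns$sd,
         train_meta = list(seed = as.integer(seed),
                           iterations = unname(best$counts[["function"]]),
                           vn = best$value,
                           converged = best$convergence == 0L,
                           start = best$start,
                           n_train = length(reg$target))),
    class = c("narx_model", "gait_model"))
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<%s_model> order=%d%s fs=%g Hz, V_N=%.6g (n=%d)\n",
              x$kind, x$order,
              if (x$kind == "narx") sprintf(" r=%d basis=%s", x$r, x$basis) else "",
              x$fs, x$train_meta$vn, x$train_meta$n_train))
  invisible(x)
}

## One-step prediction on the z-scored scale from a regressor matrix whose
## rows are (y(t-1), ..., y(t-order)), already z-scored.
predict_z <- function(model, Xz) {
  if (model$kind == "arx") {
    drop(Xz %*% (-model$a)) + model$c0
  } else {
    drop(sigmoid(cbind(Xz, 1) %*% model$beta) %*% model$alpha) + model$c0
  }
}

#' One-step-ahead prediction from measured history
#'
#' Open-loop prediction: always conditions on the measured history, never on
#' the model's own previous predictions (the sliding prediction window of the
#' online detector moves over measured samples).
#'
#' @param model an `arx_model` or `narx_model`.
#' @param history numeric vector of the `model$order` most recent measured
#'   samples in chronological order (oldest first), in original units.
#' @return The predicted next sample, in original (de-normalized) units.
#' @export
predict_one_step <- function(model, history) {
  stopifnot(inherits(model, "gait_model"))
  history <- as.numeric(history)
  if (length(history) != model$order)
    stop_gaitnarx(sprintf("`history` must have length %d (model order), got %d",
                          model$order, length(history)),
                  "gaitnarx_contract_error")
  if (!all(is.finite(history)))
    stop_gaitnarx("`history` contains non-finite values", "gaitnarx_contract_error")
  z <- (rev(history) - model$norm_mu) / model$norm_sd
  model$norm_mu + model$norm_sd * predict_z(model, matrix(z, nrow = 1))
}

#' One-step-ahead predictions along a whole signal
#'
#' Vectorized open-loop prediction: element `t` of the result is the model's
#' prediction of `y[t]` from the measured samples `y[t-order], ..., y[t-1]`;
#' the first `order` elements are `NA` (insufficient history).
#'
#' @param model an `arx_model` or `narx_model`.
#' @param y numeric vector in original units, longer than the model order.
#' @return Numeric vector the same length as `y`.
#' @export
predict_series <- function(model, y) {
  stopifnot(inherits(model, "gait_model"))
  y <- as.numeric(y)
  reg <- build_regressors(y, model$order)
  Xz <- (reg$X - model$norm_mu) / model$norm_sd
  c(rep(NA_real_, model$order),
    model$norm_mu + model$norm_sd * predict_z(model, Xz))
}

#' Free-run simulation of a fitted model (diagnostic)
#'
#' Iterates the model on its own predictions from a measured initial history.
#' Purely diagnostic: the online detector never runs the model closed-loop.
#'
#' @param model an `arx_model` or `narx_model`.
#' @param history initial `model$order` samples, chronological order,
#'   original units.
#' @param n_steps number of samples to simulate.
#' @return Numeric vector of `n_steps` simulated samples.
#' @export
simulate_free_run <- function(model, history, n_steps) {
  stopifnot(inherits(model, "gait_model"))
  buf <- as.numeric(history)
  out <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    out[i] <- predict_one_step(model, buf)
    buf <- c(buf[-1], out[i])
  }
  out
}

#' RMSE and FIT of predictions against measurements
#'
#' `rmse = sqrt(mean((predicted - measured)^2))` and
#' `fit = 1 - rmse / s`, where by default `s` is the population standard
#' deviation of the *prediction* sequence. A perfectly predicted window has
#' `fit = 1`; model mismatch drives `fit` towards (and below) 0, which is
#' what the online detector thresholds. When the denominator is zero the
#' report is flagged degenerate and `fit` is `NA`.
#'
#' @param predicted,measured numeric vectors of equal length `n >= 2`.
#' @param denominator `"predicted"` (default) or `"measured"`: which
#'   sequence's population sd normalizes the RMSE. The measured-denominator
#'   variant exists for sensitivity analysis only.
#' @return An object of class `fit_report`: list with `rmse`, `fit`, `n`,
#'   `residuals` (predicted - measured), `degenerate`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 5))
#' @export
goodness_of_fit <- function(predicted, measured,
                            denominator = c("predicted", "measured")) {
  denominator <- match.arg(denominator)
  predicted <- as.numeric(predicted); measured <- as.numeric(measured)
  if (length(predicted) != length(measured))
    stop_gaitnarx("`predicted` and `measured` must have equal length",
                  "gaitnarx_contract_error")
  n <- length(predicted)
  if (n < 2L)
    stop_gaitnarx("goodness of fit needs at least 2 samples",
                  "gaitnarx_insufficient_data_error")
  rmse <- sqrt(mean((predicted - measured)^2))
  denom <- psd(if (denominator == "predicted") predicted else measured)
  degenerate <- denom == 0
  fit <- if (degenerate) NA_real_ else 1 - rmse / denom
  structure(list(rmse = rmse, fit = fit, n = n,
                 residuals = predicted - measured,
                 degenerate = degenerate),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> n=%d rmse=%.6g fit=%s%s\n", x$n, x$rmse,
              if (is.na(x$fit)) "NA" else sprintf("%.6g", x$fit),
              if (x$degenerate) " [degenerate: zero denominator]" else ""))
  invisible(x)
}
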