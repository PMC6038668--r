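## Classical comparator features for accelerometer gait analysis: Hjorth
## parameters, signal energy, signal magnitude area/vector, peak statistics
## and co-occurrence matrix summaries. These are the feature families used
## by feature+classifier fall-risk baselines; the package computes them for
## comparison against the model-based detector.

#' Hjorth parameters of a signal
#'
#' Time-domain descriptors: activity is the population variance (signal
#' power); mobility, `sqrt(var(y') / var(y))`, the mean angular frequency in
#' rad/s (smoothness of the curve); complexity, `mobility(y') / mobility(y)`,
#' the deviation from a pure sinusoid (irregularity in the frequency
#' domain). Derivatives are forward first differences scaled by `fs`.
#'
#' @param y numeric vector, length at least 3.
#' @param fs sampling frequency in Hz.
#' @return Named list `activity`, `mobility`, `complexity`. For a constant
#'   signal activity is 0 and mobility/complexity are `NA` (undefined).
#' @export
hjorth_params <- function(y, fs) {
  y <- as.numeric(y)
  if (length(y) < 3L)
    stop_gaitnarx("Hjorth parameters need at least 3 samples",
                  "gaitnarx_insufficient_data_error")
  check_scalar_number(fs, "fs", positive = TRUE)
  d1 <- diff(y) * fs
  d2 <- diff(d1) * fs
  v0 <- pvar(y); v1 <- pvar(d1); v2 <- pvar(d2)
  if (v0 == 0) return(list(activity = 0, mobility = NA_real_,
                           complexity = NA_real_))
  mob <- sqrt(v1 / v0)
  comp <- if (v1 == 0) NA_real_ else sqrt(v2 / v1) / mob
  list(activity = v0, mobility = mob, complexity = comp)
}

#' Energy of a signal
#'
#' Time integral of the squared signal, by the trapezoidal rule with
#' `dt = 1/fs`. Estimates the strength of floor contact over the window.
#'
#' @param y numeric vector, length at least 2.
#' @param fs sampling frequency in Hz.
#' @return Scalar energy (units of `y^2 * s`).
#' @export
signal_energy <- function(y, fs) {
  y <- as.numeric(y)
  if (length(y) < 2L)
    stop_gaitnarx("energy needs at least 2 samples",
                  "gaitnarx_insufficient_data_error")
  check_scalar_number(fs, "fs", positive = TRUE)
  pracma::trapz((seq_along(y) - 1) / fs, y^2)
}

#' Signal magnitude area of a recording
#'
#' `(1/T) * (integral |ax| + integral |ay| + integral |az|)` over the
#' monitored interval `T`, integrals by the trapezoidal rule on the
#' recording's timestamps. A classical activity-intensity feature.
#'
#' @param rec a [gait_recording()] with at least 2 samples.
#' @return Scalar SMA in m/s^2.
#' @export
sma <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  n <- n_samples(rec)
  if (n < 2L)
    stop_gaitnarx("SMA needs at least 2 samples",
                  "gaitnarx_insufficient_data_error")
  T_ <- rec$t[n] - rec$t[1]
  if (T_ <= 0)
    stop_gaitnarx("zero-length monitored interval", "gaitnarx_contract_error")
  (pracma::trapz(rec$t, abs(rec$ax)) + pracma::trapz(rec$t, abs(rec$ay)) +
     pracma::trapz(rec$t, abs(rec$az))) / T_
}

#' Signal magnitude vector of a recording
#'
#' Mean over samples of the per-sample Euclidean norm of the three axes:
#' the degree of movement intensity.
#'
#' @param rec a [gait_recording()].
#' @return Scalar SMV in m/s^2.
#' @export
smv <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  mean(magnitude_series(rec))
}

#' Peak statistics of a signal
#'
#' @param y numeric vector (length at least 1; at least 2 for the
#'   derivative).
#' @param fs sampling frequency in Hz (for the derivative scaling).
#' @return Named list `peak` (maximum value), `peak_to_peak` (maximum minus
#'   minimum) and `max_abs_derivative` (largest absolute first difference
#'   times `fs`; `NA` for a single sample).
#' @export
peak_stats <- function(y, fs) {
  y <- as.numeric(y)
  if (length(y) < 1L)
    stop_gaitnarx("peak statistics need at least 1 sample",
                  "gaitnarx_contract_error")
  check_scalar_number(fs, "fs", positive = TRUE)
  list(peak = max(y),
       peak_to_peak = max(y) - min(y),
       max_abs_derivative = if (length(y) < 2L) NA_real_
                            else max(abs(diff(y))) * fs)
}

## Equal-width quantization of a continuous signal into K levels over its
## observed range; a constant signal occupies level 1 only.
quantize_levels <- function(y, K) {
  lo <- min(y); hi <- max(y)
  if (hi == lo) return(rep(1L, length(y)))
  idx <- floor((y - lo) / (hi - lo) * K) + 1L
  pmin(idx, K)
}

#' Co-occurrence matrix features of a signal
#'
#' Quantizes `y` into `K` equal-width levels over its observed range, forms
#' the normalized joint histogram `p[i, j]` of level pairs at lag `offset`
#' (directional, not symmetrized), and summarizes it with the standard
#' texture statistics: contrast `sum (i-j)^2 p`, homogeneity
#' `sum p / (1 + |i-j|)`, correlation
#' `sum (i - m_r)(j - m_c) p / (s_r * s_c)` with row/column means `m` and
#' standard deviations `s`, uniformity `sum p^2`, and the maximum
#' probability `max p`.
#'
#' @param y numeric vector, longer than `offset`.
#' @param K number of quantization levels (default 8).
#' @param offset pair lag in samples (default 1).
#' @return Named list `contrast`, `homogeneity`, `correlation` (`NA` when a
#'   marginal standard deviation is zero), `uniformity`, `max_probability`,
#'   plus the matrix itself as `p`.
#' @export
cooccurrence_features <- function(y, K = 8L, offset = 1L) {
  y <- as.numeric(y)
  K <- as.integer(K); offset <- as.integer(offset)
  if (K < 2L) stop_gaitnarx("`K` must be >= 2", "gaitnarx_contract_error")
  if (length(y) <= offset)
    stop_gaitnarx(sprintf("need more than `offset` = %d samples, got %d",
                          offset, length(y)),
                  "gaitnarx_insufficient_data_error")
  lev <- quantize_levels(y, K)
  n <- length(y) - offset
  counts <- matrix(0, K, K)
  pairs <- cbind(lev[seq_len(n)], lev[seq_len(n) + offset])
  for (row in seq_len(n)) counts[pairs[row, 1], pairs[row, 2]] <-
    counts[pairs[row, 1], pairs[row, 2]] + 1
  p <- counts / n
  i <- row(p); j <- col(p)
  m_r <- sum(i * p); m_c <- sum(j * p)
  s_r <- sqrt(sum((i - m_r)^2 * p)); s_c <- sqrt(sum((j - m_c)^2 * p))
  correlation <- if (s_r * s_c == 0) NA_real_
                 else sum((i - m_r) * (j - m_c) * p) / (s_r * s_c)
  list(contrast = sum((i - j)^2 * p),
       homogeneity = sum(p / (1 + abs(i - j))),
       correlation = correlation,
       uniformity = sum(p^2),
       max_probability = max(p),
       p = p)
}

#' Windowed feature table for a recording
#'
#' Slides a window over the magnitude channel (and the raw axes for SMA/SMV)
#' and computes the full comparator feature set per window: Hjorth
#' parameters, energy, SMA, SMV, peak statistics and co-occurrence features.
#'
#' @param rec a [gait_recording()].
#' @param window,hop window length and stride in samples.
#' @param K,offset co-occurrence quantization levels and lag.
#' @return A data frame with one row per window: `subject`, `trial`,
#'   `label`, `start_index`/`end_index` (0-based), then one column per
#'   feature.
#' @export
feature_table <- function(rec, window = 50L, hop = 25L, K = 8L, offset = 1L) {
  stopifnot(inherits(rec, "gait_recording"))
  window <- as.integer(window); hop <- as.integer(hop)
  n <- n_samples(rec)
  if (n < window)
    stop_gaitnarx("recording shorter than the feature window",
                  "gaitnarx_insufficient_data_error")
  mag <- magnitude_series(rec)
  starts <- seq.int(1L, n - window + 1L, by = hop)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    sub <- gait_recording(rec$t[idx], rec$ax[idx], rec$ay[idx], rec$az[idx],
                          fs = rec$fs)
    h <- hjorth_params(mag[idx], rec$fs)
    pk <- peak_stats(mag[idx], rec$fs)
    co <- cooccurrence_features(mag[idx], K = K, offset = offset)
    data.frame(subject = rec$subject_id, trial = rec$trial_id,
               label = rec$label,
               start_index = s - 1L, end_index = s + window - 2L,
               activity = h$activity, mobility = h$mobility,
               complexity = h$complexity,
               energy = signal_energy(mag[idx], rec$fs),
               sma = sma(sub), smv = smv(sub),
               peak = pk$peak, peak_to_peak = pk$peak_to_peak,
               max_abs_derivative = pk$max_abs_derivative,
               contrast = co$contrast, homogeneity = co$homogeneity,
               correlation = co$correlation, uniformity = co$uniformity,
               max_probability = co$max_probability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
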