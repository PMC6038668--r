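# Independent brute-force oracles: straightforward loop implementations of
# every statistic, kept deliberately naive and separate from the package's
# vectorized code paths.

oracle_rmse <- function(pred, meas) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - meas[i])^2
  sqrt(s / length(pred))
}

oracle_fit <- function(pred, meas) {
  n <- length(pred)
  mb <- sum(pred) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (pred[i] - mb)^2
  denom <- sqrt(ss / n)
  if (denom == 0) return(NA_real_)
  1 - oracle_rmse(pred, meas) / denom
}

oracle_pvar <- function(y) {
  m <- sum(y) / length(y)
  s <- 0
  for (v in y) s <- s + (v - m)^2
  s / length(y)
}

oracle_hjorth <- function(y, fs) {
  d1 <- numeric(length(y) - 1)
  for (i in seq_along(d1)) d1[i] <- (y[i + 1] - y[i]) * fs
  d2 <- numeric(length(d1) - 1)
  for (i in seq_along(d2)) d2[i] <- (d1[i + 1] - d1[i]) * fs
  v0 <- oracle_pvar(y); v1 <- oracle_pvar(d1); v2 <- oracle_pvar(d2)
  if (v0 == 0) return(list(activity = 0, mobility = NA_real_,
                           complexity = NA_real_))
  mob <- sqrt(v1 / v0)
  list(activity = v0, mobility = mob,
       complexity = if (v1 == 0) NA_real_ else sqrt(v2 / v1) / mob)
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}

oracle_energy <- function(y, fs) {
  oracle_trapz((seq_along(y) - 1) / fs, y^2)
}

oracle_sma <- function(rec) {
  T_ <- rec$t[length(rec$t)] - rec$t[1]
  (oracle_trapz(rec$t, abs(rec$ax)) + oracle_trapz(rec$t, abs(rec$ay)) +
     oracle_trapz(rec$t, abs(rec$az))) / T_
}

oracle_smv <- function(rec) {
  s <- 0
  for (i in seq_along(rec$t))
    s <- s + sqrt(rec$ax[i]^2 + rec$ay[i]^2 + rec$az[i]^2)
  s / length(rec$t)
}

oracle_peak <- function(y, fs) {
  mx <- y[1]; mn <- y[1]
  for (v in y) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  md <- 0
  for (i in seq_len(length(y) - 1))
    md <- max(md, abs(y[i + 1] - y[i]) * fs)
  list(peak = mx, peak_to_peak = mx - mn, max_abs_derivative = md)
}

oracle_quantize <- function(y, K) {
  lo <- min(y); hi <- max(y)
  out <- integer(length(y))
  for (i in seq_along(y)) {
    out[i] <- if (hi == lo) 1L else min(K, floor((y[i] - lo) / (hi - lo) * K) + 1L)
  }
  out
}

oracle_cooc <- function(y, K, offset) {
  lev <- oracle_quantize(y, K)
  p <- matrix(0, K, K)
  n <- length(y) - offset
  for (i in seq_len(n)) p[lev[i], lev[i + offset]] <- p[lev[i], lev[i + offset]] + 1 / n
  contrast <- 0; homog <- 0; unif <- 0; maxp <- 0
  m_r <- 0; m_c <- 0
  for (i in 1:K) for (j in 1:K) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    homog <- homog + p[i, j] / (1 + abs(i - j))
    unif <- unif + p[i, j]^2
    if (p[i, j] > maxp) maxp <- p[i, j]
    m_r <- m_r + i * p[i, j]
    m_c <- m_c + j * p[i, j]
  }
  s_r <- 0; s_c <- 0; num <- 0
  for (i in 1:K) for (j in 1:K) {
    s_r <- s_r + (i - m_r)^2 * p[i, j]
    s_c <- s_c + (j - m_c)^2 * p[i, j]
    num <- num + (i - m_r) * (j - m_c) * p[i, j]
  }
  corr <- if (sqrt(s_r) * sqrt(s_c) == 0) NA_real_
          else num / (sqrt(s_r) * sqrt(s_c))
  list(contrast = contrast, homogeneity = homog, correlation = corr,
       uniformity = unif, max_probability = maxp, p = p)
}

# Normal-equations least-squares oracle for a pure autoregression on the
# z-scored signal (sample sd), returning coefficients in the package's
# left-hand-side sign convention.
oracle_ar_ls <- function(y, order) {
  z <- (y - mean(y)) / sd(y)
  n <- length(z)
  m <- n - order
  A <- matrix(1, m, order + 1)
  b <- numeric(m)
  for (k in seq_len(m)) {
    t_ <- k + order
    for (j in seq_len(order)) A[k, 1 + j] <- z[t_ - j]
    b[k] <- z[t_]
  }
  coef <- solve(t(A) %*% A, t(A) %*% b)
  list(c0 = coef[1], a = -coef[-1])
}

# Independent double-loop sliding-window FIT sequence over a prediction
# vector (windows + the goodness statistic recomputed naively).
oracle_window_fits <- function(preds, y, pred_window, fit_window, hop) {
  n <- length(y)
  ends <- seq(pred_window + fit_window, n, by = hop)
  fits <- numeric(length(ends))
  for (w in seq_along(ends)) {
    idx <- (ends[w] - fit_window + 1):ends[w]
    fits[w] <- oracle_fit(preds[idx], y[idx])
  }
  list(ends = ends, fits = fits)
}
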