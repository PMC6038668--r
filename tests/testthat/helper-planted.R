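# Planted-model fixtures: a hand-specified NARX system with a non-trivial
# oscillatory attractor, used for self-consistency and recovery tests.

mk_narx <- function(alpha, B, c0, norm_mu = 0, norm_sd = 1, fs = 10) {
  structure(list(kind = "narx", order = nrow(B) - 1L, r = ncol(B),
                 alpha = alpha, beta = B, c0 = c0, basis = "sigmoid",
                 fs = fs, norm_mu = norm_mu, norm_sd = norm_sd,
                 train_meta = list(vn = 0, n_train = 0L)),
            class = c("narx_model", "gait_model"))
}

# order 3, r = 2; free-run settles into a bounded oscillation (sd ~ 3).
planted_narx <- function() {
  mk_narx(alpha = c(4, -4),
          B = matrix(c(3, -2, 1, 0, -2, 3, -1, 0.5), 4, 2),
          c0 = 0)
}

# Simulate the true stochastic system: next sample = planted map of the
# measured history plus innovation noise.
sim_planted <- function(model, n, noise_sd, seed) {
  set.seed(seed)
  buf <- rep(0.1, model$order)
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- predict_one_step(model, buf) + rnorm(1, 0, noise_sd)
    buf <- c(buf[-1], y[i])
  }
  y
}

# Small deterministic seed combiner for parameterised test loops.
derive_seed_for_test <- function(...) {
  sum(c(...) * 101L^(seq_along(c(...)) - 1L)) %% 100000L
}

# A noise-free settled trajectory of the planted model (attractor samples).
planted_trajectory <- function(model, n, burn = 200) {
  y <- simulate_free_run(model, rep(0.1, model$order), n + burn)
  y[(burn + 1):(burn + n)]
}
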