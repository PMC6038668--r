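## Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded package functions never perturb the user's
#' random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # materialize a state to restore
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

## Deterministic sub-seed derivation (stays below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h)
}

stop_gaitnarx <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gaitnarx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gaitnarx(sprintf("`%s` must be a single finite number", name),
                  "gaitnarx_contract_error")
  if (positive && x <= 0)
    stop_gaitnarx(sprintf("`%s` must be > 0", name), "gaitnarx_contract_error")
  invisible(x)
}

## Population (1/n) variance; the package-wide convention.
pvar <- function(x) mean((x - mean(x))^2)
psd <- function(x) sqrt(pvar(x))

fmt_num <- function(x) sprintf("%.17g", x)
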