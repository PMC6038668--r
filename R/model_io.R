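## Versioned plain-text serialization of fitted gait models. Floats are
## written with 17 significant digits so save -> load is bit-exact.

MODEL_FORMAT_VERSION <- 1L

model_field <- function(key, values) {
  paste0(key, ": ", paste(if (is.numeric(values)) fmt_num(values)
                          else as.character(values), collapse = " "))
}

#' Save a fitted gait model to a plain-text file
#'
#' Writes a versioned key/value text file recording the model kind, order,
#' all coefficients at full precision, normalization statistics, sampling
#' rate and training metadata. [load_model()] restores a bit-exact copy.
#'
#' @param model an `arx_model` or `narx_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  lines <- c(
    sprintf("gaitnarx-model v%d", MODEL_FORMAT_VERSION),
    model_field("kind", model$kind),
    model_field("order", model$order),
    model_field("fs", model$fs),
    model_field("norm_mu", model$norm_mu),
    model_field("norm_sd", model$norm_sd),
    model_field("c0", model$c0))
  if (model$kind == "arx") {
    lines <- c(lines, model_field("a", model$a))
  } else {
    lines <- c(lines,
               model_field("r", model$r),
               model_field("basis", model$basis),
               model_field("alpha", model$alpha),
               model_field("beta", as.vector(model$beta)))
  }
  tm <- model$train_meta
  lines <- c(lines,
             model_field("train_meta",
                         as.numeric(c(tm$seed %||% NA, tm$iterations %||% NA,
                                      tm$vn, tm$converged %||% NA,
                                      tm$start %||% NA, tm$n_train))))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_gaitnarx(sprintf("cannot write %s", path), "gaitnarx_io_error")
  invisible(path)
}

parse_fields <- function(lines, path) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([a-z0-9_]+): (.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop_gaitnarx(sprintf("malformed line in model file %s: %s", path, ln),
                    "gaitnarx_parse_error")
    kv[[m[2]]] <- strsplit(m[3], " ", fixed = TRUE)[[1]]
  }
  kv
}

field_num <- function(kv, key, path, allow_na = FALSE) {
  if (is.null(kv[[key]]))
    stop_gaitnarx(sprintf("model file %s is missing field `%s` (truncated?)",
                          path, key), "gaitnarx_parse_error")
  v <- suppressWarnings(as.numeric(kv[[key]]))
  if (anyNA(v) && !(allow_na && all(is.na(v) == (kv[[key]] == "NA"))))
    stop_gaitnarx(sprintf("non-numeric value for `%s` in model file %s",
                          key, path), "gaitnarx_parse_error")
  v
}

#' Load a gait model saved by [save_model()]
#'
#' @param path path to a model file.
#' @param expect `"any"` (default), `"arx"` or `"narx"`: the model kind the
#'   caller requires; a mismatch raises a kind-mismatch error rather than
#'   returning the wrong class.
#' @return An `arx_model` or `narx_model`, bit-identical to the saved one.
#' @export
load_model <- function(path, expect = c("any", "arx", "narx")) {
  expect <- match.arg(expect)
  if (!file.exists(path))
    stop_gaitnarx(sprintf("model file not found: %s", path), "gaitnarx_io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop_gaitnarx(sprintf("model file %s is truncated", path),
                  "gaitnarx_parse_error")
  m <- regmatches(lines[1], regexec("^gaitnarx-model v([0-9]+)$", lines[1]))[[1]]
  if (length(m) != 2L)
    stop_gaitnarx(sprintf("%s is not a gaitnarx model file", path),
                  "gaitnarx_parse_error")
  ver <- as.integer(m[2])
  if (ver != MODEL_FORMAT_VERSION)
    stop_gaitnarx(sprintf(
      "unsupported model format version %d in %s (this build reads v%d)",
      ver, path, MODEL_FORMAT_VERSION), "gaitnarx_version_error")
  kv <- parse_fields(lines[-1], path)
  kind <- kv$kind
  if (is.null(kind) || !kind %in% c("arx", "narx"))
    stop_gaitnarx(sprintf("missing or unknown model kind in %s", path),
                  "gaitnarx_parse_error")
  if (expect != "any" && kind != expect)
    stop_gaitnarx(sprintf("model file %s holds an %s model but %s was required",
                          path, kind, expect), "gaitnarx_kind_mismatch_error")
  order <- as.integer(field_num(kv, "order", path))
  tm_raw <- field_num(kv, "train_meta", path, allow_na = TRUE)
  tm <- list(seed = if (is.na(tm_raw[1])) NULL else as.integer(tm_raw[1]),
             iterations = if (is.na(tm_raw[2])) NULL else as.integer(tm_raw[2]),
             vn = tm_raw[3],
             converged = if (is.na(tm_raw[4])) NULL else as.logical(tm_raw[4]),
             start = if (is.na(tm_raw[5])) NULL else as.integer(tm_raw[5]),
             n_train = as.integer(tm_raw[6]))
  common <- list(kind = kind, order = order,
                 fs = field_num(kv, "fs", path),
                 norm_mu = field_num(kv, "norm_mu", path),
                 norm_sd = field_num(kv, "norm_sd", path),
                 c0 = field_num(kv, "c0", path),
                 train_meta = tm)
  if (kind == "arx") {
    a <- field_num(kv, "a", path)
    if (length(a) != order)
      stop_gaitnarx(sprintf("coefficient length mismatch in %s", path),
                    "gaitnarx_parse_error")
    structure(c(common[c("kind", "order")], list(a = a, c0 = common$c0),
                common[c("fs", "norm_mu", "norm_sd", "train_meta")]),
              class = c("arx_model", "gait_model"))
  } else {
    r <- as.integer(field_num(kv, "r", path))
    alpha <- field_num(kv, "alpha", path)
    beta <- field_num(kv, "beta", path)
    if (length(alpha) != r || length(beta) != (order + 1L) * r)
      stop_gaitnarx(sprintf("coefficient length mismatch in %s", path),
                    "gaitnarx_parse_error")
    structure(list(kind = "narx", order = order, r = r,
                   alpha = alpha,
                   beta = matrix(beta, nrow = order + 1L, ncol = r),
                   c0 = common$c0,
                   basis = (kv$basis %||% "sigmoid"),
                   fs = common$fs, norm_mu = common$norm_mu,
                   norm_sd = common$norm_sd, train_meta = tm),
              class = c("narx_model", "gait_model"))
  }
}
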