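#' Construct a gait recording
#'
#' A `gait_recording` is a uniformly (or near-uniformly) sampled tri-axial
#' acceleration time series with label metadata: the container every other
#' function in the package consumes. Acceleration is in m/s^2, timestamps in
#' seconds from recording start.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param ax,ay,az numeric vectors of acceleration components in m/s^2, each
#'   the same length as `t`.
#' @param fs sampling frequency in Hz. If `NULL`, inferred as the reciprocal
#'   of the median sampling interval (requires at least 2 samples).
#' @param subject_id,trial_id opaque identifier strings.
#' @param label one of `"normal"`, `"abnormal"`, `"unlabeled"`.
#' @param meta free-form named list of annotations (e.g. perturbation onset
#'   indices written by the simulator; all sample indices in `meta` and in
#'   exported decision traces are 0-based, matching the CSV interfaces).
#' @return An object of class `gait_recording`: a list with fields
#'   `t`, `ax`, `ay`, `az`, `fs`, `subject_id`, `trial_id`, `label`, `meta`.
#' @examples
#' rec <- gait_recording(t = seq(0, 0.9, by = 0.1),
#'                       ax = rnorm(10), ay = rnorm(10), az = rnorm(10) + 9.81)
#' rec$fs
#' @export
gait_recording <- function(t, ax, ay, az, fs = NULL,
                           subject_id = "s0", trial_id = "t0",
                           label = c("unlabeled", "normal", "abnormal"),
                           meta = list()) {
  label <- match.arg(label)
  t <- as.numeric(t); ax <- as.numeric(ax)
  ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(t)
  if (n < 1L)
    stop_gaitnarx("a recording needs at least one sample", "gaitnarx_empty_error")
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop_gaitnarx("t, ax, ay, az must have equal length", "gaitnarx_contract_error")
  if (!all(is.finite(t)) || !all(is.finite(ax)) ||
      !all(is.finite(ay)) || !all(is.finite(az)))
    stop_gaitnarx("recording contains non-finite values", "gaitnarx_validation_error")
  if (n > 1L && any(diff(t) <= 0))
    stop_gaitnarx("timestamps must be strictly increasing", "gaitnarx_validation_error")
  if (is.null(fs)) {
    if (n < 2L)
      stop_gaitnarx("cannot infer fs from a single sample; supply `fs`",
                    "gaitnarx_contract_error")
    fs <- 1 / median(diff(t))
  }
  check_scalar_number(fs, "fs", positive = TRUE)
  structure(
    list(t = t, ax = ax, ay = ay, az = az, fs = fs,
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         label = label, meta = meta),
    class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> subject=%s trial=%s label=%s\n  N=%d samples, fs=%g Hz, span=%.3f s%s\n",
    x$subject_id, x$trial_id, x$label, length(x$t), x$fs,
    x$t[length(x$t)] - x$t[1],
    if (isTRUE(x$meta$nonuniform)) " [non-uniform sampling]" else ""))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a [gait_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$t)

#' Read an accelerometer recording from CSV
#'
#' Expects a comma-separated file with header `t,ax,ay,az` (an optional
#' `label` column, constant per file, sets the recording label). Values use
#' `.` as decimal separator; `t` is in seconds and the axes in m/s^2 unless
#' `units = "g"`, in which case accelerations are converted on read with
#' 1 g = 9.80665 m/s^2.
#'
#' @param path path to the CSV file.
#' @param fs_expected expected sampling frequency in Hz, or `NULL`. When
#'   given and the median sampling interval deviates from `1/fs_expected` by
#'   more than 5\%, the recording is flagged non-uniform
#'   (`meta$nonuniform = TRUE`) and should be passed through
#'   [resample_recording()] before modelling.
#' @param units `"ms2"` (default) or `"g"`.
#' @param subject_id,trial_id identifiers attached to the recording.
#' @return A [gait_recording()].
#' @seealso [write_recording()], [resample_recording()]
#' @export
read_recording <- function(path, fs_expected = NULL, units = c("ms2", "g"),
                           subject_id = "s0", trial_id = "t0") {
  units <- match.arg(units)
  if (!file.exists(path))
    stop_gaitnarx(sprintf("file not found: %s", path), "gaitnarx_io_error")
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_gaitnarx(
      sprintf("cannot parse %s: %s", path, conditionMessage(e)),
      "gaitnarx_parse_error"))
  if (nrow(df) == 0L)
    stop_gaitnarx(sprintf("empty recording file: %s", path), "gaitnarx_empty_error")
  required <- c("t", "ax", "ay", "az")
  extra <- setdiff(names(df), c(required, "label"))
  if (!all(required %in% names(df)) || length(extra) > 0L)
    stop_gaitnarx(sprintf(
      "bad header in %s: need columns t,ax,ay,az (optional label), got %s",
      path, paste(names(df), collapse = ",")), "gaitnarx_format_error")
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_gaitnarx(sprintf("non-numeric value in column %s, data row %d of %s",
                            col, bad, path), "gaitnarx_parse_error")
    }
    if (anyNA(v))
      stop_gaitnarx(sprintf("missing value in column %s of %s", col, path),
                    "gaitnarx_parse_error")
  }
  label <- "unlabeled"
  if ("label" %in% names(df)) {
    labs <- unique(as.character(df$label))
    if (length(labs) == 1L && labs %in% c("normal", "abnormal", "unlabeled"))
      label <- labs
  }
  scale <- if (units == "g") 9.80665 else 1
  rec <- gait_recording(df$t, df$ax * scale, df$ay * scale, df$az * scale,
                        subject_id = subject_id, trial_id = trial_id,
                        label = label)
  if (!is.null(fs_expected) && nrow(df) >= 2L) {
    check_scalar_number(fs_expected, "fs_expected", positive = TRUE)
    med <- median(diff(rec$t))
    if (abs(med - 1 / fs_expected) > 0.05 / fs_expected) {
      rec$meta$nonuniform <- TRUE
    } else {
      rec$fs <- fs_expected
    }
  }
  rec
}

#' Write a recording to CSV
#'
#' Writes the `t,ax,ay,az` dialect read by [read_recording()] at full float
#' precision (17 significant digits), plus a `label` column when the
#' recording is labelled.
#'
#' @param rec a valid [gait_recording()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gait_recording"))
  vals <- c(rec$t, rec$ax, rec$ay, rec$az)
  if (!all(is.finite(vals)))
    stop_gaitnarx("refusing to write recording with non-finite values",
                  "gaitnarx_validation_error")
  header <- "t,ax,ay,az"
  rows <- sprintf("%s,%s,%s,%s", fmt_num(rec$t), fmt_num(rec$ax),
                  fmt_num(rec$ay), fmt_num(rec$az))
  if (rec$label != "unlabeled") {
    header <- paste0(header, ",label")
    rows <- paste0(rows, ",", rec$label)
  }
  ok <- tryCatch({
    writeLines(c(header, rows), con = path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop_gaitnarx(sprintf("cannot write %s", path), "gaitnarx_io_error")
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation of each axis onto a uniform grid at `fs_target`
#' spanning `[t[1], t[N]]`. Used to bring non-uniform or differently sampled
#' recordings to the detector's fixed rate (10 Hz by default across the
#' package).
#'
#' @param rec a [gait_recording()] with at least 2 samples.
#' @param fs_target target sampling frequency in Hz.
#' @return A uniformly sampled [gait_recording()] at `fs_target`.
#' @export
resample_recording <- function(rec, fs_target) {
  stopifnot(inherits(rec, "gait_recording"))
  check_scalar_number(fs_target, "fs_target", positive = TRUE)
  n <- n_samples(rec)
  if (n < 2L)
    stop_gaitnarx("resampling needs at least 2 samples",
                  "gaitnarx_insufficient_data_error")
  span <- rec$t[n] - rec$t[1]
  m <- floor(span * fs_target + 1e-9) + 1
  tt <- rec$t[1] + (seq_len(m) - 1) / fs_target
  interp <- function(y) stats::approx(rec$t, y, xout = tt, rule = 2)$y
  out <- gait_recording(tt, interp(rec$ax), interp(rec$ay), interp(rec$az),
                        fs = fs_target, subject_id = rec$subject_id,
                        trial_id = rec$trial_id, label = rec$label,
                        meta = rec$meta)
  out$meta$nonuniform <- NULL
  out
}

#' Acceleration magnitude channel
#'
#' Per-sample Euclidean norm `sqrt(ax^2 + ay^2 + az^2)` of the three axes:
#' the orientation-robust scalar signal the gait models are identified on by
#' default.
#'
#' @param rec a [gait_recording()].
#' @return Numeric vector of length `n_samples(rec)`, in m/s^2.
#' @export
magnitude_series <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
}

#' Extract the modelled scalar channel from a recording
#'
#' @param rec a [gait_recording()].
#' @param channel `"magnitude"` (default) or a single axis `"ax"`, `"ay"`,
#'   `"az"`.
#' @return Numeric vector of length `n_samples(rec)`.
#' @export
signal_channel <- function(rec, channel = c("magnitude", "ax", "ay", "az")) {
  channel <- match.arg(channel)
  if (channel == "magnitude") magnitude_series(rec) else rec[[channel]]
}
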