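## The online threshold classifier: slide a prediction window and a larger
## FIT window over incoming acceleration samples; a window whose FIT (of
## open-loop one-step predictions against measurements) falls on the wrong
## side of the threshold is declared abnormal.

#' Detector configuration
#'
#' Default values are the detector's operating point: a 10-sample prediction
#' window (1 s at 10 Hz), a 50-sample FIT window (5 s), threshold 0.02 on
#' FIT, decisions at every sample (`hop = 1`), abnormal when FIT falls
#' *below* the threshold. High FIT means the window is well explained by the
#' subject's normal-walk model, so the default rule flags low FIT; the
#' opposite rule (`"fit_above"`) is available for sensitivity analysis.
#'
#' @param pred_window prediction window length in samples; must be at least
#'   the model order.
#' @param fit_window FIT window length in samples; must be at least
#'   `pred_window`.
#' @param threshold decision threshold on FIT.
#' @param hop decision stride in samples.
#' @param rule `"fit_below"` (default: abnormal when FIT < threshold) or
#'   `"fit_above"` (abnormal when FIT > threshold). A FIT exactly equal to
#'   the threshold is classified normal under either rule.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(pred_window = 10L, fit_window = 50L,
                            threshold = 0.02, hop = 1L,
                            rule = c("fit_below", "fit_above")) {
  rule <- match.arg(rule)
  pred_window <- as.integer(pred_window)
  fit_window <- as.integer(fit_window)
  hop <- as.integer(hop)
  if (pred_window < 1L || fit_window < pred_window || hop < 1L)
    stop_gaitnarx(
      "need pred_window >= 1, fit_window >= pred_window, hop >= 1",
      "gaitnarx_contract_error")
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop_gaitnarx("`threshold` must be a number", "gaitnarx_contract_error")
  structure(list(pred_window = pred_window, fit_window = fit_window,
                 threshold = threshold, hop = hop, rule = rule),
            class = "detector_config")
}

#' Number of decision windows for a stream length
#'
#' Closed-form bookkeeping for [classify_stream()]: with `n` samples the
#' first decision is taken at (1-based) sample `pred_window + fit_window`
#' and subsequent decisions every `hop` samples.
#'
#' @param n stream length in samples.
#' @param cfg a [detector_config()].
#' @return Integer window count (0 when the stream is shorter than warm-up).
#' @export
n_decision_windows <- function(n, cfg) {
  warm <- cfg$pred_window + cfg$fit_window
  if (n < warm) return(0L)
  as.integer((n - warm) %/% cfg$hop + 1L)
}

#' Classify a stream of acceleration samples against a normal-walk model
#'
#' For each FIT window end `e` (stepping by `hop` after a warm-up of
#' `pred_window + fit_window` samples), computes open-loop one-step-ahead
#' predictions for every sample in the window from the preceding measured
#' samples, the FIT of predictions against measurements over the window, and
#' a normal/abnormal decision by comparing FIT to the threshold. Windows
#' whose FIT is degenerate (zero prediction variance — a flat prediction
#' stream from a walking model is itself anomalous) are classified abnormal
#' and flagged.
#'
#' @param model an `arx_model` or `narx_model`; its order must not exceed
#'   `cfg$pred_window`.
#' @param y numeric vector of the scalar acceleration signal, length at
#'   least `cfg$pred_window + cfg$fit_window`.
#' @param cfg a [detector_config()].
#' @param t optional timestamps (seconds) for the trace; defaults to
#'   `index / model$fs`.
#' @return An object of class `decision_trace`: a data frame with one row
#'   per evaluated window — `end_index` (0-based index of the window's last
#'   sample), `end_time_s`, `fit`, `decision` (`"normal"`/`"abnormal"`),
#'   `degenerate` — with the configuration and
#'   `first_abnormal_index` (0-based, `NA` if never abnormal) as attributes.
#' @seealso [detection_latency()], [write_trace()]
#' @export
classify_stream <- function(model, y, cfg = detector_config(), t = NULL) {
  stopifnot(inherits(model, "gait_model"), inherits(cfg, "detector_config"))
  if (model$order > cfg$pred_window)
    stop_gaitnarx(sprintf(
      "model order (%d) exceeds the prediction window (%d)",
      model$order, cfg$pred_window), "gaitnarx_contract_error")
  y <- as.numeric(y)
  n <- length(y)
  warm <- cfg$pred_window + cfg$fit_window
  if (n < warm)
    stop_gaitnarx(sprintf(
      "stream too short: need at least pred_window + fit_window = %d samples, got %d",
      warm, n), "gaitnarx_insufficient_data_error")
  preds <- predict_series(model, y)
  ends <- seq.int(warm, n, by = cfg$hop)
  fit <- numeric(length(ends)); degen <- logical(length(ends))
  for (i in seq_along(ends)) {
    idx <- (ends[i] - cfg$fit_window + 1L):ends[i]
    rep_ <- goodness_of_fit(preds[idx], y[idx])
    fit[i] <- if (rep_$degenerate) NA_real_ else rep_$fit
    degen[i] <- rep_$degenerate
  }
  abnormal <- degen |
    (!is.na(fit) & if (cfg$rule == "fit_below") fit < cfg$threshold
                   else fit > cfg$threshold)
  tt <- if (is.null(t)) (ends - 1) / model$fs else as.numeric(t)[ends]
  trace <- data.frame(end_index = ends - 1L,   # 0-based external convention
                      end_time_s = tt,
                      fit = fit,
                      decision = ifelse(abnormal, "abnormal", "normal"),
                      degenerate = degen,
                      stringsAsFactors = FALSE)
  first_ab <- if (any(abnormal)) trace$end_index[which(abnormal)[1]] else NA_integer_
  structure(trace, class = c("decision_trace", "data.frame"),
            config = cfg, fs = model$fs, n_samples = n,
            first_abnormal_index = first_ab)
}

#' First-abnormal summary of a decision trace
#'
#' @param trace a [classify_stream()] result.
#' @return 0-based sample index of the first abnormal window end, or `NA`.
#' @export
first_abnormal_index <- function(trace) {
  stopifnot(inherits(trace, "decision_trace"))
  attr(trace, "first_abnormal_index")
}

#' Detection latency after an abnormality onset
#'
#' Signal time from a (0-based) onset sample index to the end of the first
#' window decided abnormal at or after the onset.
#'
#' @param trace a [classify_stream()] result.
#' @param onset_index 0-based sample index of the abnormality onset; must not
#'   exceed the last classified window end.
#' @param fs sampling frequency in Hz; defaults to the trace's.
#' @return Latency in seconds, or `NA_real_` if no abnormal decision occurs
#'   at or after the onset.
#' @export
detection_latency <- function(trace, onset_index, fs = NULL) {
  stopifnot(inherits(trace, "decision_trace"))
  fs <- fs %||% attr(trace, "fs")
  if (onset_index > max(trace$end_index) || onset_index < 0)
    stop_gaitnarx("`onset_index` is outside the classified range",
                  "gaitnarx_contract_error")
  hit <- trace$decision == "abnormal" & trace$end_index >= onset_index
  if (!any(hit)) return(NA_real_)
  (trace$end_index[which(hit)[1]] - onset_index) / fs
}

#' Export a decision trace as CSV
#'
#' Columns `end_index,end_time_s,fit,decision` (0-based `end_index`).
#'
#' @param trace a [classify_stream()] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "decision_trace"))
  df <- data.frame(end_index = trace$end_index,
                   end_time_s = fmt_num(trace$end_time_s),
                   fit = ifelse(is.na(trace$fit), "NA", fmt_num(trace$fit)),
                   decision = trace$decision)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
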