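## Trial-level evaluation harness: confusion metrics, stratified k-fold
## cross-validation of the detector over a cohort, and the
## detection-latency study.

#' Confusion-matrix summary of labelled decisions
#'
#' Abnormal is the positive class. `error_rate` is computed as
#' `1 - accuracy` and `generality` as `1 - specificity`, so the two
#' complement identities hold exactly.
#'
#' @param truth,predicted character vectors of `"normal"`/`"abnormal"`
#'   labels, equal length, at least one pair.
#' @return An object of class `confusion_summary`: counts `tp`, `fp`, `tn`,
#'   `fn` and rates `accuracy`, `error_rate`, `sensitivity`, `specificity`,
#'   `generality` (a rate is `NA` when its denominator is 0).
#' @examples
#' confusion_summary(c("abnormal", "abnormal", "normal"),
#'                   c("abnormal", "normal", "normal"))
#' @export
confusion_summary <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop_gaitnarx("need at least one (truth, predicted) pair of equal length",
                  "gaitnarx_contract_error")
  ok <- c("normal", "abnormal")
  if (!all(truth %in% ok) || !all(predicted %in% ok))
    stop_gaitnarx("labels must be 'normal' or 'abnormal'",
                  "gaitnarx_contract_error")
  tp <- sum(truth == "abnormal" & predicted == "abnormal")
  fn <- sum(truth == "abnormal" & predicted == "normal")
  tn <- sum(truth == "normal" & predicted == "normal")
  fp <- sum(truth == "normal" & predicted == "abnormal")
  n <- tp + fn + tn + fp
  accuracy <- (tp + tn) / n
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = accuracy, error_rate = 1 - accuracy,
                 sensitivity = sensitivity, specificity = specificity,
                 generality = 1 - specificity),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "   NA" else sprintf("%5.2f", 100 * v)
  cat("Measure      Value (%)\n")
  cat(sprintf("Accuracy     %s\n", pct(x$accuracy)))
  cat(sprintf("Error rate   %s\n", pct(x$error_rate)))
  cat(sprintf("Sensitivity  %s\n", pct(x$sensitivity)))
  cat(sprintf("Generality   %s\n", pct(x$generality)))
  cat(sprintf("(tp=%d fp=%d tn=%d fn=%d)\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classify a whole trial recording
#'
#' Runs [classify_stream()] on the recording's scalar channel and aggregates
#' the window decisions to one trial-level label.
#'
#' @param model an `arx_model` or `narx_model`.
#' @param rec a [gait_recording()].
#' @param cfg a [detector_config()].
#' @param aggregate `"any"` (default: the trial is abnormal if at least one
#'   window is) or `"majority"`.
#' @param channel scalar channel to classify, see [signal_channel()].
#' @return List with `decision` (`"normal"`/`"abnormal"`) and the full
#'   `trace`.
#' @export
classify_trial <- function(model, rec, cfg = detector_config(),
                           aggregate = c("any", "majority"),
                           channel = "magnitude") {
  aggregate <- match.arg(aggregate)
  trace <- classify_stream(model, signal_channel(rec, channel), cfg,
                           t = rec$t)
  ab <- trace$decision == "abnormal"
  decision <- if (aggregate == "any") {
    if (any(ab)) "abnormal" else "normal"
  } else {
    if (mean(ab) > 0.5) "abnormal" else "normal"
  }
  list(decision = decision, trace = trace)
}

#' Train a per-subject normal-walk model from recordings
#'
#' Fits one model on the concatenated scalar channels of the given
#' recordings (lag windows never span recording boundaries). Abnormal-
#' labelled inputs trigger a warning: the detector models *normal* walking.
#'
#' @param recordings list of [gait_recording()].
#' @param method `"narx"` or `"arx"`.
#' @param order model order; `r` the number of sigmoid basis functions
#'   (NARX only).
#' @param r number of basis functions (NARX only).
#' @param seed,max_iter,n_starts NARX optimizer settings, see [fit_narx()].
#' @param channel scalar channel, see [signal_channel()].
#' @return An `arx_model` or `narx_model`.
#' @export
train_gait_model <- function(recordings, method = c("narx", "arx"),
                             order = 10L, r = 20L, seed = 1L,
                             max_iter = 500L, n_starts = 3L,
                             channel = "magnitude") {
  method <- match.arg(method)
  if (inherits(recordings, "gait_recording")) recordings <- list(recordings)
  if (any(vapply(recordings, `[[`, "", "label") == "abnormal"))
    warning("training input includes abnormal-labelled recordings; ",
            "the model is meant to describe normal walking")
  fs <- recordings[[1]]$fs
  segs <- lapply(recordings, signal_channel, channel = channel)
  if (method == "narx")
    fit_narx(segs, order_n = order, r = r, seed = seed, max_iter = max_iter,
             n_starts = n_starts, fs = fs)
  else
    fit_arx(segs, order_na = order, fs = fs)
}

## Stratified, seeded fold assignment over manifest rows.
assign_folds <- function(labels, folds, seed) {
  m <- length(labels)
  if (folds < 2L || folds > m)
    stop_gaitnarx(sprintf("`folds` must be in [2, %d]", m),
                  "gaitnarx_configuration_error")
  fold <- integer(m)
  with_seed(derive_seed(seed, 23), {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
    }
  })
  fold
}

#' Cross-validated evaluation of the detector over a cohort
#'
#' Trials are partitioned into seeded, label-stratified folds. For each
#' fold and each subject appearing in it, a model is trained on up to
#' `train_trials` of that subject's *normal* trials outside the fold, and
#' every in-fold trial of the subject is classified at trial level.
#' Identical training sets are fitted once and reused.
#'
#' @param cohort a `gait_cohort` from [generate_cohort()] or
#'   [load_cohort()].
#' @param method `"narx"` (default) or `"arx"`.
#' @param cfg a [detector_config()].
#' @param folds number of folds (default 10).
#' @param seed seed for fold assignment and model initialization.
#' @param train_trials maximum normal trials used to train each model
#'   (default 3).
#' @param order,r,max_iter,n_starts model hyperparameters, see
#'   [train_gait_model()].
#' @param aggregate trial-level aggregation rule, see [classify_trial()].
#' @return An object of class `cv_result`: list with `summary` (pooled
#'   [confusion_summary()]), `per_fold` (list of summaries), `decisions`
#'   (data frame: subject, trial, label, fold, decision), `skipped`
#'   (rows skipped for lack of training data).
#' @export
cross_validate <- function(cohort, method = c("narx", "arx"),
                           cfg = detector_config(), folds = 10L, seed = 1L,
                           train_trials = 3L, order = 10L, r = 20L,
                           max_iter = 500L, n_starts = 3L,
                           aggregate = "any") {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "gait_cohort"))
  man <- cohort$manifest
  if (length(unique(man$label)) < 2L)
    stop_gaitnarx("cohort must contain both normal and abnormal trials",
                  "gaitnarx_configuration_error")
  fold <- assign_folds(man$label, as.integer(folds), seed)
  cache <- new.env(parent = emptyenv())
  decisions <- vector("list", nrow(man))
  skipped <- character(0)
  for (f in sort(unique(fold))) {
    test_rows <- which(fold == f)
    for (k in test_rows) {
      subj <- man$subject[k]
      train_rows <- which(man$subject == subj & man$label == "normal" &
                            fold != f)
      if (length(train_rows) == 0L) {
        warning(sprintf("subject %s has no out-of-fold normal trial in fold %d; skipping its in-fold trials",
                        subj, f))
        skipped <- c(skipped, man$file[k])
        next
      }
      train_rows <- head(train_rows[order(man$trial[train_rows])],
                         train_trials)
      key <- paste(c(method, man$file[train_rows]), collapse = "|")
      model <- cache[[key]]
      if (is.null(model)) {
        model <- train_gait_model(
          cohort$recordings[man$file[train_rows]], method = method,
          order = order, r = r, seed = derive_seed(seed, 29, match(subj, unique(man$subject))),
          max_iter = max_iter, n_starts = n_starts)
        cache[[key]] <- model
      }
      res <- classify_trial(model, cohort$recordings[[man$file[k]]], cfg,
                            aggregate = aggregate)
      decisions[[k]] <- data.frame(subject = subj, trial = man$trial[k],
                                   label = man$label[k], fold = f,
                                   decision = res$decision,
                                   stringsAsFactors = FALSE)
    }
  }
  decisions <- do.call(rbind, decisions)
  per_fold <- lapply(sort(unique(decisions$fold)), function(f) {
    d <- decisions[decisions$fold == f, ]
    confusion_summary(d$label, d$decision)
  })
  structure(list(summary = confusion_summary(decisions$label,
                                             decisions$decision),
                 per_fold = per_fold, decisions = decisions,
                 skipped = skipped, method = method, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %s detector, %d trials\n",
              x$folds, toupper(x$method), nrow(x$decisions)))
  print(x$summary)
  invisible(x)
}

#' Detection-latency study over a cohort's abnormal trials
#'
#' Per subject, trains a model on the first `train_trials` normal trials,
#' classifies each abnormal trial, and measures [detection_latency()]
#' against the first perturbation onset at or after the first decidable
#' window end (the detector needs one full FIT window of history before it
#' can decide, so onsets inside that warm-up cannot be charged to the
#' detector). Trials whose onsets all fall inside the warm-up are excluded
#' and counted.
#'
#' @inheritParams cross_validate
#' @return List with `latencies_s` (per usable abnormal trial; `NA` =
#'   undetected), `median_s`, `p90_s` (of detected trials), `fraction_undetected`,
#'   `n_trials`, `n_excluded`.
#' @export
latency_study <- function(cohort, method = c("narx", "arx"),
                          cfg = detector_config(), seed = 1L,
                          train_trials = 3L, order = 10L, r = 20L,
                          max_iter = 500L, n_starts = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "gait_cohort"))
  man <- cohort$manifest
  lat <- numeric(0); n_excluded <- 0L
  for (subj in unique(man$subject)) {
    train_rows <- which(man$subject == subj & man$label == "normal")
    train_rows <- head(train_rows[order(man$trial[train_rows])], train_trials)
    if (length(train_rows) == 0L) next
    model <- train_gait_model(
      cohort$recordings[man$file[train_rows]], method = method,
      order = order, r = r,
      seed = derive_seed(seed, 29, match(subj, unique(man$subject))),
      max_iter = max_iter, n_starts = n_starts)
    ab_rows <- which(man$subject == subj & man$label == "abnormal")
    for (k in ab_rows) {
      rec <- cohort$recordings[[man$file[k]]]
      onsets <- rec$meta$onsets
      if (is.null(onsets))
        stop_gaitnarx(sprintf("abnormal trial %s has no onset metadata",
                              man$file[k]), "gaitnarx_contract_error")
      trace <- classify_stream(model, signal_channel(rec), cfg, t = rec$t)
      usable <- onsets[onsets >= trace$end_index[1]]
      if (length(usable) == 0L) { n_excluded <- n_excluded + 1L; next }
      lat <- c(lat, detection_latency(trace, usable[1]))
    }
  }
  detected <- lat[!is.na(lat)]
  list(latencies_s = lat,
       median_s = if (length(detected)) median(detected) else NA_real_,
       p90_s = if (length(detected)) unname(quantile(detected, 0.9)) else NA_real_,
       fraction_undetected = if (length(lat)) mean(is.na(lat)) else NA_real_,
       n_trials = length(lat), n_excluded = n_excluded)
}
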