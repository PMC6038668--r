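## Seeded simulator of normal and obstacle-perturbed walking accelerometry.
## It emulates the data-collection protocol the detector is designed for:
## a lower-back tri-axial accelerometer at 10 Hz, per subject 5 repetitions
## of 10 s normal walk and 10 s walk through obstacles. Normal gait is a
## subject-specific quasi-periodic signal (stride fundamental plus
## harmonics, vertical axis dominant, gravity offset, sensor noise);
## abnormality is transient stumble-like bursts added to the normal signal.

#' Specification of a synthetic walking cohort
#'
#' Defaults are the simulated study conditions: 31 subjects, 5 trials per
#' condition, 10 s per trial at 10 Hz, stride fundamentals drawn uniformly
#' from 0.8-1.2 Hz with 3 harmonics, sensor noise 0.1 m/s^2, and stumble
#' perturbations at 1 event/s lasting 3 samples with amplitude 4x the
#' subject's oscillatory RMS.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per subject per condition.
#' @param duration_s trial duration in seconds.
#' @param fs sampling frequency in Hz.
#' @param stride_hz_range range the per-subject stride fundamental is drawn
#'   from, in Hz.
#' @param n_harmonics number of stride harmonics.
#' @param noise_sd i.i.d. Gaussian sensor noise, m/s^2.
#' @param perturb_rate perturbation events per second in abnormal trials.
#' @param perturb_mult burst amplitude as a multiple of the subject's
#'   per-axis oscillatory RMS.
#' @param perturb_duration burst duration in samples.
#' @param seed master seed; the whole cohort is a pure function of the spec
#'   including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 31L, trials_per_condition = 5L,
                        duration_s = 10, fs = 10,
                        stride_hz_range = c(0.8, 1.2), n_harmonics = 3L,
                        noise_sd = 0.1, perturb_rate = 1.0,
                        perturb_mult = 4, perturb_duration = 3L,
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               trials_per_condition = as.integer(trials_per_condition),
               duration_s = duration_s, fs = fs,
               stride_hz_range = as.numeric(stride_hz_range),
               n_harmonics = as.integer(n_harmonics),
               noise_sd = noise_sd, perturb_rate = perturb_rate,
               perturb_mult = perturb_mult,
               perturb_duration = as.integer(perturb_duration),
               seed = as.integer(seed))
  if (spec$n_subjects < 1L || spec$trials_per_condition < 1L ||
      spec$n_harmonics < 1L || spec$perturb_duration < 1L)
    stop_gaitnarx("all counts in a cohort spec must be >= 1",
                  "gaitnarx_contract_error")
  if (spec$noise_sd < 0 || spec$perturb_rate < 0 || spec$perturb_mult < 0)
    stop_gaitnarx("noise_sd, perturb_rate, perturb_mult must be >= 0",
                  "gaitnarx_contract_error")
  check_scalar_number(spec$fs, "fs", positive = TRUE)
  check_scalar_number(spec$duration_s, "duration_s", positive = TRUE)
  structure(spec, class = "cohort_spec")
}

## Per-subject gait signature, a pure function of (spec$seed, subject):
## stride fundamental, per-axis per-harmonic amplitudes and phases.
subject_params <- function(spec, subject) {
  with_seed(derive_seed(spec$seed, 11, subject), {
    stride_hz <- runif(1, spec$stride_hz_range[1], spec$stride_hz_range[2])
    h <- seq_len(spec$n_harmonics)
    base <- list(ax = 0.8 / h, ay = 0.8 / h, az = 2.5 / h)
    amps <- lapply(base, function(b) b * runif(spec$n_harmonics, 0.8, 1.2))
    phases <- lapply(1:3, function(i) runif(spec$n_harmonics, 0, 2 * pi))
    names(phases) <- c("ax", "ay", "az")
    list(stride_hz = stride_hz, amps = amps, phases = phases)
  })
}

GRAVITY <- 9.80665

## Noise-free periodic component of one axis at time points tt (s), with a
## trial-level time offset tau.
axis_waveform <- function(sp, axis, tt, tau) {
  h <- seq_along(sp$amps[[axis]])
  out <- numeric(length(tt))
  for (k in h)
    out <- out + sp$amps[[axis]][k] *
      sin(2 * pi * k * sp$stride_hz * (tt + tau) + sp$phases[[axis]][k])
  out
}

gen_base <- function(spec, subject, trial) {
  sp <- subject_params(spec, subject)
  n <- round(spec$duration_s * spec$fs)
  tt <- (seq_len(n) - 1) / spec$fs
  with_seed(derive_seed(spec$seed, 13, subject, trial), {
    tau <- runif(1, 0, 1 / sp$stride_hz)
    ax <- axis_waveform(sp, "ax", tt, tau) + rnorm(n, 0, spec$noise_sd)
    ay <- axis_waveform(sp, "ay", tt, tau) + rnorm(n, 0, spec$noise_sd)
    az <- GRAVITY + axis_waveform(sp, "az", tt, tau) +
      rnorm(n, 0, spec$noise_sd)
    list(t = tt, ax = ax, ay = ay, az = az, params = sp)
  })
}

#' Generate one synthetic normal-walk recording
#'
#' The per-axis signal is the subject's sum of stride harmonics (drawn once
#' per subject, so all of a subject's trials share a gait signature) at a
#' trial-specific phase, a gravity offset on the vertical axis, and i.i.d.
#' Gaussian sensor noise. Deterministic given `(spec, subject, trial)`.
#'
#' @param spec a [cohort_spec()].
#' @param subject subject index (1-based).
#' @param trial trial index (1-based).
#' @return A [gait_recording()] with `label = "normal"`.
#' @export
generate_normal <- function(spec, subject, trial) {
  stopifnot(inherits(spec, "cohort_spec"))
  b <- gen_base(spec, subject, trial)
  gait_recording(b$t, b$ax, b$ay, b$az, fs = spec$fs,
                 subject_id = sprintf("s%02d", subject),
                 trial_id = sprintf("t%d", trial), label = "normal")
}

#' Generate one synthetic obstacle-perturbed (abnormal) recording
#'
#' The subject's normal signal for the same `(subject, trial)` sub-seed,
#' plus seeded transient bursts emulating stepping/tripping/stumbling over
#' obstacles: event onsets from a Poisson process at `perturb_rate`, each
#' event adding to every axis a half-sine burst of `perturb_duration`
#' samples with amplitude `perturb_mult` times that axis's oscillatory RMS,
#' random sign and sub-sample phase jitter. Onset indices (0-based) are
#' recorded in `meta$onsets` and the manifest. With `perturb_mult = 0` the
#' recording equals the matching normal one exactly.
#'
#' @inheritParams generate_normal
#' @return A [gait_recording()] with `label = "abnormal"` and onset metadata.
#' @export
generate_abnormal <- function(spec, subject, trial) {
  stopifnot(inherits(spec, "cohort_spec"))
  b <- gen_base(spec, subject, trial)
  n <- length(b$t)
  d <- spec$perturb_duration
  ## closed-form oscillatory RMS of a sum of sinusoids: sqrt(sum A_h^2 / 2)
  rms <- vapply(b$params$amps, function(a) sqrt(sum(a^2) / 2), numeric(1))
  ev <- with_seed(derive_seed(spec$seed, 17, subject, trial), {
    n_ev <- stats::rpois(1, spec$perturb_rate * spec$duration_s)
    onsets <- sort(sample.int(max(1L, n - d), n_ev, replace = FALSE))
    signs <- matrix(sample(c(-1, 1), 3 * n_ev, replace = TRUE), ncol = 3)
    jitter <- runif(n_ev, -0.5, 0.5)
    list(onsets = onsets, signs = signs, jitter = jitter)
  })
  for (e in seq_along(ev$onsets)) {
    idx <- ev$onsets[e]:(ev$onsets[e] + d - 1L)
    env <- sin(pi * (seq_len(d) - 0.5 + ev$jitter[e]) / d)
    b$ax[idx] <- b$ax[idx] + ev$signs[e, 1] * spec$perturb_mult * rms["ax"] * env
    b$ay[idx] <- b$ay[idx] + ev$signs[e, 2] * spec$perturb_mult * rms["ay"] * env
    b$az[idx] <- b$az[idx] + ev$signs[e, 3] * spec$perturb_mult * rms["az"] * env
  }
  gait_recording(b$t, b$ax, b$ay, b$az, fs = spec$fs,
                 subject_id = sprintf("s%02d", subject),
                 trial_id = sprintf("t%d", trial), label = "abnormal",
                 meta = list(onsets = as.integer(ev$onsets - 1L)))  # 0-based
}

#' Generate a full synthetic cohort
#'
#' `n_subjects x trials_per_condition` normal and as many abnormal
#' recordings, plus a manifest. Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, every recording is written
#'   as CSV (dialect of [write_recording()]) together with `manifest.csv`
#'   (header `subject,trial,label,file,onsets`, onsets semicolon-separated
#'   0-based sample indices). When `NULL` the cohort is returned in memory
#'   only.
#' @return An object of class `gait_cohort`: list with `manifest` (data
#'   frame), `recordings` (named list of [gait_recording()]), `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list(); rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (tr in seq_len(spec$trials_per_condition)) {
      for (lab in c("normal", "abnormal")) {
        rec <- if (lab == "normal") generate_normal(spec, s, tr)
               else generate_abnormal(spec, s, tr)
        file <- sprintf("s%02d_t%d_%s.csv", s, tr, lab)
        recs[[file]] <- rec
        rows[[file]] <- data.frame(
          subject = rec$subject_id, trial = rec$trial_id, label = lab,
          file = file,
          onsets = paste(rec$meta$onsets %||% integer(0), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop_gaitnarx(sprintf("cannot create directory %s", out_dir),
                    "gaitnarx_io_error")
    for (f in names(recs)) write_recording(recs[[f]], file.path(out_dir, f))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE, quote = FALSE)
  }
  structure(list(manifest = manifest, recordings = recs, spec = spec),
            class = "gait_cohort")
}

#' Load a cohort written by [generate_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the recording CSVs.
#' @return A `gait_cohort` (without the generating spec).
#' @export
load_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath))
    stop_gaitnarx(sprintf("no manifest.csv in %s", dir), "gaitnarx_io_error")
  manifest <- read.csv(mpath, stringsAsFactors = FALSE,
                       colClasses = c(onsets = "character"))
  recs <- list()
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    rec <- read_recording(file.path(dir, row$file),
                          subject_id = row$subject, trial_id = row$trial)
    rec$label <- row$label
    ons <- row$onsets
    if (!is.na(ons) && nzchar(ons))
      rec$meta$onsets <- as.integer(strsplit(ons, ";", fixed = TRUE)[[1]])
    recs[[row$file]] <- rec
  }
  structure(list(manifest = manifest, recordings = recs, spec = NULL),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d recordings (%d normal, %d abnormal), %d subjects\n",
              nrow(x$manifest), sum(x$manifest$label == "normal"),
              sum(x$manifest$label == "abnormal"),
              length(unique(x$manifest$subject))))
  invisible(x)
}
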