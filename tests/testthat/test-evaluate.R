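test_that("confusion summary matches hand arithmetic with abnormal positive", {
  truth <- c(rep("abnormal", 10), rep("normal", 10))
  pred <- c(rep("abnormal", 9), "normal", rep("normal", 10))
  s <- confusion_summary(truth, pred)
  expect_equal(c(s$tp, s$fn, s$tn, s$fp), c(9, 1, 10, 0))
  expect_equal(s$sensitivity, 0.9)
  expect_equal(s$specificity, 1.0)
  expect_equal(s$generality, 0.0)
  expect_equal(s$accuracy, 0.95)
})

test_that("complement identities hold exactly and perfect prediction scores 1", {
  s <- confusion_summary(c("normal", "abnormal"), c("normal", "abnormal"))
  expect_identical(s$accuracy, 1)
  expect_identical(s$error_rate, 0)
  set.seed(6)
  truth <- sample(c("normal", "abnormal"), 37, replace = TRUE)
  pred <- sample(c("normal", "abnormal"), 37, replace = TRUE)
  s2 <- confusion_summary(truth, pred)
  expect_identical(s2$accuracy + s2$error_rate, 1)
  expect_identical(s2$generality, 1 - s2$specificity)
  expect_error(confusion_summary(character(0), character(0)),
               class = "gaitnarx_contract_error")
  # no abnormal instances: sensitivity undefined
  s3 <- confusion_summary(c("normal", "normal"), c("normal", "abnormal"))
  expect_true(is.na(s3$sensitivity))
})

small_cohort <- function(seed, n_subjects = 2, trials = 3) {
  generate_cohort(cohort_spec(n_subjects = n_subjects,
                              trials_per_condition = trials, seed = seed))
}

test_that("cross-validation partitions trials exactly once and conserves counts", {
  cohort <- small_cohort(13)
  cv2 <- cross_validate(cohort, "arx", folds = 2, seed = 1)
  expect_equal(nrow(cv2$decisions), nrow(cohort$manifest))
  key <- paste(cv2$decisions$subject, cv2$decisions$trial, cv2$decisions$label)
  expect_equal(sort(key), sort(paste(cohort$manifest$subject,
                                     cohort$manifest$trial,
                                     cohort$manifest$label)))
  # leave-one-out conserves the same totals
  loo <- cross_validate(cohort, "arx", folds = nrow(cohort$manifest), seed = 1)
  s2 <- cv2$summary; sl <- loo$summary
  expect_equal(s2$tp + s2$fp + s2$tn + s2$fn, nrow(cohort$manifest))
  expect_equal(sl$tp + sl$fp + sl$tn + sl$fn, nrow(cohort$manifest))
  # per-fold counts add up to the pooled counts
  tot <- Reduce(`+`, lapply(cv2$per_fold, function(f) f$tp + f$fp + f$tn + f$fn))
  expect_equal(tot, nrow(cohort$manifest))
})

test_that("cross-validation is deterministic given the seed", {
  cohort <- small_cohort(17)
  a <- cross_validate(cohort, "arx", folds = 3, seed = 5)
  b <- cross_validate(cohort, "arx", folds = 3, seed = 5)
  expect_identical(a$decisions, b$decisions)
  c_ <- cross_validate(cohort, "arx", folds = 3, seed = 6)
  expect_false(identical(a$decisions$fold, c_$decisions$fold))
})

test_that("cross-validation refuses single-label cohorts and bad fold counts", {
  cohort <- small_cohort(19)
  keep <- cohort$manifest$label == "normal"
  normal_only <- structure(list(manifest = cohort$manifest[keep, ],
                                recordings = cohort$recordings[cohort$manifest$file[keep]],
                                spec = cohort$spec), class = "gait_cohort")
  expect_error(cross_validate(normal_only, "arx"),
               class = "gaitnarx_configuration_error")
  expect_error(cross_validate(cohort, "arx", folds = 1),
               class = "gaitnarx_configuration_error")
  expect_error(cross_validate(cohort, "arx", folds = 1000),
               class = "gaitnarx_configuration_error")
})

test_that("training on abnormal-labelled input warns", {
  cohort <- small_cohort(23)
  ab_file <- cohort$manifest$file[cohort$manifest$label == "abnormal"][1]
  expect_warning(train_gait_model(cohort$recordings[ab_file], method = "arx"),
                 "abnormal")
})

test_that("latency study with zero-amplitude perturbations detects nothing", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 2,
                                        trials_per_condition = 3,
                                        perturb_mult = 0, seed = 29))
  ls <- latency_study(cohort, method = "arx", seed = 1)
  expect_true(all(is.na(ls$latencies_s)))
  expect_equal(ls$fraction_undetected, 1.0)
})

test_that("latency study agrees with direct per-trial recomputation", {
  cohort <- small_cohort(37)
  ls <- latency_study(cohort, method = "arx", seed = 2)
  man <- cohort$manifest
  cfg <- detector_config()
  lat <- numeric(0); excluded <- 0L
  for (subj in unique(man$subject)) {
    rows <- which(man$subject == subj & man$label == "normal")
    rows <- head(rows[order(man$trial[rows])], 3)
    model <- train_gait_model(cohort$recordings[man$file[rows]], "arx")
    for (k in which(man$subject == subj & man$label == "abnormal")) {
      rec <- cohort$recordings[[man$file[k]]]
      trace <- classify_stream(model, magnitude_series(rec), cfg, t = rec$t)
      usable <- rec$meta$onsets[rec$meta$onsets >= trace$end_index[1]]
      if (!length(usable)) { excluded <- excluded + 1L; next }
      lat <- c(lat, detection_latency(trace, usable[1]))
    }
  }
  expect_equal(ls$latencies_s, lat)
  expect_equal(ls$n_excluded, excluded)
  expect_equal(ls$median_s, median(lat[!is.na(lat)]))
})
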