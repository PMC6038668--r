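test_that("detector config validates window geometry", {
  expect_error(detector_config(pred_window = 10, fit_window = 5),
               class = "gaitnarx_contract_error")
  expect_error(detector_config(hop = 0), class = "gaitnarx_contract_error")
  cfg <- detector_config()
  expect_equal(c(cfg$pred_window, cfg$fit_window, cfg$hop), c(10L, 50L, 1L))
  expect_equal(cfg$threshold, 0.02)
  expect_equal(cfg$rule, "fit_below")
})

test_that("a model's own noise-free trajectory is classified normal everywhere", {
  planted <- planted_narx()
  y <- planted_trajectory(planted, 200)
  trace <- classify_stream(planted, y, detector_config())
  expect_true(all(trace$decision == "normal"))
  expect_true(all(trace$fit > 0.99))
  expect_true(is.na(first_abnormal_index(trace)))
})

test_that("heavy unrelated noise is classified abnormal in the majority of windows", {
  spec <- cohort_spec(n_subjects = 1, seed = 21)
  model <- fit_narx(lapply(1:3, function(tr)
    magnitude_series(generate_normal(spec, 1, tr))), seed = 4)
  set.seed(99)
  noise <- rnorm(150, mean = 9.8, sd = 3)
  trace <- classify_stream(model, noise, detector_config())
  expect_gt(mean(trace$decision == "abnormal"), 0.5)
})

test_that("decision-window bookkeeping matches closed-form arithmetic", {
  planted <- planted_narx()
  fw <- 20L
  cfg <- detector_config(pred_window = 3L, fit_window = fw, hop = fw)
  y <- planted_trajectory(planted, 2L * fw + planted$order)
  trace <- classify_stream(planted, y, cfg)
  expect_equal(nrow(trace), 2L)
  expect_equal(n_decision_windows(length(y), cfg), 2L)
  expect_equal(trace$end_index, c(fw + 3L, 2L * fw + 3L) - 1L)
  short <- planted_trajectory(planted, fw)
  expect_error(classify_stream(planted, short, cfg),
               class = "gaitnarx_insufficient_data_error")
})

test_that("degenerate thresholds give all-normal / all-abnormal decisions", {
  planted <- planted_narx()
  y <- planted_trajectory(planted, 150)
  lo <- classify_stream(planted, y, detector_config(threshold = -Inf))
  hi <- classify_stream(planted, y, detector_config(threshold = Inf))
  expect_true(all(lo$decision == "normal"))
  expect_true(all(hi$decision == "abnormal"))
})

test_that("stored FIT values equal an independent double-loop recomputation", {
  spec <- cohort_spec(n_subjects = 1, seed = 31)
  model <- fit_arx(magnitude_series(generate_normal(spec, 1, 1)), order_na = 5)
  rec <- generate_abnormal(spec, 1, 2)
  y <- magnitude_series(rec)[1:100]
  for (cfg in list(detector_config(pred_window = 5, fit_window = 30, hop = 1),
                   detector_config(pred_window = 10, fit_window = 25, hop = 7))) {
    trace <- classify_stream(model, y, cfg)
    preds <- predict_series(model, y)
    oracle <- oracle_window_fits(preds, y, cfg$pred_window, cfg$fit_window,
                                 cfg$hop)
    expect_equal(trace$end_index, oracle$ends - 1L)
    expect_equal(trace$fit, oracle$fits, tolerance = 1e-10)
  }
})

test_that("decisions are invariant to dropping leading samples", {
  planted <- planted_narx()
  y <- planted_trajectory(planted, 160)
  cfg <- detector_config(pred_window = 3, fit_window = 30)
  full <- classify_stream(planted, y, cfg)
  k <- 2L   # k < order
  shifted <- classify_stream(planted, y[(k + 1):length(y)], cfg)
  common <- intersect(full$end_index, shifted$end_index + k)
  expect_gt(length(common), 100)
  expect_equal(shifted$fit[match(common, shifted$end_index + k)],
               full$fit[match(common, full$end_index)], tolerance = 1e-12)
})

test_that("detection latency counts samples from onset to first abnormal window end", {
  spec <- cohort_spec(n_subjects = 1, seed = 41)
  model <- fit_narx(lapply(1:3, function(tr)
    magnitude_series(generate_normal(spec, 1, tr))), seed = 6)
  rec <- generate_abnormal(spec, 1, 4)
  y <- magnitude_series(rec)
  cfg <- detector_config()
  trace <- classify_stream(model, y, cfg)
  onsets <- rec$meta$onsets
  onset <- onsets[onsets >= trace$end_index[1]][1]
  expect_false(is.na(onset))
  lat <- detection_latency(trace, onset)
  # hand recomputation from the trace itself
  hits <- trace$end_index[trace$decision == "abnormal" &
                            trace$end_index >= onset]
  expect_equal(lat, (hits[1] - onset) / rec$fs)
  expect_error(detection_latency(trace, max(trace$end_index) + 1),
               class = "gaitnarx_contract_error")
  # a trace with no abnormal decisions gives NA
  normal_trace <- classify_stream(model,
                                  magnitude_series(generate_normal(spec, 1, 5)),
                                  cfg)
  expect_true(all(normal_trace$decision == "normal"))
  expect_true(is.na(detection_latency(normal_trace, normal_trace$end_index[1])))
})

test_that("trace CSV export has one row per window and the documented header", {
  planted <- planted_narx()
  y <- planted_trajectory(planted, 100)
  trace <- classify_stream(planted, y, detector_config(pred_window = 3,
                                                       fit_window = 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(trace, path)
  lines <- readLines(path)
  expect_equal(lines[1], "end_index,end_time_s,fit,decision")
  expect_equal(length(lines) - 1L, nrow(trace))
})
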