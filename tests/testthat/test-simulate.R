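test_that("ground truth is reproducible and conserves the recording span", {
  spec <- sim_spec(duration_s = 7200)
  a <- simulate_hypnogram(spec, seed = 5)
  b <- simulate_hypnogram(spec, seed = 5)
  expect_identical(a$hypnogram$state, b$hypnogram$state)
  expect_identical(a$events, b$events)
  expect_false(identical(
    a$hypnogram$state, simulate_hypnogram(spec, seed = 6)$hypnogram$state
  ))
  expect_equal(sum(a$bouts$duration_s), 7200)
  expect_equal(nrow(a$hypnogram), 7200)
})

test_that("degenerate wake-dominated spec gives an all-wake truth", {
  spec <- sim_spec(duration_s = 3600,
                   sleep_fraction = c(light = 1e-6, dark = 1e-6),
                   sleep_bout_median_s = c(light = 60, dark = 60),
                   min_sleep_bout_s = 60, brief_arousal_rate_per_h = 0)
  # wake medians derived from a near-zero sleep fraction are enormous:
  # the first wake bout swallows the recording (given a wake start)
  gt <- simulate_hypnogram(spec, seed = 12)
  expect_equal(as.character(unique(gt$hypnogram$state)), "wake")
})

test_that("realised light-phase sleep fraction matches its target", {
  spec <- sim_spec(duration_s = 43200, light_s = 86400,  # all light phase
                   brief_arousal_rate_per_h = 0)
  fracs <- vapply(1:30, function(s) {
    gt <- simulate_hypnogram(spec, seed = s)
    mean(gt$hypnogram$state == "sleep")
  }, 0)
  expect_equal(mean(fracs), spec$sleep_fraction[["light"]], tolerance = 0.03 / 0.65)
})

test_that("arousals are brief, logged, and carved out of sleep", {
  spec <- sim_spec(duration_s = 14400, brief_arousal_rate_per_h = 20)
  gt <- simulate_hypnogram(spec, seed = 9)
  expect_gt(nrow(gt$events), 0)
  expect_true(all(gt$events$duration_s < 40))
  expect_true(all(gt$events$duration_s >= 2))
  # each logged arousal is wake in the truth labels
  for (i in seq_len(min(5, nrow(gt$events)))) {
    b <- round(gt$events$onset_s[i]) + 1
    expect_equal(as.character(gt$hypnogram$state[b]), "wake")
  }
})

test_that("intervention multipliers shift sleep in the expected direction", {
  base <- sim_spec(duration_s = 43200)
  caffeine <- sim_spec(duration_s = 43200,
                       intervention_multipliers = c(sleep = 0.4, wake = 2.5))
  diazepam <- sim_spec(duration_s = 43200,
                       intervention_multipliers = c(sleep = 2.0, wake = 0.5))
  tot <- function(spec) mean(vapply(1:8, function(s)
    total_sleep(simulate_hypnogram(spec, seed = s)$hypnogram), 0))
  expect_lt(tot(caffeine), tot(base))
  expect_gt(tot(diazepam), tot(base))
})

test_that("separated trace noise lets the scorer recover the truth exactly", {
  spec <- sim_spec(duration_s = 14400, quantize_s = 10,
                   brief_arousal_rate_per_h = 0, min_sleep_bout_s = 60)
  gt <- simulate_hypnogram(spec, seed = 31)
  tr <- simulate_trace(gt, trace_noise_spec(dropout_prob = 0), seed = 32)
  expect_identical(simulate_trace(gt, seed = 32)$count, tr$count)
  h <- score_sleep(binarize(tr, 5, 1000), 40)
  expect_identical(as.character(h$state), as.character(gt$hypnogram$state))
})

test_that("all-sleep truth with sub-threshold breathing scores as full sleep", {
  spec <- sim_spec(duration_s = 3600, quantize_s = 10,
                   sleep_fraction = c(light = 0.999999, dark = 0.999999),
                   sleep_bout_median_s = c(light = 1e6, dark = 1e6),
                   brief_arousal_rate_per_h = 0)
  gt <- simulate_hypnogram(spec, seed = 3)
  expect_equal(as.character(unique(gt$hypnogram$state)), "sleep")
  tr <- simulate_trace(gt, seed = 4)
  expect_equal(total_sleep(score_sleep(binarize(tr, 5, 1000), 40)), 3600)
})

test_that("scorer accuracy degrades monotonically as distributions overlap", {
  spec <- sim_spec(duration_s = 14400, brief_arousal_rate_per_h = 0)
  gt <- simulate_hypnogram(spec, seed = 77)
  truth <- as.character(gt$hypnogram$state)
  acc <- vapply(c(0, 60, 120, 200), function(overlap) {
    noise <- trace_noise_spec(wake_mean = 500 - overlap * 1.5,
                              wake_floor = max(0, 100 - overlap),
                              sleep_mean = 8 + overlap)
    tr <- simulate_trace(gt, noise, seed = 78)
    h <- score_sleep(binarize(tr, 5, 1000), 40)
    mean(as.character(h$state) == truth)
  }, 0)
  expect_true(all(diff(acc) <= 1e-9))
  expect_lt(acc[4], acc[1])
})

test_that("trace respects dropout and the frame-area ceiling", {
  spec <- sim_spec(duration_s = 7200)
  gt <- simulate_hypnogram(spec, seed = 41)
  noise <- trace_noise_spec(dropout_prob = 0.3, frame_area = 300)
  tr <- simulate_trace(gt, noise, seed = 42)
  expect_true(all(tr$count >= 0 & tr$count <= 300))
  wake_bins <- gt$hypnogram$state == "wake"
  expect_gt(mean(tr$count[wake_bins] == 0), 0.2)   # dropout visible in wake
})

test_that("degraded references flip epochs at the requested rates", {
  spec <- sim_spec(duration_s = 86400, quantize_s = 10)
  gt <- simulate_hypnogram(spec, seed = 55)
  ref <- degrade_reference(gt, sensitivity = 1, specificity = 1,
                           rem_fraction = 0.12, seed = 56)
  truth_epochs <- resample_epochs(gt$hypnogram, 10)
  expect_identical(as.character(collapse_reference(ref)$state),
                   as.character(truth_epochs$state))

  # sensitivity 0: no sleep epoch survives where the truth slept
  ref0 <- degrade_reference(gt, sensitivity = 0, specificity = 1, seed = 57)
  truth_sleep <- truth_epochs$state == "sleep"
  expect_true(all(ref0$label[truth_sleep] == "wake"))

  # 0.9/0.9: empirical epoch agreement 0.9 within binomial tolerance (n = 8640)
  ref9 <- degrade_reference(gt, sensitivity = 0.9, specificity = 0.9, seed = 58)
  agree <- mean((ref9$label != "wake") == truth_sleep)
  expect_equal(agree, 0.9, tolerance = 0.01 / 0.9)

  # REM fraction among scored-sleep epochs
  sleep_lab <- as.character(ref9$label[ref9$label != "wake"])
  expect_equal(mean(sleep_lab == "rem"), 0.12, tolerance = 0.25)
})

test_that("generated artifacts satisfy downstream preconditions", {
  spec <- sim_spec(duration_s = 7200, quantize_s = 10)
  gt <- simulate_hypnogram(spec, seed = 71)
  tr <- simulate_trace(gt, seed = 72)
  ref <- degrade_reference(gt, seed = 73)
  # contract: these compose without error
  cal <- calibrate_threshold(tr, collapse_reference(ref))
  h <- score_sleep(binarize(tr, cal$best_pct, cal$reference_count), 40)
  rep <- compare_hypnograms(h, ref)
  expect_s3_class(rep, "agreement_report")
  expect_true(is.finite(rep$consistency_pct))
  sw <- parameter_sweep(tr, ref)
  expect_equal(nrow(sw), 3)
})
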