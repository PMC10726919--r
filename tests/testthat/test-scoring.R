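test_that("binarize applies a strict threshold on the reference-count scale", {
  tr <- make_trace(c(10, 300, 12))
  a <- binarize(tr, threshold_pct = 5, reference_count = 1000)  # cutoff 50 px
  expect_equal(a$active, c(FALSE, TRUE, FALSE))

  # all-zero counts are inactive at any positive threshold
  expect_false(any(binarize(make_trace(rep(0, 50)), 10)$active))

  # threshold 0: strictly positive counts are active, zeros are not
  a0 <- binarize(make_trace(c(0, 1, 0, 7)), 0, reference_count = 1000)
  expect_equal(a0$active, c(FALSE, TRUE, FALSE, TRUE))

  expect_error(binarize(tr, 5, reference_count = 0), "positive")
  expect_error(binarize(tr, 101, reference_count = 10), "<= 100")
})

test_that("default reference count is the 99th percentile of positive counts", {
  counts <- c(rep(0, 10), 1:100)
  tr <- make_trace(counts)
  a <- binarize(tr, 50)
  expect_equal(attr(a, "reference_count"), quantile(1:100, .99, names = FALSE))
})

test_that("immobility rule labels whole qualifying runs as sleep", {
  act <- function(x) {
    structure(tibble::tibble(time_s = seq_along(x) - 1, active = x),
              bin_s = 1, start_clock = "08:00",
              class = c("activity_series", "tbl_df", "tbl", "data.frame"))
  }
  # one hour fully immobile -> one sleep bout of 3600 s
  h <- score_sleep(act(rep(FALSE, 3600)), 40)
  expect_equal(total_sleep(h), 3600)
  expect_equal(nrow(to_bouts(h)), 1)

  # 39 s immobile run flanked by activity stays wake
  h39 <- score_sleep(act(c(TRUE, rep(FALSE, 39), TRUE)), 40)
  expect_equal(total_sleep(h39), 0)

  # exactly 40 s qualifies (inclusive rule)
  h40 <- score_sleep(act(c(TRUE, rep(FALSE, 40), TRUE)), 40)
  expect_equal(total_sleep(h40), 40)

  # runs of 50, 30, 120 s separated by single active bins: 50 + 120 = 170 s
  x <- c(rep(FALSE, 50), TRUE, rep(FALSE, 30), TRUE, rep(FALSE, 120))
  expect_equal(total_sleep(score_sleep(act(x), 40)), 170)

  # edge-truncated runs qualify by observed duration
  expect_equal(total_sleep(score_sleep(act(rep(FALSE, 45)), 40)), 45)

  # rule must be a multiple of the bin width and at least one bin
  expect_error(score_sleep(act(rep(FALSE, 100)), 40.5), "multiple")
  expect_error(score_sleep(act(rep(FALSE, 100)), 0.5), ">=")
})

test_that("score_sleep agrees with the brute-force run scan on random activity", {
  for (seed in 1:25) {
    x <- random_activity(2000, seed = seed)
    tr <- make_trace(ifelse(x, 500L, 0L))
    for (T in c(35, 40, 45)) {
      h <- score_sleep(binarize(tr, 5, 1000), T)
      expect_identical(as.character(h$state), oracle_score_sleep(x, 1, T))
    }
  }
})

test_that("hourly sleep conserves total sleep and validates the span", {
  h <- random_hypnogram(24 * 3600, seed = 11)
  hs <- hourly_sleep(h)
  expect_equal(nrow(hs), 24)
  expect_equal(sum(hs$sleep_s), total_sleep(h))
  expect_true(all(hs$sleep_s >= 0 & hs$sleep_s <= 3600))

  all_sleep <- hypnogram(rep("sleep", 86400))
  expect_equal(hourly_sleep(all_sleep)$sleep_s, rep(3600, 24))
  expect_equal(total_sleep(all_sleep), 86400)

  one_hour <- hypnogram(c(rep("sleep", 3600), rep("wake", 3600)))
  expect_equal(hourly_sleep(one_hour)$sleep_s, c(3600, 0))

  expect_error(hourly_sleep(hypnogram(rep("wake", 5000))), "whole number of hours")
})

test_that("bout round-trip is the identity and matches a naive scan", {
  for (seed in 1:10) {
    h <- random_hypnogram(500, seed = seed)
    b <- to_bouts(h)
    # contiguous, alternating, reconstructs exactly
    expect_equal(b$onset_s, cumsum(c(0, head(b$duration_s, -1))))
    expect_true(all(b$state[-1] != head(b$state, -1)))
    h2 <- bouts_to_hypnogram(b)
    expect_equal(as.character(h2$state), as.character(h$state))
    # naive scan oracle
    r <- rle(as.character(h$state))
    expect_equal(b$state, r$values)
    expect_equal(b$duration_s, as.numeric(r$lengths))
  }
  # alternating single bins at T = bin_s
  alt <- hypnogram(rep(c("sleep", "wake"), 10))
  expect_true(all(to_bouts(alt)$duration_s == 1))
})

test_that("threshold calibration finds separated cutoffs and reports the curve", {
  # wake counts 800, sleep counts 0, reference 1000: thresholds 5..75 perfect
  states <- rep(c("wake", "sleep"), each = 300)
  tr <- make_trace(ifelse(states == "wake", 800L, 0L))
  ref <- hypnogram(states)
  cal <- calibrate_threshold(tr, ref, reference_count = 1000)
  perfect <- cal$curve$accuracy == 1
  expect_equal(cal$curve$threshold_pct[perfect], seq(0, 75, 5))
  expect_equal(cal$best_pct, 0)  # ties go to the lowest threshold

  # all-wake reference with an always-active trace: flat curve at 1 below counts
  tr2 <- make_trace(rep(600L, 200))
  cal2 <- calibrate_threshold(tr2, hypnogram(rep("wake", 200)),
                              reference_count = 1000)
  low <- cal2$curve$threshold_pct < 60
  expect_true(all(cal2$curve$accuracy[low] == 1))

  expect_error(calibrate_threshold(make_trace(1:10), hypnogram(rep("wake", 9))),
               "misaligned")
})

test_that("calibration lands within a grid step of a fine-grid brute force", {
  for (rep_i in 1:8) {
    sim <- overlap_trace_fixture(rep_i)
    cal <- calibrate_threshold(sim$trace, sim$reference, reference_count = 1000)
    fine <- seq(0, 100, 0.1)
    acc <- vapply(fine, function(p) {
      oracle_threshold_accuracy(sim$trace$count, sim$wake, p / 100 * 1000)
    }, 0)
    best_fine <- fine[which.max(acc)]
    expect_lte(abs(cal$best_pct - best_fine), 5 + 1e-9)
  }
})

test_that("sleep is monotone in the immobility rule and the threshold", {
  set.seed(99)
  for (i in 1:10) {
    counts <- pmax(0L, as.integer(round(rnorm(3000, 80, 90))))
    tr <- make_trace(counts)
    sleepy <- function(T, pct) {
      total_sleep(score_sleep(binarize(tr, pct, 400), T))
    }
    # longer required immobility never adds sleep
    expect_true(sleepy(35, 10) >= sleepy(40, 10))
    expect_true(sleepy(40, 10) >= sleepy(45, 10))
    # bin-level subset property
    h35 <- score_sleep(binarize(tr, 10, 400), 35)
    h45 <- score_sleep(binarize(tr, 10, 400), 45)
    expect_true(all(which(h45$state == "sleep") %in% which(h35$state == "sleep")))
    # raising the threshold never deactivates sleep
    expect_true(sleepy(40, 30) >= sleepy(40, 10))
  }
})

test_that("parameter sweep tabulates rules with non-increasing video totals", {
  set.seed(5)
  gt <- simulate_hypnogram(sim_spec(duration_s = 7200), seed = 2)
  tr <- simulate_trace(gt, seed = 3)
  ref <- degrade_reference(gt, 0.95, 0.95, seed = 4)
  sw <- parameter_sweep(tr, ref, T_values = c(35, 40, 45))
  expect_equal(sw$immobility_s, c(35, 40, 45))
  expect_true(all(diff(sw$video_sleep_s) <= 0))
  expect_true(all(sw$loa_low_s <= sw$bias_s & sw$bias_s <= sw$loa_high_s))

  # a fully inactive trace gives equal video totals across rules
  tr0 <- make_trace(rep(0L, 7200))
  sw0 <- parameter_sweep(tr0, ref, T_values = c(35, 40, 45))
  expect_equal(length(unique(sw0$video_sleep_s)), 1)
})
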