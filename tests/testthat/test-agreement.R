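test_that("reference collapse maps NREM and REM to sleep", {
  expect_equal(
    as.character(collapse_reference(reference_hypnogram(rep("rem", 5)))$state),
    rep("sleep", 5)
  )
  r <- reference_hypnogram(c("wake", "nrem", "rem", "wake"))
  expect_equal(as.character(collapse_reference(r)$state),
               c("wake", "sleep", "sleep", "wake"))
  expect_error(reference_hypnogram(c("wake", "paradoxical")), "paradoxical")

  # sleep seconds = (NREM + REM epochs) x epoch width, on random references
  set.seed(3)
  for (i in 1:10) {
    lab <- sample(c("wake", "nrem", "rem"), 500, replace = TRUE)
    ref <- reference_hypnogram(lab, epoch_s = 10)
    expect_equal(total_sleep(collapse_reference(ref)),
                 sum(lab %in% c("nrem", "rem")) * 10)
  }
})

test_that("epoch resampling takes the majority and sends ties to wake", {
  h <- hypnogram(rep("sleep", 60))
  expect_equal(as.character(resample_epochs(h, 10)$state), rep("sleep", 6))
  expect_equal(as.character(resample_epochs(h, 60)$state), "sleep")

  h64 <- hypnogram(c(rep("sleep", 6), rep("wake", 4)))
  expect_equal(as.character(resample_epochs(h64, 10)$state), "sleep")
  h55 <- hypnogram(c(rep("sleep", 5), rep("wake", 5)))
  expect_equal(as.character(resample_epochs(h55, 10)$state), "wake")

  expect_error(resample_epochs(h, 7.5), "multiple")
  expect_error(resample_epochs(hypnogram(rep("wake", 25)), 10), "divide")
})

test_that("paired hourly sleep matches per-hypnogram hour sums", {
  v <- random_hypnogram(2 * 3600, seed = 21)
  r <- random_hypnogram(2 * 3600, seed = 22)
  p <- paired_hourly(v, r, subject = "m1")
  expect_equal(p$video_sleep_s, hourly_sleep(v)$sleep_s)
  expect_equal(p$reference_sleep_s, hourly_sleep(r)$sleep_s)
  expect_equal(p$subject, rep("m1", 2))

  ident <- paired_hourly(v, v)
  expect_true(all(ident$video_sleep_s == ident$reference_sleep_s))

  allv <- hypnogram(rep("sleep", 86400))
  allr <- hypnogram(rep("wake", 86400))
  p2 <- paired_hourly(allv, allr)
  expect_equal(p2$video_sleep_s, rep(3600, 24))
  expect_equal(p2$reference_sleep_s, rep(0, 24))

  expect_error(paired_hourly(v, random_hypnogram(3600, seed = 1)), "span mismatch")
})

test_that("Bland-Altman statistics match closed forms", {
  mk <- function(v, r) tibble::tibble(subject = "s", hour = seq_along(v) - 1,
                                      video_sleep_s = v, reference_sleep_s = r)
  eq <- bland_altman(mk(c(100, 200), c(100, 200)))
  expect_equal(eq$bias_s, 0)
  expect_equal(c(eq$loa_low_s, eq$loa_high_s), c(0, 0))

  # differences {-1, +1}: bias 0, sd sqrt(2), limits +/- 1.96 sqrt(2)
  ba <- bland_altman(mk(c(99, 101), c(100, 100)))
  expect_equal(ba$bias_s, 0)
  expect_equal(ba$sd_diff_s, sqrt(2))
  expect_equal(ba$loa_high_s, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low_s, -1.96 * sqrt(2), tolerance = 1e-12)
  expect_true(ba$loa_low_s <= ba$bias_s && ba$bias_s <= ba$loa_high_s)

  expect_error(bland_altman(mk(100, 100)), "at least 2")
})

test_that("consistency formulas behave as declared", {
  mk <- function(v, r) tibble::tibble(video_sleep_s = v, reference_sleep_s = r)
  # worked arithmetic: sum|d| = 200, sum ref = 4000 -> 95%
  expect_equal(consistency_pct(mk(c(1800, 2000), c(2000, 2000))), 95)
  expect_equal(consistency_pct(mk(c(10, 20, 30), c(10, 20, 30))), 100)
  expect_equal(consistency_pct(mk(c(0, 0), c(500, 700))), 0)
  expect_error(consistency_pct(mk(c(1, 2), c(0, 0))), "zero")

  # 100 iff all pairs equal (sum-abs formula)
  set.seed(8)
  v <- runif(20, 0, 3600); r <- v; r[7] <- r[7] + 1
  expect_lt(consistency_pct(mk(v, r)), 100)
  expect_equal(consistency_pct(mk(v, v)), 100)

  # total-ratio ignores cancelling errors, sum-abs does not
  p <- mk(c(1000, 2000), c(2000, 1000))
  expect_equal(consistency_pct(p, "total-ratio"), 100)
  expect_lt(consistency_pct(p, "sum-abs"), 100)
})

test_that("agreement is symmetric and scale-equivariant", {
  set.seed(13)
  mk <- function(v, r) tibble::tibble(subject = "s", hour = seq_along(v) - 1,
                                      video_sleep_s = v, reference_sleep_s = r)
  v <- runif(48, 500, 3000); r <- runif(48, 500, 3000)
  ba <- bland_altman(mk(v, r))
  sw <- bland_altman(mk(r, v))
  expect_equal(sw$bias_s, -ba$bias_s)
  expect_equal(sw$loa_low_s, -ba$loa_high_s)
  expect_equal(sw$loa_high_s, -ba$loa_low_s)

  k <- 2.5
  sc <- bland_altman(mk(k * v, k * r))
  expect_equal(sc$bias_s, k * ba$bias_s)
  expect_equal(sc$sd_diff_s, k * ba$sd_diff_s)
  expect_equal(sc$loa_high_s, k * ba$loa_high_s)
  expect_equal(sc$consistency_pct, ba$consistency_pct)
})

test_that("estimated limits cover about 95% of normal differences", {
  set.seed(31)
  n <- 10000
  r <- runif(n, 1000, 3000)
  d <- rnorm(n, 50, 120)
  ba <- bland_altman(tibble::tibble(subject = "s", hour = seq_len(n) - 1,
                                    video_sleep_s = r + d, reference_sleep_s = r))
  cover <- mean(d >= ba$loa_low_s & d <= ba$loa_high_s)
  expect_equal(cover, 0.95, tolerance = 0.015)
})

test_that("compare_hypnograms composes the full agreement pipeline", {
  set.seed(17)
  gt <- simulate_hypnogram(sim_spec(duration_s = 7200, quantize_s = 10,
                                    brief_arousal_rate_per_h = 0), seed = 41)
  # self-comparison against its own epoch collapse: perfect agreement
  ref <- degrade_reference(gt, 1, 1, epoch_s = 10, seed = 42)
  rep <- compare_hypnograms(gt$hypnogram, ref)
  expect_equal(rep$bias_s, 0)
  expect_equal(rep$consistency_pct, 100)
  expect_equal(rep$n_pairs, 2)

  # multi-subject pooling: one row of pairs per subject-hour
  gts <- lapply(1:3, function(s) simulate_hypnogram(
    sim_spec(duration_s = 7200, quantize_s = 10), seed = s))
  refs <- lapply(gts, degrade_reference, sensitivity = 0.9, specificity = 0.9,
                 seed = 5)
  reps <- compare_hypnograms(lapply(gts, `[[`, "hypnogram"), refs,
                             subjects = c("a", "b", "c"))
  expect_equal(reps$n_pairs, 6)
  expect_equal(unique(tidy(reps)$subject), c("a", "b", "c"))
  expect_true(all(c("sum-abs", "total-ratio", "ccc") %in%
                    reps$consistency_all$formula))
})

test_that("report JSON round-trips the headline numbers", {
  set.seed(23)
  v <- random_hypnogram(3 * 3600, seed = 51)
  r <- random_hypnogram(3 * 3600, seed = 52)
  rep <- compare_hypnograms(v, r)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$bias_s, rep$bias_s)
  expect_equal(back$loa, c(rep$loa_low_s, rep$loa_high_s))
  expect_equal(back$formula, "sum-abs")
  expect_equal(nrow(back$per_hour), rep$n_pairs)
})
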