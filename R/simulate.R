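# Ground-truthed synthetic behaviour. Bout durations are lognormal with
# phase-specific medians; the wake-bout medians are derived from the
# phase sleep-fraction targets (mice are nocturnal: high sleep fraction in
# the light phase). These are declared test fixtures with the statistical
# structure the scoring pipeline assumes, not biological claims.

#' Behavioural simulation specification
#'
#' @param duration_s Recording length, seconds (default one 24 h day).
#' @param bin_s Label resolution, seconds.
#' @param start_clock Wall-clock start of the recording.
#' @param lights_on Wall-clock time the lights turn on.
#' @param cycle_s Length of one light/dark cycle (default 24 h; shorter
#'   values give a "condensed day" for quick end-to-end runs).
#' @param light_s Lit portion of the cycle (default 12 h).
#' @param sleep_bout_median_s Named vector `c(light=, dark=)` of median
#'   sleep-bout durations, seconds.
#' @param sleep_fraction Named vector `c(light=, dark=)` of target sleep
#'   fractions per phase; wake-bout medians are derived from these so the
#'   expected realised fraction matches the target.
#' @param sleep_sdlog,wake_sdlog Lognormal shape parameters.
#' @param min_sleep_bout_s Lower bound on sleep-bout durations (resampled
#'   below it); brief immobility below the scoring rule is modelled
#'   separately as arousals, not as sleep bouts.
#' @param brief_arousal_rate_per_h Brief-arousal events per hour of sleep.
#' @param arousal_duration_range_s Arousal duration bounds, seconds; must
#'   stay below the 40 s immobility rule.
#' @param quantize_s Bout boundaries are rounded to this grid (default the
#'   label resolution; set 10 to align with reference scoring epochs).
#' @param intervention_multipliers Named scalars `c(sleep=, wake=)`
#'   multiplying the bout medians, emulating pharmacological or stress
#'   effects (caffeine: wake up; diazepam: sleep up).
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(duration_s = 86400, bin_s = 1, start_clock = "08:00",
                     lights_on = "08:00", cycle_s = 86400, light_s = 43200,
                     sleep_bout_median_s = c(light = 300, dark = 150),
                     sleep_fraction = c(light = 0.65, dark = 0.30),
                     sleep_sdlog = 0.5, wake_sdlog = 0.8,
                     min_sleep_bout_s = 60,
                     brief_arousal_rate_per_h = 4,
                     arousal_duration_range_s = c(2, 20),
                     quantize_s = bin_s,
                     intervention_multipliers = c(sleep = 1, wake = 1)) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(bin_s, "bin_s", min = 0, strict_min = TRUE)
  check_number(cycle_s, "cycle_s", min = 0, strict_min = TRUE)
  check_number(light_s, "light_s", min = 0, max = cycle_s)
  check_number(quantize_s, "quantize_s", min = bin_s)
  if (!is_multiple(quantize_s, bin_s) || !is_multiple(duration_s, bin_s))
    abort("`quantize_s` and `duration_s` must be multiples of `bin_s`")
  stopifnot(all(c("light", "dark") %in% names(sleep_bout_median_s)),
            all(c("light", "dark") %in% names(sleep_fraction)))
  if (any(sleep_fraction <= 0 | sleep_fraction >= 1))
    abort("`sleep_fraction` targets must lie strictly between 0 and 1")
  if (any(sleep_bout_median_s <= 0)) abort("sleep bout medians must be positive")
  check_number(brief_arousal_rate_per_h, "brief_arousal_rate_per_h", min = 0)
  if (length(arousal_duration_range_s) != 2 ||
      arousal_duration_range_s[1] <= 0 ||
      arousal_duration_range_s[2] < arousal_duration_range_s[1] ||
      arousal_duration_range_s[2] >= 40) {
    abort("`arousal_duration_range_s` must be increasing, positive and below the 40 s immobility rule")
  }
  if (any(intervention_multipliers <= 0))
    abort("intervention multipliers must be positive")
  structure(
    list(duration_s = duration_s, bin_s = bin_s, start_clock = start_clock,
         lights_on = lights_on, cycle_s = cycle_s, light_s = light_s,
         sleep_bout_median_s = sleep_bout_median_s,
         sleep_fraction = sleep_fraction,
         sleep_sdlog = sleep_sdlog, wake_sdlog = wake_sdlog,
         min_sleep_bout_s = min_sleep_bout_s,
         brief_arousal_rate_per_h = brief_arousal_rate_per_h,
         arousal_duration_range_s = arousal_duration_range_s,
         quantize_s = quantize_s,
         intervention_multipliers = intervention_multipliers),
    class = "sim_spec"
  )
}

# light/dark phase of a time offset (seconds from recording start)
phase_at <- function(spec, t) {
  tod <- (parse_clock(spec$start_clock) - parse_clock(spec$lights_on) + t) %% spec$cycle_s
  ifelse(tod < spec$light_s, "light", "dark")
}

# Wake-bout median giving the target sleep fraction for lognormal bouts:
# fraction = E[sleep] / (E[sleep] + E[wake]) with E = median * exp(sdlog^2/2).
wake_median_for <- function(spec, phase) {
  f <- spec$sleep_fraction[[phase]]
  sleep_mean <- spec$sleep_bout_median_s[[phase]] * exp(spec$sleep_sdlog^2 / 2)
  wake_mean <- sleep_mean * (1 - f) / f
  wake_mean / exp(spec$wake_sdlog^2 / 2)
}

#' Simulate a ground-truth hypnogram
#'
#' Alternating sleep/wake bouts are sampled from phase-appropriate lognormal
#' distributions until the recording is covered; brief arousals (shorter
#' than the immobility rule) are carved out of sleep bouts and logged. The
#' result is deterministic for a given `(spec, seed)`.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @return A `ground_truth` object: `$hypnogram`, `$bouts`, `$events`
#'   (arousals), plus the generating spec and seed.
#' @export
simulate_hypnogram <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(seed, {
    n_bins <- round(spec$duration_s / spec$bin_s)
    q <- spec$quantize_s
    mult <- spec$intervention_multipliers
    sample_bout <- function(state, t) {
      ph <- phase_at(spec, t)
      med <- if (state == "sleep") {
        spec$sleep_bout_median_s[[ph]] * mult[["sleep"]]
      } else {
        wake_median_for(spec, ph) * mult[["wake"]]
      }
      sdlog <- if (state == "sleep") spec$sleep_sdlog else spec$wake_sdlog
      for (i in 1:100) {
        d <- rlnorm(1, log(med), sdlog)
        if (state != "sleep" || d >= spec$min_sleep_bout_s) break
      }
      d <- max(d, if (state == "sleep") spec$min_sleep_bout_s else q)
      max(q, round(d / q) * q)
    }
    state <- if (runif(1) < spec$sleep_fraction[[phase_at(spec, 0)]]) "sleep" else "wake"
    t <- 0
    st <- character(0); on <- numeric(0); du <- numeric(0)
    while (t < spec$duration_s) {
      d <- min(sample_bout(state, t), spec$duration_s - t)
      st <- c(st, state); on <- c(on, t); du <- c(du, d)
      t <- t + d
      state <- if (state == "sleep") "wake" else "sleep"
    }
    labels <- rep(rep(st, times = round(du / spec$bin_s)), length.out = n_bins)

    # brief arousals inside sleep bouts
    events <- tibble(type = character(0), onset_s = numeric(0),
                     duration_s = numeric(0))
    if (spec$brief_arousal_rate_per_h > 0) {
      for (i in which(st == "sleep")) {
        k <- rpois(1, spec$brief_arousal_rate_per_h * du[i] / 3600)
        if (k == 0) next
        ad <- runif(k, spec$arousal_duration_range_s[1],
                    spec$arousal_duration_range_s[2])
        ad <- pmax(q, round(ad / q) * q)
        ao <- round((on[i] + runif(k) * pmax(0, du[i] - ad)) / q) * q
        for (j in seq_len(k)) {
          b0 <- round(ao[j] / spec$bin_s) + 1
          b1 <- min(n_bins, b0 + round(ad[j] / spec$bin_s) - 1)
          if (b0 > n_bins) next
          labels[b0:b1] <- "wake"
          events <- dplyr::bind_rows(events, tibble(
            type = "arousal", onset_s = ao[j], duration_s = ad[j]
          ))
        }
      }
    }
    h <- hypnogram(labels, bin_s = spec$bin_s, start_clock = spec$start_clock)
    structure(
      list(hypnogram = h, bouts = to_bouts(h), events = events,
           spec = spec, seed = seed),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground truth: %.4g h, %d bouts, %d arousal events, sleep %.1f%% (seed %d)>\n",
    span_s(x$hypnogram) / 3600, nrow(x$bouts), nrow(x$events),
    100 * mean(x$hypnogram$state == "sleep"), x$seed
  ))
  invisible(x)
}

#' Motion-count noise specification
#'
#' Wake bins draw counts from a gamma distribution shifted by a hard floor
#' (a locomoting mouse always displaces at least its limb area of pixels);
#' sleep bins draw small counts from breathing-band pulsation plus Poisson
#' noise. Defaults separate the two by well over 5x; lower `wake_floor` and
#' `wake_mean` or raise `sleep_mean` to create overlap for stress-testing
#' calibration.
#'
#' @param wake_mean Mean wake count, pixels (about the blob area).
#' @param wake_shape Gamma shape of the wake distribution.
#' @param wake_floor Hard lower bound on wake counts.
#' @param sleep_mean Mean Poisson micro-motion count during sleep.
#' @param breathing_amp Peak breathing-band count amplitude.
#' @param breathing_hz Breathing frequency, Hz.
#' @param dropout_prob Probability a bin drops to zero (signal loss).
#' @param frame_area Frame area, pixels (the count ceiling).
#' @return A `trace_noise_spec` list.
#' @export
trace_noise_spec <- function(wake_mean = 500, wake_shape = 4, wake_floor = 100,
                             sleep_mean = 8, breathing_amp = 10,
                             breathing_hz = 2.5, dropout_prob = 0,
                             frame_area = 320 * 240) {
  check_number(wake_mean, "wake_mean", min = 0, strict_min = TRUE)
  check_number(wake_shape, "wake_shape", min = 0, strict_min = TRUE)
  check_number(wake_floor, "wake_floor", min = 0, max = wake_mean)
  check_number(sleep_mean, "sleep_mean", min = 0)
  check_number(breathing_amp, "breathing_amp", min = 0)
  check_number(breathing_hz, "breathing_hz", min = 0)
  check_number(dropout_prob, "dropout_prob", min = 0, max = 1)
  check_number(frame_area, "frame_area", min = 1)
  structure(
    list(wake_mean = wake_mean, wake_shape = wake_shape,
         wake_floor = wake_floor, sleep_mean = sleep_mean,
         breathing_amp = breathing_amp, breathing_hz = breathing_hz,
         dropout_prob = dropout_prob, frame_area = frame_area),
    class = "trace_noise_spec"
  )
}

#' Simulate a motion trace from a ground truth
#'
#' Per-bin counts are drawn from the state-appropriate distribution of the
#' noise spec (arousal bins count as wake).
#'
#' @param gt A `ground_truth` from [simulate_hypnogram()].
#' @param noise A [trace_noise_spec()].
#' @param seed Integer seed.
#' @return A `motion_trace`.
#' @export
simulate_trace <- function(gt, noise = trace_noise_spec(), seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(noise, "trace_noise_spec"))
  withr::with_seed(seed, {
    h <- gt$hypnogram
    n <- nrow(h)
    bs <- bin_s_of(h)
    is_wake <- h$state == "wake"
    counts <- integer(n)
    nw <- sum(is_wake)
    if (nw > 0) {
      excess <- noise$wake_mean - noise$wake_floor
      counts[is_wake] <- noise$wake_floor + if (excess > 0) {
        rgamma(nw, shape = noise$wake_shape,
               rate = noise$wake_shape / excess)
      } else 0
    }
    ns <- sum(!is_wake)
    if (ns > 0) {
      phi <- runif(1, 0, 2 * pi)
      t_sleep <- h$time_s[!is_wake]
      breath <- noise$breathing_amp *
        abs(sin(2 * pi * noise$breathing_hz * t_sleep + phi))
      counts[!is_wake] <- rpois(ns, noise$sleep_mean) + round(breath)
    }
    if (noise$dropout_prob > 0) {
      counts[runif(n) < noise$dropout_prob] <- 0L
    }
    counts <- pmin(pmax(round(counts), 0L), noise$frame_area)
    new_motion_trace(counts, bs, start_clock_of(h), noise$frame_area)
  })
}

#' Degrade a ground truth into an imperfect reference scoring
#'
#' Emulates manual EEG/EMG epoch scoring: the truth is resampled to epochs
#' (majority vote, ties to wake), each sleep epoch is kept sleep with
#' probability `sensitivity` and each wake epoch kept wake with probability
#' `specificity`; retained sleep epochs are assigned REM with probability
#' `rem_fraction`, else NREM.
#'
#' @param gt A `ground_truth`.
#' @param sensitivity,specificity Epoch-level retention probabilities.
#' @param rem_fraction Fraction of sleep epochs labelled REM.
#' @param epoch_s Scoring epoch, seconds.
#' @param seed Integer seed.
#' @return A `reference_hypnogram`.
#' @export
degrade_reference <- function(gt, sensitivity = 0.95, specificity = 0.95,
                              rem_fraction = 0.12, epoch_s = 10, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  check_number(sensitivity, "sensitivity", min = 0, max = 1)
  check_number(specificity, "specificity", min = 0, max = 1)
  check_number(rem_fraction, "rem_fraction", min = 0, max = 1)
  withr::with_seed(seed, {
    epochs <- resample_epochs(gt$hypnogram, epoch_s)
    n <- nrow(epochs)
    is_sleep <- epochs$state == "sleep"
    keep <- runif(n) < ifelse(is_sleep, sensitivity, specificity)
    scored_sleep <- ifelse(keep, is_sleep, !is_sleep)
    lab <- ifelse(scored_sleep,
                  ifelse(runif(n) < rem_fraction, "rem", "nrem"),
                  "wake")
    reference_hypnogram(lab, epoch_s = epoch_s,
                        start_clock = start_clock_of(gt$hypnogram))
  })
}
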