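# Activity thresholding and immobility-rule sleep scoring. The threshold is
# expressed as a percentage of a reference pixel count (by default the 99th
# percentile of the trace's positive counts, a proxy for full-body motion, so
# the percentage is scale-free across camera resolutions). A maximal run of
# inactive bins lasting at least immobility_min_s is scored as sleep over its
# entire extent, from run onset.

default_reference_count <- function(trace) {
  pos <- trace$count[trace$count > 0]
  if (length(pos) == 0) return(1)
  unname(quantile(pos, 0.99, names = FALSE, type = 7))
}

#' Threshold a motion trace into an activity series
#'
#' A bin is active iff its count strictly exceeds
#' `threshold_pct / 100 * reference_count`; sub-threshold micro-motion
#' (abdominal breathing, ear movements) stays inactive.
#'
#' @param trace A `motion_trace`.
#' @param threshold_pct Activity threshold, percent of `reference_count`
#'   (0-100).
#' @param reference_count Pixel count defining 100%; default the 99th
#'   percentile of the trace's positive counts.
#' @return An `activity_series` tibble with columns `time_s`, `active`.
#' @export
binarize <- function(trace, threshold_pct, reference_count = NULL) {
  if (nrow(trace) == 0) abort("`trace` is empty")
  check_number(threshold_pct, "threshold_pct", min = 0, max = 100)
  reference_count <- reference_count %||% default_reference_count(trace)
  if (!is.numeric(reference_count) || length(reference_count) != 1 ||
      reference_count <= 0) {
    abort("`reference_count` must be a single positive number")
  }
  cutoff <- threshold_pct / 100 * reference_count
  out <- tibble(time_s = trace$time_s, active = trace$count > cutoff)
  structure(out, bin_s = bin_s_of(trace), start_clock = start_clock_of(trace),
            threshold_pct = threshold_pct, reference_count = reference_count,
            class = c("activity_series", class(out)))
}

#' Score sleep by the immobility rule
#'
#' Every maximal run of inactive bins with total duration at least
#' `immobility_min_s` is labelled sleep over its entire extent (whole-run
#' labelling, from run onset); all other bins are wake. Runs of exactly the
#' minimum duration qualify, as do runs truncated by the recording edges
#' whose observed duration qualifies.
#'
#' @param activity An `activity_series` from [binarize()].
#' @param immobility_min_s Minimum immobility scored as sleep, seconds
#'   (default 40; the classical alternatives are 35 and 45). Must be a
#'   multiple of the bin width and at least one bin.
#' @return A `hypnogram`.
#' @export
score_sleep <- function(activity, immobility_min_s = 40) {
  bs <- bin_s_of(activity)
  check_number(immobility_min_s, "immobility_min_s", min = bs)
  if (!is_multiple(immobility_min_s, bs)) {
    abort(sprintf("`immobility_min_s` (%g) must be an integer multiple of the bin width (%g s)",
                  immobility_min_s, bs))
  }
  r <- rle(activity$active)
  sleep_run <- !r$values & (r$lengths * bs >= immobility_min_s)
  labels <- inverse.rle(list(
    lengths = r$lengths,
    values = ifelse(sleep_run, "sleep", "wake")
  ))
  hypnogram(labels, bin_s = bs, start_clock = start_clock_of(activity))
}

score_trace <- function(trace, threshold_pct, immobility_min_s = 40,
                        reference_count = NULL) {
  score_sleep(binarize(trace, threshold_pct, reference_count), immobility_min_s)
}

align_reference_bins <- function(reference, trace) {
  rb <- bin_s_of(reference)
  tb <- bin_s_of(trace)
  if (isTRUE(all.equal(rb, tb))) {
    labels <- as.character(reference$state)
  } else if (is_multiple(rb, tb)) {
    labels <- rep(as.character(reference$state), each = round(rb / tb))
  } else {
    abort(sprintf("reference bin width (%g s) is not a multiple of the trace bin width (%g s)",
                  rb, tb))
  }
  if (length(labels) != nrow(trace)) {
    abort(sprintf("misaligned spans: reference covers %.6g s, trace covers %.6g s",
                  nrow(reference) * rb, nrow(trace) * tb))
  }
  labels
}

#' Calibrate the activity threshold against a reference hypnogram
#'
#' Scores sleep at every threshold on a percentage grid (default a 5% grid
#' from 0% to 100%) and measures bin-level accuracy against the reference;
#' the threshold maximising accuracy wins, ties going to the lowest
#' threshold (favouring wake sensitivity).
#'
#' @param trace A `motion_trace`.
#' @param reference A `hypnogram` covering the same span (a collapsed
#'   EEG/EMG reference; coarser bins are expanded automatically).
#' @param grid_step_pct Grid step, percent.
#' @param immobility_min_s Immobility rule used while scoring.
#' @param reference_count As in [binarize()].
#' @return A `threshold_calibration` object: `best_pct`, the full
#'   `curve` (threshold vs accuracy), and the calibration settings.
#'   [tidy()] returns the curve, [glance()] the optimum.
#' @export
calibrate_threshold <- function(trace, reference, grid_step_pct = 5,
                                immobility_min_s = 40, reference_count = NULL) {
  check_number(grid_step_pct, "grid_step_pct", min = 0, max = 100, strict_min = TRUE)
  ref_labels <- align_reference_bins(reference, trace)
  reference_count <- reference_count %||% default_reference_count(trace)
  grid <- seq(0, 100, by = grid_step_pct)
  if (tail(grid, 1) < 100) grid <- c(grid, 100)
  acc <- vapply(grid, function(pct) {
    h <- score_trace(trace, pct, immobility_min_s, reference_count)
    mean(as.character(h$state) == ref_labels)
  }, 0)
  structure(
    list(best_pct = grid[which.max(acc)],
         curve = tibble(threshold_pct = grid, accuracy = acc),
         reference_count = reference_count,
         immobility_min_s = immobility_min_s,
         grid_step_pct = grid_step_pct),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "<threshold calibration: best %g%% of reference count %.4g (accuracy %.4f), %g%% grid, immobility rule %g s>\n",
    x$best_pct, x$reference_count, max(x$curve$accuracy), x$grid_step_pct,
    x$immobility_min_s
  ))
  invisible(x)
}

#' @export
tidy.threshold_calibration <- function(x, ...) x$curve

#' @export
glance.threshold_calibration <- function(x, ...) {
  tibble(best_pct = x$best_pct, accuracy = max(x$curve$accuracy),
         reference_count = x$reference_count,
         immobility_min_s = x$immobility_min_s,
         grid_step_pct = x$grid_step_pct)
}

#' @rdname autoplot_sleepcam
#' @export
autoplot.threshold_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$threshold_pct, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_pct, linetype = 2) +
    ggplot2::labs(x = "activity threshold (% of reference count)",
                  y = "bin-level accuracy vs reference") +
    ggplot2::theme_minimal()
}

#' Immobility-rule parameter sweep
#'
#' Re-scores one or more trace/reference pairs at several immobility rules
#' (classically 35, 40 and 45 s) and tabulates total sleep times,
#' Bland-Altman limits of agreement and the consistency coefficient per rule.
#' Video totals are non-increasing in the rule: lengthening the required
#' immobility can only disqualify runs.
#'
#' @param trace A `motion_trace` or list of traces (one per subject).
#' @param reference A `reference_hypnogram` (or sleep/wake `hypnogram`), or a
#'   list matching `trace`.
#' @param T_values Immobility rules to sweep, seconds.
#' @param threshold_pct,reference_count Passed to [binarize()].
#' @param consistency_formula Passed to [bland_altman()].
#' @return A tibble with one row per rule: `immobility_s`,
#'   `video_sleep_s`, `reference_sleep_s`, `bias_s`, `loa_low_s`,
#'   `loa_high_s`, `consistency_pct`, `n_pairs`.
#' @export
parameter_sweep <- function(trace, reference, T_values = c(35, 40, 45),
                            threshold_pct = 5, reference_count = NULL,
                            consistency_formula = "sum-abs") {
  traces <- if (inherits(trace, "motion_trace")) list(trace) else trace
  refs <- if (inherits(reference, "reference_hypnogram") ||
              inherits(reference, "hypnogram")) list(reference) else reference
  if (length(traces) != length(refs))
    abort("`trace` and `reference` must pair up one per subject")
  refs <- lapply(refs, function(r) {
    if (inherits(r, "reference_hypnogram")) collapse_reference(r) else r
  })
  rows <- lapply(sort(T_values), function(T) {
    videos <- lapply(traces, score_trace, threshold_pct = threshold_pct,
                     immobility_min_s = T, reference_count = reference_count)
    pairs <- dplyr::bind_rows(purrr::pmap(
      list(videos, refs, as.character(seq_along(videos))), paired_hourly
    ))
    ba <- bland_altman(pairs, consistency_formula = consistency_formula)
    tibble(immobility_s = T,
           video_sleep_s = sum(vapply(videos, total_sleep, 0)),
           reference_sleep_s = sum(vapply(refs, total_sleep, 0)),
           bias_s = ba$bias_s, loa_low_s = ba$loa_low_s,
           loa_high_s = ba$loa_high_s, consistency_pct = ba$consistency_pct,
           n_pairs = ba$n_pairs)
  })
  dplyr::bind_rows(rows)
}
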