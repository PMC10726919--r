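# Hypnograms: per-bin sleep/wake label series, the common currency between
# the video scorer and the collapsed EEG/EMG reference.

hypnogram_states <- c("sleep", "wake")

#' Construct a sleep/wake hypnogram
#'
#' @param states Character or factor vector over `"sleep"`/`"wake"`.
#' @param bin_s Seconds per bin (> 0).
#' @param start_clock Wall-clock time of bin 0.
#' @return A `hypnogram` tibble with columns `time_s`, `state`.
#' @export
hypnogram <- function(states, bin_s = 1, start_clock = "08:00") {
  states <- as.character(states)
  bad <- setdiff(unique(states), hypnogram_states)
  if (length(bad) > 0) {
    abort(sprintf("unknown hypnogram state%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste(sQuote(bad), collapse = ", ")))
  }
  check_number(bin_s, "bin_s", min = 0, strict_min = TRUE)
  out <- tibble(time_s = (seq_along(states) - 1) * bin_s,
                state = factor(states, levels = hypnogram_states))
  structure(out, bin_s = bin_s, start_clock = start_clock,
            class = c("hypnogram", class(out)))
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("# hypnogram: %d bins x %.3g s (%.4g h), start %s, sleep %.1f%%\n",
              nrow(x), bin_s_of(x), span_s(x) / 3600, start_clock_of(x),
              100 * mean(x$state == "sleep")))
  NextMethod()
}

#' Total sleep time of a hypnogram
#'
#' @param h A `hypnogram`.
#' @return Sleep seconds (count of sleep bins times bin width).
#' @export
total_sleep <- function(h) {
  sum(h$state == "sleep") * bin_s_of(h)
}

#' Per-hour sleep seconds
#'
#' Splits the recording into 1 h segments anchored at recording start and
#' sums sleep seconds per segment. The hypnogram must cover a whole number of
#' hours (a 24 h recording gives the standard 24 x 1 h segmentation).
#'
#' @param h A `hypnogram`.
#' @param anchor `"start"` (segments from recording start) or `"clock"`
#'   (segments aligned to wall-clock hours; requires the recording to start
#'   on a full hour).
#' @return A tibble with columns `hour` (0-based index) and `sleep_s`
#'   (each in `[0, 3600]`; their sum equals [total_sleep()]).
#' @export
hourly_sleep <- function(h, anchor = c("start", "clock")) {
  anchor <- match.arg(anchor)
  bs <- bin_s_of(h)
  span <- span_s(h)
  if (span < 3600 || !is_multiple(span, 3600)) {
    abort(sprintf(
      "hypnogram covers %.6g s (%.4g h); hourly segmentation needs a whole number of hours",
      span, span / 3600
    ))
  }
  if (anchor == "clock" && !is_multiple(parse_clock(start_clock_of(h)), 3600)) {
    abort(sprintf(
      "clock-anchored segmentation needs a recording starting on a full hour (start is %s); trim the leading partial hour first",
      start_clock_of(h)
    ))
  }
  hour <- floor(h$time_s / 3600)
  sleep_s <- vapply(split(h$state == "sleep", hour), sum, 0) * bs
  tibble(hour = as.integer(names(sleep_s)), sleep_s = unname(sleep_s))
}

#' Run-length encode a hypnogram into bouts
#'
#' @param h A `hypnogram`.
#' @return A `bout_table` tibble with columns `state`, `onset_s`,
#'   `duration_s`; rows are contiguous, non-overlapping, and alternate state,
#'   and concatenating them reconstructs the hypnogram exactly.
#' @export
to_bouts <- function(h) {
  bs <- bin_s_of(h)
  r <- rle(as.character(h$state))
  dur <- r$lengths * bs
  out <- tibble(state = r$values,
                onset_s = cumsum(c(0, head(dur, -1))),
                duration_s = dur)
  structure(out, bin_s = bs, start_clock = start_clock_of(h),
            class = c("bout_table", class(out)))
}

#' Expand a bout table back into a hypnogram
#'
#' Inverse of [to_bouts()].
#'
#' @param bouts A `bout_table` (or tibble with `state`, `duration_s`).
#' @param bin_s Seconds per bin; bout durations must be multiples of it.
#' @param start_clock Wall-clock time of bin 0.
#' @return A `hypnogram`.
#' @export
bouts_to_hypnogram <- function(bouts, bin_s = attr(bouts, "bin_s") %||% 1,
                               start_clock = attr(bouts, "start_clock") %||% "08:00") {
  if (!all(vapply(bouts$duration_s, is_multiple, TRUE, of = bin_s)))
    abort("bout durations must be whole multiples of `bin_s`")
  hypnogram(rep(bouts$state, times = round(bouts$duration_s / bin_s)),
            bin_s = bin_s, start_clock = start_clock)
}

#' @rdname autoplot_sleepcam
#' @export
autoplot.hypnogram <- function(object, ...) {
  d <- to_bouts(object)
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$onset_s / 3600, xmax = (.data$onset_s + .data$duration_s) / 3600,
      ymin = 0, ymax = 1, fill = .data$state
    )) +
    ggplot2::scale_fill_manual(values = c(sleep = "#26456e", wake = "#f0a830")) +
    ggplot2::labs(x = "time from recording start (h)", y = NULL, fill = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::theme_minimal()
}
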