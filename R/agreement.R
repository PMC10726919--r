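# Agreement between the video-derived hypnogram and an EEG/EMG reference:
# collapse Wake/NREM/REM epochs to sleep/wake, pair per-hour sleep seconds,
# and summarise with Bland-Altman bias, 95% limits of agreement and a
# consistency coefficient. Comparison granularity is per-hour totals: each
# paired observation is one subject-hour.

reference_labels <- c("wake", "nrem", "rem")

#' Construct a reference hypnogram (manual EEG/EMG scoring)
#'
#' @param labels Epoch labels over `"wake"`, `"nrem"`, `"rem"`.
#' @param epoch_s Seconds per scoring epoch (default 10, the conventional
#'   manual-scoring window).
#' @param start_clock Wall-clock time of epoch 0.
#' @return A `reference_hypnogram` tibble with columns `epoch`, `label`.
#' @export
reference_hypnogram <- function(labels, epoch_s = 10, start_clock = "08:00") {
  labels <- tolower(as.character(labels))
  bad <- setdiff(unique(labels), reference_labels)
  if (length(bad) > 0) {
    abort(sprintf("unknown reference label%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste(sQuote(bad), collapse = ", ")))
  }
  check_number(epoch_s, "epoch_s", min = 0, strict_min = TRUE)
  out <- tibble(epoch = seq_along(labels) - 1L,
                label = factor(labels, levels = reference_labels))
  structure(out, epoch_s = epoch_s, start_clock = start_clock,
            class = c("reference_hypnogram", class(out)))
}

#' @export
print.reference_hypnogram <- function(x, ...) {
  es <- attr(x, "epoch_s")
  cat(sprintf("# reference hypnogram: %d x %g s epochs (%.4g h), start %s\n",
              nrow(x), es, nrow(x) * es / 3600, start_clock_of(x)))
  NextMethod()
}

#' Collapse a Wake/NREM/REM reference to sleep/wake
#'
#' Total sleep is the union of REM and NREM: both collapse to sleep, wake
#' stays wake. The result is a [hypnogram()] with `bin_s = epoch_s`.
#'
#' @param ref A `reference_hypnogram`.
#' @return A `hypnogram`.
#' @export
collapse_reference <- function(ref) {
  if (!inherits(ref, "reference_hypnogram"))
    abort("`ref` must be a reference_hypnogram")
  hypnogram(ifelse(ref$label == "wake", "wake", "sleep"),
            bin_s = attr(ref, "epoch_s"), start_clock = start_clock_of(ref))
}

#' Resample a hypnogram to coarser epochs by majority vote
#'
#' Each epoch takes the majority label of its bins; exact ties go to wake
#' (conservative against over-scoring sleep). Constant hypnograms are
#' unchanged.
#'
#' @param h A `hypnogram`.
#' @param epoch_s Target epoch width; must be a multiple of the bin width,
#'   and the recording must divide into whole epochs.
#' @return A `hypnogram` with `bin_s = epoch_s`.
#' @export
resample_epochs <- function(h, epoch_s) {
  bs <- bin_s_of(h)
  if (!is_multiple(epoch_s, bs)) {
    abort(sprintf("`epoch_s` (%g) must be a multiple of the bin width (%g s)",
                  epoch_s, bs))
  }
  k <- round(epoch_s / bs)
  if (nrow(h) %% k != 0) {
    abort(sprintf("recording of %d bins does not divide into %g s epochs",
                  nrow(h), epoch_s))
  }
  sleep_bins <- matrix(h$state == "sleep", nrow = k)
  maj <- colSums(sleep_bins) * 2 > k        # strict majority; ties -> wake
  hypnogram(ifelse(maj, "sleep", "wake"), bin_s = epoch_s,
            start_clock = start_clock_of(h))
}

#' Pair per-hour sleep times from two hypnograms
#'
#' @param video Video-derived `hypnogram`.
#' @param reference Reference sleep/wake `hypnogram` (already collapsed)
#'   covering the same span.
#' @param subject Subject identifier carried into the pairs.
#' @return A tibble with columns `subject`, `hour`, `video_sleep_s`,
#'   `reference_sleep_s`.
#' @export
paired_hourly <- function(video, reference, subject = "s1") {
  if (!isTRUE(all.equal(span_s(video), span_s(reference)))) {
    abort(sprintf("span mismatch: video covers %.6g s, reference covers %.6g s",
                  span_s(video), span_s(reference)))
  }
  hv <- hourly_sleep(video)
  hr <- hourly_sleep(reference)
  tibble(subject = subject, hour = hv$hour,
         video_sleep_s = hv$sleep_s, reference_sleep_s = hr$sleep_s)
}

#' Consistency coefficient between paired sleep times
#'
#' The default `"sum-abs"` formula is
#' `100 * (1 - sum(|video_i - reference_i|) / sum(reference_i))` over all
#' subject-hours. Alternatives: `"total-ratio"`,
#' `100 * (1 - |sum(video) - sum(reference)| / sum(reference))`, and
#' `"ccc"`, Lin's concordance correlation coefficient as a percentage. The
#' exact published formula behind this class of coefficients is not uniquely
#' determined by printed group totals, so reports always state which formula
#' produced the number.
#'
#' @param pairs A tibble from [paired_hourly()] (columns `video_sleep_s`,
#'   `reference_sleep_s`).
#' @param formula One of `"sum-abs"`, `"total-ratio"`, `"ccc"`.
#' @return Percent consistency (100 iff all paired values are equal for the
#'   default formula).
#' @export
consistency_pct <- function(pairs, formula = c("sum-abs", "total-ratio", "ccc")) {
  formula <- match.arg(formula)
  v <- pairs$video_sleep_s
  r <- pairs$reference_sleep_s
  if (sum(r) <= 0) abort("reference sleep total is zero; consistency undefined")
  switch(formula,
    "sum-abs" = 100 * (1 - sum(abs(v - r)) / sum(r)),
    "total-ratio" = 100 * (1 - abs(sum(v) - sum(r)) / sum(r)),
    "ccc" = {
      if (length(v) < 2) abort("ccc needs at least 2 pairs")
      100 * 2 * cov(v, r) / (var(v) + var(r) + (mean(v) - mean(r))^2)
    }
  )
}

#' Bland-Altman agreement between paired sleep times
#'
#' Differences are video minus reference; bias is their mean, the 95% limits
#' of agreement are bias plus/minus 1.96 sample standard deviations (n - 1
#' denominator).
#'
#' @param pairs A tibble from [paired_hourly()]; at least 2 pairs.
#' @param consistency_formula Formula for the consistency coefficient, see
#'   [consistency_pct()].
#' @return An `agreement_report`: `bias_s`, `sd_diff_s`, `loa_low_s`,
#'   `loa_high_s`, `consistency_pct`, `consistency_all` (all formulas side
#'   by side), `n_pairs` and the per-pair table. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
bland_altman <- function(pairs, consistency_formula = "sum-abs") {
  if (nrow(pairs) < 2)
    abort("Bland-Altman needs at least 2 pairs (SD of differences undefined)")
  d <- pairs$video_sleep_s - pairs$reference_sleep_s
  bias <- mean(d)
  s <- sd(d)
  cons_all <- tibble(
    formula = c("sum-abs", "total-ratio", "ccc"),
    consistency_pct = vapply(
      c("sum-abs", "total-ratio", "ccc"),
      function(f) tryCatch(consistency_pct(pairs, f), error = function(e) NA_real_),
      0
    )
  )
  structure(
    list(bias_s = bias, sd_diff_s = s,
         loa_low_s = bias - 1.96 * s, loa_high_s = bias + 1.96 * s,
         consistency_pct = consistency_pct(pairs, consistency_formula),
         consistency_formula = consistency_formula,
         consistency_all = cons_all,
         n_pairs = nrow(pairs), pairs = pairs),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Bland-Altman agreement (video - reference, per subject-hour)\n")
  cat(sprintf("  pairs:        %d (pooled across subjects)\n", x$n_pairs))
  cat(sprintf("  bias:         %.1f s\n", x$bias_s))
  cat(sprintf("  SD of diffs:  %.1f s\n", x$sd_diff_s))
  cat(sprintf("  95%% limits:   %.1f to %.1f s\n", x$loa_low_s, x$loa_high_s))
  cat(sprintf("  consistency:  %.1f%% (formula: %s)\n",
              x$consistency_pct, x$consistency_formula))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::mutate(x$pairs,
                diff_s = .data$video_sleep_s - .data$reference_sleep_s,
                mean_s = (.data$video_sleep_s + .data$reference_sleep_s) / 2)
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble(bias_s = x$bias_s, sd_diff_s = x$sd_diff_s,
         loa_low_s = x$loa_low_s, loa_high_s = x$loa_high_s,
         consistency_pct = x$consistency_pct,
         consistency_formula = x$consistency_formula, n_pairs = x$n_pairs)
}

#' Plot methods for sleepcam result objects
#'
#' `autoplot()` draws a Bland-Altman scatter for an `agreement_report`, a
#' state ribbon for a `hypnogram`, the accuracy curve for a
#' `threshold_calibration`, and the count series for a `motion_trace`.
#'
#' @param object The result object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name autoplot_sleepcam
NULL

#' @rdname autoplot_sleepcam
#' @export
autoplot.agreement_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_s, .data$diff_s)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias_s, colour = "#26456e") +
    ggplot2::geom_hline(yintercept = c(object$loa_low_s, object$loa_high_s),
                        linetype = 2, colour = "#26456e") +
    ggplot2::labs(x = "mean of paired hourly sleep times (s)",
                  y = "video - reference (s)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_sleepcam
#' @export
autoplot.motion_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s / 3600, .data$count)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time from recording start (h)",
                  y = "foreground pixels per bin") +
    ggplot2::theme_minimal()
}

#' Compare a video hypnogram against EEG/EMG references
#'
#' The full agreement pipeline: collapse each reference to sleep/wake, pair
#' per-hour sleep times per subject, pool pairs, and summarise with
#' [bland_altman()]. Pooling treats all subject-hours alike (no random
#' subject effect).
#'
#' @param video A `hypnogram` or list of hypnograms (one per subject).
#' @param reference A `reference_hypnogram` (or collapsed `hypnogram`) or a
#'   matching list.
#' @param subjects Subject identifiers; default `s1, s2, ...`.
#' @param consistency_formula See [consistency_pct()].
#' @return An `agreement_report`.
#' @export
compare_hypnograms <- function(video, reference, subjects = NULL,
                               consistency_formula = "sum-abs") {
  videos <- if (inherits(video, "hypnogram")) list(video) else video
  refs <- if (inherits(reference, "reference_hypnogram") ||
              inherits(reference, "hypnogram")) list(reference) else reference
  if (length(videos) != length(refs))
    abort("`video` and `reference` must pair up one per subject")
  subjects <- subjects %||% paste0("s", seq_along(videos))
  refs <- lapply(refs, function(r) {
    if (inherits(r, "reference_hypnogram")) collapse_reference(r) else r
  })
  pairs <- dplyr::bind_rows(purrr::pmap(list(videos, refs, subjects), paired_hourly))
  bland_altman(pairs, consistency_formula = consistency_formula)
}
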