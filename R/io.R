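# Plain-text interchange: trace CSV (time_s,count), hypnogram CSV
# (time_s,state), bout CSV (state,onset_s,duration_s), reference CSV
# (epoch_index,label), agreement report JSON.

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read and write motion-trace CSV
#'
#' The trace format is `time_s,count`, one row per bin; the bin width is
#' inferred from the time column on read.
#'
#' @param trace A `motion_trace`.
#' @param path CSV path.
#' @param start_clock,frame_area Metadata not carried by the CSV.
#' @return `read_trace()` a `motion_trace`; `write_trace()` the path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  write_atomic(function(p) {
    readr::write_csv(tibble(time_s = trace$time_s, count = trace$count), p)
  }, path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, start_clock = "08:00", frame_area = NULL) {
  d <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  if (!all(c("time_s", "count") %in% names(d)))
    abort(sprintf("'%s' is not a trace CSV (needs columns time_s,count)", path))
  bin_s <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else 1
  new_motion_trace(d$count, bin_s, start_clock,
                   frame_area %||% max(d$count, 1))
}

#' Read and write hypnogram CSV
#'
#' Format `time_s,state` with state in `{sleep, wake}`.
#'
#' @param h A `hypnogram`.
#' @param path CSV path.
#' @param start_clock Metadata not carried by the CSV.
#' @return `read_hypnogram()` a `hypnogram`; `write_hypnogram()` the path,
#'   invisibly.
#' @export
write_hypnogram <- function(h, path) {
  write_atomic(function(p) {
    readr::write_csv(tibble(time_s = h$time_s, state = as.character(h$state)), p)
  }, path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, start_clock = "08:00") {
  d <- readr::read_csv(path, col_types = "dc", progress = FALSE)
  if (!all(c("time_s", "state") %in% names(d)))
    abort(sprintf("'%s' is not a hypnogram CSV (needs columns time_s,state)", path))
  bin_s <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else 1
  hypnogram(d$state, bin_s = bin_s, start_clock = start_clock)
}

#' Write a bout table CSV
#'
#' Format `state,onset_s,duration_s`.
#'
#' @param bouts A `bout_table` from [to_bouts()].
#' @param path CSV path.
#' @export
write_bouts <- function(bouts, path) {
  write_atomic(function(p) readr::write_csv(as_tibble(bouts), p), path)
}

#' Read and write reference-hypnogram CSV
#'
#' Format `epoch_index,label` with label in `{wake, nrem, rem}`.
#'
#' @param ref A `reference_hypnogram`.
#' @param path CSV path.
#' @param epoch_s,start_clock Metadata not carried by the CSV.
#' @return `read_reference()` a `reference_hypnogram`; `write_reference()`
#'   the path, invisibly.
#' @export
write_reference <- function(ref, path) {
  write_atomic(function(p) {
    readr::write_csv(tibble(epoch_index = ref$epoch,
                            label = as.character(ref$label)), p)
  }, path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path, epoch_s = 10, start_clock = "08:00") {
  d <- readr::read_csv(path, col_types = "dc", progress = FALSE)
  if (!all(c("epoch_index", "label") %in% names(d)))
    abort(sprintf("'%s' is not a reference CSV (needs columns epoch_index,label)", path))
  reference_hypnogram(d$label, epoch_s = epoch_s, start_clock = start_clock)
}

#' Serialise an agreement report to JSON
#'
#' Writes `{bias_s, sd_diff_s, loa: [low, high], consistency_pct, formula,
#' n_pairs, per_hour: [...]}`.
#'
#' @param report An `agreement_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  write_atomic(function(p) {
    jsonlite::write_json(
      list(bias_s = report$bias_s, sd_diff_s = report$sd_diff_s,
           loa = c(report$loa_low_s, report$loa_high_s),
           consistency_pct = report$consistency_pct,
           formula = report$consistency_formula,
           consistency_all = report$consistency_all,
           n_pairs = report$n_pairs,
           pooling = "simple pooling across subjects (no random subject effect)",
           per_hour = report$pairs),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }, path)
}
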