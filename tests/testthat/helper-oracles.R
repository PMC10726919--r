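# Independent oracles: deliberately naive implementations used to check the
# package's vectorised paths.

# Single-pass scan over bins, tracking each maximal inactive run and labelling
# it sleep when its duration reaches T. Independent of rle().
oracle_score_sleep <- function(active, bin_s, T) {
  n <- length(active)
  labels <- rep("wake", n)
  run_start <- NA_integer_
  for (i in seq_len(n + 1)) {
    inactive <- i <= n && !active[i]
    if (inactive && is.na(run_start)) run_start <- i
    if (!inactive && !is.na(run_start)) {
      if ((i - run_start) * bin_s >= T) labels[run_start:(i - 1)] <- "sleep"
      run_start <- NA_integer_
    }
  }
  labels
}

# Random activity sequences with mixed bout scales (short flips and long runs)
random_activity <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- logical(0)
  state <- runif(1) < 0.5
  scales <- c(2, 10, 45, 120)
  while (length(out) < n) {
    len <- 1 + rpois(1, sample(scales, 1))
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n)]
}

random_hypnogram <- function(n, bin_s = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hypnogram(ifelse(random_activity(n), "wake", "sleep"), bin_s = bin_s)
}

make_trace <- function(counts, bin_s = 1, start_clock = "08:00",
                       frame_area = 76800) {
  sleepcam:::new_motion_trace(as.integer(counts), bin_s, start_clock, frame_area)
}

# Naive per-pixel foreground oracle for a model whose every sample equals a
# constant background level: foreground iff |v - bg| > radius.
oracle_foreground_count <- function(frame, bg, radius) {
  sum(abs(frame - bg) > radius)
}

# A filled ellipse mask (matrix) used to build frames with known blob area.
ellipse_mask <- function(h, w, cx, cy, ax, ay) {
  col <- matrix(rep(0:(w - 1), each = h), h, w)
  row <- matrix(rep(0:(h - 1), times = w), h, w)
  ((col - cx) / ax)^2 + ((row - cy) / ay)^2 <= 1
}

flat_frame <- function(h, w, level) matrix(as.integer(level), h, w)

with_blob <- function(frame, mask, level) {
  frame[mask] <- as.integer(level)
  frame
}

# Bin-accuracy of immobility scoring at one raw-count cutoff, computed
# directly from vectors (used as the fine-grid calibration oracle; the
# scoring rule itself is validated against oracle_score_sleep elsewhere).
oracle_threshold_accuracy <- function(counts, ref_wake, cutoff, T = 40) {
  active <- counts > cutoff
  r <- rle(active)
  sleep_run <- !r$values & r$lengths >= T
  scored_wake <- inverse.rle(list(lengths = r$lengths, values = !sleep_run))
  mean(scored_wake == ref_wake)
}

# Overlapping wake/sleep count distributions with a well-defined optimal
# cutoff (truncated normals: wake N(400, 100), sleep N(120, 60)); bout
# lengths around two minutes.
overlap_trace_fixture <- function(seed, n = 3600) {
  set.seed(seed)
  states <- logical(0); s <- TRUE
  while (length(states) < n) {
    states <- c(states, rep(s, 30 + rpois(1, 90)))
    s <- !s
  }
  states <- states[seq_len(n)]
  counts <- as.integer(ifelse(states,
                              pmax(0, round(rnorm(n, 400, 100))),
                              pmax(0, round(rnorm(n, 120, 60)))))
  list(trace = make_trace(counts), wake = states,
       reference = hypnogram(ifelse(states, "wake", "sleep")))
}
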