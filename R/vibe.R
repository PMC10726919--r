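# Sample-based background subtraction. Each pixel keeps n_samples past
# intensities; a pixel is background when at least min_matches samples lie
# within match_radius (inclusive) of its current value. Background pixels
# refresh their own model and a random neighbour's, each with probability
# 1/subsample_factor. Pixels foreground for absorb_after consecutive frames
# are absorbed into the background model (static-target handling: a mouse
# that has settled to sleep must stop registering as motion).

#' Background-subtraction parameters
#'
#' Canonical defaults follow the original sample-based formulation
#' (20 samples, radius 20, 2 matches, subsampling 16). `absorb_after`
#' (consecutive foreground frames before a static pixel is absorbed into the
#' background model) defaults to `5 * subsample_factor`; set it to `Inf` for
#' the pure conservative update in which foreground never updates the model.
#'
#' @param n_samples Background samples kept per pixel.
#' @param match_radius Intensity distance (inclusive) for a sample match.
#' @param min_matches Matches required to call a pixel background.
#' @param subsample_factor Expected update interval, in frames.
#' @param burn_in_s Seconds of frames discarded while the model stabilises.
#' @param absorb_after Consecutive foreground frames before absorption;
#'   `Inf` disables absorption.
#' @return A `vibe_params` list.
#' @export
vibe_params <- function(n_samples = 20, match_radius = 20, min_matches = 2,
                        subsample_factor = 16, burn_in_s = 2,
                        absorb_after = 5 * subsample_factor) {
  check_number(n_samples, "n_samples", min = 1, integerish = TRUE)
  check_number(match_radius, "match_radius", min = 0, strict_min = TRUE)
  check_number(min_matches, "min_matches", min = 1, integerish = TRUE)
  check_number(subsample_factor, "subsample_factor", min = 1, integerish = TRUE)
  check_number(burn_in_s, "burn_in_s", min = 0)
  if (!identical(absorb_after, Inf))
    check_number(absorb_after, "absorb_after", min = 1, integerish = TRUE)
  if (min_matches > n_samples) abort("`min_matches` must be <= `n_samples`")
  structure(
    list(n_samples = as.integer(n_samples), match_radius = match_radius,
         min_matches = as.integer(min_matches),
         subsample_factor = as.integer(subsample_factor),
         burn_in_s = burn_in_s, absorb_after = absorb_after),
    class = "vibe_params"
  )
}

as_int_frame <- function(frame) {
  if (!is.matrix(frame) || any(dim(frame) == 0))
    abort("`frame` must be a non-empty matrix of intensities 0-255")
  storage.mode(frame) <- "integer"
  frame
}

#' Initialise a background model from the first frame
#'
#' Every pixel's samples are drawn (with replacement, seeded) from the
#' intensities in its 8-neighbourhood of the first frame; border pixels use
#' clamped neighbourhoods.
#'
#' @param frame Grayscale matrix, intensities 0-255.
#' @param params A [vibe_params()] list.
#' @param seed Integer seed for the model's private RNG stream.
#' @return A `vibe_model`.
#' @export
vibe_init <- function(frame, params = vibe_params(), seed = 1L) {
  frame <- as_int_frame(frame)
  init <- vibe_init_cpp(frame, params$n_samples, seed)
  structure(
    list(samples = init$samples,
         counter = integer(length(frame)),
         rng_state = init$rng_state,
         height = nrow(frame), width = ncol(frame), params = params),
    class = "vibe_model"
  )
}

#' @export
print.vibe_model <- function(x, ...) {
  cat(sprintf("<vibe_model: %d x %d px, %d samples/pixel>\n",
              x$width, x$height, x$params$n_samples))
  invisible(x)
}

absorb_frames <- function(params) {
  if (identical(params$absorb_after, Inf)) 0L else as.integer(params$absorb_after)
}

#' Classify one frame and update the model
#'
#' @param model A `vibe_model`.
#' @param frame Grayscale matrix matching the model's dimensions.
#' @return A list with `mask` (binary foreground matrix), `count`
#'   (foreground pixels) and `model` (the updated model). The input model is
#'   not modified.
#' @export
vibe_step <- function(model, frame) {
  frame <- as_int_frame(frame)
  if (nrow(frame) != model$height || ncol(frame) != model$width) {
    abort(sprintf("frame is %d x %d px but the model expects %d x %d",
                  ncol(frame), nrow(frame), model$width, model$height))
  }
  p <- model$params
  res <- vibe_run_cpp(model$samples, model$counter, model$rng_state,
                      as.integer(frame), model$height, model$width, 1L,
                      p$n_samples, as.integer(p$match_radius), p$min_matches,
                      p$subsample_factor, absorb_frames(p), TRUE)
  model$samples <- res$samples
  model$counter <- res$counter
  model$rng_state <- res$rng_state
  list(mask = matrix(res$masks, model$height, model$width),
       count = res$counts[1], model = model)
}

new_motion_trace <- function(counts, bin_s, start_clock, frame_area) {
  out <- tibble(time_s = (seq_along(counts) - 1) * bin_s,
                count = as.integer(counts))
  structure(out, bin_s = bin_s, start_clock = start_clock,
            frame_area = frame_area,
            class = c("motion_trace", class(out)))
}

#' Extract a motion trace from a frame stream
#'
#' Runs the background-subtraction classifier over the stream and aggregates
#' per-frame foreground-pixel counts into fixed-width time bins: the
#' actigraphy signal of the system. Frames within the burn-in window update
#' the model but contribute no counts; the trace starts when burn-in ends.
#'
#' @param stream A `frame_stream` (in-memory or renderer-backed).
#' @param params A [vibe_params()] list.
#' @param bin_s Seconds per output bin; `fps * bin_s` must be integral.
#' @param seed Integer seed for the model's stochastic updates.
#' @param aggregate `"max"` (default: one vigorous movement marks the whole
#'   bin active) or `"mean"` per-bin aggregation of per-frame counts.
#' @param chunk_size Frames processed per batch.
#' @return A `motion_trace` tibble with columns `time_s` and `count` and
#'   attributes `bin_s`, `start_clock` and `frame_area`.
#' @export
motion_trace <- function(stream, params = vibe_params(), bin_s = 1,
                         seed = 1L, aggregate = c("max", "mean"),
                         chunk_size = 250L) {
  aggregate <- match.arg(aggregate)
  check_number(bin_s, "bin_s", min = 0, strict_min = TRUE)
  fpb <- stream$fps * bin_s
  if (!is_multiple(fpb, 1)) {
    abort(sprintf("fps * bin_s = %g must be a whole number of frames per bin", fpb))
  }
  fpb <- as.integer(round(fpb))
  burn <- as.integer(round(params$burn_in_s * stream$fps))
  if (stream$n_frames <= burn) {
    abort(sprintf(
      "stream has %d frames but burn-in needs more than %d (%.3g s at %.3g fps)",
      stream$n_frames, burn, params$burn_in_s, stream$fps
    ))
  }
  first <- get_frames(stream, 1L)[, , 1]
  model <- vibe_init(first, params, seed)
  p <- params
  counts <- integer(stream$n_frames)
  done <- 0L
  while (done < stream$n_frames) {
    idx <- (done + 1L):min(done + chunk_size, stream$n_frames)
    block <- get_frames(stream, idx)
    res <- vibe_run_cpp(model$samples, model$counter, model$rng_state,
                        as.integer(block), model$height, model$width,
                        length(idx), p$n_samples, as.integer(p$match_radius),
                        p$min_matches, p$subsample_factor, absorb_frames(p),
                        FALSE)
    counts[idx] <- res$counts
    model$samples <- res$samples
    model$counter <- res$counter
    model$rng_state <- res$rng_state
    done <- idx[length(idx)]
  }
  post <- counts[(burn + 1L):stream$n_frames]
  n_bins <- length(post) %/% fpb
  if (n_bins < 1) abort("stream too short: no complete bins after burn-in")
  post <- post[seq_len(n_bins * fpb)]
  grp <- matrix(post, nrow = fpb)
  binned <- if (aggregate == "max") apply(grp, 2, max) else round(colMeans(grp))
  new_motion_trace(binned, bin_s,
                   format_clock(parse_clock(stream$start_clock) + burn / stream$fps),
                   stream$height * stream$width)
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("# motion trace: %d bins x %.3g s, start %s, frame area %s px\n",
              nrow(x), bin_s_of(x), start_clock_of(x),
              format(attr(x, "frame_area") %||% NA)))
  NextMethod()
}
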