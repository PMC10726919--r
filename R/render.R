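# Synthetic cage video: an elliptical target random-walks during wake, holds
# position with breathing-band area pulsation and occasional 1-2 px ear
# flickers during sleep. Frames are rendered lazily in chunks (a day of video
# never sits in memory) with per-frame noise seeds, so streams are
# bit-reproducible and chunk-size invariant.

#' Synthetic video specification
#'
#' @param width,height Frame size, pixels (test default 320 x 240; the
#'   reference hardware records 1920 x 1080).
#' @param fps Frames per second.
#' @param blob_axes Ellipse semi-axes `c(ax, ay)` of the target, pixels.
#' @param bg_level,blob_level Background and target intensities (0-255);
#'   their difference should exceed the detector's match radius.
#' @param noise_sd Gaussian pixel noise SD, intensity units.
#' @param step_px Random-walk step SD per frame during wake.
#' @param breathing_area_frac Peak fractional area change of the breathing
#'   pulsation during sleep (default +/-3%).
#' @param breathing_hz Breathing frequency, Hz.
#' @param flicker_prob Per-frame probability of a brief ear-flicker patch
#'   during sleep.
#' @param flicker_px Flicker patch edge length, pixels (1-2).
#' @param lead_in_s Seconds of pre-recording frames prepended before the
#'   behavioural clock starts, so the detector's burn-in does not consume
#'   scored recording (default matches the default burn-in).
#' @return A `video_spec` list.
#' @export
video_spec <- function(width = 320, height = 240, fps = 5,
                       blob_axes = c(24, 14), bg_level = 40, blob_level = 200,
                       noise_sd = 2, step_px = 6,
                       breathing_area_frac = 0.03, breathing_hz = 2.5,
                       flicker_prob = 0.1, flicker_px = 2, lead_in_s = 2) {
  check_number(width, "width", min = 8, integerish = TRUE)
  check_number(height, "height", min = 8, integerish = TRUE)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  if (length(blob_axes) != 2 || any(blob_axes <= 0))
    abort("`blob_axes` must be two positive semi-axes")
  if (2 * blob_axes[1] + 4 >= width || 2 * blob_axes[2] + 4 >= height)
    abort("blob does not fit in the frame")
  check_number(bg_level, "bg_level", min = 0, max = 255)
  check_number(blob_level, "blob_level", min = 0, max = 255)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(step_px, "step_px", min = 0)
  check_number(breathing_area_frac, "breathing_area_frac", min = 0, max = 0.5)
  check_number(breathing_hz, "breathing_hz", min = 0)
  check_number(flicker_prob, "flicker_prob", min = 0, max = 1)
  check_number(flicker_px, "flicker_px", min = 0, integerish = TRUE)
  check_number(lead_in_s, "lead_in_s", min = 0)
  structure(
    list(width = width, height = height, fps = fps, blob_axes = blob_axes,
         bg_level = bg_level, blob_level = blob_level, noise_sd = noise_sd,
         step_px = step_px, breathing_area_frac = breathing_area_frac,
         breathing_hz = breathing_hz, flicker_prob = flicker_prob,
         flicker_px = flicker_px, lead_in_s = lead_in_s),
    class = "video_spec"
  )
}

#' Render a ground truth as a synthetic cage video
#'
#' Returns a lazy `frame_stream`: the whole trajectory is computed up front
#' (cheap), frames are rasterised on demand via [get_frames()]. The target
#' never leaves the frame (reflective boundaries). The stream starts
#' `lead_in_s` before the behavioural recording, holding the initial pose,
#' so that detector burn-in consumes lead-in rather than scored time.
#'
#' @param gt A `ground_truth` from [simulate_hypnogram()].
#' @param vspec A [video_spec()].
#' @param seed Integer seed (trajectory and per-frame noise).
#' @return A `frame_stream` (lazy).
#' @export
render_video <- function(gt, vspec = video_spec(), seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(vspec, "video_spec"))
  withr::with_seed(seed, {
    fps <- vspec$fps
    n_lead <- round(vspec$lead_in_s * fps)
    n_rec <- round(span_s(gt$hypnogram) * fps)
    nf <- n_lead + n_rec
    bs <- bin_s_of(gt$hypnogram)
    # per-frame state: lead-in frames replicate the state at t = 0
    rec_bin <- pmin(nrow(gt$hypnogram),
                    floor((seq_len(n_rec) - 1) / fps / bs) + 1)
    sleep_f <- c(rep(gt$hypnogram$state[1] == "sleep", n_lead),
                 (gt$hypnogram$state == "sleep")[rec_bin])
    ax <- vspec$blob_axes[1]; ay <- vspec$blob_axes[2]
    lox <- ax + 2; hix <- vspec$width - 1 - ax - 2
    loy <- ay + 2; hiy <- vspec$height - 1 - ay - 2
    steps_x <- rnorm(nf, 0, vspec$step_px) * !sleep_f
    steps_y <- rnorm(nf, 0, vspec$step_px) * !sleep_f
    x0 <- runif(1, lox, hix); y0 <- runif(1, loy, hiy)
    cx <- fold_reflect(x0 + cumsum(steps_x), lox, hix)
    cy <- fold_reflect(y0 + cumsum(steps_y), loy, hiy)
    # breathing: area scales by (1 + frac * sin), each axis by its sqrt
    tf <- (seq_len(nf) - 1) / fps
    phi <- runif(1, 0, 2 * pi)
    scale <- sqrt(1 + vspec$breathing_area_frac *
                    sin(2 * pi * vspec$breathing_hz * tf + phi))
    scale[!sleep_f] <- 1
    # ear flickers at the blob rim during sleep
    flick <- sleep_f & runif(nf) < vspec$flicker_prob & vspec$flicker_px > 0
    theta <- runif(nf, 0, 2 * pi)
    fx <- ifelse(flick, round(cx + (ax + 1) * cos(theta)), -1L)
    fy <- ifelse(flick, round(cy + (ay + 1) * sin(theta)), -1L)
    fsize <- ifelse(flick, vspec$flicker_px, 0L)
    traj <- list(cx = cx, cy = cy, ax = ax * scale, ay = ay * scale,
                 fx = as.integer(fx), fy = as.integer(fy),
                 fsize = as.integer(fsize))
    structure(
      list(n_frames = nf, height = vspec$height, width = vspec$width,
           fps = fps,
           start_clock = format_clock(parse_clock(start_clock_of(gt$hypnogram)) -
                                        vspec$lead_in_s),
           traj = traj, vspec = vspec, noise_seed = seed),
      class = c("lazy_frame_stream", "frame_stream")
    )
  })
}

#' @export
get_frames.lazy_frame_stream <- function(stream, idx = seq_len(stream$n_frames)) {
  tr <- stream$traj
  v <- stream$vspec
  render_frames_cpp(stream$height, stream$width, as.integer(idx - 1L),
                    tr$cx[idx], tr$cy[idx], tr$ax[idx], tr$ay[idx],
                    v$bg_level, v$blob_level, v$noise_sd,
                    as.double(stream$noise_seed),
                    tr$fx[idx], tr$fy[idx], tr$fsize[idx])
}
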