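# Frame streams: ordered grayscale frame sequences with frame-rate and
# wall-clock metadata. Two backings share one interface: an in-memory integer
# array, and a lazy renderer-backed stream that materialises frames on demand
# (see render_video()), so day-long recordings never sit in RAM at once.

#' Construct an in-memory frame stream
#'
#' A frame stream is an ordered sequence of 2-D grayscale intensity grids
#' (integers 0-255) plus acquisition metadata. All frames share one size and
#' the frame rate must be positive.
#'
#' @param frames A `height x width x n` integer array, a single matrix, or a
#'   list of equally sized matrices, intensities in 0-255.
#' @param fps Frames per second (> 0).
#' @param start_clock Wall-clock time of the first frame, `"hh:mm"` or
#'   `"hh:mm:ss"`.
#' @return A `frame_stream` object.
#' @examples
#' fs <- frame_stream(array(0L, c(24, 32, 10)), fps = 5)
#' fs
#' @export
frame_stream <- function(frames, fps, start_clock = "08:00") {
  if (is.list(frames) && !is.array(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1 || length(dims[[1]]) != 2)
      abort("all frames must be matrices sharing the same dimensions")
    d <- dims[[1]]
    frames <- array(unlist(frames, use.names = FALSE), c(d[1], d[2], length(frames)))
  }
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3)
    abort("`frames` must be a height x width x n array, matrix, or list of matrices")
  if (dim(frames)[3] < 1) abort("a frame stream needs at least one frame")
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  storage.mode(frames) <- "integer"
  if (anyNA(frames) || min(frames) < 0 || max(frames) > 255)
    abort("frame intensities must be integers in 0-255")
  parse_clock(start_clock)
  structure(
    list(frames = frames, n_frames = dim(frames)[3],
         height = dim(frames)[1], width = dim(frames)[2],
         fps = fps, start_clock = start_clock),
    class = c("array_frame_stream", "frame_stream")
  )
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf(
    "<frame_stream: %d frames, %d x %d px, %.3g fps, start %s%s>\n",
    x$n_frames, x$width, x$height, x$fps, x$start_clock,
    if (inherits(x, "lazy_frame_stream")) ", lazy render" else ""
  ))
  invisible(x)
}

#' Materialise frames from a stream
#'
#' @param stream A `frame_stream`.
#' @param idx Frame indices (1-based); defaults to every frame.
#' @return A `height x width x length(idx)` integer array.
#' @export
get_frames <- function(stream, idx = seq_len(stream$n_frames)) {
  UseMethod("get_frames")
}

#' @export
get_frames.array_frame_stream <- function(stream, idx = seq_len(stream$n_frames)) {
  stream$frames[, , idx, drop = FALSE]
}

# Rec. 601 luma: the conversion used for RGB input; infrared night-vision
# footage is effectively single-channel already.
luma <- function(img) {
  if (length(dim(img)) == 2) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read a recording as a frame stream
#'
#' Reads a directory of grayscale PNG frames (sorted by file name) plus an
#' optional `stream.json` holding `fps` and `start_clock`. Colour frames are
#' converted to grayscale by standard luma weighting.
#'
#' @param path Directory containing the frame images.
#' @param fps Frames per second; overrides (or supplies, when the metadata
#'   lacks it) the recorded value.
#' @param start_clock Optional wall-clock start, overriding the metadata.
#' @return A `frame_stream`.
#' @seealso [write_frames()] for the matching writer.
#' @export
read_frames <- function(path, fps = NULL, start_clock = NULL) {
  if (!dir.exists(path)) abort(sprintf("cannot read video frames: '%s' is not a directory", path))
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    abort(sprintf("cannot decode '%s': no PNG frames found", path))
  meta <- list()
  mf <- file.path(path, "stream.json")
  if (file.exists(mf)) meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  fps <- fps %||% meta$fps
  if (is.null(fps) || !is.numeric(fps) || fps <= 0) {
    abort(sprintf(
      "frame rate missing or zero in metadata for '%s'; pass fps explicitly", path
    ))
  }
  start_clock <- start_clock %||% meta$start_clock %||% "08:00"
  mats <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f), error = function(e) {
      abort(sprintf("cannot decode frame '%s': %s", f, conditionMessage(e)))
    })
    if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]  # gray+alpha
    if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
    round(luma(img) * 255)
  })
  frame_stream(lapply(mats, function(m) { storage.mode(m) <- "integer"; m }),
               fps = fps, start_clock = start_clock)
}

#' Write a frame stream as a PNG sequence
#'
#' Writes one grayscale PNG per frame (`frame_000001.png`, ...) and a
#' `stream.json` with the acquisition metadata, the plain-file interchange
#' format read back by [read_frames()].
#'
#' @param stream A `frame_stream`.
#' @param path Output directory (created if needed).
#' @param chunk_size Frames materialised per batch for lazy streams.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stream, path, chunk_size = 200L) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  done <- 0L
  while (done < stream$n_frames) {
    idx <- (done + 1L):min(done + chunk_size, stream$n_frames)
    block <- get_frames(stream, idx)
    for (j in seq_along(idx)) {
      png::writePNG(block[, , j] / 255,
                    file.path(path, sprintf("frame_%06d.png", idx[j])))
    }
    done <- idx[length(idx)]
  }
  jsonlite::write_json(
    list(fps = stream$fps, start_clock = stream$start_clock,
         n_frames = stream$n_frames, width = stream$width,
         height = stream$height),
    file.path(path, "stream.json"), auto_unbox = TRUE
  )
  invisible(path)
}
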