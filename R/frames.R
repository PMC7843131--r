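#' Time-ordered stack of intensity frames for one sample
#'
#' The canonical video container: a 3-D numeric array `[row, col, frame]`
#' holding 8-bit-range intensities (0-255, stored as doubles so derived
#' signals never wrap), together with the acquisition frame rate, the
#' sample-plane pixel pitch and per-frame timestamps. The row axis is by
#' convention the image axis parallel to the lateral displacement `y`
#' (the stretched axis); the column axis is orthogonal to it.
#'
#' @param frames A 3-D numeric array `[row, col, frame]`, a matrix (one
#'   frame) or a list of equally sized matrices.
#' @param fps Frames per second for this sample (after any demultiplexing).
#' @param pixel_pitch Sample-plane pixel pitch (um); `NA` if unknown.
#' @param sample_id Optional sample identifier.
#' @param times Optional per-frame timestamps (s); defaults to
#'   `(0:(n-1))/fps`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, pixel_pitch = NA_real_,
                        sample_id = NULL, times = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share the same dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(
    "frames must be a numeric 3-D array" = is.array(frames) &&
      length(dim(frames)) == 3 && is.numeric(frames),
    "frames must contain finite intensities" = all(is.finite(frames)),
    "fps must be positive" = is.numeric(fps) && fps > 0
  )
  n <- dim(frames)[3]
  if (is.null(times)) times <- (seq_len(n) - 1) / fps
  stopifnot("times must match the number of frames" = length(times) == n,
            "times must be increasing" = n < 2 || all(diff(times) > 0))
  structure(
    list(frames = frames, fps = as.numeric(fps),
         pixel_pitch = as.numeric(pixel_pitch),
         sample_id = sample_id, times = as.numeric(times)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d frames of %d x %d px @ %g fps", d[3], d[1],
              d[2], x$fps))
  if (!is.null(x$sample_id)) cat(sprintf(" [sample %s]", x$sample_id))
  if (!is.na(x$pixel_pitch)) cat(sprintf(", %g um/px", x$pixel_pitch))
  cat(sprintf("\n  intensity range [%g, %g], t = %.4g..%.4g s\n",
              min(x$frames), max(x$frames), x$times[1], x$times[d[3]]))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack A [frame_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[3]
}

# subset frames of a stack by index, preserving metadata and timestamps
stack_subset <- function(stack, idx, fps = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  frame_stack(stack$frames[, , idx, drop = FALSE],
              fps = if (is.null(fps)) stack$fps else fps,
              pixel_pitch = stack$pixel_pitch,
              sample_id = stack$sample_id,
              times = stack$times[idx])
}

#' Raw multiplexed acquisition stream
#'
#' The camera-order frame sequence before demultiplexing, carrying the LED
#' schedule that assigns every frame to a sample. Frame `k` (1-based) is
#' timestamped `(k-1)/base_fps` seconds; LED switching and exposure are
#' treated as instantaneous.
#'
#' @param frames 3-D array, matrix or list of matrices (camera order).
#' @param schedule An [led_schedule()] whose assignment covers the frames.
#' @return An object of class `multiplexed_stream`.
#' @export
multiplexed_stream <- function(frames, schedule) {
  stopifnot(inherits(schedule, "led_schedule"))
  stk <- frame_stack(frames, fps = schedule$base_fps)
  n <- n_frames(stk)
  assignment <- schedule_assignment(schedule, n)  # validates length
  structure(
    list(frames = stk$frames, schedule = schedule,
         times = stk$times, assignment = assignment),
    class = "multiplexed_stream"
  )
}

#' @export
print.multiplexed_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "multiplexed_stream: %d frames of %d x %d px @ %g fps, %d samples (%s mode)\n",
    d[3], d[1], d[2], x$schedule$base_fps, x$schedule$n_samples,
    x$schedule$mode))
  invisible(x)
}
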