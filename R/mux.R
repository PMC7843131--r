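#' Per-sample frame rate under round-robin multiplexing
#'
#' With `n` samples sharing one camera, each sample is captured once every
#' `n` frames, so its effective rate is `base_fps / n`. A 500 fps camera
#' therefore records 50 dishes at 10 fps each, or two dishes at 250 fps.
#'
#' @param base_fps Camera frame rate (frames/s).
#' @param n_samples Number of samples sharing the camera (>= 1).
#' @return Effective frames per second per sample.
#' @export
per_sample_fps <- function(base_fps, n_samples) {
  stopifnot("base_fps must be positive" = is.numeric(base_fps) && base_fps > 0)
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("n_samples must be a positive count")
  }
  base_fps / n_samples
}

#' Disk-bandwidth-limited base frame rate
#'
#' Sustained acquisition is bounded by how fast frames can be written:
#' `fps = disk_rate / frame_size`, with frame sizes expressed in binary
#' megabytes (2^20 bytes), the convention under which a 1280 x 1024
#' single-byte frame is 1.25 MB and a 150 MB/s disk sustains 120 fps.
#'
#' @param disk_rate Sustained write rate (MB/s, binary MB).
#' @param frame Numeric vector `c(width_px, height_px, bytes_per_px)`.
#' @return Maximum sustained frames per second (not floored).
#' @examples
#' bandwidth_limited_fps(150, c(1280, 1024, 1)) # 120
#' @export
bandwidth_limited_fps <- function(disk_rate, frame) {
  stopifnot("disk_rate must be positive" = disk_rate > 0,
            "frame must be c(width, height, bytes/px)" = length(frame) == 3,
            "frame entries must be positive" = all(frame > 0))
  frame_mb <- frame[1] * frame[2] * frame[3] / 2^20
  disk_rate / frame_mb
}

#' Total duration of a block-scanned plate assay
#'
#' `n_wells * frames_per_well` camera frames acquired at `base_fps`:
#' an 80-well assay at 100 frames/well and 120 fps takes 8000 frames,
#' just over a minute.
#'
#' @param n_wells Number of wells imaged.
#' @param frames_per_well Frames recorded per well.
#' @param base_fps Camera frame rate (frames/s).
#' @return A list with `total_frames`, exact `seconds`, and `seconds_rounded`
#'   (nearest second, the conventional report).
#' @examples
#' assay_duration(80, 100, 120)$seconds_rounded # 67
#' @export
assay_duration <- function(n_wells, frames_per_well, base_fps) {
  stopifnot(n_wells >= 1, frames_per_well >= 0, base_fps > 0)
  total <- n_wells * frames_per_well
  secs <- total / base_fps
  list(total_frames = total, seconds = secs,
       seconds_rounded = round(secs))
}

#' LED illumination schedule
#'
#' Defines which sample's LED is lit for every camera frame. Two modes:
#' \describe{
#'   \item{round-robin}{a repeating cycle in which each sample appears
#'     exactly once, so each is captured once every `n` frames;}
#'   \item{block}{the plate-scan pattern: consecutive groups of
#'     `wells_per_block` wells are interleaved for `frames_per_well` cycles
#'     each before moving to the next group (e.g. 80 wells in blocks of 8 at
#'     100 frames/well gives 10 blocks of 800 frames, 8000 assignments).}
#' }
#'
#' @param sample_ids Character vector of sample identifiers (opaque labels;
#'   see [well_ids_96()] for plate coordinates).
#' @param base_fps Camera frame rate (frames/s).
#' @param mode `"round_robin"` or `"block"`.
#' @param frames_per_well Frames per well (block mode only).
#' @param wells_per_block Wells interleaved in parallel (block mode only).
#'   A final smaller block is allowed when it does not divide the well count.
#' @return An object of class `led_schedule` with fields `mode`,
#'   `sample_ids`, `base_fps`, `n_samples`, and for block mode the explicit
#'   per-frame `assignment`.
#' @export
make_schedule <- function(sample_ids, base_fps,
                          mode = c("round_robin", "block"),
                          frames_per_well = NULL, wells_per_block = NULL) {
  mode <- match.arg(mode)
  sample_ids <- as.character(sample_ids)
  stopifnot("sample_ids must be non-empty" = length(sample_ids) >= 1,
            "sample_ids must be unique" = !anyDuplicated(sample_ids),
            "base_fps must be positive" = base_fps > 0)
  out <- list(mode = mode, sample_ids = sample_ids,
              base_fps = as.numeric(base_fps),
              n_samples = length(sample_ids))
  if (mode == "block") {
    stopifnot("frames_per_well required in block mode" =
                !is.null(frames_per_well) && frames_per_well >= 1,
              "wells_per_block required in block mode" =
                !is.null(wells_per_block) && wells_per_block >= 1)
    blocks <- split(sample_ids,
                    ceiling(seq_along(sample_ids) / wells_per_block))
    out$assignment <- unlist(lapply(blocks, function(b) {
      rep(b, times = frames_per_well)  # interleaved cycles within the block
    }), use.names = FALSE)
    out$frames_per_well <- as.integer(frames_per_well)
    out$wells_per_block <- as.integer(wells_per_block)
  }
  structure(out, class = "led_schedule")
}

#' @rdname make_schedule
#' @export
led_schedule <- make_schedule

#' @export
print.led_schedule <- function(x, ...) {
  cat(sprintf("led_schedule (%s): %d samples @ %g fps base", x$mode,
              x$n_samples, x$base_fps))
  if (x$mode == "round_robin") {
    cat(sprintf(" -> %g fps/sample\n", x$base_fps / x$n_samples))
  } else {
    cat(sprintf(", %d frames/well in blocks of %d (%d assignments)\n",
                x$frames_per_well, x$wells_per_block, length(x$assignment)))
  }
  invisible(x)
}

#' Per-frame sample assignment of a schedule
#'
#' Expands a schedule into the sample id lit for each camera frame. In
#' round-robin mode `n_frames` must be a whole number of cycles; in block
#' mode the stored assignment's length must be matched exactly (when
#' `n_frames` is given).
#'
#' @param schedule An [led_schedule()].
#' @param n_frames Number of stream frames to cover; defaults to one cycle
#'   (round-robin) or the full block assignment.
#' @return Character vector of sample ids, one per frame.
#' @export
schedule_assignment <- function(schedule, n_frames = NULL) {
  stopifnot(inherits(schedule, "led_schedule"))
  if (schedule$mode == "round_robin") {
    n <- schedule$n_samples
    if (is.null(n_frames)) n_frames <- n
    if (n_frames %% n != 0) {
      stop(sprintf(
        "stream length %d is not a whole number of round-robin cycles of %d (truncated cycle after frame %d)",
        n_frames, n, n * (n_frames %/% n)))
    }
    rep(schedule$sample_ids, times = n_frames / n)
  } else {
    if (!is.null(n_frames) && n_frames != length(schedule$assignment)) {
      stop(sprintf("stream has %d frames but the block schedule assigns %d",
                   n_frames, length(schedule$assignment)))
    }
    schedule$assignment
  }
}

#' Split a multiplexed stream into per-sample stacks
#'
#' Routes every frame of the camera stream to the sample whose LED was lit,
#' preserving order and timestamps. No frame is duplicated or dropped: the
#' per-sample frame counts always sum to the stream length. The effective
#' per-sample rate is recorded (`base_fps / n` in round-robin mode;
#' `base_fps / wells_per_block` within a block scan).
#'
#' @param stream A [multiplexed_stream()].
#' @return Named list of [frame_stack()] objects, one per sample id, in
#'   schedule order.
#' @export
demultiplex <- function(stream) {
  stopifnot(inherits(stream, "multiplexed_stream"))
  sched <- stream$schedule
  assignment <- stream$assignment
  eff_fps <- if (sched$mode == "round_robin") {
    sched$base_fps / sched$n_samples
  } else {
    sched$base_fps / sched$wells_per_block
  }
  out <- lapply(sched$sample_ids, function(id) {
    idx <- which(assignment == id)
    frame_stack(stream$frames[, , idx, drop = FALSE],
                fps = eff_fps, sample_id = id,
                times = stream$times[idx])
  })
  names(out) <- sched$sample_ids
  out
}

#' Interleave per-sample stacks back into a camera-order stream
#'
#' Inverse of [demultiplex()]: emits frames in schedule order, consuming
#' each sample's stack sequentially. Every scheduled sample must be present
#' with at least as many frames as the schedule assigns it.
#'
#' @param stacks Named list of [frame_stack()] objects keyed by sample id.
#' @param schedule An [led_schedule()].
#' @param n_frames Stream length for round-robin mode (defaults to the
#'   number of whole cycles the shortest stack supports).
#' @return A [multiplexed_stream()].
#' @export
remultiplex <- function(stacks, schedule, n_frames = NULL) {
  stopifnot(inherits(schedule, "led_schedule"), is.list(stacks))
  if (schedule$mode == "round_robin" && is.null(n_frames)) {
    missing <- setdiff(schedule$sample_ids, names(stacks))
    if (length(missing)) {
      stop("missing sample(s) in stacks: ", paste(missing, collapse = ", "))
    }
    n_cycles <- min(vapply(stacks[schedule$sample_ids], n_frames_safe, 1L))
    n_frames <- n_cycles * schedule$n_samples
  }
  assignment <- schedule_assignment(schedule, n_frames)
  counts <- table(assignment)
  missing <- setdiff(names(counts), names(stacks))
  if (length(missing)) {
    stop("missing sample(s) in stacks: ", paste(missing, collapse = ", "))
  }
  for (id in names(counts)) {
    have <- n_frames_safe(stacks[[id]])
    if (have < counts[[id]]) {
      stop(sprintf("stack for sample %s has %d frames but the schedule needs %d",
                   id, have, counts[[id]]))
    }
  }
  d <- dim(as_frame_array(stacks[[assignment[1]]]))[1:2]
  arr <- array(0, dim = c(d, length(assignment)))
  cursor <- stats::setNames(integer(length(counts)), names(counts))
  for (k in seq_along(assignment)) {
    id <- assignment[k]
    cursor[id] <- cursor[id] + 1L
    arr[, , k] <- as_frame_array(stacks[[id]])[, , cursor[id]]
  }
  multiplexed_stream(arr, schedule)
}

n_frames_safe <- function(x) {
  if (inherits(x, "frame_stack")) n_frames(x)
  else if (is.array(x) && length(dim(x)) == 3) dim(x)[3]
  else stop("stacks must be frame_stack objects or 3-D arrays")
}

as_frame_array <- function(x) {
  if (inherits(x, "frame_stack")) x$frames else x
}

#' 96-well plate coordinate labels
#'
#' Row-major well names "A1".."H12" with optional exclusions for wells
#' obscured by hardware or left unilluminated.
#'
#' @param exclude Character vector of well names to drop.
#' @return Character vector of well ids.
#' @examples
#' length(well_ids_96())                     # 96
#' length(well_ids_96(exclude = well_ids_96()[1:16])) # 80
#' @export
well_ids_96 <- function(exclude = character()) {
  ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  setdiff(ids, exclude)
}
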