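#' Read and write frame stacks as multi-page TIFF
#'
#' Stacks travel as 8-bit greyscale multi-page TIFF. Intensities are
#' stored in the package's 0-255 convention and scaled to the TIFF 0-1
#' range on write. Frame-rate and pitch metadata (which TIFF does not
#' carry portably) live in an optional JSON sidecar written beside the
#' stack.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @param sidecar Write `<path>.json` with fps / pitch / sample metadata
#'   (default TRUE).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  frames <- lapply(seq_len(n_frames(stack)), function(k) {
    pmin(pmax(stack$frames[, , k] / 255, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  if (sidecar) {
    meta <- list(fps = stack$fps, sample_id = stack$sample_id,
                 times = stack$times)
    if (!is.na(stack$pixel_pitch)) meta$pixel_pitch <- stack$pixel_pitch
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_stack
#' @param fps,pixel_pitch,sample_id Metadata overrides used when no
#'   sidecar file is found.
#' @return For `read_stack`, a [frame_stack()].
#' @export
read_stack <- function(path, fps = NULL, pixel_pitch = NA_real_,
                       sample_id = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra channels
    p * 255
  })
  times <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(fps)) fps <- meta$fps
    if (is.na(pixel_pitch) && is.numeric(meta$pixel_pitch)) {
      pixel_pitch <- meta$pixel_pitch
    }
    if (is.null(sample_id)) sample_id <- meta$sample_id
    times <- meta$times
  }
  if (is.null(fps)) stop("fps not given and no sidecar metadata found")
  frame_stack(pages, fps = fps, pixel_pitch = pixel_pitch,
              sample_id = sample_id, times = times)
}

#' Serialize and restore LED schedules as JSON
#'
#' @param schedule An [led_schedule()].
#' @param path JSON path.
#' @return `path` invisibly; `read_schedule` returns an [led_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "led_schedule"))
  obj <- list(mode = schedule$mode, sample_ids = schedule$sample_ids,
              base_fps = schedule$base_fps)
  if (schedule$mode == "block") {
    obj$frames_per_well <- schedule$frames_per_well
    obj$wells_per_block <- schedule$wells_per_block
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_schedule(obj$sample_ids, base_fps = obj$base_fps, mode = obj$mode,
                frames_per_well = obj$frames_per_well,
                wells_per_block = obj$wells_per_block)
}

#' Load an optical configuration from a YAML or JSON file
#'
#' The file may name a `preset` and/or override individual fields
#' (`f_M`, `f_L`, `lens_diameter`, `sensor_px`, `pixel_pitch`,
#' `wavelength`, `f_number`, `coc`). Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [rap_config()].
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("preset", "f_M", "f_L", "lens_diameter", "sensor_px",
             "pixel_pitch", "wavelength", "f_number", "coc")
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(rap_config, obj)
}
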