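#' Simulate a beating cardiac monolayer as a travelling intensity wave
#'
#' Generates a bright-field-like video of a confluent monolayer crossed by
#' a periodic planar contraction wave. Each pixel's intensity is a baseline
#' plus a smooth pulse evaluated at the local phase
#' `t - (x cos(phi) + y sin(phi)) / v`: a raised-cosine upstroke of
#' duration `rise_time` (contraction), a plateau, and a raised-cosine
#' return of duration `fall_time` (relaxation), repeating every `period`
#' seconds. Differencing such a pulse with [motion_signal()] yields the
#' characteristic two motion transients per cycle. Gaussian noise is added
#' and intensities are clipped to 0-255.
#'
#' The ground truth returned beside the pixels is the per-pixel activation
#' time of the first wave (the upstroke midpoint) together with the true
#' speed and direction, so downstream accuracy is always measured against
#' the generator, never against biological data.
#'
#' @param width,height Frame size (px).
#' @param fps Frames per second.
#' @param duration Recording length (s).
#' @param pixel_pitch Sample-plane pixel pitch (um).
#' @param speed Wave speed (mm/s).
#' @param direction Propagation direction (degrees counter-clockwise from
#'   the +column axis).
#' @param period Beat period (s); must exceed
#'   `rise_time + plateau + fall_time`.
#' @param amplitude Pulse amplitude (intensity units).
#' @param baseline Resting intensity.
#' @param rise_time,plateau,fall_time Pulse phase durations (s).
#' @param t0 Activation time at the image centre for the first beat (s).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; every call with the same seed is
#'   bit-identical.
#' @return A list with `stack` (a [frame_stack()]) and `truth` (list:
#'   `activation_time` matrix in s, `speed`, `direction_deg`, `period`).
#' @export
simulate_monolayer <- function(width = 100, height = 100, fps = 40,
                               duration = 2.5, pixel_pitch = 20,
                               speed = 20, direction = 0, period = 1,
                               amplitude = 80, baseline = 120,
                               rise_time = 0.06, plateau = 0.20,
                               fall_time = 0.12, t0 = 0.30,
                               noise_sd = 2, seed = 1) {
  stopifnot(speed > 0, amplitude >= 0, period > 0)
  if (rise_time + plateau + fall_time >= period) {
    stop("wave period is shorter than the pulse support ",
         "(rise + plateau + fall)")
  }
  if (!is.null(seed)) set.seed(seed)
  nt <- max(2L, round(duration * fps))
  phi <- direction * pi / 180
  # pixel positions in mm relative to the image centre
  xx <- (seq_len(width) - (width + 1) / 2) * pixel_pitch / 1000
  yy <- (seq_len(height) - (height + 1) / 2) * pixel_pitch / 1000
  proj <- outer(yy * sin(phi), xx * cos(phi), `+`)  # [row, col] mm
  t_act <- t0 + proj / speed
  arr <- array(0, dim = c(height, width, nt))
  times <- (seq_len(nt) - 1) / fps
  for (k in seq_len(nt)) {
    tau <- (times[k] - t_act) %% period
    tau[times[k] < t_act] <- NA  # quiescent before the first wave arrives
    p <- pulse_profile(tau, rise_time, plateau, fall_time)
    arr[, , k] <- baseline + amplitude * p
  }
  if (noise_sd > 0) {
    arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  }
  arr <- pmin(pmax(arr, 0), 255)
  list(stack = frame_stack(arr, fps = fps, pixel_pitch = pixel_pitch),
       truth = list(activation_time = t_act + rise_time / 2, speed = speed,
                    direction_deg = direction %% 360, period = period))
}

# smooth biphasic beat: raised-cosine rise, plateau, raised-cosine fall
pulse_profile <- function(tau, rise, plateau, fall) {
  p <- numeric(length(tau))
  idx_r <- which(tau >= 0 & tau < rise)
  p[idx_r] <- 0.5 * (1 - cos(pi * tau[idx_r] / rise))
  idx_p <- which(tau >= rise & tau < rise + plateau)
  p[idx_p] <- 1
  idx_f <- which(tau >= rise + plateau & tau < rise + plateau + fall)
  p[idx_f] <- 0.5 * (1 + cos(pi * (tau[idx_f] - rise - plateau) / fall))
  dim(p) <- dim(tau)
  p
}

#' Simulate thrashing C. elegans as undulating dark curves
#'
#' Renders worms as dark, anti-aliased sinusoidal polylines on a bright
#' background. Each worm's undulation phase advances by
#' `2 pi frequency / fps` per frame; its centroid performs a seeded,
#' reflected random walk of step `drift` pixels per frame. Overlapping
#' bodies take the darker value. With zero frequency and zero drift the
#' stack is static and the activity metric is exactly zero.
#'
#' @param width,height Frame size (px).
#' @param fps Frames per second (15 in the plate assay).
#' @param n_frames Number of frames (100 per well in the plate assay).
#' @param n_worms Worms per well.
#' @param body_length Worm length (px).
#' @param body_width Rendered body width (px); soft-edged so the activity
#'   metric does not alias with phase.
#' @param amplitude Undulation amplitude (px). The default keeps the
#'   frame-to-frame body displacement at wild-type thrash rates comparable
#'   to the body width at 15 fps, the sampling regime in which the
#'   pixel-change metric tracks thrash frequency rather than saturating.
#' @param wavelength Undulation wavelength along the body (px); default
#'   two-thirds of the body length (about 1.5 waves per body).
#' @param frequency Thrash frequency (Hz), >= 0.
#' @param drift Centroid random-walk step (px/frame), >= 0.
#' @param background Background intensity.
#' @param contrast Body darkness below background (intensity units).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed (bit-identical reruns).
#' @return A list with `stack` (a [frame_stack()]) and `truth` (list:
#'   `centrelines` - per frame, per worm, an n x 2 matrix of (row, col)
#'   body points - plus `frequency` and `n_worms`).
#' @export
simulate_worms <- function(width = 64, height = 64, fps = 15,
                           n_frames = 100, n_worms = 5, body_length = 28,
                           body_width = 3, amplitude = 2.5,
                           wavelength = body_length / 1.5, frequency = 2,
                           drift = 0.5, background = 220, contrast = 160,
                           noise_sd = 2, seed = 1) {
  stopifnot(frequency >= 0, drift >= 0, n_worms >= 1, n_frames >= 1,
            body_length >= 4, contrast >= 0, contrast <= background)
  if (!is.null(seed)) set.seed(seed)
  margin <- body_length / 2 + amplitude + body_width
  if (2 * margin >= min(width, height)) {
    stop("worms do not fit in the frame: reduce body_length or enlarge frame")
  }
  centres <- cbind(stats::runif(n_worms, margin, height - margin),
                   stats::runif(n_worms, margin, width - margin))
  alpha <- stats::runif(n_worms, 0, 2 * pi)    # body orientation
  phi0 <- stats::runif(n_worms, 0, 2 * pi)     # initial undulation phase
  dphi <- 2 * pi * frequency / fps
  s <- seq(-body_length / 2, body_length / 2, by = 0.6)  # arc-length samples
  arr <- array(background, dim = c(height, width, n_frames))
  centrelines <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    dark <- matrix(0, height, width)
    frame_lines <- vector("list", n_worms)
    for (w in seq_len(n_worms)) {
      if (drift > 0) {
        step_dir <- stats::runif(1, 0, 2 * pi)
        centres[w, ] <- centres[w, ] + drift * c(sin(step_dir), cos(step_dir))
        centres[w, 1] <- reflect_into(centres[w, 1], margin, height - margin)
        centres[w, 2] <- reflect_into(centres[w, 2], margin, width - margin)
      }
      phase <- phi0[w] + (k - 1) * dphi
      lat <- amplitude * sin(2 * pi * s / wavelength - phase)
      rows <- centres[w, 1] + s * sin(alpha[w]) + lat * cos(alpha[w])
      cols <- centres[w, 2] + s * cos(alpha[w]) - lat * sin(alpha[w])
      dark <- stamp_polyline(dark, rows, cols, body_width)
      frame_lines[[w]] <- cbind(row = rows, col = cols)
    }
    arr[, , k] <- background - contrast * dark
    centrelines[[k]] <- frame_lines
  }
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
  arr <- pmin(pmax(arr, 0), 255)
  list(stack = frame_stack(arr, fps = fps, pixel_pitch = NA_real_),
       truth = list(centrelines = centrelines, frequency = frequency,
                    n_worms = n_worms))
}

reflect_into <- function(x, lo, hi) {
  if (x < lo) x <- lo + (lo - x)
  if (x > hi) x <- hi - (x - hi)
  min(max(x, lo), hi)
}

# max-combine soft-edged stamps along a polyline: darkness in [0, 1]
stamp_polyline <- function(dark, rows, cols, width) {
  h <- nrow(dark); w <- ncol(dark)
  r_half <- width / 2
  rk <- ceiling(r_half + 1)
  offs <- expand.grid(dr = -rk:rk, dc = -rk:rk)
  for (i in seq_along(rows)) {
    pr <- rows[i]; pc <- cols[i]
    rr <- round(pr) + offs$dr
    cc <- round(pc) + offs$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (!any(ok)) next
    d <- sqrt((rr[ok] - pr)^2 + (cc[ok] - pc)^2)
    val <- pmin(pmax(r_half + 0.5 - d, 0), 1)  # anti-aliased capsule edge
    idx <- cbind(rr[ok], cc[ok])
    dark[idx] <- pmax(dark[idx], val)
  }
  dark
}

#' Plate-level rendering parameters
#'
#' Describes how per-sample scenes are degraded and interleaved into one
#' camera stream: each sample's lateral displacement sets its geometric
#' distortion; brightness falls off with displacement
#' (`exp(-falloff * y)`); optical blur grows linearly with displacement
#' (`blur_fwhm_um = blur0 + blur_slope * y`); an optional per-LED-colour
#' chromatic focal offset adds defocus blur of width
#' `offset x NA` (the geometric blur disc of a defocused beam).
#'
#' @param y Named numeric vector of lateral displacements (mm), one per
#'   sample id in the schedule.
#' @param schedule An [led_schedule()].
#' @param config A [rap_config()].
#' @param falloff Brightness falloff coefficient (1/mm), >= 0.
#' @param blur0,blur_slope Blur FWHM intercept (um) and slope (um/mm).
#' @param chromatic_offset_um Focal-plane offset of the active LED colour
#'   relative to best focus (um); 0 disables chromatic blur. The
#'   red-to-blue shift of the single-element objectives is 981 um.
#' @param sample_pitch_um Sample-plane pixel pitch (um) used to convert
#'   blur widths to pixels.
#' @param noise_sd Additive Gaussian camera noise (intensity units).
#' @param fill Fill intensity for out-of-field pixels after warping.
#' @return An object of class `plate_params`.
#' @export
plate_params <- function(y, schedule, config, falloff = 0.004,
                         blur0 = 0, blur_slope = 0,
                         chromatic_offset_um = 0, sample_pitch_um = 4.8,
                         noise_sd = 0, fill = 0) {
  stopifnot(inherits(schedule, "led_schedule"),
            inherits(config, "rap_config"),
            falloff >= 0, blur0 >= 0, blur_slope >= 0, noise_sd >= 0,
            "y must be named by sample id" = !is.null(names(y)))
  missing <- setdiff(schedule$sample_ids, names(y))
  if (length(missing)) {
    stop("no displacement y given for sample(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(y < 0) || any(y >= 2 * config$f_M)) {
    stop("displacements must lie within [0, 2*f_M)")
  }
  if (any(exp(-falloff * y) <= 0)) stop("falloff annihilates intensities")
  structure(list(y = y, schedule = schedule, config = config,
                 falloff = falloff, blur0 = blur0, blur_slope = blur_slope,
                 chromatic_offset_um = chromatic_offset_um,
                 sample_pitch_um = sample_pitch_um,
                 noise_sd = noise_sd, fill = fill),
            class = "plate_params")
}

#' Render per-sample scenes into a multiplexed camera stream
#'
#' Composes the full forward model of the instrument: for every scheduled
#' frame, the assigned sample's next scene frame is warped through the
#' off-axis geometric distortion at that sample's displacement
#' ([forward_project()]), attenuated by the brightness falloff, blurred by
#' the displacement- and colour-dependent Gaussian PSF, and degraded with
#' camera noise. The result is the interleaved stream a RAP camera would
#' record, alongside the ground truth needed to score any downstream
#' recovery.
#'
#' @param scenes Named list of [frame_stack()] objects (or bare 3-D
#'   arrays), keyed by sample id, each long enough for its scheduled
#'   frame count.
#' @param plate A [plate_params()].
#' @param seed Integer seed for the noise (bit-identical reruns).
#' @return A list with `stream` (a [multiplexed_stream()]) and `truth`
#'   (list: per-frame `assignment`, per-sample `y`, warp `factors`,
#'   `brightness` factors, `blur_fwhm_um`).
#' @export
render_plate <- function(scenes, plate, seed = 1) {
  stopifnot(inherits(plate, "plate_params"))
  sched <- plate$schedule
  missing <- setdiff(sched$sample_ids, names(scenes))
  if (length(missing)) {
    stop("schedule assigns frames to sample(s) with no scene: ",
         paste(missing, collapse = ", "))
  }
  assignment <- schedule_assignment(
    sched, if (sched$mode == "block") NULL else {
      min(vapply(scenes[sched$sample_ids], n_frames_safe, 1L)) *
        sched$n_samples
    })
  counts <- table(assignment)
  for (id in names(counts)) {
    if (n_frames_safe(scenes[[id]]) < counts[[id]]) {
      stop(sprintf("scene for sample %s has %d frames; schedule needs %d",
                   id, n_frames_safe(scenes[[id]]), counts[[id]]))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- plate$config
  ids <- sched$sample_ids
  factors <- lapply(ids, function(id) warp_factors(cfg, plate$y[[id]]))
  names(factors) <- ids
  brightness <- exp(-plate$falloff * plate$y[ids])
  blur_um <- plate$blur0 + plate$blur_slope * plate$y[ids] +
    plate$chromatic_offset_um * cfg$na
  names(brightness) <- names(blur_um) <- ids
  blur_sigma_px <- blur_um / (2 * sqrt(2 * log(2))) / plate$sample_pitch_um
  d <- dim(as_frame_array(scenes[[assignment[1]]]))[1:2]
  arr <- array(0, dim = c(d, length(assignment)))
  cursor <- stats::setNames(integer(length(counts)), names(counts))
  for (k in seq_along(assignment)) {
    id <- assignment[k]
    cursor[id] <- cursor[id] + 1L
    fr <- as_frame_array(scenes[[id]])[, , cursor[id]]
    fr <- forward_project(fr, cfg, plate$y[[id]], fill = plate$fill)
    fr <- fr * brightness[[id]]
    if (blur_sigma_px[[id]] > 0.3) {
      fr <- EBImage::gblur(fr, sigma = blur_sigma_px[[id]])
    }
    if (plate$noise_sd > 0) {
      fr <- fr + stats::rnorm(length(fr), sd = plate$noise_sd)
    }
    arr[, , k] <- pmin(pmax(fr, 0), 255)
  }
  list(stream = multiplexed_stream(arr, sched),
       truth = list(assignment = assignment, y = plate$y[ids],
                    factors = factors, brightness = brightness,
                    blur_fwhm_um = blur_um))
}

#' Built-in simulation scenarios
#'
#' Parameter bundles reproducing the instrument's demonstration
#' experiments at desk scale:
#' \describe{
#'   \item{`"cardiac-dishes"`}{four dishes of beating monolayer imaged
#'     round-robin at 160 fps base (40 fps/dish).}
#'   \item{`"worm-dishes"`}{four worm dishes round-robin at 60 fps base
#'     (15 fps/dish).}
#'   \item{`"worm-plate"`}{the 80-well plate scan: blocks of 8 wells
#'     interleaved at 120 fps base (15 fps/well), 100 frames per well,
#'     8000 camera frames in 67 s.}
#' }
#'
#' @param name Scenario name.
#' @return A list with a `schedule` ([led_schedule()]), a `config`
#'   ([rap_config()]) and scenario metadata (`scene`, per-sample
#'   displacement range).
#' @export
rap_scenario <- function(name = c("cardiac-dishes", "worm-dishes",
                                  "worm-plate")) {
  name <- match.arg(name)
  switch(name,
    "cardiac-dishes" = list(
      name = name, scene = "monolayer",
      config = rap_config("config1"),
      schedule = make_schedule(paste0("dish", 1:4), base_fps = 160),
      y = stats::setNames(c(40, 40, 40, 40), paste0("dish", 1:4))
    ),
    "worm-dishes" = list(
      name = name, scene = "worms",
      config = rap_config("config1"),
      schedule = make_schedule(paste0("dish", 1:4), base_fps = 60),
      y = stats::setNames(c(40, 40, 40, 40), paste0("dish", 1:4))
    ),
    "worm-plate" = {
      wells <- well_ids_96()[1:80]
      list(
        name = name, scene = "worms",
        config = rap_config("config2"),
        schedule = make_schedule(wells, base_fps = 120, mode = "block",
                                 frames_per_well = 100, wells_per_block = 8),
        y = stats::setNames(seq(10, 70, length.out = 80), wells)
      )
    })
}
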