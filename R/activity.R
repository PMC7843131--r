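#' Dye-free motion signal by running background subtraction
#'
#' Per-pixel absolute difference with a frame `lag` frames earlier:
#' `|P_t - P_{t-lag}|`. The default lag of 6 frames turns the slow intensity
#' modulation of a contracting cardiac monolayer into a bright transient at
#' every contraction and relaxation. The output stack is `lag` frames
#' shorter, with timestamps inherited from the later frame of each pair.
#'
#' @param stack A [frame_stack()].
#' @param lag Frame offset `n >= 1`, default 6.
#' @return A [frame_stack()] of non-negative motion intensities.
#' @export
motion_signal <- function(stack, lag = 6) {
  stopifnot(inherits(stack, "frame_stack"),
            "lag must be a positive integer" = lag >= 1)
  nt <- n_frames(stack)
  if (lag >= nt) stop(sprintf("lag %d >= stack length %d", lag, nt))
  idx <- (lag + 1):nt
  out <- abs(stack$frames[, , idx, drop = FALSE] -
             stack$frames[, , idx - lag, drop = FALSE])
  res <- frame_stack(out, fps = stack$fps, pixel_pitch = stack$pixel_pitch,
                     sample_id = stack$sample_id, times = stack$times[idx])
  attr(res, "lag") <- lag
  res
}

#' Mean motion trace over a rectangular ROI
#'
#' Averages the motion signal over a region of interest (default 20 x 20 px)
#' for each frame, producing the intensity-versus-time trace whose double
#' spikes mark contraction followed by relaxation.
#'
#' @param motion A motion [frame_stack()] (see [motion_signal()]).
#' @param centre ROI centre as `c(row, col)` in pixels.
#' @param size ROI extent `c(rows, cols)`, default `c(20, 20)`.
#' @return A `data.frame` with columns `time` (s) and `value` (mean motion
#'   intensity), with the ROI recorded in attribute `roi`.
#' @export
roi_trace <- function(motion, centre, size = c(20, 20)) {
  stopifnot(inherits(motion, "frame_stack"), length(centre) == 2,
            length(size) == 2, all(size >= 1))
  d <- dim(motion$frames)
  r0 <- round(centre[1]) - (size[1] %/% 2)
  c0 <- round(centre[2]) - (size[2] %/% 2)
  rows <- (r0 + 1):(r0 + size[1])
  cols <- (c0 + 1):(c0 + size[2])
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2]) {
    stop("ROI extends outside the frame")
  }
  vals <- apply(motion$frames[rows, cols, , drop = FALSE], 3, mean)
  out <- data.frame(time = motion$times, value = vals)
  attr(out, "roi") <- list(centre = centre, size = size)
  out
}

#' Count trace peaks above a prominence floor
#'
#' Local maxima whose height exceeds `min_frac` of the trace maximum,
#' separated by at least `min_separation` samples. Used to verify the
#' two-peaks-per-cycle (contraction + relaxation) signature of cardiac
#' ROI traces.
#'
#' @param values Numeric trace.
#' @param min_frac Height floor as a fraction of `max(values)`, default 0.25.
#' @param min_separation Minimum peak spacing in samples, default 3.
#' @return Integer peak count.
#' @export
count_peaks <- function(values, min_frac = 0.25, min_separation = 3) {
  stopifnot(is.numeric(values), length(values) >= 3)
  if (max(values) <= 0) return(0L)
  pk <- pracma::findpeaks(values, minpeakheight = min_frac * max(values),
                          minpeakdistance = min_separation)
  if (is.null(pk)) 0L else nrow(pk)
}

#' Per-pixel activation map of a propagating contraction wave
#'
#' For each pixel, the activation time is the first moment the
#' spatio-temporally smoothed motion signal crosses `level` times that
#' pixel's own temporal maximum, linearly interpolated between frames.
#' Pixels whose maximum stays below `noise_floor` times the stack's global
#' motion maximum are marked unactivated (`NA`). Smoothing is a separable
#' box mean: `smooth_px` pixels in each spatial axis and `smooth_frames`
#' frames in time.
#'
#' @param motion A motion [frame_stack()].
#' @param smooth_px Spatial box width (px, odd), default 3.
#' @param smooth_frames Temporal box width (frames, odd), default 3.
#' @param level Crossing level as a fraction of the per-pixel maximum,
#'   default 0.5.
#' @param noise_floor Activation floor as a fraction of the global motion
#'   maximum, default 0.05.
#' @return An `activation_map`: numeric matrix of activation times (s) with
#'   `NA` for unactivated pixels; attributes record `fps`, `pixel_pitch`
#'   and the smoothing parameters.
#' @export
activation_map <- function(motion, smooth_px = 3, smooth_frames = 3,
                           level = 0.5, noise_floor = 0.05) {
  stopifnot(inherits(motion, "frame_stack"), level > 0, level <= 1,
            smooth_px >= 1, smooth_frames >= 1)
  d <- dim(motion$frames)
  sm <- motion$frames
  if (smooth_px > 1) {
    for (k in seq_len(d[3])) sm[, , k] <- box_smooth_2d(sm[, , k], smooth_px)
  }
  if (smooth_frames > 1 && d[3] >= smooth_frames) {
    sm <- box_smooth_time(sm, smooth_frames)
  }
  npx <- d[1] * d[2]
  p <- matrix(sm, nrow = npx, ncol = d[3])  # pixels x time
  pmaxv <- do.call(pmax, lapply(seq_len(d[3]), function(k) p[, k]))
  g <- max(pmaxv)
  if (g <= 0) {
    warning("all-quiet stack: no pixel shows motion; map is all unactivated")
    out <- matrix(NA_real_, d[1], d[2])
  } else {
    active <- pmaxv >= noise_floor * g & pmaxv > 0
    th <- level * pmaxv
    above <- p >= th
    first <- apply(above, 1, which.max)  # first crossing frame
    prev <- pmax(first - 1L, 1L)
    s_at <- p[cbind(seq_len(npx), first)]
    s_prev <- p[cbind(seq_len(npx), prev)]
    denom <- s_at - s_prev
    frac <- ifelse(denom > 0, (th - s_prev) / denom, 1)
    dt <- 1 / motion$fps
    t_act <- motion$times[first] - (1 - frac) * dt * (first > 1)
    t_act[!active] <- NA_real_
    out <- matrix(t_act, d[1], d[2])
  }
  structure(out, class = c("activation_map", "matrix"),
            fps = motion$fps, pixel_pitch = motion$pixel_pitch,
            params = list(smooth_px = smooth_px, smooth_frames = smooth_frames,
                          level = level, noise_floor = noise_floor))
}

# separable box mean over rows then columns (edge-renormalised)
box_smooth_2d <- function(m, width) {
  k <- rep(1, width)
  norm_row <- as.numeric(stats::filter(rep(1, nrow(m)), k, sides = 2))
  norm_col <- as.numeric(stats::filter(rep(1, ncol(m)), k, sides = 2))
  norm_row[is.na(norm_row)] <- width; norm_col[is.na(norm_col)] <- width
  a <- apply(m, 2, function(col) {
    v <- as.numeric(stats::filter(col, k, sides = 2))
    v[is.na(v)] <- col[is.na(v)] * norm_row[is.na(v)]  # keep edges finite
    v / norm_row
  })
  t(apply(a, 1, function(row) {
    v <- as.numeric(stats::filter(row, k, sides = 2))
    v[is.na(v)] <- row[is.na(v)] * norm_col[is.na(v)]
    v / norm_col
  }))
}

# temporal running mean along the third axis
box_smooth_time <- function(arr, width) {
  d <- dim(arr)
  p <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  k <- rep(1, width) / width
  ps <- t(apply(p, 1, function(v) {
    s <- as.numeric(stats::filter(v, k, sides = 2))
    s[is.na(s)] <- v[is.na(s)]  # edges: keep raw value
    s
  }))
  array(ps, dim = d)
}

#' Conduction velocity from an activation map
#'
#' Fits activation time as an affine function of pixel position by least
#' squares over the activated pixels. The fitted gradient (s/px) gives the
#' wave slowness; speed is its reciprocal converted through the pixel
#' pitch, and direction is the gradient's orientation (the direction of
#' propagation, degrees counter-clockwise from the +column axis).
#'
#' @param map An [activation_map()].
#' @param pixel_pitch Sample-plane pixel pitch (um); defaults to the map's
#'   recorded pitch.
#' @param min_gradient Gradient magnitude (s/px) below which activation is
#'   reported as quasi-simultaneous, default 1e-6.
#' @return A list with `speed_mm_s`, `direction_deg`, `gradient` (s/px,
#'   `c(col, row)`), `n_pixels` and logical `quasi_simultaneous` (when set,
#'   `speed_mm_s` is `NA`).
#' @export
conduction_velocity <- function(map, pixel_pitch = attr(map, "pixel_pitch"),
                                min_gradient = 1e-6) {
  stopifnot(inherits(map, "activation_map"))
  if (is.null(pixel_pitch) || is.na(pixel_pitch)) {
    stop("pixel_pitch is required to convert px to mm")
  }
  act <- which(!is.na(map), arr.ind = TRUE)
  if (nrow(act) < 10) stop("need at least 10 activated pixels")
  if (length(unique(act[, 1])) < 2 && length(unique(act[, 2])) < 2) {
    stop("activated pixels are collinear; plane fit is degenerate")
  }
  tt <- map[act]
  fit <- stats::lm.fit(cbind(1, act[, "col"], act[, "row"]), tt)
  g <- fit$coefficients[2:3]  # s/px along (col, row)
  gmag <- sqrt(sum(g^2))
  if (!is.finite(gmag) || gmag < min_gradient) {
    return(list(speed_mm_s = NA_real_, direction_deg = NA_real_,
                gradient = unname(g), n_pixels = nrow(act),
                quasi_simultaneous = TRUE))
  }
  speed_px_s <- 1 / gmag
  list(speed_mm_s = speed_px_s * pixel_pitch / 1000,
       direction_deg = as_degrees(atan2(g[2], g[1])) %% 360,
       gradient = unname(g), n_pixels = nrow(act),
       quasi_simultaneous = FALSE)
}

#' Whole-well activity metric for C. elegans thrashing
#'
#' Over consecutive frame pairs of a normalized (0-255) stack, counts
#' pixels whose absolute intensity change strictly exceeds `threshold`
#' (default 65 units, about 25 percent of the 8-bit range), then divides
#' the total count by the number of frame pairs. Reported both as a raw
#' mean count per analysed frame pair and as a fraction of the frame's
#' pixels.
#'
#' @param stack A [frame_stack()] with at least 2 frames, normalized to
#'   0-255 (see [normalize_stack()]).
#' @param threshold Intensity change threshold (strict), default 65.
#' @return A `well_activity` list: `sample_id`, `pixels_per_frame`,
#'   `fraction`, `threshold`, `n_frames`, `n_pairs`.
#' @export
worm_activity <- function(stack, threshold = 65) {
  stopifnot(inherits(stack, "frame_stack"), threshold >= 0)
  nt <- n_frames(stack)
  if (nt < 2) stop("need at least 2 frames to measure intensity change")
  d <- abs(stack$frames[, , -1, drop = FALSE] -
           stack$frames[, , -nt, drop = FALSE])
  n_pairs <- nt - 1
  total <- sum(d > threshold)
  npx <- prod(dim(stack$frames)[1:2])
  structure(list(sample_id = stack$sample_id,
                 pixels_per_frame = total / n_pairs,
                 fraction = total / n_pairs / npx,
                 threshold = threshold, n_frames = nt, n_pairs = n_pairs),
            class = "well_activity")
}

#' Compare activity metrics between two groups of wells
#'
#' Two-sample, two-tailed t-test on the per-well activity metric
#' (Welch's unequal-variance flavour by default). Degenerate input where
#' both groups are constant is handled by convention: p = 1 when the
#' groups are identical, p = 0 when they are constant but different.
#'
#' @param a,b Lists of `well_activity` objects or numeric vectors of
#'   per-well metrics (each of length >= 2).
#' @param metric Which field to compare when given `well_activity` lists:
#'   `"pixels_per_frame"` (default) or `"fraction"`.
#' @param var_equal Use the pooled-variance test instead of Welch's.
#' @return A list with `statistic`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
compare_groups <- function(a, b, metric = c("pixels_per_frame", "fraction"),
                           var_equal = FALSE) {
  metric <- match.arg(metric)
  xa <- activity_values(a, metric)
  xb <- activity_values(b, metric)
  stopifnot("each group needs at least 2 wells" =
              length(xa) >= 2 && length(xb) >= 2)
  method <- if (var_equal) "pooled two-sample t-test" else "Welch two-sample t-test"
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    same <- isTRUE(all.equal(mean(xa), mean(xb)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                mean_a = mean(xa), mean_b = mean(xb),
                method = paste(method, "(degenerate zero-variance input)")))
  }
  tt <- stats::t.test(xa, xb, var.equal = var_equal,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(xa), mean_b = mean(xb), method = method)
}

activity_values <- function(x, metric) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(x, function(w) {
    if (!inherits(w, "well_activity")) {
      stop("groups must be numeric vectors or lists of well_activity")
    }
    w[[metric]]
  }, numeric(1))
}
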