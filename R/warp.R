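#' Anisotropic scaling about the image centre (bilinear)
#'
#' Shared resampling core for [forward_project()] and [rectify()]: scales an
#' image by `sy` along rows (the axis parallel to the lateral displacement)
#' and `sx` along columns, about the geometric image centre, using inverse
#' mapping with bilinear interpolation. Samples falling outside the source
#' grid take `fill`. With `sy = sx = 1` the map is the exact identity.
#'
#' @param img Numeric matrix.
#' @param sy,sx Scale factors along rows / columns (> 0).
#' @param fill Fill value for out-of-field samples.
#' @return Matrix of the same dimensions.
#' @keywords internal
scale_about_centre <- function(img, sy, sx, fill = 0) {
  stopifnot(is.matrix(img), is.numeric(img), sy > 0, sx > 0)
  h <- nrow(img); w <- ncol(img)
  if (round(h * min(sy, 1)) < 2 || round(w * min(sx, 1)) < 2) {
    stop("requested scale would reduce the image below 2 px")
  }
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  src_r <- cy + (seq_len(h) - cy) / sy
  src_c <- cx + (seq_len(w) - cx) / sx
  r0 <- floor(src_r); fr <- src_r - r0
  c0 <- floor(src_c); fc <- src_c - c0
  # clamp lookup indices; validity tracked separately so edges stay exact
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  r0c <- pmin(pmax(r0, 1L), h); r1c <- pmin(r0c + 1L, h)
  c0c <- pmin(pmax(c0, 1L), w); c1c <- pmin(c0c + 1L, w)
  out <- outer((1 - fr), (1 - fc)) * img[r0c, c0c, drop = FALSE] +
         outer((1 - fr), fc)       * img[r0c, c1c, drop = FALSE] +
         outer(fr, (1 - fc))       * img[r1c, c0c, drop = FALSE] +
         outer(fr, fc)             * img[r1c, c1c, drop = FALSE]
  out[!ok_r, ] <- fill
  out[, !ok_c] <- fill
  out
}

# relative scale factors of the off-axis image w.r.t. the on-axis view:
# parallel axis gets the stretch S on top of the shared V/f_M magnification
warp_factors <- function(config, y) {
  stopifnot(inherits(config, "rap_config"))
  s <- stretch_factor(y, config$f_M)
  m_rel <- focus_distance(y, config$f_M) / config$f_M
  c(parallel = s * m_rel, orthogonal = m_rel)
}

#' Forward-project a frame through the RAP distortion
#'
#' Simulates what the camera records for a sample whose objective sits a
#' lateral distance `y` from the mirror axis: the image is stretched by the
#' factor `S = 1/cos(2 atan(y/2f_M))` along the displacement axis (rows) and
#' magnified isotropically by `V(y)/f_M` relative to the on-axis view, about
#' the image centre. `y = 0` is the identity.
#'
#' @param frame Numeric matrix or [frame_stack()] (applied frame-wise).
#' @param config A [rap_config()].
#' @param y Lateral displacement (mm).
#' @param fill Intensity for out-of-field samples (default 0).
#' @return Same kind as `frame`, with attributes `y` and `factors` (the
#'   applied parallel/orthogonal scale factors).
#' @export
forward_project <- function(frame, config, y, fill = 0) {
  f <- warp_factors(config, y)
  apply_warp(frame, f["parallel"], f["orthogonal"], fill, y, f)
}

#' Rectify a RAP frame (undo the geometric distortion)
#'
#' Exact inverse of [forward_project()]: compresses the image by the stretch
#' `S` along the displacement axis and removes the residual `V(y)/f_M`
#' magnification so frames from every displacement share a common scale.
#' Applied to a captured off-axis image this recovers the undistorted view
#' (a square grid target becomes square again).
#'
#' @inheritParams forward_project
#' @return Same kind as `frame`; attribute `factors` records the applied
#'   (inverse) scale factors.
#' @export
rectify <- function(frame, config, y, fill = 0) {
  f <- warp_factors(config, y)
  inv <- 1 / f
  apply_warp(frame, inv["parallel"], inv["orthogonal"], fill, y, inv)
}

apply_warp <- function(frame, sy, sx, fill, y, factors) {
  if (inherits(frame, "frame_stack")) {
    arr <- frame$frames
    for (k in seq_len(dim(arr)[3])) {
      arr[, , k] <- scale_about_centre(arr[, , k], sy, sx, fill)
    }
    out <- frame_stack(arr, fps = frame$fps, pixel_pitch = frame$pixel_pitch,
                       sample_id = frame$sample_id, times = frame$times)
  } else {
    out <- scale_about_centre(frame, sy, sx, fill)
  }
  attr(out, "y") <- unname(y)
  attr(out, "factors") <- unname(factors)
  out
}

#' Min-max rescale a stack to the 8-bit range
#'
#' One affine transform computed over the whole stack maps the global
#' minimum to 0 and the global maximum to 255. Per-stack (not per-frame)
#' scaling preserves the temporal intensity signals the activity analyses
#' depend on; the map is monotone and idempotent. A constant stack has no
#' contrast to rescale and is returned as all zeros with a warning.
#'
#' @param stack A [frame_stack()].
#' @return A [frame_stack()] with intensities in \[0, 255\].
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  if (hi == lo) {
    warning("degenerate contrast: stack is constant; returning all zeros")
    stack$frames[] <- 0
    return(stack)
  }
  stack$frames <- (stack$frames - lo) / (hi - lo) * 255
  stack
}

#' Centered crop of a frame or stack
#'
#' Crops to `width x height` pixels about the centre; when the total margin
#' is odd the extra discarded pixel goes to the high-index side (the
#' retained window starts at offset `floor(margin/2)`).
#'
#' @param x Numeric matrix or [frame_stack()].
#' @param width Target width (columns), px.
#' @param height Target height (rows), px.
#' @return Same kind as `x`, cropped.
#' @examples
#' dim(crop_center(matrix(0, 480, 640), 480, 480)) # 480 480
#' @export
crop_center <- function(x, width, height) {
  arr <- if (inherits(x, "frame_stack")) x$frames else x
  h <- dim(arr)[1]; w <- dim(arr)[2]
  if (height > h || width > w) {
    stop(sprintf("requested crop %d x %d exceeds frame size %d x %d",
                 width, height, w, h))
  }
  r0 <- (h - height) %/% 2  # odd margins: extra pixel dropped high side
  c0 <- (w - width) %/% 2
  rows <- (r0 + 1):(r0 + height)
  cols <- (c0 + 1):(c0 + width)
  if (inherits(x, "frame_stack")) {
    frame_stack(x$frames[rows, cols, , drop = FALSE], fps = x$fps,
                pixel_pitch = x$pixel_pitch, sample_id = x$sample_id,
                times = x$times)
  } else {
    arr[rows, cols, drop = FALSE]
  }
}
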