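#' Synthetic calibration-grid image
#'
#' Renders the validation target used to check the geometric model: a
#' square lattice of known pitch, either as soft-edged dark grid lines on
#' a bright field (`"lines"`, like the physical opaque grid) or as bright
#' Gaussian spots at the lattice points (`"dots"`, convenient for
#' sub-pixel corner localisation). Both are band-limited (edge softness /
#' spot width of order a pixel), so bilinear resampling round-trips with
#' small error.
#'
#' @param n_px Image side (square image, px).
#' @param pitch_um Lattice pitch at the sample plane (um); the default
#'   200 um matches the physical target.
#' @param pixel_pitch_um Sample-plane pixel pitch (um/px).
#' @param n_lines Number of lattice lines per axis (centred); the lattice
#'   must fit inside the frame with the margin needed for later warping.
#' @param line_width_um Opaque line width for `"lines"` (um).
#' @param sigma_px Edge softness / spot sigma (px).
#' @param kind `"lines"` or `"dots"`.
#' @return Numeric matrix in 0-255 with attributes `pitch_px` and
#'   `centers` (for `"dots"`, the true spot positions as (row, col)).
#' @export
synth_grid_image <- function(n_px = 480, pitch_um = 200,
                             pixel_pitch_um = 4.8, n_lines = 7,
                             line_width_um = 20, sigma_px = 1.2,
                             kind = c("dots", "lines")) {
  kind <- match.arg(kind)
  pitch_px <- pitch_um / pixel_pitch_um
  c0 <- (n_px + 1) / 2
  offsets <- (seq_len(n_lines) - (n_lines + 1) / 2) * pitch_px
  pos <- c0 + offsets
  if (min(pos) < 4 || max(pos) > n_px - 3) {
    stop("lattice does not fit in the frame; reduce n_lines")
  }
  ax <- seq_len(n_px)
  if (kind == "dots") {
    g <- vapply(pos, function(p) exp(-(ax - p)^2 / (2 * sigma_px^2)),
                numeric(n_px))           # n_px x n_lines
    prof <- rowSums(g)
    img <- 20 + 220 * outer(prof, prof)
    img <- pmin(img, 255)
    centers <- as.matrix(expand.grid(row = pos, col = pos))
  } else {
    hw <- line_width_um / pixel_pitch_um / 2
    dark <- vapply(pos, function(p) {
      # soft-edged opaque bar of half-width hw centred at p
      pmin(pmax((hw + 0.5 - abs(ax - p)) / max(sigma_px, 0.5), 0), 1)
    }, numeric(n_px))
    prof <- do.call(pmax, as.data.frame(dark))
    img <- 235 * outer(1 - prof, rep(1, n_px)) *
      outer(rep(1, n_px), 1 - prof)
    img <- img + 20
    centers <- as.matrix(expand.grid(row = pos, col = pos))
  }
  structure(img, pitch_px = pitch_px, centers = centers)
}

#' Sub-pixel spot localisation by intensity-weighted centroid
#'
#' Refines approximate spot positions to sub-pixel accuracy: in a window
#' of half-size `win` around each approximate centre, the local minimum
#' intensity is subtracted and the intensity-weighted centroid computed.
#' Used to measure where grid corners actually land after warping or
#' rectification.
#'
#' @param img Numeric matrix.
#' @param centers Matrix of approximate (row, col) positions.
#' @param win Window half-size (px), default 8.
#' @return Matrix of refined (row, col) positions, same rows as `centers`.
#' @export
locate_spots <- function(img, centers, win = 8) {
  stopifnot(is.matrix(img), is.matrix(centers), ncol(centers) == 2)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, nrow(centers), 2,
                dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(nrow(centers))) {
    r <- round(centers[i, 1]); c <- round(centers[i, 2])
    rows <- max(1, r - win):min(h, r + win)
    cols <- max(1, c - win):min(w, c + win)
    patch <- img[rows, cols] - min(img[rows, cols])
    s <- sum(patch)
    if (s <= 0) next
    out[i, 1] <- sum(rows * rowSums(patch)) / s
    out[i, 2] <- sum(cols * colSums(patch)) / s
  }
  out
}

#' Lattice spacings and aspect ratio from located spots
#'
#' Given spot positions on an `n x n` lattice (ordered as
#' `expand.grid(row_index, col_index)` like the output of
#' [synth_grid_image()]), estimates the mean spacing along rows and
#' columns by regressing position on lattice index, and returns their
#' ratio - the grid-cell aspect ratio (parallel/orthogonal), 1 for a
#' square grid.
#'
#' @param spots Matrix of (row, col) positions from [locate_spots()].
#' @param n_lines Lattice lines per axis.
#' @return List with `spacing_row`, `spacing_col` (px) and `aspect`
#'   (`spacing_row / spacing_col`).
#' @export
lattice_spacing <- function(spots, n_lines) {
  stopifnot(nrow(spots) == n_lines^2)
  idx <- expand.grid(i = seq_len(n_lines), j = seq_len(n_lines))
  ok <- stats::complete.cases(spots)
  fit_r <- stats::lm.fit(cbind(1, idx$i[ok]), spots[ok, 1])
  fit_c <- stats::lm.fit(cbind(1, idx$j[ok]), spots[ok, 2])
  sr <- unname(fit_r$coefficients[2])
  sc <- unname(fit_c$coefficients[2])
  list(spacing_row = sr, spacing_col = sc, aspect = sr / sc)
}
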