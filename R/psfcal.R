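#' Periodic grid (bar) target
#'
#' Describes the opaque calibration grid used to estimate lateral
#' resolution: opaque lines of width `line_width` repeating with period
#' `period` (a 20 um line on a 40 um period is 25 line pairs/mm). The
#' default 1-D profile models a cut across a gridline far from crossings;
#' the 2-D variant models the crossed grid, where the darkest point is a
#' line crossing.
#'
#' @param line_width Opaque line width (um).
#' @param period Line-pair period (um), `> line_width`.
#' @param dimensionality `"1d"` (profile across a line) or `"2d"`
#'   (crossed grid).
#' @return An object of class `grid_target`.
#' @export
grid_target <- function(line_width = 20, period = 40,
                        dimensionality = c("1d", "2d")) {
  dimensionality <- match.arg(dimensionality)
  stopifnot("need 0 < line_width < period" =
              line_width > 0 && line_width < period)
  structure(list(line_width = line_width, period = period,
                 dimensionality = dimensionality),
            class = "grid_target")
}

#' Forward contrast model: grid imaged with a finite-width PSF
#'
#' Renders the binary transmission profile of the grid (0 on lines, 1 in
#' gaps), convolves it with a normalized Gaussian point spread function of
#' the given full width at half maximum, and returns the intensity ratio
#' between a gap centre (brightest point) and a line centre (darkest
#' point). The convolution is computed numerically on a fine periodic
#' grid, so non-Gaussian PSF shapes can be substituted; contrast is
#' strictly decreasing in `fwhm`.
#'
#' In 2-D mode the transmission is the separable product of two such
#' profiles, and the contrast is measured between an open cell centre and
#' a line crossing (the square of the 1-D value).
#'
#' @param fwhm PSF full width at half maximum (um), positive.
#' @param grid A [grid_target()].
#' @param sampling Spatial sampling of the numeric convolution (um/point);
#'   must be at most `fwhm/10`. Default `fwhm/20`.
#' @return Contrast ratio (bright/dark, > 1 for any finite `fwhm`).
#' @examples
#' contrast_from_fwhm(15, grid_target()) # resolvable: contrast well above 1
#' @export
contrast_from_fwhm <- function(fwhm, grid = grid_target(),
                               sampling = fwhm / 20) {
  stopifnot(inherits(grid, "grid_target"),
            "fwhm must be positive" = is.numeric(fwhm) && fwhm > 0,
            "sampling must be at most fwhm/10" = sampling <= fwhm / 10)
  p <- grid$period
  # sampling aligned to the period so gap/line centres fall on grid points;
  # at least 200 points/period so edge placement does not bias the ratio
  n_per <- max(200L, 2L * ceiling(p / sampling / 2))
  step <- p / n_per
  n_periods <- max(20L, ceiling(12 * fwhm / p))  # kernel « domain
  n <- n_per * n_periods
  x <- (seq_len(n) - 1) * step
  # opaque lines centred at multiples of the period; cell edges area-weighted
  xm <- ((x + p / 2) %% p) - p / 2
  trans <- pmin(pmax((abs(xm) - grid$line_width / 2) / step + 0.5, 0), 1)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half_k <- min(ceiling(5 * sigma / step), n %/% 2 - 1)
  kern <- stats::dnorm((-half_k:half_k) * step, sd = sigma)
  kern <- kern / sum(kern)
  smoothed <- as.numeric(stats::filter(trans, kern, sides = 2,
                                       circular = TRUE))
  i_line <- smoothed[1]                    # line centre (x = 0)
  i_gap <- smoothed[1 + n_per / 2]         # gap centre (x = p/2)
  # below ~1e-6 relative modulation the numeric result is truncation
  # ripple, not optics; nothing measurable on 8-bit data lives there
  if (!is.finite(i_gap) || (i_gap - i_line) < 1e-6 * i_gap) {
    stop("contrast saturated: PSF much wider than the grid period")
  }
  contrast <- i_gap / i_line
  if (grid$dimensionality == "2d") contrast^2 else contrast
}

#' Estimate lateral PSF width from a measured grid contrast
#'
#' Inverts the monotone forward model [contrast_from_fwhm()] by bisection:
#' the PSF full width at half maximum that reproduces the measured
#' bright/dark intensity ratio on the given grid. Contrast is taken as
#' bright over dark, so it exceeds 1 for any finite PSF; values at or
#' below 1, or outside the range attainable within the search bounds, are
#' rejected with the attainable interval.
#'
#' @param contrast Measured intensity ratio (bright/dark), > 1.
#' @param grid A [grid_target()].
#' @param tol Bisection tolerance on the FWHM (um), default 0.05.
#' @param bounds Search interval for the FWHM (um), default
#'   `c(period/100, 3*period)`.
#' @return A `psf_estimate` list: `fwhm` (um), the input `contrast`, the
#'   `grid`, and the model settings used.
#' @examples
#' est <- fwhm_from_contrast(4.5, grid_target())
#' est$fwhm
#' @export
fwhm_from_contrast <- function(contrast, grid = grid_target(), tol = 0.05,
                               bounds = c(grid$period / 100, 3 * grid$period)) {
  stopifnot(inherits(grid, "grid_target"), tol > 0,
            length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  if (!is.numeric(contrast) || length(contrast) != 1 || contrast <= 1) {
    stop("contrast must be a single value > 1 (bright/dark ratio); ",
         "no finite PSF yields zero modulation on this grid")
  }
  c_hi <- tryCatch(contrast_from_fwhm(bounds[1], grid), error = function(e) Inf)
  c_lo <- tryCatch(contrast_from_fwhm(bounds[2], grid),
                   error = function(e) 1)
  if (contrast > c_hi || contrast < c_lo) {
    stop(sprintf(
      "contrast %.4g outside the attainable range [%.4g, %.4g] for fwhm in [%.3g, %.3g] um",
      contrast, c_lo, c_hi, bounds[2], bounds[1]))
  }
  lo <- bounds[1]; hi <- bounds[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    c_mid <- tryCatch(contrast_from_fwhm(mid, grid),
                      error = function(e) 1)  # saturated: modulation gone
    if (c_mid > contrast) lo <- mid else hi <- mid  # decreasing in fwhm
  }
  structure(list(fwhm = (lo + hi) / 2, contrast = contrast, grid = grid,
                 model = list(psf = "gaussian", tol = tol, bounds = bounds)),
            class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf(
    "PSF estimate: FWHM = %.2f um from contrast %.3g (%s grid, %g/%g um line/period)\n",
    x$fwhm, x$contrast, x$grid$dimensionality, x$grid$line_width,
    x$grid$period))
  invisible(x)
}
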