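#' Optical configuration of a RAP instrument
#'
#' Bundles the scalar optical parameters of one random-access parallel (RAP)
#' imaging system: the parabolic mirror, the single-element objective lenses,
#' the sensor geometry and the illumination wavelength. All lengths are
#' normalised at construction to a fixed unit per field (mm for focal lengths,
#' apertures and sensor width; um for pixel pitch and circle of confusion;
#' nm for wavelength) so downstream formulas never convert units.
#'
#' Two named presets reproduce the instrument builds:
#' \describe{
#'   \item{`"config1"`}{25 mm diameter, 100 mm focal length objectives on a
#'     640 x 480 sensor with 4.8 um pixels (four-dish system).}
#'   \item{`"config2"`}{6 mm diameter, 72 mm focal length objectives on a
#'     1280 x 1024 sensor with 4.8 um pixels (96-well plate system).}
#' }
#' Both share the 100 mm focal length parabolic mirror.
#'
#' @param preset Optional preset name, `"config1"` or `"config2"`. Explicit
#'   arguments override preset fields.
#' @param f_M Parabolic mirror focal length (mm).
#' @param f_L Objective focal length (mm).
#' @param lens_diameter Objective clear aperture (mm).
#' @param sensor_px Integer vector `c(width, height)` of sensor pixel counts.
#' @param pixel_pitch Sensor pixel size (um).
#' @param wavelength Illumination centre wavelength (nm), in \[350, 780\].
#' @param f_number Working f-number (dimensionless).
#' @param coc Circle of confusion (um) used in the depth-of-field
#'   approximation; defaults to twice the 18 um lateral resolution.
#' @return An object of class `rap_config`: a list with the validated fields
#'   plus derived `sensor_width_mm` and `na` (numerical aperture).
#' @examples
#' cfg <- rap_config("config1")
#' cfg$na            # 0.124
#' cfg$sensor_width_mm
#' @export
rap_config <- function(preset = NULL,
                       f_M = 100, f_L = 100, lens_diameter = 25,
                       sensor_px = c(640L, 480L), pixel_pitch = 4.8,
                       wavelength = 622.5, f_number = 12, coc = 36) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("config1", "config2"))
    defaults <- switch(preset,
      config1 = list(f_M = 100, f_L = 100, lens_diameter = 25,
                     sensor_px = c(640L, 480L), pixel_pitch = 4.8),
      config2 = list(f_M = 100, f_L = 72, lens_diameter = 6,
                     sensor_px = c(1280L, 1024L), pixel_pitch = 4.8)
    )
    call <- as.list(match.call())[-1]
    for (nm in names(defaults)) {
      if (!nm %in% names(call)) assign(nm, defaults[[nm]])
    }
  }
  stopifnot(
    "f_M must be a positive scalar" = is.numeric(f_M) && length(f_M) == 1 && f_M > 0,
    "f_L must be a positive scalar" = is.numeric(f_L) && length(f_L) == 1 && f_L > 0,
    "lens_diameter must be positive" = is.numeric(lens_diameter) && lens_diameter > 0,
    "sensor_px must be two positive counts" =
      length(sensor_px) == 2 && all(sensor_px >= 1),
    "pixel_pitch must be positive" = pixel_pitch > 0,
    "wavelength must lie in [350, 780] nm" =
      wavelength >= 350 && wavelength <= 780,
    "f_number must be positive" = f_number > 0,
    "coc must be positive" = coc > 0
  )
  if (lens_diameter >= 2 * f_L) {
    stop("lens_diameter must be smaller than twice the objective focal length")
  }
  out <- list(
    f_M = as.numeric(f_M), f_L = as.numeric(f_L),
    lens_diameter = as.numeric(lens_diameter),
    sensor_px = as.integer(sensor_px), pixel_pitch = as.numeric(pixel_pitch),
    wavelength = as.numeric(wavelength), f_number = as.numeric(f_number),
    coc = as.numeric(coc),
    preset = if (is.null(preset)) NA_character_ else preset
  )
  out$sensor_width_mm <- out$sensor_px[1] * out$pixel_pitch / 1000
  out$na <- numerical_aperture(out$lens_diameter, out$f_L)
  structure(out, class = "rap_config")
}

#' @export
print.rap_config <- function(x, ...) {
  cat("RAP optical configuration",
      if (!is.na(x$preset)) sprintf("(preset '%s')", x$preset), "\n")
  cat(sprintf("  mirror focal length  f_M = %g mm\n", x$f_M))
  cat(sprintf("  objective            f_L = %g mm, aperture %g mm (NA = %.3f)\n",
              x$f_L, x$lens_diameter, x$na))
  cat(sprintf("  sensor               %d x %d px @ %g um (width %g mm)\n",
              x$sensor_px[1], x$sensor_px[2], x$pixel_pitch, x$sensor_width_mm))
  cat(sprintf("  wavelength %g nm, f-number %g, circle of confusion %g um\n",
              x$wavelength, x$f_number, x$coc))
  invisible(x)
}

#' Chief-ray incidence angle at the detector
#'
#' Angle at which the central ray of the imaging bundle from an objective
#' displaced laterally by `y` from the mirror axis meets the detector plane:
#' `theta = 2 * atan(y / (2 * f_M))`, the reflection-doubled half-angle of the
#' parabola. On axis (`y = 0`) the angle is zero; it grows monotonically with
#' displacement and stays below 90 degrees for `y < 2 * f_M`.
#'
#' @param y Lateral displacement of the objective axis from the mirror axis
#'   (mm), non-negative.
#' @param f_M Mirror focal length (mm), positive.
#' @return Angle in radians. Use [as_degrees()] for presentation.
#' @examples
#' as_degrees(chief_ray_angle(70, 100)) # about 38.6 degrees
#' @export
chief_ray_angle <- function(y, f_M) {
  check_displacement(y, f_M)
  2 * atan(y / (2 * f_M))
}

#' Convert radians to degrees
#' @param x Angle(s) in radians.
#' @return Angle(s) in degrees.
#' @export
as_degrees <- function(x) x * 180 / pi

#' Anisotropic stretch of the off-axis image
#'
#' The image forms normal to the chief ray, so the detector records a
#' projection stretched along the displacement direction by
#' `S = 1 / cos(2 * atan(y / (2 * f_M)))`. `S >= 1`, with equality only
#' on axis.
#'
#' @inheritParams chief_ray_angle
#' @return Stretch factor `S` (dimensionless).
#' @examples
#' stretch_factor(70, 100) # about 1.281
#' @export
stretch_factor <- function(y, f_M) {
  theta <- chief_ray_angle(y, f_M)
  if (any(theta >= pi / 2)) {
    stop("chief-ray angle reaches 90 degrees (y >= 2*f_M): image plane ",
         "parallel to the chief ray, stretch undefined")
  }
  1 / cos(theta)
}

#' Mirror-to-image focus distance
#'
#' Distance from the reflection point on the parabola at height `y` to the
#' focal point: `V = sqrt(y^2 + (f_M - y^2 / (4 f_M))^2)`. Equals `f_M` on
#' axis and grows with displacement; it sets the isotropic magnification.
#'
#' @inheritParams chief_ray_angle
#' @return Focus distance `V` (mm).
#' @export
focus_distance <- function(y, f_M) {
  check_displacement(y, f_M)
  sqrt(y^2 + (f_M - y^2 / (4 * f_M))^2)
}

#' Isotropic magnification of an off-axis sample
#'
#' `M = V(y) / f_L`: the ratio of the mirror-to-image distance to the
#' objective focal length, identical in both image dimensions.
#'
#' @inheritParams chief_ray_angle
#' @param f_L Objective focal length (mm), positive.
#' @return Magnification `M` (dimensionless).
#' @examples
#' magnification(0, f_L = 72, f_M = 100) # 100/72, the "1.4x" system
#' @export
magnification <- function(y, f_L, f_M) {
  if (!is.numeric(f_L) || any(f_L <= 0)) stop("f_L must be positive")
  focus_distance(y, f_M) / f_L
}

#' Combined magnification along and across the displacement axis
#'
#' The stretch acts only along the displacement direction, so the image
#' magnification is `M * S` along the axis parallel to `y` and `M`
#' orthogonal to it.
#'
#' @inheritParams magnification
#' @return Named numeric vector `c(parallel = M*S, orthogonal = M)`.
#' @export
combined_magnification <- function(y, f_L, f_M) {
  m <- magnification(y, f_L, f_M)
  s <- stretch_factor(y, f_M)
  c(parallel = m * s, orthogonal = m)
}

#' Defocus span across the sensor
#'
#' Because the image plane is tilted by the chief-ray angle, focus sweeps
#' through the sensor; the distance along the chief ray between the image at
#' either sensor edge is `Df = Ds * sin(theta)`.
#'
#' @param Ds Sensor width (mm).
#' @param theta Chief-ray angle (radians) in \[0, pi/2).
#' @return Defocus span `Df` (mm).
#' @export
defocus_span <- function(Ds, theta) {
  stopifnot("Ds must be positive" = Ds > 0,
            "theta must lie in [0, pi/2)" = theta >= 0 && theta < pi / 2)
  Ds * sin(theta)
}

#' Depth of field of a single-element objective
#'
#' Thin-lens approximation `DOF = 2 u^2 N c / f^2`. With the subject at the
#' focal plane (`u = f`, the RAP working condition) this reduces to
#' `2 N c`, independent of focal length.
#'
#' @param f Objective focal length (mm).
#' @param n Working f-number (dimensionless).
#' @param coc Circle of confusion (um).
#' @param u Subject distance (mm); defaults to `f`.
#' @return Depth of field (mm).
#' @examples
#' depth_of_field(72, 12, 36) # 0.864 mm, i.e. 0.9 mm to one decimal
#' @export
depth_of_field <- function(f, n, coc, u = f) {
  stopifnot(f > 0, n > 0, coc > 0, u > 0)
  2 * u^2 * n * (coc / 1000) / f^2
}

#' Numerical aperture from clear aperture and focal length
#'
#' Marginal-ray half-angle of a lens of diameter `d` focused at `f`:
#' `NA = sin(atan(d / (2 f)))`.
#'
#' @param diameter Clear aperture (mm), must be `< 2 * f_L`.
#' @param f_L Focal length (mm).
#' @return Numerical aperture in (0, 1).
#' @examples
#' numerical_aperture(25, 100) # 0.124
#' numerical_aperture(6, 72)   # prints as 0.04
#' @export
numerical_aperture <- function(diameter, f_L) {
  stopifnot("diameter must be positive" = diameter > 0,
            "f_L must be positive" = f_L > 0)
  if (diameter >= 2 * f_L) {
    stop("diameter must be smaller than 2*f_L for a real marginal ray")
  }
  sin(atan(diameter / (2 * f_L)))
}

#' Diffraction-limited lateral PSF width
#'
#' `PSF_XY = prefactor * lambda / NA`, returned in micrometres. The 0.6
#' prefactor is the instrument's quoted convention for the lateral
#' resolution scale (the classical Rayleigh coefficient is 0.61; the two
#' differ by about 2 percent).
#'
#' @param wavelength Wavelength (nm).
#' @param na Numerical aperture in (0, 1).
#' @param prefactor Resolution prefactor, default 0.6.
#' @return Lateral PSF width (um).
#' @examples
#' diffraction_psf_width(622.5, numerical_aperture(6, 72)) # about 9 um
#' @export
diffraction_psf_width <- function(wavelength, na, prefactor = 0.6) {
  stopifnot(wavelength > 0, na > 0, na < 1, prefactor > 0)
  prefactor * wavelength / na / 1000
}

#' All derived optical quantities for one configuration
#'
#' Evaluates every closed-form quantity of the system at a given lateral
#' displacement: chief-ray angle, stretch, focus distance, magnifications,
#' defocus span, depth of field, numerical aperture and diffraction-limited
#' PSF width.
#'
#' @param config A [rap_config()].
#' @param y Lateral displacement (mm), default 0 (on axis).
#' @return A one-row `data.frame` of named quantities with units in the
#'   column names.
#' @export
optics_summary <- function(config, y = 0) {
  stopifnot(inherits(config, "rap_config"))
  theta <- chief_ray_angle(y, config$f_M)
  mc <- combined_magnification(y, config$f_L, config$f_M)
  data.frame(
    y_mm = y,
    theta_deg = as_degrees(theta),
    stretch = stretch_factor(y, config$f_M),
    focus_distance_mm = focus_distance(y, config$f_M),
    magnification = unname(mc["orthogonal"]),
    magnification_parallel = unname(mc["parallel"]),
    defocus_span_mm = defocus_span(config$sensor_width_mm, theta),
    depth_of_field_mm = depth_of_field(config$f_L, config$f_number, config$coc),
    numerical_aperture = config$na,
    psf_xy_um = diffraction_psf_width(config$wavelength, config$na)
  )
}

# shared domain checks for the closed-form geometry
check_displacement <- function(y, f_M) {
  if (!is.numeric(f_M) || any(f_M <= 0)) stop("f_M must be positive")
  if (!is.numeric(y) || any(y < 0)) stop("y must be non-negative")
  invisible(TRUE)
}
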