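test_that("chief-ray angle follows the parabola's reflection geometry", {
  expect_identical(chief_ray_angle(0, 100), 0)
  # independent evaluation of the doubled half-angle
  expect_equal(chief_ray_angle(70, 100), 2 * atan(0.35), tolerance = 1e-12)
  expect_equal(as_degrees(chief_ray_angle(70, 100)), 38.58009,
               tolerance = 1e-6)
  # the widest objective position of a 220 mm mirror stays under 60 degrees
  expect_lt(as_degrees(chief_ray_angle(110, 100)), 60)
  expect_equal(as_degrees(chief_ray_angle(110, 100)), 57.62209,
               tolerance = 1e-5)
  # monotone in y
  y <- seq(0, 100, by = 5)
  expect_true(all(diff(chief_ray_angle(y, 100)) > 0))
  expect_error(chief_ray_angle(-1, 100), "non-negative")
  expect_error(chief_ray_angle(10, 0), "positive")
})

test_that("stretch factor is 1/cos(theta), >= 1, and fails past 90 degrees", {
  expect_identical(stretch_factor(0, 100), 1)
  expect_identical(stretch_factor(0, 55), 1)
  expect_equal(stretch_factor(70, 100), 1 / cos(2 * atan(0.35)),
               tolerance = 1e-12)
  expect_equal(stretch_factor(70, 100), 1.2792, tolerance = 1e-4)
  set.seed(42)
  y <- stats::runif(100, 0, 150)
  expect_equal(stretch_factor(y, 100),
               1 / cos(chief_ray_angle(y, 100)), tolerance = 1e-12)
  expect_true(all(stretch_factor(y, 100) >= 1))
  expect_true(all(stretch_factor(y, 100) * cos(chief_ray_angle(y, 100)) - 1
                  < 1e-12))
  expect_error(stretch_factor(200, 100), "90 degrees")
})

test_that("focus distance has the parabola's closed form", {
  expect_identical(focus_distance(0, 100), 100)
  expect_equal(focus_distance(70, 100), sqrt(4900 + 87.75^2),
               tolerance = 1e-12)
  expect_equal(focus_distance(70, 100), 112.25, tolerance = 1e-4)
  # at y = 2 f_M the sag equals f_M and the focus is 2 f_M away
  expect_equal(focus_distance(200, 100), 200, tolerance = 1e-12)
  y <- seq(0, 200, by = 10)
  expect_true(all(diff(focus_distance(y, 100)) > 0))
})

test_that("magnification is V/f_L with the combined stretch on one axis", {
  expect_identical(magnification(0, 100, 100), 1)
  expect_equal(magnification(0, 72, 100), 100 / 72, tolerance = 1e-12)
  expect_equal(magnification(0, 72, 100), 1.39, tolerance = 1e-2)
  expect_equal(magnification(70, 100, 100), 1.1225, tolerance = 1e-4)
  expect_error(magnification(10, -5, 100), "positive")

  expect_equal(combined_magnification(0, 100, 100),
               c(parallel = 1, orthogonal = 1))
  mc <- combined_magnification(70, 100, 100)
  expect_equal(unname(mc["parallel"]), 1.2792 * 1.1225, tolerance = 1e-3)
  expect_equal(unname(mc["orthogonal"]), 1.1225, tolerance = 1e-4)
  set.seed(7)
  for (y in stats::runif(20, 0, 120)) {
    mc <- combined_magnification(y, 80, 100)
    expect_equal(unname(mc["parallel"] / mc["orthogonal"]),
                 stretch_factor(y, 100), tolerance = 1e-12)
    expect_gte(mc[["parallel"]], mc[["orthogonal"]])
  }
})

test_that("defocus span is Ds sin(theta)", {
  expect_identical(defocus_span(2.4, 0), 0)
  expect_equal(defocus_span(2.4, chief_ray_angle(70, 100)), 1.4967,
               tolerance = 1e-4)
  # the exact value slightly exceeds 2 mm at the mirror edge; reported as-is
  expect_equal(defocus_span(2.4, chief_ray_angle(110, 100)), 2.0269,
               tolerance = 1e-4)
})

test_that("depth of field reduces to 2Nc at the focal plane", {
  expect_equal(depth_of_field(72, 12, 36), 0.864, tolerance = 1e-12)
  expect_equal(round(depth_of_field(72, 12, 36), 1), 0.9)
  # independent of f when u = f
  expect_equal(depth_of_field(123.4, 12, 18), 2 * 12 * 0.018,
               tolerance = 1e-12)
  expect_equal(depth_of_field(50, 12, 36), 2 * depth_of_field(50, 12, 18),
               tolerance = 1e-12)
})

test_that("numerical aperture matches the marginal-ray half-angle", {
  expect_equal(round(numerical_aperture(25, 100), 3), 0.124)
  expect_equal(numerical_aperture(6, 72), 0.0416, tolerance = 1e-3)
  expect_equal(round(numerical_aperture(6, 72), 2), 0.04)
  # small-aperture limit: NA -> d/(2f) within 0.1%
  expect_equal(numerical_aperture(5, 60), 5 / 120, tolerance = 1e-3)
  expect_error(numerical_aperture(200, 100), "smaller than 2")
})

test_that("diffraction-limited PSF width is prefactor*lambda/NA in um", {
  na2 <- numerical_aperture(6, 72)
  psf <- diffraction_psf_width(622.5, na2)
  expect_equal(psf, 0.6 * 622.5 / na2 / 1000, tolerance = 1e-12)
  # agrees with the quoted 9.1 um within the prefactor/rounding ambiguity
  expect_lt(abs(psf - 9.1) / 9.1, 0.02)
  expect_equal(diffraction_psf_width(500, 0.2),
               diffraction_psf_width(500, 0.1) / 2, tolerance = 1e-12)
  expect_equal(diffraction_psf_width(469, 0.0416), 6.765, tolerance = 1e-3)
})

test_that("configurations validate and derive sensor width and NA", {
  c1 <- rap_config("config1")
  expect_equal(c1$sensor_width_mm, 640 * 4.8 / 1000)
  expect_equal(round(c1$na, 3), 0.124)
  c2 <- rap_config("config2")
  expect_equal(c2$f_L, 72)
  expect_equal(c2$sensor_px, c(1280L, 1024L))
  # preset fields can be overridden
  c2b <- rap_config("config2", wavelength = 469)
  expect_equal(c2b$wavelength, 469)
  expect_equal(c2b$f_L, 72)
  expect_error(rap_config(wavelength = 1000), "wavelength")
  expect_error(rap_config(f_M = -1), "f_M")
  expect_error(rap_config(lens_diameter = 300, f_L = 100), "smaller")
  smry <- optics_summary(c1, y = 70)
  expect_equal(smry$stretch, stretch_factor(70, 100))
  expect_equal(smry$psf_xy_um, diffraction_psf_width(622.5, c1$na))
})

test_that("optics operations are pure (bit-identical reruns)", {
  a <- c(chief_ray_angle(63.7, 100), stretch_factor(63.7, 100),
         focus_distance(63.7, 100), magnification(63.7, 72, 100))
  b <- c(chief_ray_angle(63.7, 100), stretch_factor(63.7, 100),
         focus_distance(63.7, 100), magnification(63.7, 72, 100))
  expect_identical(a, b)
})
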