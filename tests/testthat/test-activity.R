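test_that("motion signal is the lagged absolute difference", {
  cst <- frame_stack(array(42, c(5, 5, 10)), fps = 10)
  m <- motion_signal(cst, 6)
  expect_equal(n_frames(m), 4)
  expect_true(all(m$frames == 0))

  # a +10 step in one pixel registers for exactly `lag` output frames
  arr <- array(100, c(4, 4, 20))
  arr[2, 3, 8:20] <- 110
  m <- motion_signal(frame_stack(arr, fps = 10), lag = 6)
  trace <- m$frames[2, 3, ]
  expect_equal(which(trace == 10), 2:7)  # frames 8..13 of the input
  expect_true(all(m$frames >= 0))
  expect_true(all(m$frames[setdiff(1:4, 2), , ] == 0))

  expect_error(motion_signal(cst, 10), ">= stack length")
  expect_error(motion_signal(cst, 0), "positive")
})

test_that("motion of a sinusoidal pixel peaks at 2a|sin(pi f n / fps)|", {
  fps <- 40; f <- 1.3; a <- 30; lag <- 6
  t <- (0:199) / fps
  s <- 100 + a * sin(2 * pi * f * t)
  arr <- array(rep(s, each = 4), c(2, 2, 200))
  m <- motion_signal(frame_stack(arr, fps = fps), lag)
  # brute-force oracle: the lagged difference of the sampled sine itself
  oracle <- max(abs(s[(lag + 1):200] - s[1:(200 - lag)]))
  expect_equal(max(m$frames), oracle, tolerance = 1e-12)
  expect_equal(max(m$frames), 2 * a * abs(sin(pi * f * lag / fps)),
               tolerance = 0.02)
})

test_that("ROI traces average the motion signal over the window", {
  zero <- frame_stack(array(0, c(40, 40, 5)), fps = 10)
  tr <- roi_trace(zero, centre = c(20, 20))
  expect_equal(tr$value, rep(0, 5))
  expect_equal(tr$time, zero$times)

  arr <- array(0, c(40, 40, 3))
  arr[15, 25, 2] <- 400
  tr <- roi_trace(frame_stack(arr, fps = 10), centre = c(15, 25))
  expect_equal(tr$value, c(0, 1, 0))  # 400 / (20*20)
  expect_error(roi_trace(frame_stack(arr, fps = 10), centre = c(5, 5)),
               "outside")
})

test_that("activation times interpolate the level crossing per pixel", {
  # two pixels with linear upstrokes crossing half-max at known frames
  arr <- array(0, c(1, 2, 10))
  arr[1, 1, ] <- c(0, 0, 0, 10, 20, 20, 20, 20, 20, 20)  # cross 10 at frame 4
  arr[1, 2, ] <- c(0, 0, 0, 0, 0, 0, 0, 10, 20, 20)      # cross 10 at frame 8
  fps <- 5
  m <- frame_stack(arr, fps = fps)
  am <- activation_map(m, smooth_px = 1, smooth_frames = 1, level = 0.5)
  expect_equal(am[1, 1], 3 / fps)  # 0-based frame index 3
  expect_equal(am[1, 2], 7 / fps)

  # a spatially uniform flash activates everywhere within one frame
  fl <- array(0, c(6, 6, 8)); fl[, , 5:8] <- 50
  amf <- activation_map(frame_stack(fl, fps = 10))
  expect_lt(diff(range(amf)), 1 / 10)

  # padding with quiet frames shifts all activation times by the pad
  pad <- array(0, c(1, 2, 4))
  arr2 <- array(c(pad, arr), c(1, 2, 14))
  am2 <- activation_map(frame_stack(arr2, fps = fps), smooth_px = 1,
                        smooth_frames = 1, level = 0.5)
  expect_equal(as.numeric(am2), as.numeric(am) + 4 / fps, tolerance = 1e-9)

  expect_warning(qam <- activation_map(frame_stack(array(0, c(3, 3, 5)),
                                                   fps = 10)), "all-quiet")
  expect_true(all(is.na(qam)))
})

test_that("conduction velocity recovers a planar gradient exactly", {
  # noiseless synthetic map: t = 0.1 + gx*col + gy*row (s), 20 um pixels
  g <- c(gx = 0.002, gy = 0.001)
  rc <- expand.grid(row = 1:30, col = 1:30)
  tmap <- matrix(0.1 + g["gx"] * rc$col + g["gy"] * rc$row, 30, 30)
  am <- structure(tmap, class = c("activation_map", "matrix"),
                  fps = 40, pixel_pitch = 20)
  cv <- conduction_velocity(am)
  expect_false(cv$quasi_simultaneous)
  expect_equal(cv$speed_mm_s, 1 / sqrt(sum(g^2)) * 20 / 1000,
               tolerance = 1e-9)
  expect_equal(cv$direction_deg, as_degrees(atan2(g["gy"], g["gx"])),
               tolerance = 1e-6, ignore_attr = TRUE)

  # rotating the map 90 degrees rotates direction, speed unchanged
  rot <- t(tmap)[, rev(seq_len(30))]  # counter-clockwise quarter turn
  amr <- structure(rot, class = c("activation_map", "matrix"),
                   fps = 40, pixel_pitch = 20)
  cvr <- conduction_velocity(amr)
  expect_equal(cvr$speed_mm_s, cv$speed_mm_s, tolerance = 1e-6)
  expect_equal(unname((cvr$direction_deg - cv$direction_deg) %% 360), 90,
               tolerance = 1e-4)

  # uniform activation is quasi-simultaneous
  amu <- structure(matrix(0.5, 20, 20),
                   class = c("activation_map", "matrix"),
                   fps = 40, pixel_pitch = 20)
  expect_true(conduction_velocity(amu)$quasi_simultaneous)

  few <- structure(matrix(c(1:5, rep(NA, 20)), 5, 5),
                   class = c("activation_map", "matrix"),
                   fps = 40, pixel_pitch = 20)
  expect_error(conduction_velocity(few), "at least 10")
})

test_that("worm activity counts supra-threshold pixel changes per pair", {
  static <- frame_stack(array(128, c(10, 10, 5)), fps = 15)
  expect_equal(worm_activity(static)$pixels_per_frame, 0)

  arr <- array(100, c(100, 100, 2))
  arr[1:5, 1:100, 2] <- 200  # exactly 500 pixels change by 100
  wa <- worm_activity(frame_stack(arr, fps = 15))
  expect_equal(wa$pixels_per_frame, 500)
  expect_equal(wa$fraction, 0.05)
  expect_equal(wa$n_pairs, 1)

  # the comparison is strict: a change of exactly 65 does not count
  arr65 <- array(0, c(4, 4, 2)); arr65[, , 2] <- 65
  expect_equal(worm_activity(frame_stack(arr65, fps = 15))$pixels_per_frame, 0)
  arr66 <- array(0, c(4, 4, 2)); arr66[, , 2] <- 66
  expect_equal(worm_activity(frame_stack(arr66, fps = 15))$pixels_per_frame, 16)

  expect_error(worm_activity(frame_stack(array(1, c(3, 3, 1)), fps = 15)),
               "at least 2")
})

test_that("worm activity is shift-invariant and reversal-equivariant", {
  sim <- simulate_worms(n_frames = 20, seed = 11)$stack
  base <- worm_activity(sim)$pixels_per_frame
  shifted <- frame_stack(pmin(sim$frames + 0, 255) - 30 + 30, fps = sim$fps)
  expect_equal(worm_activity(shifted)$pixels_per_frame, base)
  plus <- frame_stack(sim$frames - 20, fps = sim$fps)  # constant offset
  expect_equal(worm_activity(plus)$pixels_per_frame, base)
  rev_stack <- frame_stack(sim$frames[, , 20:1], fps = sim$fps)
  expect_equal(worm_activity(rev_stack)$pixels_per_frame, base)
})

test_that("group comparison is a symmetric two-tailed t-test", {
  a <- c(10, 12, 11, 13); b <- c(6, 7, 8, 6.5)
  res <- compare_groups(a, b)
  oracle <- stats::t.test(a, b)
  expect_equal(res$p_value, oracle$p.value)
  expect_equal(res$statistic, unname(oracle$statistic))
  res_swap <- compare_groups(b, a)
  expect_equal(res_swap$p_value, res$p_value)
  expect_equal(res_swap$statistic, -res$statistic)

  # identical degenerate groups: p = 1 by convention
  same <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)

  pooled <- compare_groups(a, b, var_equal = TRUE)
  expect_equal(pooled$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value)

  # well_activity lists are unwrapped by metric
  arr <- array(100, c(10, 10, 2)); arr[1, 1, 2] <- 255
  w <- worm_activity(frame_stack(arr, fps = 15))
  expect_equal(compare_groups(list(w, w), list(w, w))$p_value, 1)
})
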