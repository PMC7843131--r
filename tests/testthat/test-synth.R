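test_that("monolayer simulation is deterministic with sensible degeneracies", {
  a <- simulate_monolayer(width = 30, height = 30, duration = 1.5, seed = 5)
  b <- simulate_monolayer(width = 30, height = 30, duration = 1.5, seed = 5)
  expect_identical(a$stack$frames, b$stack$frames)

  flat <- simulate_monolayer(width = 20, height = 20, duration = 1.2,
                             amplitude = 0, noise_sd = 0)
  expect_equal(diff(range(flat$stack$frames)), 0)

  expect_error(simulate_monolayer(period = 0.3, rise_time = 0.1,
                                  plateau = 0.2, fall_time = 0.1),
               "shorter than the pulse")
})

test_that("the cardiac pipeline recovers the simulated wave", {
  sim <- simulate_monolayer(seed = 21)
  m <- motion_signal(sim$stack, 6)
  am <- activation_map(m)
  # measured activation gradient equals the ground-truth slowness 1/v
  cv <- conduction_velocity(am)
  expect_lt(abs(cv$speed_mm_s - sim$truth$speed) / sim$truth$speed, 0.05)
  gradient_mag_px <- sqrt(sum(cv$gradient^2))
  truth_slowness <- 1 / (sim$truth$speed / (sim$stack$pixel_pitch / 1000))
  expect_lt(abs(gradient_mag_px - truth_slowness) / truth_slowness, 0.05)
})

test_that("ROI traces show two motion peaks per contraction cycle", {
  sim <- simulate_monolayer(duration = 2.2, seed = 9)
  m <- motion_signal(sim$stack, 6)
  tr <- roi_trace(m, centre = c(50, 50))
  # two full cycles in the window: contraction + relaxation each
  expect_equal(count_peaks(tr$value), 4L)
})

test_that("worm simulation is deterministic and static when frozen", {
  a <- simulate_worms(n_frames = 10, seed = 3)
  b <- simulate_worms(n_frames = 10, seed = 3)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_length(a$truth$centrelines, 10)

  frozen <- simulate_worms(n_frames = 10, frequency = 0, drift = 0,
                           noise_sd = 0, seed = 4)
  expect_equal(worm_activity(frozen$stack)$pixels_per_frame, 0)
  expect_equal(frozen$stack$frames[, , 1], frozen$stack$frames[, , 10])

  expect_error(simulate_worms(width = 20, height = 20, body_length = 30),
               "do not fit")
})

test_that("the activity metric increases with thrash frequency", {
  # sampled fast enough that the phase step is below aliasing for 10 Hz
  metric <- vapply(c(2, 5, 10), function(f) {
    mean(vapply(1:3, function(i) {
      s <- simulate_worms(frequency = f, fps = 30, seed = i)$stack
      worm_activity(normalize_stack(s))$pixels_per_frame
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(metric) > 0))
})

test_that("an identity plate renders and demultiplexes to the exact scenes", {
  ids <- paste0("d", 1:3)
  sched <- make_schedule(ids, 60)
  scenes <- lapply(1:3, function(i) {
    simulate_worms(n_frames = 6, fps = 20, seed = i)$stack
  })
  names(scenes) <- ids
  cfg <- rap_config("config1")
  plate <- plate_params(stats::setNames(rep(0, 3), ids), sched, cfg,
                        falloff = 0, noise_sd = 0)
  r <- render_plate(scenes, plate)
  expect_equal(dim(r$stream$frames)[3], 18)
  dm <- demultiplex(r$stream)
  for (id in ids) expect_equal(dm[[id]]$frames, scenes[[id]]$frames)
  # determinism of the full render
  r2 <- render_plate(scenes, plate)
  expect_identical(r$stream$frames, r2$stream$frames)
})

test_that("rendered brightness decreases with lateral displacement", {
  scene <- simulate_worms(n_frames = 2, seed = 6)$stack
  cfg <- rap_config("config1")
  means <- vapply(c(0, 30, 60, 90), function(y) {
    sched <- make_schedule("w", 30)
    plate <- plate_params(c(w = y), sched, cfg, noise_sd = 0,
                          fill = 0)
    r <- render_plate(list(w = scene), plate)
    mean(r$stream$frames)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("off-axis rendering is undone by rectification, end to end", {
  g <- synth_grid_image(n_px = 240, n_lines = 5, pixel_pitch_um = 9.6)
  gs <- frame_stack(array(rep(g, 2), c(240, 240, 2)), fps = 20)
  cfg <- rap_config("config1")
  sched <- make_schedule("g1", 20)
  plate <- plate_params(c(g1 = 70), sched, cfg, falloff = 0.004,
                        noise_sd = 1)
  r <- render_plate(list(g1 = gs), plate, seed = 2)
  rec <- rectify(demultiplex(r$stream)$g1$frames[, , 1], cfg, 70)
  sp <- locate_spots(rec, attr(g, "centers"))
  expect_equal(lattice_spacing(sp, 5)$aspect, 1, tolerance = 0.02)
})

test_that("chromatic focal offset blurs the rendered image", {
  g <- synth_grid_image(n_px = 120, n_lines = 3, pixel_pitch_um = 9.6)
  gs <- frame_stack(array(g, c(120, 120, 1)), fps = 10)
  cfg <- rap_config("config2")
  sched <- make_schedule("w", 10)
  sharp <- render_plate(list(w = gs),
                        plate_params(c(w = 0), sched, cfg, falloff = 0,
                                     noise_sd = 0))
  # the red-to-blue focal shift of the singlet objectives, as extra defocus
  blurred <- render_plate(list(w = gs),
                          plate_params(c(w = 0), sched, cfg, falloff = 0,
                                       noise_sd = 0,
                                       chromatic_offset_um = 981))
  expect_lt(stats::sd(blurred$stream$frames), stats::sd(sharp$stream$frames))
})

test_that("scenarios bundle schedule, optics and displacements", {
  sc <- rap_scenario("worm-plate")
  expect_equal(sc$schedule$n_samples, 80)
  expect_equal(length(schedule_assignment(sc$schedule)), 8000)
  expect_equal(sc$config$f_L, 72)
  expect_true(all(sc$y >= 0 & sc$y < 2 * sc$config$f_M))
  sc2 <- rap_scenario("cardiac-dishes")
  expect_equal(per_sample_fps(sc2$schedule$base_fps,
                              sc2$schedule$n_samples), 40)
  expect_error(render_plate(list(bogus = NULL),
                            plate_params(c(w = 0), make_schedule("w", 10),
                                         rap_config("config1"))),
               "no scene")
})
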