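test_that("a delta decay maps to (1, 0) up to the half-channel phase", {
  decay <- c(1000, rep(0, 63))
  p <- pixel_phasor(decay, st64, ps_full)
  # all photons at the first channel centre: exact phase omega * dt/2
  phase <- omega1 * st64$channel_width / 2
  expect_equal(unname(p), c(cos(phase), sin(phase)), tolerance = 1e-12)
  expect_equal(unname(p), c(1, 0), tolerance = 0.1)
})

test_that("uniform counts over one full harmonic cycle give (0, 0)", {
  for (k in c(1L, 2L, 4L)) {
    ps <- phasor_settings(harmonic = k, window_fraction = 1 / k,
                          window_start = 1, threshold_fraction = 0)
    p <- pixel_phasor(rep(7, 64), st64, ps)
    expect_equal(unname(p), c(0, 0), tolerance = 1e-12)
  }
})

test_that("a densely sampled exponential matches the closed-form phasor", {
  # tau = 2500 ps, T = 12500 ps, k = 1: omega*tau = 2*pi/5
  decay <- noiseless_decay(2500, st_dense)
  ps <- phasor_settings(harmonic = 1, window_fraction = 1, window_start = 1,
                        threshold_fraction = 0)
  p <- pixel_phasor(decay, st_dense, ps)
  expect_equal(unname(p), c(0.38773, 0.48720), tolerance = 1e-3)
})

test_that("pixel_phasor agrees with the brute-force Fourier sum", {
  set.seed(101)
  for (rep in 1:10) {
    decay <- rpois(64, runif(64, 0, 50))
    k <- sample(1:4, 1)
    ps <- phasor_settings(harmonic = k, window_fraction = runif(1, 0.25, 1),
                          window_start = sample(1:10, 1),
                          threshold_fraction = 0)
    if (sum(decay) == 0) next
    expect_equal(pixel_phasor(decay, st64, ps),
                 brute_phasor(decay, st64, ps), tolerance = 1e-13)
  }
})

test_that("empty and invalid pixels are handled as specified", {
  p <- pixel_phasor(rep(0, 64), st64, ps_full)
  expect_true(all(is.na(p)))                     # empty-pixel condition
  expect_error(pixel_phasor(c(-1, rep(1, 63)), st64, ps_full), "non-negative")
  expect_error(pixel_phasor(rep(1, 10), st64, ps_full), "channels")
})

test_that("the intensity threshold excludes pixels below 30% of the brightest", {
  # three pixels: 1000, 400 and 200 total photons
  counts <- array(0, dim = c(1, 3, 64))
  counts[1, 1, ] <- rep(c(250, 0), c(4, 60))
  counts[1, 2, ] <- rep(c(100, 0), c(4, 60))
  counts[1, 3, ] <- rep(c(50, 0), c(4, 60))
  cube <- decay_cube(counts, st64)

  cloud <- transform_cube(cube, phasor_settings(threshold_fraction = 0.30,
                                                window_start = 1))
  expect_equal(nrow(cloud), 2L)                  # 200 < 300 excluded
  expect_setequal(cloud$intensity, c(1000, 400))

  cloud0 <- transform_cube(cube, phasor_settings(threshold_fraction = 0,
                                                 window_start = 1))
  expect_equal(nrow(cloud0), 3L)                 # threshold 0 keeps all

  # the brightest pixel always passes its own threshold
  top <- transform_cube(cube, phasor_settings(threshold_fraction = 0.99,
                                              window_start = 1))
  expect_equal(nrow(top), 1L)
  expect_equal(top$intensity, 1000)
})

test_that("raising the threshold never adds points", {
  sim <- simulate_cube(synthetic_spec(
    components = data.frame(tau = 2500, fraction = 1),
    photons_per_pixel = 200, shape = c(8, 8), spatial_pattern = "ring",
    seed = 3), st64)
  sizes <- vapply(c(0, 0.1, 0.3, 0.5, 0.7), function(th) {
    nrow(transform_cube(sim$cube, phasor_settings(threshold_fraction = th)))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("a uniform cube transforms to one repeated pixel phasor", {
  decay <- noiseless_decay(1800, st64, photons = 5000)
  counts <- array(rep(decay, each = 6), dim = c(2, 3, 64))
  cube <- decay_cube(counts, st64)
  ps <- phasor_settings(harmonic = 2, window_fraction = 0.5)
  cloud <- transform_cube(cube, ps)
  ref <- pixel_phasor(decay, st64, ps)
  expect_equal(nrow(cloud), 6L)
  expect_equal(cloud$g, rep(unname(ref["g"]), 6), tolerance = 1e-12)
  expect_equal(cloud$s, rep(unname(ref["s"]), 6), tolerance = 1e-12)
})

test_that("the phasor transform is linear in the decay", {
  d1 <- noiseless_decay(600, st64, photons = 4000)
  d2 <- noiseless_decay(3000, st64, photons = 8000)
  ps <- phasor_settings(harmonic = 2, window_fraction = 0.5, window_start = 1,
                        threshold_fraction = 0)
  p1 <- pixel_phasor(d1, st64, ps)
  p2 <- pixel_phasor(d2, st64, ps)
  p12 <- pixel_phasor(d1 + d2, st64, ps)
  win <- phasor_window(d1 + d2, st64, ps)
  w1 <- sum(d1[win]) / sum(d1[win] + d2[win])  # weights: in-window intensity
  expect_equal(unname(p12), unname(w1 * p1 + (1 - w1) * p2),
               tolerance = 1e-12)
})

test_that("phasor scatter shrinks as the photon budget grows", {
  spread <- vapply(c(1e2, 1e3, 1e4), function(ph) {
    sim <- simulate_cube(synthetic_spec(
      components = data.frame(tau = 2000, fraction = 1),
      photons_per_pixel = ph, irf_fwhm = 0, shape = c(12, 12), seed = 17),
      st64)
    cloud <- transform_cube(sim$cube, phasor_settings(threshold_fraction = 0))
    sd(cloud$g) + sd(cloud$s)
  }, 0)
  expect_true(all(diff(spread) < 0))
})

test_that("analytic mono-exponential phasors sit exactly on the universal circle", {
  expect_equal(unname(mono_exponential_phasor(0, omega1)), c(1, 0))
  expect_equal(unname(mono_exponential_phasor(1 / omega1, omega1)),
               c(0.5, 0.5))
  expect_equal(unname(mono_exponential_phasor(2500, omega1)),
               c(0.38773, 0.48720), tolerance = 1e-4)
  for (tau in c(0, 300, 750, 1000, 2500, 5000, 1e6)) {
    p <- mono_exponential_phasor(tau, omega1)
    expect_equal(sqrt((p["g"] - 0.5)^2 + p["s"]^2), c(g = 0.5),
                 tolerance = 1e-9)
  }
})

test_that("lifetime_from_point inverts the mono-exponential phasor", {
  expect_equal(lifetime_from_point(c(0.5, 0.5), omega1), 12500 / (2 * pi),
               tolerance = 1e-12)
  expect_equal(lifetime_from_point(c(1, 0), omega1), 0)
  for (tau in c(10, 300, 2500, 8000))
    expect_equal(lifetime_from_point(mono_exponential_phasor(tau, omega1),
                                     omega1), tau, tolerance = 1e-9)
  expect_warning(out <- lifetime_from_point(c(0, 0.2), omega1), "unbounded")
  expect_identical(out, Inf)
})

test_that("reference calibration maps and preserves as specified", {
  # cloud whose mean is already on target: identity calibration
  tau_ref <- 2000
  target <- mono_exponential_phasor(tau_ref, omega1)
  ref <- cloud_from_points(target["g"] + c(-0.01, 0.01),
                           target["s"] + c(0.01, -0.01))
  cal <- calibrate_cloud(ref, ref, tau_ref)
  expect_equal(c(mean(cal$g), mean(cal$s)), unname(target), tolerance = 1e-12)

  already <- cloud_from_points(rep(target["g"], 3), rep(target["s"], 3))
  out <- calibrate_cloud(already, already, tau_ref)
  expect_equal(out$g, already$g, tolerance = 1e-12)
  expect_equal(out$s, already$s, tolerance = 1e-12)

  origin <- cloud_from_points(c(-1e-13, 1e-13), c(0, 0))
  expect_error(calibrate_cloud(already, origin, tau_ref), "origin")
})

test_that("same-IRF reference calibration recovers simulated lifetimes within 1%", {
  ps <- phasor_settings(harmonic = 2, window_fraction = 0.5)
  sample <- simulate_cube(synthetic_spec(
    components = data.frame(tau = 2500, fraction = 1),
    photons_per_pixel = 2e6, shape = c(4, 4), seed = 21), st64)
  ref <- simulate_cube(synthetic_spec(
    components = data.frame(tau = 2500, fraction = 1),
    photons_per_pixel = 2e6, shape = c(4, 4), seed = 22), st64)
  out <- phasor_pipeline(sample$cube, ps,
                         reference_cube = ref$cube, reference_tau = 2500)
  taus <- lifetime_from_point(out$cloud, cloud_omega(out$cloud))
  expect_true(all(abs(taus / 2500 - 1) < 0.01))
})

test_that("truncated 64-channel transforms stay near the circle within 0.02", {
  ps <- phasor_settings(harmonic = 2, window_fraction = 0.5, window_start = 1,
                        threshold_fraction = 0)
  for (tau in c(500, 1000, 2500)) {
    p <- pixel_phasor(noiseless_decay(tau, st64), st64, ps)
    expect_equal(unname(sqrt((p["g"] - 0.5)^2 + p["s"]^2)), 0.5,
                 tolerance = 0.02)
  }
})
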