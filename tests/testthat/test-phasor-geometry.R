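test_that("TLS recovers exact lines and is symmetric in the axes", {
  line <- tls_fit(cloud_from_points(c(0.2, 0.4, 0.6), c(0.4, 0.4, 0.4)))
  expect_equal(unname(line$centroid), c(0.4, 0.4))
  expect_equal(unname(line$direction), c(1, 0))

  diag <- tls_fit(cloud_from_points(c(0, 1), c(0, 1)))
  expect_equal(unname(diag$direction), c(1, 1) / sqrt(2), tolerance = 1e-12)

  # exchanging g and s exchanges the fitted direction
  set.seed(5)
  g <- runif(50); s <- 0.3 * g + rnorm(50, 0, 0.02)
  a <- tls_fit(cloud_from_points(g, s))
  b <- tls_fit(cloud_from_points(s, g))
  expect_equal(unname(a$direction), unname(rev(b$direction)),
               tolerance = 1e-10)
})

test_that("TLS recovers a known slope from noisy points", {
  set.seed(11)
  g <- runif(1e4, 0.1, 0.9)
  s <- -0.5 * g + 0.7
  cloud <- cloud_from_points(g + rnorm(1e4, 0, 0.01),
                             s + rnorm(1e4, 0, 0.01))
  line <- tls_fit(cloud)
  slope <- line$direction[2] / line$direction[1]
  expect_equal(unname(slope), -0.5, tolerance = 0.01)
})

test_that("degenerate clouds raise the specified errors", {
  expect_error(tls_fit(cloud_from_points(0.3, 0.3)), "at least 2")
  expect_error(tls_fit(cloud_from_points(rep(0.3, 5), rep(0.2, 5))),
               "coincident")
  square <- cloud_from_points(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_error(tls_fit(square), "ambiguous")
})

test_that("TLS matches a brute-force angular grid search on small clouds", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    g <- runif(n); s <- 0.8 * g + rnorm(n, 0, 0.1)
    line <- tls_fit(cloud_from_points(g, s))
    fitted_angle <- atan2(line$direction[2], line$direction[1]) %% pi
    oracle <- brute_tls_angle(g, s)
    d <- abs(fitted_angle - oracle)
    expect_lt(min(d, pi - d), 1e-3)
  }
})

test_that("circle intersections solve the chord geometry exactly", {
  # line through (1, 0) and (0.5, 0.5)
  line <- tls_fit(cloud_from_points(c(1, 0.5), c(0, 0.5)))
  pair <- circle_intersections(line, omega1)
  expect_equal(pair$tau1, 0, tolerance = 1e-9)
  expect_equal(pair$tau2, 12500 / (2 * pi), tolerance = 1e-6)
  for (p in list(pair$p1, pair$p2)) {
    expect_equal(unname(p["g"]^2 + p["s"]^2), unname(p["g"]),
                 tolerance = 1e-9)                  # on-circle identity
  }
  expect_lt(pair$tau1, pair$tau2)
  expect_gt(pair$p1["g"], pair$p2["g"])
})

test_that("lines missing, tangent to, or crossing below the circle error out", {
  up <- structure(list(centroid = c(g = 0.5, s = 0.7),
                       direction = c(g = 1, s = 0)), class = "fitted_line")
  expect_error(circle_intersections(up, omega1), "does not intersect")
  tangent <- structure(list(centroid = c(g = 0.5, s = 0.5),
                            direction = c(g = 1, s = 0)),
                       class = "fitted_line")
  expect_error(circle_intersections(tangent, omega1), "tangent")
  vertical <- structure(list(centroid = c(g = 0.5, s = 0.2),
                             direction = c(g = 0, s = 1)),
                        class = "fitted_line")
  expect_error(circle_intersections(vertical, omega1), "half-plane")
})

test_that("a noiseless mixture chord recovers both NADH-like lifetimes", {
  taus <- c(750, 2900)
  p1 <- mono_exponential_phasor(taus[1], omega1)
  p2 <- mono_exponential_phasor(taus[2], omega1)
  for (f in c(0.2, 0.35, 0.6)) {
    mix_lo <- f * p1 + (1 - f) * p2
    mix_hi <- (f + 0.2) * p1 + (1 - f - 0.2) * p2
    cloud <- cloud_from_points(c(mix_lo["g"], mix_hi["g"]),
                               c(mix_lo["s"], mix_hi["s"]))
    pair <- circle_intersections(tls_fit(cloud), omega1)
    expect_equal(pair$tau1, taus[1], tolerance = 0.01)
    expect_equal(pair$tau2, taus[2], tolerance = 0.01)
  }
})

test_that("the lever rule reports the chord fraction with clipping", {
  taus <- c(750, 2900)
  p1 <- mono_exponential_phasor(taus[1], omega1)
  p2 <- mono_exponential_phasor(taus[2], omega1)
  line <- tls_fit(cloud_from_points(c(p1["g"], p2["g"]),
                                    c(p1["s"], p2["s"])))
  pair <- circle_intersections(line, omega1)

  mid <- (p1 + p2) / 2
  expect_equal(contributions(cloud_from_points(mid["g"], mid["s"]),
                             pair)$alpha1, 0.5, tolerance = 1e-9)
  expect_equal(contributions(cloud_from_points(p1["g"], p1["s"]),
                             pair)$alpha1, 1, tolerance = 1e-9)
  expect_equal(contributions(cloud_from_points(p2["g"], p2["s"]),
                             pair)$alpha1, 0, tolerance = 1e-9)

  # a mean beyond p1 projects outside the chord: clipped and flagged
  beyond <- p1 + 1.2 * (p1 - p2)
  res <- contributions(cloud_from_points(beyond["g"], beyond["s"]), pair)
  expect_equal(res$alpha1, 1)
  expect_true(res$boundary)

  # beta distances partition the chord
  some <- 0.3 * p1 + 0.7 * p2
  r <- contributions(cloud_from_points(some["g"], some["s"]), pair)
  expect_equal(r$beta1 + r$beta2, sqrt(sum((pair$p1 - pair$p2)^2)),
               tolerance = 1e-9)
})

test_that("for noiseless mixtures the lever fraction equals the intensity fraction", {
  taus <- c(750, 2900)
  p1 <- mono_exponential_phasor(taus[1], omega1)
  p2 <- mono_exponential_phasor(taus[2], omega1)
  line <- tls_fit(cloud_from_points(c(p1["g"], p2["g"]), c(p1["s"], p2["s"])))
  pair <- circle_intersections(line, omega1)
  for (f1 in c(0.1, 0.34, 0.8)) {
    mix <- f1 * p1 + (1 - f1) * p2
    res <- contributions(cloud_from_points(mix["g"], mix["s"]), pair)
    expect_equal(res$alpha1, f1, tolerance = 1e-3)
  }
})

test_that("the literal beta orientation reverses the lever fraction", {
  taus <- c(750, 2900)
  p1 <- mono_exponential_phasor(taus[1], omega1)
  p2 <- mono_exponential_phasor(taus[2], omega1)
  line <- tls_fit(cloud_from_points(c(p1["g"], p2["g"]), c(p1["s"], p2["s"])))
  pair <- circle_intersections(line, omega1)
  mix <- 0.3 * p1 + 0.7 * p2
  cl <- cloud_from_points(mix["g"], mix["s"])
  lever <- contributions(cl, pair, orientation = "lever")$alpha1
  literal <- contributions(cl, pair, orientation = "literal")$alpha1
  expect_equal(lever + literal, 1, tolerance = 1e-9)
})

test_that("increasing the short-lifetime fraction strictly increases alpha1", {
  # the computational content of a cyanide-induced free-NADH rise
  taus <- c(750, 2900)
  p1 <- mono_exponential_phasor(taus[1], omega1)
  p2 <- mono_exponential_phasor(taus[2], omega1)
  line <- tls_fit(cloud_from_points(c(p1["g"], p2["g"]), c(p1["s"], p2["s"])))
  pair <- circle_intersections(line, omega1)
  f <- seq(0.1, 0.9, by = 0.1)
  alphas <- vapply(f, function(f1) {
    mix <- f1 * p1 + (1 - f1) * p2
    contributions(cloud_from_points(mix["g"], mix["s"]), pair)$alpha1
  }, 0)
  expect_true(all(diff(alphas) > 0))
  gs <- vapply(f, function(f1) unname((f1 * p1 + (1 - f1) * p2)["g"]), 0)
  expect_true(all(diff(gs) > 0))  # mean phasor moves toward p1 (larger g)
})

test_that("confidence ellipse axes follow the covariance eigenvalues", {
  # four points whose sample covariance is diag(8, 2) * h^2 / 3: ratio 2
  h <- 0.01
  cl <- cloud_from_points(0.4 + c(-2 * h, 2 * h, 0, 0),
                          0.3 + c(0, 0, -h, h))
  e <- confidence_ellipse(cl)
  expect_equal(e$ratio, 2, tolerance = 1e-12)
  expect_equal(unname(e$center), c(0.4, 0.3))
  # semi-axes scale with the chi-square quantile for 2 dof
  C <- stats::cov(cbind(cl$g, cl$s))
  expect_equal(e$a, sqrt(eigen(C)$values[1] * qchisq(0.95, 2)),
               tolerance = 1e-12)
  expect_gte(e$a, e$b)
})

test_that("large isotropic clouds give ellipse ratios near 1", {
  set.seed(31)
  cl <- cloud_from_points(0.5 + rnorm(1e4, 0, 0.02),
                          0.3 + rnorm(1e4, 0, 0.02))
  expect_lt(confidence_ellipse(cl)$ratio, 1.05)
})

test_that("rigid rotation rotates the ellipse and preserves a/b exactly", {
  set.seed(37)
  g <- rnorm(500, 0, 0.03); s <- rnorm(500, 0, 0.01)
  e0 <- confidence_ellipse(cloud_from_points(0.5 + g, 0.25 + s))
  th <- 0.7
  gr <- g * cos(th) - s * sin(th)
  sr <- g * sin(th) + s * cos(th)
  e1 <- confidence_ellipse(cloud_from_points(0.5 + gr, 0.25 + sr))
  expect_equal(e1$ratio, e0$ratio, tolerance = 1e-12)
  d <- (e1$orientation - e0$orientation - th) %% pi
  expect_lt(min(d, pi - d), 1e-9)
})

test_that("collinear clouds raise a degenerate-ellipse error", {
  cl <- cloud_from_points(seq(0.1, 0.5, length.out = 10),
                          seq(0.2, 0.4, length.out = 10))
  expect_error(confidence_ellipse(cl), "eigenvalue")
  expect_error(confidence_ellipse(cloud_from_points(c(0.1, 0.2), c(0, 0))),
               "at least 3")
})

test_that("analyze_cloud falls back to a single lifetime for compact clusters", {
  sim <- coumarin_fixture(st64, photons_per_pixel = 2000, shape = c(32, 32),
                          seed = 41)
  cloud <- transform_cube(sim$cube, phasor_settings(harmonic = 2,
                                                    window_fraction = 0.5))
  res <- analyze_cloud(cloud)
  expect_equal(res$model, "monoexponential")
  expect_equal(res$tau1, 2500, tolerance = 0.05)
  expect_true(is.na(res$tau2))
  expect_lt(res$ellipse$ratio, 1.5)
})

test_that("analyze_cloud runs the full chain on two-component clouds", {
  sim <- simulate_cube(synthetic_spec(
    components = data.frame(tau = c(750, 2900), fraction = c(0.3, 0.7)),
    photons_per_pixel = 1e4, shape = c(24, 24),
    spatial_pattern = "two-region", seed = 43), st64)
  res <- analyze_cloud(transform_cube(sim$cube, phasor_settings()))
  expect_equal(res$model, "biexponential")
  expect_equal(res$tau1, 750, tolerance = 0.10)
  expect_equal(res$tau2, 2900, tolerance = 0.10)
  expect_gt(res$ellipse$ratio, 1.5)
  expect_s3_class(as.data.frame(res), "data.frame")

  expect_error(analyze_cloud(cloud_from_points(numeric(0), numeric(0))),
               "empty")
})
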