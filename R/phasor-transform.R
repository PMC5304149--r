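#' Resolve the summation window of the phasor transform
#'
#' Given a pooled (or single-pixel) decay, returns the channel indices summed
#' by the transform. The window length is `round(window_fraction * n_channels)`
#' channels; it starts either at a fixed channel or at the channel of maximum
#' pooled intensity (the decay onset) and is clipped to the recorded channels.
#'
#' @param pooled Numeric vector of pooled channel counts (used only when
#'   `window_start = "peak"`).
#' @param settings An [acquisition_settings()] object.
#' @param phasor_settings A [phasor_settings()] object.
#' @return Integer vector of 1-based channel indices.
#' @export
phasor_window <- function(pooled, settings, phasor_settings) {
  n <- settings$n_channels
  len <- max(1L, round(phasor_settings$window_fraction * n))
  start <- if (identical(phasor_settings$window_start, "peak")) {
    which.max(pooled)
  } else {
    as.integer(phasor_settings$window_start)
  }
  if (start > n) stop("window start beyond the last recorded channel")
  end <- min(n, start + len - 1L)
  seq.int(start, end)
}

.pre_rise_offset <- function(decay) {
  peak <- which.max(decay)
  if (peak <= 1L) min(decay) else min(decay[seq_len(peak - 1L)])
}

#' Phasor coordinates of one decay histogram
#'
#' Maps a single pixel's TCSPC histogram to its phasor coordinates
#' `g = sum(I cos(omega t)) / sum(I)` and `s = sum(I sin(omega t)) / sum(I)`,
#' with the sums over the configured window, `t` at channel centres measured
#' from the window start, and `omega = 2 pi k / T`. With baseline subtraction
#' enabled the per-pixel offset (minimum count before the rising edge,
#' clipped at zero after subtraction) is removed first.
#'
#' @param decay Numeric vector of channel counts, length
#'   `settings$n_channels`, non-negative.
#' @param settings An [acquisition_settings()] object.
#' @param phasor_settings A [phasor_settings()] object.
#' @param window Optional pre-resolved channel window (integer indices), e.g.
#'   shared across the pixels of a cube; default resolves from `decay` itself.
#' @return Named numeric vector `c(g =, s =)`. An empty summation window
#'   (zero total intensity) yields `c(g = NA, s = NA)`, the empty-pixel
#'   condition: callers exclude such pixels rather than fail.
#' @examples
#' st <- acquisition_settings()
#' ps <- phasor_settings(harmonic = 1, window_fraction = 1, window_start = 1,
#'                       baseline_subtraction = FALSE)
#' decay <- c(1000, rep(0, 63))       # delta decay: all photons at t ~ 0
#' pixel_phasor(decay, st, ps)        # close to (1, 0)
#' @export
pixel_phasor <- function(decay, settings, phasor_settings,
                         window = NULL) {
  stopifnot(inherits(settings, "acquisition_settings"),
            inherits(phasor_settings, "phasor_settings"))
  if (length(decay) != settings$n_channels)
    stop(sprintf("decay has %d channels, settings declare %d",
                 length(decay), settings$n_channels))
  if (anyNA(decay) || any(decay < 0))
    stop("channel counts must be non-negative and free of NA")
  if (is.null(window))
    window <- phasor_window(decay, settings, phasor_settings)
  x <- decay
  if (phasor_settings$baseline_subtraction)
    x <- pmax(x - .pre_rise_offset(x), 0)
  x <- x[window]
  total <- sum(x)
  if (total <= 0) return(c(g = NA_real_, s = NA_real_))
  omega <- angular_frequency(settings, phasor_settings$harmonic)
  t <- (seq_along(window) - 0.5) * settings$channel_width
  c(g = sum(x * cos(omega * t)) / total,
    s = sum(x * sin(omega * t)) / total)
}

#' Construct a phasor cloud
#'
#' A phasor cloud is the set of per-pixel `(g, s)` coordinates produced by
#' [transform_cube()], together with per-pixel intensities, the transform
#' frequency and the settings that produced it.
#'
#' @param points A data frame with columns `row`, `col`, `g`, `s`,
#'   `intensity`.
#' @param omega Angular transform frequency in rad/ps.
#' @param source_settings The [phasor_settings()] used (may be `NULL` for
#'   synthetic clouds).
#' @return An object of class `phasor_cloud` (a data frame with attributes
#'   `omega` and `source_settings`).
#' @export
phasor_cloud <- function(points, omega, source_settings = NULL) {
  req <- c("row", "col", "g", "s", "intensity")
  if (!is.data.frame(points) || !all(req %in% names(points)))
    stop("'points' must be a data frame with columns ",
         paste(req, collapse = ", "))
  structure(points[req],
            omega = as.numeric(omega),
            source_settings = source_settings,
            class = c("phasor_cloud", "data.frame"))
}

#' @export
print.phasor_cloud <- function(x, ...) {
  cat(sprintf("phasor_cloud: %d points, omega = %.6g rad/ps\n",
              nrow(x), attr(x, "omega")))
  cat(sprintf("  mean (g, s) = (%.4f, %.4f)\n", mean(x$g), mean(x$s)))
  invisible(x)
}

#' Transform frequency of a phasor cloud
#' @param cloud A [phasor_cloud()].
#' @return Angular frequency in rad/ps.
#' @export
cloud_omega <- function(cloud) {
  stopifnot(inherits(cloud, "phasor_cloud"))
  attr(cloud, "omega")
}

#' Phasor transform of a decay cube
#'
#' Applies [pixel_phasor()] to every pixel whose total intensity reaches
#' `threshold_fraction` of the brightest pixel's total. All pixels share one
#' summation window, resolved from the pooled (image-summed) decay, so the
#' transform phase is common across the image. Pixels with an empty window
#' after baseline subtraction are dropped.
#'
#' @param cube A [decay_cube()].
#' @param phasor_settings A [phasor_settings()] object.
#' @return A [phasor_cloud()] with one point per retained pixel.
#' @examples
#' sim <- simulate_cube(synthetic_spec(
#'   components = data.frame(tau = 2500, fraction = 1),
#'   photons_per_pixel = 500, shape = c(8, 8), seed = 1))
#' transform_cube(sim$cube, phasor_settings(harmonic = 1, window_fraction = 1))
#' @export
transform_cube <- function(cube, phasor_settings = phasor_settings()) {
  stopifnot(inherits(cube, "decay_cube"),
            inherits(phasor_settings, "phasor_settings"))
  st <- cube$settings
  d <- dim(cube$counts)
  npix <- d[1] * d[2]
  counts <- matrix(cube$counts, nrow = npix, ncol = d[3])  # column-major: pixel rows

  totals <- rowSums(counts)
  thr <- phasor_settings$threshold_fraction * max(totals)
  keep <- totals >= thr & totals > 0
  if (!any(keep))
    stop(sprintf(
      "no pixel reaches the intensity threshold (%g%% of the brightest pixel = %g photons)",
      100 * phasor_settings$threshold_fraction, thr))

  pooled <- colSums(counts)
  window <- phasor_window(pooled, st, phasor_settings)

  x <- counts[keep, , drop = FALSE]
  if (phasor_settings$baseline_subtraction) {
    peak <- which.max(pooled)
    off <- if (peak <= 1L) apply(x, 1L, min)
           else apply(x[, seq_len(peak - 1L), drop = FALSE], 1L, min)
    x <- pmax(x - off, 0)
  }
  xw <- x[, window, drop = FALSE]
  wt <- rowSums(xw)
  omega <- angular_frequency(st, phasor_settings$harmonic)
  t <- (seq_along(window) - 0.5) * st$channel_width
  g <- as.vector(xw %*% cos(omega * t))
  s <- as.vector(xw %*% sin(omega * t))

  idx <- which(keep)
  pts <- data.frame(
    row = ((idx - 1L) %% d[1]) + 1L,
    col = ((idx - 1L) %/% d[1]) + 1L,
    g = g / wt, s = s / wt,
    intensity = totals[keep])
  ok <- wt > 0
  cloud <- phasor_cloud(pts[ok, , drop = FALSE], omega, phasor_settings)
  attr(cloud, "acquisition") <- st
  attr(cloud, "window") <- window
  cloud
}

#' Closed-form phasor of a mono-exponential decay
#'
#' `g = 1 / (1 + (omega tau)^2)`, `s = omega tau / (1 + (omega tau)^2)`:
#' the point on the universal semicircle (radius 0.5 centred at (0.5, 0))
#' corresponding to lifetime `tau` at transform frequency `omega`. `tau = 0`
#' maps to (1, 0); `tau -> Inf` approaches (0, 0).
#'
#' @param tau Lifetime(s) in ps, `>= 0` (vectorised).
#' @param omega Angular frequency in rad/ps, `> 0`.
#' @return For scalar `tau`, a named vector `c(g =, s =)`; for vector `tau`,
#'   a two-column matrix.
#' @export
mono_exponential_phasor <- function(tau, omega) {
  if (any(tau < 0)) stop("'tau' must be >= 0")
  if (omega <= 0) stop("'omega' must be > 0")
  wt <- omega * tau
  g <- 1 / (1 + wt^2)
  s <- wt / (1 + wt^2)
  if (length(tau) == 1L) c(g = g, s = s) else cbind(g = g, s = s)
}

#' Lifetime of a phasor point
#'
#' Inverts the mono-exponential phasor mapping: `tau = s / (g * omega)`.
#' Exact on the universal circle; for points off the circle it is the phase
#' lifetime of the point.
#'
#' @param point Numeric `(g, s)` pair (vector of length 2, or a matrix /
#'   data frame with columns `g`, `s`).
#' @param omega Angular frequency in rad/ps.
#' @return Lifetime in ps. `g <= 0` is a non-decaying, out-of-range point
#'   and is reported as `Inf` with a warning.
#' @export
lifetime_from_point <- function(point, omega) {
  if (is.data.frame(point) || is.matrix(point)) {
    g <- if (is.data.frame(point)) point$g else point[, 1]
    s <- if (is.data.frame(point)) point$s else point[, 2]
  } else {
    g <- point[[1]]; s <- point[[2]]
  }
  tau <- s / (g * omega)
  bad <- g <= 0
  if (any(bad)) {
    warning("phasor point(s) with g <= 0: lifetime unbounded, reported as Inf")
    tau[bad] <- Inf
  }
  unname(tau)
}

.cloud_mean_z <- function(cloud) {
  complex(real = mean(cloud$g), imaginary = mean(cloud$s))
}

#' Calibrate a phasor cloud against a reference fluorophore
#'
#' Rotates and scales every point of `cloud` by the complex factor that maps
#' the mean phasor of `reference` onto the closed-form phasor of the known
#' reference lifetime. This removes the common phase and modulation bias
#' introduced by the instrument response and the discretised, truncated
#' transform, provided the reference was measured (or simulated) with
#' identical settings.
#'
#' @param cloud A [phasor_cloud()] to calibrate.
#' @param reference A [phasor_cloud()] of the reference fluorophore, measured
#'   with identical acquisition and transform settings.
#' @param reference_tau Known mono-exponential lifetime of the reference, ps.
#' @return A calibrated [phasor_cloud()]; attribute `calibration` records the
#'   complex factor applied.
#' @export
calibrate_cloud <- function(cloud, reference, reference_tau) {
  stopifnot(inherits(cloud, "phasor_cloud"), inherits(reference, "phasor_cloud"))
  omega <- cloud_omega(cloud)
  if (abs(omega - cloud_omega(reference)) > 1e-12 * omega)
    stop("cloud and reference were transformed at different frequencies")
  zref <- .cloud_mean_z(reference)
  if (Mod(zref) < 1e-12)
    stop("reference mean phasor is at the origin: calibration undefined")
  target <- mono_exponential_phasor(reference_tau, omega)
  factor <- complex(real = target["g"], imaginary = target["s"]) / zref
  z <- complex(real = cloud$g, imaginary = cloud$s) * factor
  out <- cloud
  out$g <- Re(z)
  out$s <- Im(z)
  attr(out, "calibration") <- factor
  out
}
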