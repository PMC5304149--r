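#' Specification of a synthetic TCSPC measurement
#'
#' Describes a simulated FLIM measurement with known ground truth: the
#' mono- or multi-exponential decay components (by *fractional intensity*,
#' the quantity the phasor lever rule measures), the photon budget, the
#' Gaussian IRF width, a constant background rate, the image shape and an
#' optional spatial pattern, and the random seed. Amplitude fractions (what
#' a bi-exponential fit reports) are derived via `alpha_i proportional to
#' f_i / tau_i` and returned in the ground-truth record of
#' [simulate_cube()].
#'
#' Spatial patterns:
#' * `"uniform"` — every pixel identical.
#' * `"two-region"` — left and right image halves get fraction
#'   `f1 -/+ pattern_delta` for component 1 (within-image metabolic
#'   heterogeneity); requires exactly 2 components.
#' * `"ring"` — a bright annulus ("cyst-like" section) at full photon
#'   budget, corners and lumen at `dim_factor` of it.
#'
#' @param components Data frame with columns `tau` (ps) and `fraction`
#'   (fractional intensities summing to 1).
#' @param photons_per_pixel Expected decay photons per pixel (excluding
#'   background).
#' @param irf_fwhm Gaussian IRF full width at half maximum in ps; `0` means
#'   an ideal (delta) response.
#' @param irf_center Centre of the IRF within the period, ps.
#' @param background_rate Expected background counts per channel.
#' @param shape Image dimensions `c(rows, cols)`.
#' @param spatial_pattern `"uniform"`, `"two-region"` or `"ring"`.
#' @param pattern_delta Half-separation of the component-1 fraction between
#'   the two halves of the `"two-region"` pattern.
#' @param dim_factor Intensity of the dim pixels of the `"ring"` pattern,
#'   as a fraction of `photons_per_pixel`.
#' @param seed Integer seed; fixed seed implies bit-reproducible cubes.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(components,
                           photons_per_pixel = 1e4,
                           irf_fwhm = 250,
                           irf_center = 1250,
                           background_rate = 0,
                           shape = c(64L, 64L),
                           spatial_pattern = c("uniform", "two-region", "ring"),
                           pattern_delta = 0.06,
                           dim_factor = 0.1,
                           seed = 1L) {
  spatial_pattern <- match.arg(spatial_pattern)
  if (!is.data.frame(components) ||
      !all(c("tau", "fraction") %in% names(components)))
    stop("'components' must be a data frame with columns tau and fraction")
  if (any(components$tau <= 0)) stop("component lifetimes must be positive")
  if (any(components$fraction < 0))
    stop("component fractions must be non-negative")
  if (abs(sum(components$fraction) - 1) > 1e-12)
    stop("component fractions must sum to 1")
  if (photons_per_pixel <= 0) stop("'photons_per_pixel' must be > 0")
  if (irf_fwhm < 0 || background_rate < 0)
    stop("rates and widths must be >= 0")
  if (spatial_pattern == "two-region" && nrow(components) != 2L)
    stop("the two-region pattern needs exactly 2 components")
  structure(
    list(components = components[c("tau", "fraction")],
         photons_per_pixel = photons_per_pixel,
         irf_fwhm = irf_fwhm, irf_center = irf_center,
         background_rate = background_rate,
         shape = as.integer(shape),
         spatial_pattern = spatial_pattern,
         pattern_delta = pattern_delta,
         dim_factor = dim_factor,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic TCSPC spec: %d component(s), %g photons/pixel, IRF FWHM %g ps, %dx%d %s, seed %d\n",
    nrow(x$components), x$photons_per_pixel, x$irf_fwhm,
    x$shape[1], x$shape[2], x$spatial_pattern, x$seed))
  invisible(x)
}

.spec_irf <- function(spec, settings) {
  if (spec$irf_fwhm > 0)
    irf_gaussian(settings, spec$irf_fwhm, spec$irf_center)
  else NULL
}

#' Expected channel intensities of a multi-component decay
#'
#' The noiseless per-channel expectation: the intensity-weighted sum of
#' normalised single-exponential channel shapes (`sum_i f_i * D(t; tau_i)`,
#' each `D` channel-integrated and optionally period-wrapped and
#' IRF-convolved), scaled to the photon budget, plus the constant
#' background. The sum over channels equals
#' `photons + n_channels * background` exactly.
#'
#' @param components Data frame with columns `tau` (ps) and `fraction`.
#' @param settings An [acquisition_settings()] object.
#' @param irf An [irf()] object or `NULL`.
#' @param wrap Wrap decays over the repetition period (see [decay_shape()]).
#' @param photons Expected total decay photons.
#' @param background Expected background counts per channel.
#' @return Numeric vector of expected channel intensities.
#' @export
ideal_decay_curve <- function(components, settings, irf = NULL, wrap = TRUE,
                              photons = 1, background = 0) {
  if (any(components$tau <= 0)) stop("component lifetimes must be positive")
  f <- components$fraction / sum(components$fraction)
  shape <- numeric(settings$n_channels)
  for (i in seq_along(f))
    shape <- shape + f[i] * decay_shape(components$tau[i], settings, irf, wrap)
  photons * shape + background
}

#' Simulate a TCSPC decay cube with known ground truth
#'
#' Draws independent Poisson counts around the pattern-scaled ideal decay
#' expectation of every pixel. The returned ground truth records the
#' per-pixel component-1 intensity fraction, the component lifetimes, and
#' the derived amplitude fractions (`alpha_i proportional to f_i / tau_i`).
#'
#' @param spec A [synthetic_spec()].
#' @param settings An [acquisition_settings()] object.
#' @return A list with elements `cube` (a [decay_cube()]), `truth` (list:
#'   `tau`, `fraction`, `alpha`, `f1_map`, `intensity_map`, `spec`) and
#'   `irf` (the [irf()] used, or `NULL`).
#' @examples
#' sim <- simulate_cube(synthetic_spec(
#'   components = data.frame(tau = c(750, 2900), fraction = c(0.3, 0.7)),
#'   photons_per_pixel = 2000, shape = c(16, 16), seed = 7))
#' sim$truth$alpha    # amplitude fractions implied by the intensity fractions
#' @export
simulate_cube <- function(spec, settings = acquisition_settings()) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(settings, "acquisition_settings"))
  rows <- spec$shape[1]; cols <- spec$shape[2]
  n <- settings$n_channels
  the_irf <- .spec_irf(spec, settings)

  f1_map <- matrix(spec$components$fraction[1], rows, cols)
  intensity_map <- matrix(1, rows, cols)
  if (spec$spatial_pattern == "two-region") {
    half <- cols %/% 2L
    f1_map[, seq_len(half)] <- f1_map[, seq_len(half)] - spec$pattern_delta
    f1_map[, (half + 1L):cols] <- f1_map[, (half + 1L):cols] + spec$pattern_delta
    if (any(f1_map < 0 | f1_map > 1))
      stop("two-region pattern pushes the component-1 fraction outside [0, 1]")
  } else if (spec$spatial_pattern == "ring") {
    cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
    r <- sqrt(outer((seq_len(rows) - cr)^2, (seq_len(cols) - cc)^2, `+`))
    rmax <- min(rows, cols) / 2
    annulus <- r >= 0.45 * rmax & r <= 0.9 * rmax
    intensity_map[!annulus] <- spec$dim_factor
  }

  # expected curves for each distinct f1 value (<= 2 distinct values)
  set.seed(spec$seed)
  counts <- array(0, dim = c(rows, cols, n))
  for (f1 in unique(as.vector(f1_map))) {
    comp <- spec$components
    if (nrow(comp) == 2L) comp$fraction <- c(f1, 1 - f1)
    curve <- ideal_decay_curve(comp, settings, the_irf, wrap = TRUE,
                               photons = spec$photons_per_pixel,
                               background = spec$background_rate)
    sel <- which(f1_map == f1)
    lam <- outer(as.vector(intensity_map)[sel], curve)   # pixels x channels
    draws <- matrix(stats::rpois(length(lam), lam), nrow = length(sel))
    for (ch in seq_len(n))
      counts[sel + (ch - 1L) * rows * cols] <- draws[, ch]
  }

  tau <- spec$components$tau
  f <- spec$components$fraction
  alpha <- (f / tau) / sum(f / tau)
  list(cube = decay_cube(counts, settings),
       truth = list(tau = tau, fraction = f, alpha = alpha,
                    f1_map = f1_map, intensity_map = intensity_map,
                    spec = spec),
       irf = the_irf)
}

#' Coumarin-6-like validation fixture
#'
#' A mono-exponential cube at the literature coumarin-6 lifetime of 2.5 ns,
#' with a realistic photon budget and Gaussian IRF: the standard dye
#' measurement used to validate a phasor pipeline (its cloud clusters at one
#' point on the universal circle).
#'
#' @param settings An [acquisition_settings()] object.
#' @param photons_per_pixel Expected photons per pixel (default 1e4: a bright
#'   dye solution; on a 64 x 64 image about 4e7 total photons).
#' @param shape Image dimensions.
#' @param irf_fwhm IRF width in ps.
#' @param seed Integer seed.
#' @return As [simulate_cube()].
#' @export
coumarin_fixture <- function(settings = acquisition_settings(),
                             photons_per_pixel = 1e4,
                             shape = c(64L, 64L),
                             irf_fwhm = 250, seed = 1L) {
  simulate_cube(
    synthetic_spec(components = data.frame(tau = 2500, fraction = 1),
                   photons_per_pixel = photons_per_pixel,
                   irf_fwhm = irf_fwhm, shape = shape, seed = seed),
    settings)
}

#' Paired before/after cubes emulating a metabolic shift
#'
#' Two cubes sharing the same component lifetimes but different
#' short-component intensity fractions, the synthetic analogue of imaging
#' the same specimen before and after a treatment that shifts the free /
#' protein-bound NADH balance (cyanide raises the free fraction; peroxide
#' lowers it). Each cube carries two-region within-image heterogeneity
#' (`pattern_delta`) so its own phasor cloud determines the fitted line.
#'
#' @param f1_before,f1_after Short-component intensity fractions of the two
#'   cubes.
#' @param taus Component lifetimes `c(tau1, tau2)` in ps; defaults lie in
#'   the free / bound NADH ranges.
#' @param photons_per_pixel,shape,irf_fwhm,pattern_delta,seed Passed to
#'   [synthetic_spec()]; the `after` cube uses `seed + 1`.
#' @param settings An [acquisition_settings()] object.
#' @return List with elements `before` and `after`, each as
#'   [simulate_cube()].
#' @export
metabolic_shift_fixture <- function(f1_before = 0.30, f1_after = 0.36,
                                    taus = c(750, 2900),
                                    photons_per_pixel = 2000,
                                    shape = c(16L, 16L),
                                    irf_fwhm = 250,
                                    pattern_delta = 0.06,
                                    seed = 1L,
                                    settings = acquisition_settings()) {
  make <- function(f1, sd) simulate_cube(
    synthetic_spec(components = data.frame(tau = taus,
                                           fraction = c(f1, 1 - f1)),
                   photons_per_pixel = photons_per_pixel,
                   irf_fwhm = irf_fwhm, shape = shape,
                   spatial_pattern = "two-region",
                   pattern_delta = pattern_delta, seed = sd),
    settings)
  list(before = make(f1_before, seed),
       after = make(f1_after, seed + 1L))
}
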