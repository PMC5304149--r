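#' Gaussian instrument response function on the channel grid
#'
#' Builds an IRF object: a non-negative per-channel weight profile summing
#' to 1. The Gaussian is parameterised by its full width at half maximum
#' (FWHM) and its centre position within the period, sampled at channel
#' centres with periodic wrap-around (so mass falling before t = 0 reappears
#' at the end of the period, as in a real repetitive excitation).
#'
#' @param settings An [acquisition_settings()] object.
#' @param fwhm Full width at half maximum in ps (`> 0`). Typical two-photon
#'   TCSPC responses are 200-300 ps.
#' @param center Centre of the IRF peak within the period, ps.
#' @return An object of class `irf` with elements `profile` and `settings`.
#' @export
irf_gaussian <- function(settings, fwhm = 250, center = 1250) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (fwhm <= 0) stop("'fwhm' must be > 0")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  t <- channel_times(settings)
  T <- settings$repetition_period
  # wrap the tails over adjacent periods
  p <- 0
  for (shift in -2:2) p <- p + stats::dnorm(t + shift * T, mean = center, sd = sigma)
  irf(p / sum(p), settings)
}

#' Construct an IRF from an arbitrary profile
#'
#' @param profile Non-negative channel weights of length
#'   `settings$n_channels`; normalised internally to sum to 1.
#' @param settings An [acquisition_settings()] object.
#' @return An object of class `irf`.
#' @export
irf <- function(profile, settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (length(profile) != settings$n_channels)
    stop("IRF profile length must equal n_channels")
  if (anyNA(profile) || any(profile < 0))
    stop("IRF profile must be non-negative and free of NA")
  total <- sum(profile)
  if (total <= 0) stop("IRF profile sums to zero")
  structure(list(profile = profile / total, settings = settings),
            class = "irf")
}

#' Estimate the IRF from a measured reference cube
#'
#' Pools the cube's counts over pixels, subtracts the pre-rise baseline and
#' normalises; suitable for measurements of a near-instantaneous scatterer
#' such as urea crystals.
#'
#' @param cube A [decay_cube()] of the IRF measurement.
#' @return An object of class `irf`.
#' @export
irf_from_cube <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  pooled <- apply(cube$counts, 3L, sum)
  pooled <- pmax(pooled - .pre_rise_offset(pooled), 0)
  irf(pooled, cube$settings)
}

.circular_convolve <- function(x, kernel) {
  Re(stats::fft(stats::fft(x) * stats::fft(kernel), inverse = TRUE)) / length(x)
}

#' Expected channel shape of an exponential decay
#'
#' Channel-integrated intensities of `exp(-t / tau) / tau`, optionally
#' wrapped over the repetition period (photons excited by previous pulses
#' that have not fully decayed) and convolved with an IRF profile by
#' circular discrete convolution. The result is normalised to sum to 1.
#'
#' @param tau Lifetime in ps, `> 0`.
#' @param settings An [acquisition_settings()] object.
#' @param irf An [irf()] object or `NULL` for an ideal (delta) response.
#' @param wrap Wrap the incomplete decay around the period? Default `TRUE`.
#' @return Numeric vector of length `n_channels` summing to 1.
#' @export
decay_shape <- function(tau, settings, irf = NULL, wrap = TRUE) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (!is.finite(tau) || tau <= 0) stop("'tau' must be a positive lifetime (ps)")
  n <- settings$n_channels
  w <- settings$channel_width
  edges <- (0:n) * w
  base <- exp(-edges[-(n + 1L)] / tau) - exp(-edges[-1L] / tau)  # integral / tau
  if (wrap) {
    T <- settings$repetition_period
    base <- base / (1 - exp(-T / tau))  # geometric sum over earlier pulses
  }
  shape <- base / sum(base)
  if (!is.null(irf)) {
    stopifnot(inherits(irf, "irf"))
    if (wrap) {
      shape <- .circular_convolve(shape, irf$profile)
    } else {
      # linear convolution truncated to the recorded channels
      full <- .circular_convolve(c(shape, numeric(n)), c(irf$profile, numeric(n)))
      shape <- full[seq_len(n)]
    }
    shape <- pmax(shape, 0)
    shape <- shape / sum(shape)
  }
  shape
}
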