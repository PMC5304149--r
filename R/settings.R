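#' Acquisition settings for a TCSPC measurement
#'
#' Describes the timing discretisation of a time-correlated single photon
#' counting (TCSPC) measurement: the laser repetition period `T`, the number
#' of time channels and their width. All durations are in picoseconds.
#'
#' The defaults correspond to a Ti:Sapphire system running at 80 MHz
#' (`T = 12500` ps) recording 64 time channels, a common configuration for
#' two-photon NADH FLIM. The measurement window `n_channels * channel_width`
#' must fit inside one repetition period.
#'
#' @param repetition_period Laser repetition period in ps.
#' @param n_channels Number of time channels (positive integer).
#' @param channel_width Width of one time channel in ps. Defaults to
#'   `repetition_period / n_channels` (channels tile the full period).
#' @param excitation_wavelength Optional excitation wavelength in nm
#'   (metadata only).
#' @return An object of class `acquisition_settings`.
#' @examples
#' acquisition_settings()                    # 12.5 ns period, 64 channels
#' acquisition_settings(10000, 256)          # 100 MHz system, 256 channels
#' @export
acquisition_settings <- function(repetition_period = 12500,
                                 n_channels = 64L,
                                 channel_width = repetition_period / n_channels,
                                 excitation_wavelength = NULL) {
  if (!is.numeric(repetition_period) || length(repetition_period) != 1L ||
      !is.finite(repetition_period) || repetition_period <= 0)
    stop("'repetition_period' must be a single positive number (ps)")
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 1 || n_channels != round(n_channels))
    stop("'n_channels' must be a single positive integer")
  if (!is.numeric(channel_width) || length(channel_width) != 1L ||
      !is.finite(channel_width) || channel_width <= 0)
    stop("'channel_width' must be a single positive number (ps)")
  span <- n_channels * channel_width
  if (span > repetition_period * (1 + 1e-9))
    stop(sprintf(
      "measurement window (%g ps = %d channels x %g ps) exceeds the repetition period (%g ps)",
      span, as.integer(n_channels), channel_width, repetition_period))
  structure(
    list(repetition_period = as.numeric(repetition_period),
         n_channels = as.integer(n_channels),
         channel_width = as.numeric(channel_width),
         excitation_wavelength = excitation_wavelength),
    class = "acquisition_settings")
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat(sprintf("TCSPC acquisition: T = %g ps, %d channels x %g ps",
              x$repetition_period, x$n_channels, x$channel_width))
  if (!is.null(x$excitation_wavelength))
    cat(sprintf(", excitation %g nm", x$excitation_wavelength))
  cat("\n")
  invisible(x)
}

#' Time channel centres
#'
#' Channel-centre times of an acquisition, in ps, measured from the start of
#' the measurement window: `t_i = (i - 1/2) * channel_width`.
#'
#' @param settings An [acquisition_settings()] object.
#' @return Numeric vector of length `n_channels`.
#' @export
channel_times <- function(settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  (seq_len(settings$n_channels) - 0.5) * settings$channel_width
}

#' Angular transform frequency
#'
#' The phasor transform frequency `omega = 2 * pi * k / T` (rad/ps) for
#' harmonic `k` of the laser repetition rate.
#'
#' @param settings An [acquisition_settings()] object.
#' @param harmonic Harmonic number `k` (positive integer).
#' @return Angular frequency in rad/ps.
#' @export
angular_frequency <- function(settings, harmonic = 1L) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (harmonic < 1 || harmonic != round(harmonic))
    stop("'harmonic' must be a positive integer")
  2 * pi * harmonic / settings$repetition_period
}

#' A 3D TCSPC photon-count cube
#'
#' The raw FLIM measurement: a `rows x cols x channels` array of non-negative
#' integer photon counts plus the acquisition metadata. Dimension 3 is the
#' time axis; channel 1 is the earliest time bin.
#'
#' @param counts 3D numeric array `[row, col, channel]` of non-negative
#'   integer counts.
#' @param settings An [acquisition_settings()] object; `n_channels` must
#'   match `dim(counts)[3]`.
#' @return An object of class `decay_cube` with elements `counts` and
#'   `settings`.
#' @export
decay_cube <- function(counts, settings) {
  stopifnot(inherits(settings, "acquisition_settings"))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("'counts' must be a 3D array [row, col, channel]")
  if (dim(counts)[3] != settings$n_channels)
    stop(sprintf("cube has %d time channels but settings declare %d",
                 dim(counts)[3], settings$n_channels))
  if (anyNA(counts) || any(counts < 0))
    stop("photon counts must be non-negative and free of NA")
  if (any(counts != round(counts)))
    stop("photon counts must be integers")
  structure(list(counts = counts, settings = settings), class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("decay_cube: %d x %d pixels, %d time channels, %g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Per-pixel total photon counts
#'
#' @param cube A [decay_cube()].
#' @return A `rows x cols` matrix of per-pixel totals (sum over channels).
#' @export
pixel_totals <- function(cube) {
  stopifnot(inherits(cube, "decay_cube"))
  rowSums(cube$counts, dims = 2L)
}

#' Phasor transform settings
#'
#' Controls the per-pixel phasor transform: the harmonic `k`, the fraction of
#' the repetition period summed over, where that window starts, the relative
#' intensity threshold for including pixels, and whether a per-pixel baseline
#' is subtracted first.
#'
#' Pairing the harmonic with a window of one matching cycle (`k = 2` with the
#' first half period, or `k = 4` with the first quarter) makes the truncated
#' transform of an exponential agree with the closed-form phasor, because the
#' window then spans exactly one cycle of the transform frequency. The
#' defaults (`harmonic = 2`, `window_fraction = 1/2`) are the settings used
#' for cell data; `harmonic = 4` with `window_fraction = 1/4` suits short
#' mono-exponential dyes.
#'
#' @param harmonic Harmonic number `k >= 1`.
#' @param window_fraction Fraction of the repetition period summed, in (0, 1].
#' @param window_start Either the string `"peak"` (start at the channel of
#'   the pooled-intensity maximum, excluding the instrument-response rising
#'   edge) or a fixed 1-based channel index.
#' @param threshold_fraction Pixels whose total intensity falls below this
#'   fraction of the brightest pixel are excluded; in \[0, 1). Default 0.30.
#' @param baseline_subtraction Subtract the per-pixel offset (minimum count
#'   before the rising edge, clipped at zero) before transforming? Off by
#'   default: with a repetitive excitation the pre-rise channels carry the
#'   wrapped tail of the previous pulse, so subtracting them removes real
#'   signal and biases the modulation of long-lifetime components. Enable
#'   it when a genuine constant background (room light, detector dark
#'   counts) dominates the pre-rise region.
#' @return An object of class `phasor_settings`.
#' @export
phasor_settings <- function(harmonic = 2L,
                            window_fraction = 0.5,
                            window_start = "peak",
                            threshold_fraction = 0.30,
                            baseline_subtraction = FALSE) {
  if (harmonic < 1 || harmonic != round(harmonic))
    stop("'harmonic' must be a positive integer")
  if (!is.numeric(window_fraction) || window_fraction <= 0 || window_fraction > 1)
    stop("'window_fraction' must lie in (0, 1]")
  if (!is.numeric(threshold_fraction) ||
      threshold_fraction < 0 || threshold_fraction >= 1)
    stop("'threshold_fraction' must lie in [0, 1)")
  if (is.character(window_start)) {
    window_start <- match.arg(window_start, "peak")
  } else if (!is.numeric(window_start) || length(window_start) != 1L ||
             window_start < 1 || window_start != round(window_start)) {
    stop("'window_start' must be \"peak\" or a 1-based channel index")
  }
  structure(
    list(harmonic = as.integer(harmonic),
         window_fraction = window_fraction,
         window_start = window_start,
         threshold_fraction = threshold_fraction,
         baseline_subtraction = isTRUE(baseline_subtraction)),
    class = "phasor_settings")
}

#' @export
print.phasor_settings <- function(x, ...) {
  cat(sprintf(
    "phasor settings: k = %d, window = %g of period from %s, threshold = %g, baseline %s\n",
    x$harmonic, x$window_fraction,
    if (identical(x$window_start, "peak")) "pooled peak"
    else sprintf("channel %d", as.integer(x$window_start)),
    x$threshold_fraction,
    if (x$baseline_subtraction) "subtracted" else "kept"))
  invisible(x)
}

#' Read / write phasor settings as a plain-text config
#'
#' Serialises a [phasor_settings()] object to a `key = value` text file with
#' keys `harmonic`, `window_fraction`, `window_start`, `threshold_fraction`,
#' `baseline_subtraction`, and reads it back.
#'
#' @param x A `phasor_settings` object.
#' @param path File path.
#' @return `write_phasor_config` returns `path` invisibly;
#'   `read_phasor_config` returns a `phasor_settings` object.
#' @export
write_phasor_config <- function(x, path) {
  stopifnot(inherits(x, "phasor_settings"))
  lines <- c(
    sprintf("harmonic = %d", x$harmonic),
    sprintf("window_fraction = %.17g", x$window_fraction),
    sprintf("window_start = %s",
            if (identical(x$window_start, "peak")) "peak"
            else as.integer(x$window_start)),
    sprintf("threshold_fraction = %.17g", x$threshold_fraction),
    sprintf("baseline_subtraction = %s",
            if (x$baseline_subtraction) "true" else "false"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phasor_config
#' @export
read_phasor_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  get <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  ws <- get("window_start", "peak")
  phasor_settings(
    harmonic = as.integer(get("harmonic", "2")),
    window_fraction = as.numeric(get("window_fraction", "0.5")),
    window_start = if (identical(ws, "peak")) "peak" else as.integer(ws),
    threshold_fraction = as.numeric(get("threshold_fraction", "0.3")),
    baseline_subtraction = tolower(get("baseline_subtraction", "true")) %in%
      c("true", "yes", "1"))
}
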