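.schema_version <- "1"

.fnv1a <- function(x) {
  # small stable content hash for provenance records
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(settings) {
  list(software = "flimphasor",
       version = as.character(utils::packageVersion("flimphasor")),
       schema_version = .schema_version,
       settings_hash = .fnv1a(settings))
}

.settings_to_meta <- function(settings) {
  list(repetition_period_ps = settings$repetition_period,
       n_channels = settings$n_channels,
       channel_width_ps = settings$channel_width,
       excitation_wavelength_nm = settings$excitation_wavelength)
}

.settings_from_meta <- function(meta, where) {
  need <- c("repetition_period_ps", "channel_width_ps")
  missing <- need[!vapply(need, function(k) !is.null(meta[[k]]), TRUE)]
  if (length(missing))
    stop("missing timing metadata in ", where, ": ",
         paste(missing, collapse = ", "),
         " (supply a sidecar JSON or an acquisition_settings object)")
  acquisition_settings(
    repetition_period = meta$repetition_period_ps,
    n_channels = meta$n_channels,
    channel_width = meta$channel_width_ps,
    excitation_wavelength = meta$excitation_wavelength_nm)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = "tiff_stack",
         rds = "container",
         sdt = "sdt",
         stop("cannot infer cube format from extension '.", ext,
              "'; pass 'format' explicitly"))
}

#' Write a decay cube to disk
#'
#' Two layouts are supported. `"tiff_stack"` writes one 16-bit greyscale
#' TIFF page per time channel plus a JSON sidecar (`<path>.json`) holding
#' the acquisition metadata and provenance. `"container"` writes a single
#' self-describing RDS file holding counts, metadata and provenance
#' together. Both round-trip counts bit-exactly.
#'
#' @param cube A [decay_cube()].
#' @param path Output path (`.tif`/`.tiff` or `.rds`).
#' @param format `"auto"` (from the extension), `"tiff_stack"` or
#'   `"container"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "tiff_stack", "container")) {
  stopifnot(inherits(cube, "decay_cube"))
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (format == "tiff_stack") {
    if (max(cube$counts) > 65535)
      stop("counts exceed the 16-bit TIFF range")
    pages <- lapply(seq_len(dim(cube$counts)[3]),
                    function(ch) cube$counts[, , ch] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta <- c(.settings_to_meta(cube$settings),
              list(axis_order = "row-major, channel = page, channel 1 earliest",
                   provenance = .provenance(cube$settings)))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else if (format == "container") {
    saveRDS(list(counts = cube$counts,
                 metadata = .settings_to_meta(cube$settings),
                 provenance = .provenance(cube$settings)),
            path, version = 2L)
  } else stop("cannot write format '", format, "'")
  invisible(path)
}

#' Read a decay cube from disk
#'
#' Reads the formats written by [write_cube()]. TIFF time-stacks need timing
#' metadata, either from the `<path>.json` sidecar or an explicit
#' `settings` argument; reading fails with the names of the missing fields
#' otherwise. The Becker & Hickl vendor format (`.sdt`) is recognised but no
#' reader is available, and a capability error says so.
#'
#' @param path Input path.
#' @param format `"auto"`, `"tiff_stack"`, `"container"` or `"sdt"`.
#' @param settings Optional [acquisition_settings()] overriding / replacing
#'   sidecar metadata.
#' @return A [decay_cube()].
#' @export
read_cube <- function(path, format = c("auto", "tiff_stack", "container", "sdt"),
                      settings = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (format == "sdt")
    stop("vendor .sdt reading is not available in this installation; ",
         "export the measurement as a TIFF time-stack instead")
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    if (length(d) != 2L)
      stop("TIFF pages are not single-channel greyscale: ambiguous axis order")
    counts <- array(0L, dim = c(d[1], d[2], length(pages)))
    for (ch in seq_along(pages)) counts[, , ch] <- as.integer(round(pages[[ch]]))
    if (is.null(settings)) {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar))
        stop("missing timing metadata for TIFF stack '", path,
             "': no sidecar '", sidecar, "' and no 'settings' supplied ",
             "(need repetition_period_ps and channel_width_ps)")
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (is.null(meta$n_channels)) meta$n_channels <- length(pages)
      settings <- .settings_from_meta(meta, sidecar)
    }
    if (settings$n_channels != length(pages))
      stop(sprintf("TIFF stack has %d pages but settings declare %d channels",
                   length(pages), settings$n_channels))
    decay_cube(counts, settings)
  } else {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$counts) || is.null(obj$metadata))
      stop("'", path, "' is not a flimphasor cube container")
    decay_cube(obj$counts,
               if (is.null(settings)) .settings_from_meta(obj$metadata, path)
               else settings)
  }
}

#' Write an analysis result to JSON or CSV
#'
#' Serialises a [analyze_cloud()] phasor result or a [fit_cube()] MEDF
#' result with stable field names and units: lifetimes in ps (`tau1_ps`,
#' `tau2_ps`), fractions as dimensionless values in \[0, 1\]. JSON output
#' embeds the schema version and provenance; the MEDF CSV layout is the
#' per-pixel table with 0-based, row-major pixel coordinates.
#'
#' @param result A `phasor_fit_result` or `medf_cube_result`.
#' @param path Output path.
#' @param layout `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, layout = c("json", "csv")) {
  layout <- match.arg(layout)
  if (inherits(result, "phasor_fit_result")) {
    row <- as.data.frame(result)
    if (layout == "csv") {
      utils::write.csv(row, path, row.names = FALSE)
    } else {
      jsonlite::write_json(
        c(list(result_type = "phasor", schema_version = .schema_version),
          as.list(row)),
        path, auto_unbox = TRUE, digits = NA, null = "null")
    }
  } else if (inherits(result, "medf_cube_result")) {
    px <- result$pixels
    px$row <- px$row - 1L   # exported pixel coordinates are 0-based
    px$col <- px$col - 1L
    if (layout == "csv") {
      utils::write.csv(px, path, row.names = FALSE)
    } else {
      jsonlite::write_json(
        list(result_type = "medf", schema_version = .schema_version,
             aggregate = result$aggregate, pixels = px),
        path, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
    }
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))
  invisible(path)
}

#' Export a contribution map as an image
#'
#' Writes a per-pixel `alpha1` (or any fraction) map either as a 16-bit
#' greyscale TIFF (values linearly mapped from `bounds` to the full 16-bit
#' range) or as an 8-bit false-colour PNG on a red-to-blue ramp, the
#' conventional rendering of free-NADH contribution maps (low fraction red,
#' high fraction blue). Values outside `bounds` are clipped; `NA` pixels
#' (below threshold / unconverged) render black.
#'
#' @param map Numeric matrix of fractions.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @param bounds Colour-scale bounds, default `c(0.65, 0.80)`.
#' @return `path`, invisibly.
#' @export
write_fraction_map <- function(map, path, bounds = c(0.65, 0.80)) {
  stopifnot(is.matrix(map), length(bounds) == 2L, bounds[2] > bounds[1])
  scaled <- (map - bounds[1]) / (bounds[2] - bounds[1])
  scaled <- pmin(pmax(scaled, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    out <- scaled
    out[is.na(out)] <- 0
    tiff::writeTIFF(out, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    ramp <- grDevices::colorRamp(c("red", "yellow", "green", "blue"))
    na_mask <- is.na(as.vector(scaled))
    vals <- as.vector(scaled)
    vals[na_mask] <- 0
    rgb <- ramp(vals)
    rgb[na_mask, ] <- 0
    img <- array(0, dim = c(nrow(map), ncol(map), 3L))
    for (k in 1:3) img[, , k] <- matrix(rgb[, k], nrow(map)) / 255
    png::writePNG(img, path)
  } else stop("unsupported map extension '.", ext, "' (use .tif or .png)")
  invisible(path)
}
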