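#' Run the full phasor pipeline on a cube
#'
#' Convenience wrapper chaining [transform_cube()], optional
#' [calibrate_cloud()] against a reference measurement, and
#' [analyze_cloud()].
#'
#' @param cube A [decay_cube()].
#' @param phasor_settings A [phasor_settings()] object.
#' @param reference_cube Optional [decay_cube()] of a reference fluorophore
#'   measured with identical settings.
#' @param reference_tau Known lifetime (ps) of the reference; required with
#'   `reference_cube`.
#' @param ... Passed to [analyze_cloud()].
#' @return List with elements `cloud` (the, possibly calibrated,
#'   [phasor_cloud()]) and `result` (the [analyze_cloud()] output).
#' @export
phasor_pipeline <- function(cube, phasor_settings = phasor_settings(),
                            reference_cube = NULL, reference_tau = NULL,
                            ...) {
  if (identical(phasor_settings$window_start, "peak")) {
    # resolve the window once, from the sample, and share it with the
    # reference: the calibration factor transfers only between transforms
    # computed with an identical window (a one-channel start shift is a
    # phase jump of 2*pi*k/n_channels radians)
    pooled <- apply(cube$counts, 3L, sum)
    phasor_settings$window_start <- which.max(pooled)
  }
  cloud <- transform_cube(cube, phasor_settings)
  if (!is.null(reference_cube)) {
    if (is.null(reference_tau))
      stop("'reference_tau' is required when a reference cube is given")
    ref_cloud <- transform_cube(reference_cube, phasor_settings)
    cloud <- calibrate_cloud(cloud, ref_cloud, reference_tau)
  }
  list(cloud = cloud, result = analyze_cloud(cloud, ...))
}

#' Consistency check between the phasor and MEDF branches
#'
#' The two branches measure the short component differently: the phasor
#' lever rule yields its fractional *intensity*, a bi-exponential fit its
#' *amplitude* fraction. They are linked by `f1 = alpha1 * tau1 / (alpha1 *
#' tau1 + (1 - alpha1) * tau2)`. This report converts the MEDF amplitudes
#' accordingly and compares lifetimes and fractions across branches.
#'
#' @param phasor A `phasor_fit_result` from [analyze_cloud()].
#' @param medf A `biexp_fit_result` or `medf_cube_result`.
#' @param tau_rel_tol Relative lifetime tolerance for the agreement flag.
#' @param alpha_tol Absolute tolerance on the converted fraction.
#' @return An object of class `branch_comparison`: per-branch `tau1`,
#'   `tau2`, the MEDF amplitude `alpha1_medf`, its intensity-fraction
#'   conversion `f1_from_medf`, `alpha1_phasor`, the discrepancies, and
#'   `consistent`.
#' @export
compare_branches <- function(phasor, medf,
                             tau_rel_tol = 0.10, alpha_tol = 0.05) {
  stopifnot(inherits(phasor, "phasor_fit_result"))
  if (inherits(medf, "medf_cube_result")) {
    m <- list(tau1 = medf$aggregate$tau1_mean,
              tau2 = medf$aggregate$tau2_mean,
              alpha1 = medf$aggregate$alpha1_mean)
  } else if (inherits(medf, "biexp_fit_result")) {
    m <- medf[c("tau1", "tau2", "alpha1")]
  } else stop("'medf' must be a biexp_fit_result or medf_cube_result")
  if (phasor$model != "biexponential")
    stop("phasor result is mono-exponential: no two-component comparison")
  f1_medf <- amplitude_to_intensity_fraction(m$alpha1, m$tau1, m$tau2)
  dtau1 <- abs(phasor$tau1 - m$tau1) / m$tau1
  dtau2 <- abs(phasor$tau2 - m$tau2) / m$tau2
  dalpha <- abs(phasor$alpha1 - f1_medf)
  structure(list(
    tau1_phasor = phasor$tau1, tau2_phasor = phasor$tau2,
    tau1_medf = m$tau1, tau2_medf = m$tau2,
    alpha1_medf = m$alpha1, f1_from_medf = f1_medf,
    alpha1_phasor = phasor$alpha1,
    tau1_rel_diff = dtau1, tau2_rel_diff = dtau2,
    alpha_abs_diff = dalpha,
    consistent = dtau1 <= tau_rel_tol && dtau2 <= tau_rel_tol &&
      dalpha <= alpha_tol),
    class = "branch_comparison")
}

#' @export
print.branch_comparison <- function(x, ...) {
  cat("phasor vs MEDF consistency\n")
  cat(sprintf("  tau1: %.0f vs %.0f ps (%.1f%% apart)\n",
              x$tau1_phasor, x$tau1_medf, 100 * x$tau1_rel_diff))
  cat(sprintf("  tau2: %.0f vs %.0f ps (%.1f%% apart)\n",
              x$tau2_phasor, x$tau2_medf, 100 * x$tau2_rel_diff))
  cat(sprintf("  alpha1_phasor = %.3f vs f1(alpha1_MEDF = %.3f) = %.3f (|diff| = %.3f)\n",
              x$alpha1_phasor, x$alpha1_medf, x$f1_from_medf, x$alpha_abs_diff))
  cat(if (x$consistent) "  branches agree within tolerance\n"
      else "  BRANCHES DISAGREE beyond tolerance\n")
  invisible(x)
}

.draw_ellipse <- function(ellipse, n = 200, ...) {
  th <- seq(0, 2 * pi, length.out = n)
  rot <- ellipse$orientation
  x <- ellipse$a * cos(th); y <- ellipse$b * sin(th)
  graphics::lines(ellipse$center[1] + x * cos(rot) - y * sin(rot),
                  ellipse$center[2] + x * sin(rot) + y * cos(rot), ...)
}

#' Render a phasor plot
#'
#' Draws the G-S cloud, the universal semicircle, and (when a fit result is
#' given) the TLS line, the circle intersections and the confidence ellipse.
#' With `file` set, writes a PNG instead of drawing on the current device.
#'
#' @param cloud A [phasor_cloud()].
#' @param result Optional [analyze_cloud()] result to overlay.
#' @param file Optional PNG output path.
#' @param main Plot title.
#' @param col Point colour.
#' @param add Add to an existing phasor plot instead of opening a new one
#'   (for before/after overlays).
#' @param ... Passed to [graphics::points()].
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_phasor <- function(cloud, result = NULL, file = NULL,
                        main = "Phasor plot",
                        col = grDevices::rgb(0, 0, 0, 0.25),
                        add = FALSE, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 0.6), asp = 1,
                   xlab = "G", ylab = "S", main = main)
    th <- seq(0, pi, length.out = 200)
    graphics::lines(0.5 + 0.5 * cos(th), 0.5 * sin(th), col = "grey40")
  }
  graphics::points(cloud$g, cloud$s, pch = 16, cex = 0.4, col = col, ...)
  if (!is.null(result)) {
    if (!is.null(result$ellipse))
      .draw_ellipse(result$ellipse, col = "darkgreen", lwd = 2)
    if (result$model == "biexponential") {
      p1 <- result$pair$p1; p2 <- result$pair$p2
      graphics::segments(p1[1], p1[2], p2[1], p2[2], col = "red", lwd = 1.5)
      graphics::points(rbind(p1, p2), pch = 4, col = "red", cex = 1.5, lwd = 2)
      graphics::points(result$mean_phasor[1], result$mean_phasor[2],
                       pch = 3, col = "blue", cex = 1.2, lwd = 2)
    } else {
      graphics::points(result$mean_phasor[1], result$mean_phasor[2],
                       pch = 3, col = "blue", cex = 1.2, lwd = 2)
    }
  }
  invisible(file)
}

#' Per-pixel contribution map from an MEDF result
#'
#' @param medf A [fit_cube()] result.
#' @param shape Image dimensions `c(rows, cols)`.
#' @return Matrix of `alpha1` values (`NA` where not fitted or not
#'   converged).
#' @export
alpha_map <- function(medf, shape) {
  stopifnot(inherits(medf, "medf_cube_result"))
  m <- matrix(NA_real_, shape[1], shape[2])
  px <- medf$pixels[medf$pixels$converged, ]
  m[cbind(px$row, px$col)] <- px$alpha1
  m
}
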