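#' Total least squares line through a phasor cloud
#'
#' Fits the line minimising the summed squared orthogonal distances of the
#' `(g, s)` points — orthogonal regression, which treats errors in G and S
#' symmetrically. Computed exactly as the principal axis of the centred
#' sample covariance; no iteration. The returned direction is a unit vector,
#' sign-normalised so its g-component is `>= 0` (ties broken by the
#' s-component).
#'
#' @param cloud A [phasor_cloud()] or a data frame with columns `g`, `s`
#'   (at least 2 distinct points).
#' @return An object of class `fitted_line` with elements `centroid`
#'   (named `(g, s)`) and `direction` (unit 2-vector).
#' @export
tls_fit <- function(cloud) {
  g <- cloud$g; s <- cloud$s
  if (length(g) < 2L) stop("TLS fit needs at least 2 points")
  gm <- mean(g); sm <- mean(s)
  X <- cbind(g - gm, s - sm)
  if (max(abs(X)) == 0) stop("degenerate cloud: all points coincident")
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] - e$values[2] <= 1e-12 * max(e$values[1], 1e-300))
    stop("isotropic cloud: principal spreads equal, line direction ambiguous")
  d <- e$vectors[, 1]
  if (d[1] < 0 || (d[1] == 0 && d[2] < 0)) d <- -d
  structure(list(centroid = c(g = gm, s = sm),
                 direction = c(g = d[1], s = d[2])),
            class = "fitted_line")
}

#' @export
print.fitted_line <- function(x, ...) {
  cat(sprintf("TLS line: through (%.4f, %.4f), direction (%.4f, %.4f)\n",
              x$centroid[1], x$centroid[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Intersections of a fitted line with the universal circle
#'
#' Solves the quadratic for the intersections of the TLS line with the
#' universal semicircle `(g - 1/2)^2 + s^2 = 1/4` and converts each
#' intersection to a component lifetime via `tau = s / (g * omega)`.
#' Intersections in the non-physical half-plane `s < 0` are discarded; the
#' two remaining points are the phasors of the two contributing
#' mono-exponential components. `p1`, the intersection with larger `g`,
#' carries the shorter lifetime `tau1` (lifetime grows counter-clockwise
#' along the semicircle), so `tau1 < tau2` always.
#'
#' @param line A [tls_fit()] result.
#' @param omega Angular transform frequency in rad/ps.
#' @return An object of class `lifetime_pair`: `tau1`, `tau2` (ps), `p1`,
#'   `p2` (named `(g, s)` vectors on the circle).
#' @export
circle_intersections <- function(line, omega) {
  stopifnot(inherits(line, "fitted_line"))
  c0 <- unname(line$centroid) - c(0.5, 0)
  d <- unname(line$direction)
  # |c0 + t d|^2 = 1/4 with |d| = 1
  b <- sum(c0 * d)
  cc <- sum(c0^2) - 0.25
  disc <- b^2 - cc
  if (disc < 0)
    stop("fitted line does not intersect the universal circle")
  if (disc < 1e-12)
    stop("fitted line is tangent to the universal circle")
  tt <- c(-b - sqrt(disc), -b + sqrt(disc))
  pts <- cbind(g = c0[1] + tt * d[1] + 0.5, s = c0[2] + tt * d[2])
  keep <- pts[, "s"] >= -1e-9
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L)
    stop("fewer than two intersections with s >= 0: line crosses the ",
         "non-physical half-plane")
  ord <- order(pts[, "g"], decreasing = TRUE)
  p1 <- pts[ord[1], ]
  p2 <- pts[ord[2], ]
  tau <- function(p) {
    if (p["g"] <= 0) Inf else unname(p["s"] / (p["g"] * omega))
  }
  structure(list(tau1 = tau(p1), tau2 = tau(p2),
                 p1 = c(g = unname(p1["g"]), s = max(unname(p1["s"]), 0)),
                 p2 = c(g = unname(p2["g"]), s = max(unname(p2["s"]), 0))),
            class = "lifetime_pair")
}

#' @export
print.lifetime_pair <- function(x, ...) {
  cat(sprintf("component lifetimes: tau1 = %.1f ps at (%.4f, %.4f); tau2 = %s ps at (%.4f, %.4f)\n",
              x$tau1, x$p1[1], x$p1[2],
              if (is.finite(x$tau2)) sprintf("%.1f", x$tau2) else "Inf",
              x$p2[1], x$p2[2]))
  invisible(x)
}

#' Lever-rule contribution of the short-lifetime component
#'
#' Projects the unweighted mean phasor of the cloud orthogonally onto the
#' chord between the two component phasors and reports the lever-rule
#' fraction of component 1 (the short-lifetime component at `p1`):
#' `alpha1 = |projected mean - p2| / |p1 - p2|`, clipped to \[0, 1\]. By
#' phasor linearity this equals the fractional intensity of the short
#' component for noiseless mixtures, and it grows as the cloud shifts toward
#' `p1` — the direction a rise in free NADH produces. `beta1` and `beta2` are
#' the distances from the projected mean to `p1` and `p2`.
#'
#' `orientation = "literal"` instead indexes the betas by the component they
#' are measured from (`beta1` = distance from `p1`), making
#' `alpha1 = beta1 / (beta1 + beta2)` fall as the cloud approaches `p1`.
#'
#' @param cloud A [phasor_cloud()] (non-empty).
#' @param pair A [circle_intersections()] result.
#' @param orientation `"lever"` (default) or `"literal"`; see Details.
#' @return An object of class `contribution_result`: `alpha1`, `beta1`,
#'   `beta2`, `projected_mean`, and `boundary` (`TRUE` when the projection
#'   fell outside the chord and `alpha1` was clipped).
#' @export
contributions <- function(cloud, pair, orientation = c("lever", "literal")) {
  stopifnot(inherits(pair, "lifetime_pair"))
  orientation <- match.arg(orientation)
  if (nrow(cloud) < 1L) stop("empty phasor cloud")
  m <- c(mean(cloud$g), mean(cloud$s))
  p1 <- unname(pair$p1); p2 <- unname(pair$p2)
  chord <- p1 - p2
  len2 <- sum(chord^2)
  if (len2 <= 0) stop("degenerate lifetime pair: p1 and p2 coincide")
  t <- sum((m - p2) * chord) / len2       # 0 at p2, 1 at p1
  proj <- p2 + t * chord
  boundary <- t < 0 || t > 1
  alpha1 <- min(max(t, 0), 1)
  beta1 <- alpha1 * sqrt(len2)            # lever arm adjacent to p2
  beta2 <- (1 - alpha1) * sqrt(len2)
  if (orientation == "literal") {
    # betas indexed by the endpoint they are measured from
    b1 <- sqrt(sum((proj - p1)^2)); b2 <- sqrt(sum((proj - p2)^2))
    alpha1 <- b1 / (b1 + b2)
    beta1 <- b1; beta2 <- b2
  }
  structure(list(alpha1 = alpha1, beta1 = beta1, beta2 = beta2,
                 projected_mean = c(g = proj[1], s = proj[2]),
                 boundary = boundary),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("alpha1 = %.4f (beta1 = %.4f, beta2 = %.4f)%s\n",
              x$alpha1, x$beta1, x$beta2,
              if (x$boundary) " [projection clipped to chord]" else ""))
  invisible(x)
}

#' 95% confidence ellipse of a phasor cloud
#'
#' Eigen-decomposes the sample covariance of `(g, s)` and scales the
#' principal axes by the chi-square quantile for 2 degrees of freedom at the
#' requested coverage (5.991 at 0.95), the standard bivariate-normal
#' coverage ellipse. The semi-axis ratio `a/b` is a shape metric for the
#' cloud: values near 1 indicate a compact, mono-exponential-like cluster;
#' elongation indicates multi-exponential spread.
#'
#' @param cloud A [phasor_cloud()] or data frame with `g`, `s`
#'   (at least 3 non-collinear points).
#' @param coverage Coverage probability, default 0.95.
#' @return An object of class `confidence_ellipse`: `center`, semi-axes `a`
#'   `>=` `b`, `orientation` (radians, angle of the major axis), `ratio`
#'   (= a/b).
#' @export
confidence_ellipse <- function(cloud, coverage = 0.95) {
  if (nrow(cloud) < 3L) stop("confidence ellipse needs at least 3 points")
  if (coverage <= 0 || coverage >= 1) stop("'coverage' must lie in (0, 1)")
  C <- stats::cov(cbind(cloud$g, cloud$s))
  e <- eigen(C, symmetric = TRUE)
  if (e$values[2] <= 1e-14 * max(e$values[1], 1e-300))
    stop(sprintf(
      "degenerate (collinear) cloud: smallest covariance eigenvalue %.3g",
      e$values[2]))
  q <- stats::qchisq(coverage, df = 2)
  a <- sqrt(e$values[1] * q)
  b <- sqrt(e$values[2] * q)
  structure(list(center = c(g = mean(cloud$g), s = mean(cloud$s)),
                 a = a, b = b,
                 orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 ratio = a / b, coverage = coverage),
            class = "confidence_ellipse")
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf(
    "%g%% confidence ellipse: centre (%.4f, %.4f), a = %.4g, b = %.4g, a/b = %.3f\n",
    100 * x$coverage, x$center[1], x$center[2], x$a, x$b, x$ratio))
  invisible(x)
}

#' Full phasor-plane analysis of a cloud
#'
#' Runs the per-image analysis chain: TLS line fit, universal-circle
#' intersections, lever-rule contribution of the mean phasor, and the 95%
#' confidence ellipse. Clouds that look mono-exponential — ellipse ratio
#' below `mono_ratio_threshold`, an ambiguous TLS direction, or a line that
#' misses the circle — fall back to reporting the single lifetime of the
#' mean phasor.
#'
#' When the transform window covers less than the full period, the lever
#' rule measures the *in-window* intensity fraction: the long-lifetime
#' component loses the part of its photons decaying beyond the window, so
#' the raw lever overstates the short component. With `window_correction`
#' enabled (the default) and window metadata available on the cloud, the
#' reported `alpha1` is converted to a whole-decay fractional intensity by
#' dividing each component's lever weight by its in-window photon fraction,
#' computed from the fitted lifetimes via [decay_shape()]. The raw lever
#' value remains available as `contribution$alpha1`.
#'
#' @param cloud A [phasor_cloud()].
#' @param omega Angular transform frequency; defaults to the cloud's own.
#' @param mono_ratio_threshold Ellipse ratios below this are treated as
#'   mono-exponential clusters (default 1.5; a pure dye's cloud sits near 1).
#' @param coverage Ellipse coverage probability.
#' @param orientation Passed to [contributions()].
#' @param window_correction Convert the in-window lever fraction to a
#'   whole-decay intensity fraction (see Details)?
#' @return An object of class `phasor_fit_result` with elements `model`
#'   (`"biexponential"` or `"monoexponential"`), `tau1`, `tau2`, `alpha1`,
#'   `line`, `pair`, `contribution`, `ellipse`, `mean_phasor`, `n_pixels`.
#'   On the mono-exponential path `tau1` holds the mean-phasor lifetime and
#'   `tau2`, `alpha1`, `line`, `pair`, `contribution` are `NA`/`NULL`.
#' @export
analyze_cloud <- function(cloud, omega = cloud_omega(cloud),
                          mono_ratio_threshold = 1.5, coverage = 0.95,
                          orientation = "lever", window_correction = TRUE) {
  stopifnot(inherits(cloud, "phasor_cloud"))
  if (nrow(cloud) < 1L) stop("empty phasor cloud")
  mean_phasor <- c(g = mean(cloud$g), s = mean(cloud$s))
  ellipse <- tryCatch(confidence_ellipse(cloud, coverage),
                      error = function(e) NULL)
  mono <- function(reason) {
    structure(list(model = "monoexponential", reason = reason,
                   tau1 = lifetime_from_point(mean_phasor, omega),
                   tau2 = NA_real_, alpha1 = NA_real_,
                   line = NULL, pair = NULL, contribution = NULL,
                   ellipse = ellipse, mean_phasor = mean_phasor,
                   omega = omega, n_pixels = nrow(cloud)),
              class = "phasor_fit_result")
  }
  if (!is.null(ellipse) && ellipse$ratio < mono_ratio_threshold)
    return(mono(sprintf("ellipse ratio %.3f below mono threshold %.3f",
                        ellipse$ratio, mono_ratio_threshold)))
  line <- tryCatch(tls_fit(cloud), error = function(e) e)
  if (inherits(line, "error"))
    return(mono(paste("TLS:", conditionMessage(line))))
  pair <- tryCatch(circle_intersections(line, omega), error = function(e) e)
  if (inherits(pair, "error"))
    return(mono(paste("intersections:", conditionMessage(pair))))
  contrib <- contributions(cloud, pair, orientation)
  alpha1 <- contrib$alpha1
  acq <- attr(cloud, "acquisition")
  win <- attr(cloud, "window")
  if (window_correction && orientation == "lever" &&
      !is.null(acq) && !is.null(win) &&
      length(win) < acq$n_channels &&
      is.finite(pair$tau1) && is.finite(pair$tau2) &&
      pair$tau1 > 0 && pair$tau2 > 0) {
    in_window <- function(tau)
      sum(decay_shape(tau, acq, wrap = TRUE)[seq_along(win)])
    w1 <- in_window(pair$tau1)
    w2 <- in_window(pair$tau2)
    alpha1 <- (alpha1 / w1) / (alpha1 / w1 + (1 - alpha1) / w2)
  }
  structure(list(model = "biexponential", reason = NULL,
                 tau1 = pair$tau1, tau2 = pair$tau2,
                 alpha1 = alpha1,
                 line = line, pair = pair, contribution = contrib,
                 ellipse = ellipse, mean_phasor = mean_phasor,
                 omega = omega, n_pixels = nrow(cloud)),
            class = "phasor_fit_result")
}

#' @export
print.phasor_fit_result <- function(x, ...) {
  if (x$model == "biexponential") {
    cat(sprintf("phasor analysis (bi-exponential): tau1 = %.0f ps, tau2 = %.0f ps, alpha1 = %.3f\n",
                x$tau1, x$tau2, x$alpha1))
  } else {
    cat(sprintf("phasor analysis (mono-exponential cluster): tau = %.0f ps\n",
                x$tau1))
    if (!is.null(x$reason)) cat("  fallback reason: ", x$reason, "\n", sep = "")
  }
  if (!is.null(x$ellipse))
    cat(sprintf("  ellipse a/b = %.3f; %d pixels\n", x$ellipse$ratio, x$n_pixels))
  invisible(x)
}

#' Flatten a phasor fit result to one table row
#'
#' @param result A [analyze_cloud()] result.
#' @return A one-row data frame with columns `model`, `tau1_ps`, `tau2_ps`,
#'   `alpha1_phasor`, `mean_g`, `mean_s`, `a`, `b`, `ratio`, `n_pixels`.
#' @export
as.data.frame.phasor_fit_result <- function(x, ...) {
  data.frame(model = x$model,
             tau1_ps = x$tau1, tau2_ps = x$tau2,
             alpha1_phasor = x$alpha1,
             mean_g = unname(x$mean_phasor["g"]),
             mean_s = unname(x$mean_phasor["s"]),
             a = if (is.null(x$ellipse)) NA_real_ else x$ellipse$a,
             b = if (is.null(x$ellipse)) NA_real_ else x$ellipse$b,
             ratio = if (is.null(x$ellipse)) NA_real_ else x$ellipse$ratio,
             n_pixels = x$n_pixels)
}
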