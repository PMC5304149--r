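# shared fixtures: everything generated in code, nothing stored on disk

st64 <- acquisition_settings()          # 12.5 ns period, 64 channels
omega1 <- angular_frequency(st64, 1)

# dense discretisation for near-continuum checks
st_dense <- acquisition_settings(12500, 4096)

# full-period transform settings (harmonic 1), no threshold
ps_full <- phasor_settings(harmonic = 1, window_fraction = 1, window_start = 1,
                           threshold_fraction = 0)

# a noiseless mono-exponential histogram on a settings grid
noiseless_decay <- function(tau, settings, photons = 1e9, irf = NULL) {
  round(ideal_decay_curve(data.frame(tau = tau, fraction = 1),
                          settings, irf = irf, photons = photons))
}

# brute-force phasor oracle: direct complex-exponential sum over the window
brute_phasor <- function(decay, settings, phasor_settings) {
  window <- phasor_window(decay, settings, phasor_settings)
  omega <- 2 * pi * phasor_settings$harmonic / settings$repetition_period
  z <- 0 + 0i
  total <- 0
  for (i in seq_along(window)) {
    t <- (i - 0.5) * settings$channel_width
    z <- z + decay[window[i]] * exp(1i * omega * t)
    total <- total + decay[window[i]]
  }
  c(g = Re(z) / total, s = Im(z) / total)
}

# brute-force TLS oracle: grid search over line angles through the centroid
brute_tls_angle <- function(g, s, step = 5e-4) {
  gc <- g - mean(g); sc <- s - mean(s)
  angles <- seq(0, pi, by = step)
  cost <- vapply(angles, function(a) {
    n <- c(-sin(a), cos(a))          # normal of a line with direction angle a
    sum((gc * n[1] + sc * n[2])^2)
  }, 0)
  angles[which.min(cost)]
}

# small synthetic phasor cloud (no window metadata)
cloud_from_points <- function(g, s, omega = omega1) {
  phasor_cloud(data.frame(row = seq_along(g), col = rep(1L, length(g)),
                          g = g, s = s,
                          intensity = rep(1, length(g))), omega)
}
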