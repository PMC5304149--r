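# flimphasor

Phasor and multi-exponential analysis of time-domain FLIM measurements in R.

Fluorescence lifetime imaging microscopy (FLIM) with time-correlated single
photon counting (TCSPC) records, for every pixel, a histogram of photon
arrival times relative to the excitation pulse. The balance between free and
protein-bound NADH — distinguishable by their short (~0.3–0.8 ns) and long
(~1–6.5 ns) fluorescence lifetimes — reports the balance between glycolysis
and oxidative phosphorylation, so FLIM can read out metabolic shifts in
living samples without labels. `flimphasor` implements the two standard
analysis routes for such data and a simulator for validating them:

* **Phasor analysis.** Each pixel's decay `I(t)` is mapped to a point

  `G = Σ I(t) cos(ωt) / Σ I(t)`,  `S = Σ I(t) sin(ωt) / Σ I(t)`,

  with `ω = 2πk/T` a harmonic of the laser repetition rate. Mono-exponential
  decays fall on the universal semicircle `(G − ½)² + S² = ¼`; two-component
  mixtures fall on the chord between their component points. The package
  fits the pixel cloud with total least squares (orthogonal regression,
  errors in both G and S), intersects the fitted line with the circle to
  obtain the component lifetimes `τ = S/(Gω)`, projects the mean phasor onto
  the chord to get the lever-rule contribution
  `α₁ = β₁/(β₁ + β₂)` of the short-lifetime component, and summarises the
  cloud's shape by its 95% confidence ellipse and semi-axis ratio `a/b`
  (near 1 for a compact, mono-exponential-like cluster).

* **Multi-exponential decay fitting (MEDF).** Weighted nonlinear least
  squares of `I(t) = C + Σᵢ αᵢ e^(−t/τᵢ)` (two components, optional
  instrument-response convolution, period wrap-around, per-pixel offset),
  with reduced χ² as the goodness-of-fit: the reference method the phasor
  route is compared against. The two routes measure different fractions —
  MEDF an amplitude fraction, the phasor lever a fractional intensity —
  linked by `f₁ = α₁τ₁ / (α₁τ₁ + α₂τ₂)`.

* **TCSPC simulation.** Seeded decay cubes with known ground truth:
  mono/bi-exponential components, Gaussian IRF, period wrap, constant
  background, Poisson photon noise, and spatial patterns (uniform,
  two-region heterogeneity, cyst-like ring), plus ready-made fixtures for a
  coumarin-6-like validation dye and paired before/after "metabolic shift"
  measurements.

I/O covers TIFF time-stacks (16-bit, with a JSON metadata sidecar), a
single-file RDS container, JSON/CSV results, false-colour contribution
maps, and phasor-plot rendering. A command-line interface
(`inst/cli/flimphasor.R`) exposes `simulate`, `phasor`, `medf` and
`compare` subcommands.

## Worked example

Simulate an NADH-like two-component measurement (τ₁ = 750 ps free,
τ₂ = 2900 ps bound, 30% fractional intensity of the free component, with
within-image heterogeneity), then analyse it with both routes:

```r
library(flimphasor)
settings <- acquisition_settings()          # 80 MHz laser, 64 time channels

spec <- synthetic_spec(
  components = data.frame(tau = c(750, 2900), fraction = c(0.30, 0.70)),
  photons_per_pixel = 1e4, irf_fwhm = 250, shape = c(64, 64),
  spatial_pattern = "two-region", seed = 42)
sim <- simulate_cube(spec, settings)

cloud  <- transform_cube(sim$cube, phasor_settings())   # k = 2, half period
result <- analyze_cloud(cloud)
print(result)
#> phasor analysis (bi-exponential): tau1 = 800 ps, tau2 = 2817 ps, alpha1 = 0.290
#>   ellipse a/b = 5.981; 4096 pixels

medf <- fit_biexponential(pooled_decay(sim$cube), settings, irf = sim$irf)
print(medf)
#> bi-exponential fit: tau1 = 751 ps, tau2 = 2899 ps, alpha1 = 0.623, C = 0.00, chi2_red = 0.962

print(compare_branches(result, medf))
#> phasor vs MEDF consistency
#>   tau1: 800 vs 751 ps (6.6% apart)
#>   tau2: 2817 vs 2899 ps (2.8% apart)
#>   alpha1_phasor = 0.290 vs f1(alpha1_MEDF = 0.623) = 0.300 (|diff| = 0.011)
#>   branches agree within tolerance
```

Both routes recover the simulated lifetimes; the phasor lever fraction
(0.290) and the intensity fraction implied by the MEDF amplitudes (0.300)
agree with the simulated 0.30, and the elongated ellipse (`a/b ≈ 6`)
correctly diagnoses a bi-exponential cloud. The remaining ~7% bias on the
uncalibrated phasor τ₁ is the discretisation/IRF bias of the truncated
transform; calibrating against a reference dye of known lifetime
(`phasor_pipeline(..., reference_cube =, reference_tau =)`) removes most of
it. `plot_phasor(cloud, result)` draws the cloud, semicircle, fitted line,
intersections and ellipse.

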