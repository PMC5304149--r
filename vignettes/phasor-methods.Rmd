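---
title: "Phasor and multi-exponential analysis of TCSPC FLIM data: methods and design"
author: "flimphasor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor and multi-exponential analysis of TCSPC FLIM data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimphasor)
```

## The measurement and the two analysis routes

A TCSPC FLIM measurement is a cube of photon counts: for each pixel, a
histogram of photon arrival times over `n` time channels spanning (part of)
one laser repetition period `T`. For NADH autofluorescence the decay is well
approximated by two exponential components — free NADH with a short lifetime
(τ₁, ~0.3–0.8 ns) and protein-bound NADH with a long one (τ₂, ~1–6.5 ns) —
and the balance of the two tracks the glycolysis / oxidative-phosphorylation
balance of the cell.

Two standard routes extract lifetimes and contributions from such data:

1. **MEDF** fits `I(t) = C + Σᵢ αᵢ e^{−t/τᵢ}` per pixel by iterative
   weighted least squares; α₁ is an *amplitude* fraction.
2. **The phasor approach** maps each pixel to
   `(G, S) = (⟨cos ωt⟩_I , ⟨sin ωt⟩_I)` at `ω = 2πk/T` and works
   geometrically in the (G, S) plane; its lever-rule α₁ is a *fractional
   intensity*. The two are linked by `f₁ = α₁τ₁/(α₁τ₁ + α₂τ₂)`, and
   `compare_branches()` checks that link.

This vignette records the numerical choices behind the implementation, why
they were made, and what the synthetic validation does and does not show.

## The discrete phasor transform

`pixel_phasor()` sums over a window of `round(window_fraction · n)` channels
with time measured from the window start at channel centres,
`t_i = (i − ½)Δ`. Two properties drive the defaults:

* **One-cycle windows.** If the window spans exactly one cycle of harmonic
  `k` (k = 2 with the first half period, k = 4 with the first quarter), the
  *continuous* windowed transform of an exponential starting at the window
  equals the closed form `G + iS = 1/(1 − iωτ)` exactly — the truncation
  error vanishes because `e^{iωt}` completes full cycles inside the window.
  The defaults follow this pairing (k = 2, half period, the configuration
  used for cell measurements; k = 4 with the first quarter suits short-lived
  dyes). Any `(k, fraction)` pair is accepted.
* **Channel-centre sampling.** Midpoint sampling of channel-integrated
  counts multiplies the transform by `≈ (ωΔ/2)/sin(ωΔ/2)` — a real,
  lifetime-independent factor (0.16% at k = 2 with 64 channels) — plus a
  small lifetime-dependent remainder. Reference calibration (below) removes
  the common factor; the remainder is covered by the documented tolerance of
  0.02 on the on-circle property at 64 channels.

**Window start.** The window defaults to starting at the channel of the
pooled-intensity peak, which excludes the instrument-response rising edge;
a fixed channel index can be given instead. `phasor_pipeline()` resolves the
window *once, from the sample*, and reuses it for the reference: a
one-channel difference in window start is a phase jump of `2πk/n` radians
(0.39 rad at k = 4, n = 64), far larger than any other error in the chain,
so sample and reference must share the window exactly.

**Baseline subtraction is off by default.** The natural per-pixel background
estimate — the minimum count before the rising edge — is dominated, in a
repetitive excitation with no true background, by the *wrapped tail* of the
previous pulse, which is signal, not background. Subtracting it distorts the
modulation of long-lifetime components enough to move the far circle
intersection by several percent. The option remains (`baseline_subtraction =
TRUE`) for data with genuine constant background (room light, dark counts);
with backgrounds up to 5% of the peak channel it changes recovered lifetimes
by well under 1% (tested).

**Thresholding** keeps pixels whose *total* intensity reaches 30% of the
brightest pixel's (configurable); pixels are used unweighted and unbinned.

**Calibration.** `calibrate_cloud()` multiplies every point by the complex
factor mapping the reference cloud's mean onto the closed-form phasor of the
reference's known lifetime. This exactly removes any effect that enters the
transform as a common complex factor — the IRF phase/modulation at the
transform frequency and the discretisation factor above. What it cannot
remove is the residual lifetime-*dependent* part of the discretisation and
window-truncation bias; with a 2 ns reference and a 2.5 ns sample at k = 4
this residual is ≈ 0.5–1%, within the ±0.05 ns validation band. A reference
with a lifetime of the same order as the sample keeps this residual small.

## Phasor-plane geometry

* **TLS line.** The fitted line is the principal axis of the centred (g, s)
  covariance — the exact orthogonal-regression solution, treating errors in
  G and S symmetrically, with no iteration. Clouds with equal principal
  spreads (isotropic) have no defined direction and raise an error rather
  than returning an arbitrary axis.
* **Circle intersections.** The line–circle quadratic is solved exactly;
  intersections with `s < 0` (non-physical for decays) are discarded, and
  tangency or a miss raises a staged error. The larger-g intersection is the
  short-lifetime component (lifetime grows counter-clockwise along the
  semicircle), so `τ₁ < τ₂` holds by construction; `τ = s/(gω)`, and an
  intersection with `g ≤ 0` is reported as an unbounded lifetime.
* **Lever rule.** The unweighted mean phasor (the description of the
  projection uses *all data points*, with no intensity weighting) is
  projected orthogonally onto the chord; `α₁ = |proj − p₂|/|p₁ − p₂|`,
  clipped to [0, 1] with a boundary flag when noise pushes the projection
  outside the chord. The β indices follow the lever-rule orientation — α₁
  *grows* as the cloud approaches the short-lifetime intersection — because
  that is the direction in which a rise of the free-NADH fraction must move
  the statistic (and matches the MEDF cross-check); the literal alternative
  (β measured *from* each intersection, which reverses the direction) is
  available via `orientation = "literal"`.
* **Window-truncation correction of α₁.** With a half- or quarter-period
  window, the lever measures the *in-window* intensity fraction; a 2.9 ns
  component loses ~11% of its photons beyond a half-period window, inflating
  the raw lever by ~2 points. Since the fitted lifetimes are known at that
  stage, `analyze_cloud()` divides each lever weight by the component's
  in-window photon fraction (computed from `decay_shape()`), reporting a
  whole-decay fractional intensity. The raw lever remains available in the
  `contribution` element, and `contributions()` itself is the pure lever.
* **Confidence ellipse.** Eigen-decomposition of the sample covariance with
  semi-axes `√(λᵢ · q)`, `q = qchisq(coverage, 2)` (5.991 at 95%) — the
  standard bivariate-normal coverage ellipse. The ratio `a/b ≥ 1` is the
  shape metric: a pure dye's shot-noise cloud gives ratios near 1 (isotropic
  Poisson scatter is only mildly anisotropic), a genuine two-component
  spread elongates along the chord.
* **Mono-exponential fallback.** `analyze_cloud()` reports the single
  mean-phasor lifetime instead of the full chain when the cloud looks
  mono-exponential: ellipse ratio below 1.5 (a compact dye cluster measures
  ~1.1; two-component clouds with realistic heterogeneity measure ≫ 2), an
  ambiguous TLS direction, or a line that misses the circle.

## MEDF implementation

The model is `C + A·(f₁ D(t; τ₁) + (1 − f₁) D(t; τ₂))` with `D` the
unit-area channel-integrated single-exponential shape, optionally convolved
with the IRF (circular convolution when the decay wraps the period, linear
otherwise). Parametrising the mixture by the intensity fraction `f₁` keeps
the shapes normalised; the reported `α₁` is the exact amplitude conversion
`αᵢ ∝ fᵢ/τᵢ`, so `α₁ + α₂ = 1` identically. Lifetimes are box-constrained to
[10, 10000] ps — the physical NADH range with margin — and the optimiser is
`minpack.lm::nls.lm` (Levenberg–Marquardt trust region) started from three
deterministic `(τ₁, τ₂)` pairs, (300, 2000), (600, 3000) and (800, 5000) ps,
keeping the best final χ²; lifetimes are sorted and the fraction relabelled
after convergence.

Two defaults differ from the plainest textbook recipe, both for measured
reasons:

* **The offset floats.** Commercial fitting software fixes the offset at the
  pre-rise minimum. With a period-wrapped model that value is wrapped-tail
  signal, and fixing `C` there over-subtracts: on correctly specified
  synthetic data it drove reduced χ² to ~10³ and biased τ₂ by ~−19%. The
  default is therefore `offset = "float"` (`C ≥ 0` as a fifth parameter,
  which recovers `C = 0` on background-free data); `offset = "estimate"`
  (fixed at `estimate_offset()`, the pre-rise minimum) and numeric fixing
  remain available.
* **Two-pass weighting.** Pure Neyman weights (`1/max(count, 1)`) bias
  amplitude fractions by ≈ −2.4 points at 10⁴ photons per pixel (downward
  count fluctuations get overweighted). The default refits once with
  Pearson weights from the first pass's fitted model, cutting the bias to
  ≈ −0.9 points; `weights = "neyman"` restores the single pass.

Without an IRF the fit is a tail fit from the peak channel; with one, the
full histogram is fitted. A fit is flagged `effectively_mono` when the
amplitude fraction reaches a bound or the two lifetimes collapse within 5%.
`fit_cube()` applies the intensity threshold, optionally fits a
deterministic evenly spaced pixel subsample (`max_pixels`), and aggregates
converged pixels as mean ± SD; `pooled_decay()` provides the
high-statistics summed histogram for whole-image fits.

## The simulator and what validation shows

`simulate_cube()` draws independent Poisson counts around the exact
expectation: unit-area channel-integrated exponential shapes, mixed by
fractional intensity, circularly convolved with a channel-sampled Gaussian
IRF (default FWHM 250 ps, centred 1.25 ns into the period — a typical
two-photon TCSPC response), wrapped over the repetition period, scaled to
the photon budget, plus constant background. Component fractions are
specified as *intensities* (what the lever measures); the ground-truth
record also carries the implied amplitude fractions, so both branches have
unambiguous truth. Fixed seeds give bit-identical cubes.

Default study conditions used by the validation suite:

* Acquisition: `T = 12.5` ns (80 MHz Ti:Sapphire), 64 channels — the period
  is a configurable default, not a constant.
* Dye validation: mono-exponential τ = 2.5 ns (the literature coumarin-6
  lifetime), 64 × 64 pixels at 10⁴ photons/pixel (≈ 4×10⁷ total — a bright
  dye solution), analysed at k = 4 over the first quarter period and
  calibrated against a same-IRF 2 ns reference; recovery within ±0.05 ns.
* NADH-like mixtures: τ = (750, 2900) ps, fractional intensities 0.25–0.35,
  10⁴ photons/pixel, 64 × 64. A cube whose pixels all share one mixture
  produces a pure noise blob in the phasor plane, from which no line
  direction is recoverable; real tissue is metabolically heterogeneous, so
  the fixtures use a two-region pattern with the component-1 fraction offset
  by ±0.06 between image halves, letting each image determine its own chord
  as a per-image analysis does. Recovery targets: both lifetimes within 5%,
  fractions within 2 points, for both branches (the MEDF check uses the
  pooled histogram; per-pixel fits at this budget carry the ~1-point
  residual weighting bias described above).
* Metabolic-shift pairs: fractional intensity 0.30 → 0.36 (cyanide-like
  rise of free NADH) and 0.30 → 0.24 (peroxide-like fall), 16 × 16 pixels at
  2×10³ photons/pixel; the sign of Δα₁ must match the direction of the
  fraction change in ≥ 95% of 100 seeded replicates.

Problem sizes (64 × 64 cubes, pooled MEDF fits, 100 shift replicates,
150-pixel MEDF subsamples) were chosen so the full suite exercises realistic
image scales while remaining a desk-scale computation.

What passing these tests shows: the transform, geometry, correction and
fitting chains are mutually consistent and recover known ground truth under
Poisson statistics with a Gaussian IRF. What they do not show: behaviour
under afterpulsing, pile-up, detector IRF asymmetry, spectral bleed-through
(e.g. NADPH), spatial binning effects, or drift — none of which the
simulator models; the simulator also treats pixels as independent, with no
optical cross-talk.

## Degenerate inputs and numerical edges

* Empty summation window after thresholding → pixel excluded silently
  (`NA` from `pixel_phasor()`); no pixel above threshold → an error naming
  the threshold.
* Coincident or isotropic clouds → TLS errors; collinear clouds → a
  degenerate-ellipse error reporting the offending eigenvalue.
* Line tangent to (discriminant < 10⁻¹²) or missing the circle, or with
  fewer than two intersections at `s ≥ 0` → staged errors;
  `analyze_cloud()` converts these to the mono-exponential fallback.
* `g ≤ 0` points or intersections → unbounded-lifetime reporting (`Inf`
  with a warning), never a silent negative lifetime.
* Fits with fewer residuals than parameters are rejected; non-convergence
  is flagged (`converged = FALSE`) and excluded from cube aggregates.

## Known limitations

* The α₁ window-truncation correction uses IRF-free in-window fractions;
  with very broad IRFs relative to the window it under-corrects slightly
  (≈ 0.5 points at the default conditions).
* Single-reference calibration cannot remove lifetime-dependent
  discretisation bias (see above); at 64 channels this limits absolute
  single-pixel accuracy to ~1% even noiselessly.
* The MEDF branch is a per-pixel (or pooled) independent fitter: no global
  multi-pixel linking, no more than two components, and no replication of
  proprietary binning/shift heuristics of commercial packages — equivalence
  is asserted on synthetic ground truth only.
* Vendor `.sdt` files are recognised but not parsed; convert to TIFF
  time-stacks first.
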