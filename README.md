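# deerfit

Distance-distribution analysis for pulsed dipolar EPR (four-pulse
DEER/PELDOR) and short-range dipolar CW-EPR, written for spin-labeling
studies of protein conformational equilibria — the motivating system being
the Ca-dependent structural states of calmodulin (compact 2.6 nm, closed
4.3 nm, open 5.7 nm inter-label distance) free and bound to the RyR
calmodulin-binding peptide.

## What it computes

A DEER echo decay is modeled as
`V(t) = [1 − λ + λ·F(t)]·B(t)` with background `B(t) = exp(−k·t^(d/3))`,
modulation depth λ, and form factor `F(t) = ∫ K(t,r) P(r) dr`, where the
orientation-averaged dipolar kernel is

    K(t,r) = ∫₀¹ cos[(1 − 3z²)·ω(r)·t] dz,   ω(r) = 2π·52.04 MHz·(r/nm)⁻³,

evaluated in closed form with Fresnel integrals. On top of that forward
model the package provides:

* **Background fitting, correction and validation** — log-linear tail
  fits of (λ, k), systematic variation of the fit window with tracking of
  every distribution mode, flagging of background-dependent ("unstable")
  populations, and their suppression by folding into the background model.
* **Tikhonov inversion** — non-negative, second-derivative regularized,
  smoothing parameter chosen by L-curve curvature and leave-one-out
  cross-validation (both always logged).
* **Sum-of-Gaussians parameterization** — multistart Levenberg–Marquardt
  fits of the corrected waveform in the time domain, seeded from the
  Tikhonov distribution; BIC model-order selection; error-surface
  (profile-SSR) uncertainty intervals. This is where population mole
  fractions come from.
* **Dipolar CW-EPR** — Pake-pattern broadening kernels, absorption-domain
  convolution conserving the double integral, and fits of coupled spectra
  against a non-interacting reference for 0.8–2.0 nm distances.
* **Nitroxide mobility** — rotational correlation time
  `τ_R = 0.54 ns · [1 − T∥′/T∥]^(−1.36)` and order parameter
  `S = (T∥′ − T₀)/(T∥ − T₀)` from outer-extrema splittings.
* **Synthetic data** — generators for the four calmodulin study
  conditions (85/15, 29/28/44, 75/25, 97/3 population mixtures) with
  known ground truth, used by the test suite to validate the whole chain.

File formats: two-column ASCII traces/spectra/distributions, a minimal
Bruker BES3T (`.DSC`/`.DTA`) reader, JSON reports, YAML-configurable CLI
(`inst/cli/deerfit` with `simulate`, `analyze`, `cwfit`, `mobility`,
`fixture` subcommands).

## Worked example

Simulate the Ca-saturated calmodulin condition (three states populated
29/28/44, SNR 50, 6 µs evolution) and run the full pipeline:

```r
library(deerfit)

cond <- condition_fixture("CaCaM", snr = 50, seed = 1)
fx   <- make_deer_fixture(cond, default_time_grid(6))
res  <- analyze_deer(fx$trace, n_components = 3, rng_seed = 1)
print(res)
```

```
DEER analysis
=============
Background model: k = 0.04258 /us, lambda = 0.320, dimension = 3.00
Noise estimate: 2.06e-02
Tikhonov inversion: alpha = 5.22 (chosen by loocv; L-curve 1.51e+03, LOOCV 5.22)
Distance distribution: 181 points, 1.00-10.00 nm
Modes:
 center height fraction    sd   lo    hi
   2.60 0.1971   0.2617 0.476 1.00  3.45
   4.25 0.2088   0.2286 0.368 3.45  4.75
   5.70 0.3945   0.4402 0.417 4.75  6.75
   8.00 0.0665   0.0695 0.384 6.75 10.00

Selected fit:
Sum-of-Gaussians fit: 3 component(s), RMSD 2.107e-02, BIC -2843.4
Gaussian distance components:
 center   fwhm fraction  sigma
  2.637 0.9459   0.2699 0.4017
  4.241 0.9654   0.2751 0.4100
  5.691 1.0313   0.4550 0.4380
```

Reading the output: the background fit recovered the simulated decay
(k = 0.05 /µs, λ = 0.3) from the trace tail; the model-free Tikhonov
distribution already shows the three states near 2.6/4.3/5.7 nm (plus a
small long-distance ripple that the stability validation would flag); and
the parametric fit returns the three centers within ~0.06 nm and the mole
fractions 0.27/0.28/0.46 against the planted 0.29/0.28/0.44 — the kind of
agreement the test suite demands (±0.07 on fractions averaged over seeds).

The mobility functions are direct:

```r
rotational_correlation_time(0, 30)   # motional-averaging limit -> 0.54 ns
order_parameter(20, 32, 8)           # -> 0.5
```

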