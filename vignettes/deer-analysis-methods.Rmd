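---
title: "Models and methods behind deerfit"
author: "deerfit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deerfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerfit)
```

# Scope

`deerfit` analyzes pulsed dipolar EPR (four-pulse DEER/PELDOR) and
rigid-limit CW-EPR data from spin-labeled proteins. The package grew out of
the problem of resolving the Ca-dependent lobe-arrangement states of
calmodulin — compact (2.6 nm), closed (4.3 nm) and open (5.7 nm)
inter-label distance — and of the calmodulin/RyR-peptide complex, and its
synthetic-data module deliberately emulates those four experimental
conditions. Everything here is, however, generic DEER/CW machinery.

# The forward model

A DEER echo decay is modeled as

$$V(t) = \left[1 - \lambda + \lambda F(t)\right] B(t),$$

where $\lambda$ is the modulation depth (the fraction of the echo modulated
by the pumped partner spin), $B(t) = \exp(-k\,t^{d/3})$ the intermolecular
background from remote spins ($d = 3$, a plain exponential, for
homogeneous solutions), and the form factor

$$F(t) = \int K(t, r)\,P(r)\,\mathrm{d}r$$

carries the distance information through the orientation-averaged dipolar
kernel

$$K(t, r) = \int_0^1 \cos\!\left[(1 - 3z^2)\,\omega_{dd}(r)\,t\right]
\mathrm{d}z, \qquad
\omega_{dd}(r) = \frac{2\pi D}{r^3},$$

with the dipolar constant $D = 52.04\ \mathrm{MHz\,nm^3}$ for a
free-electron-like pair ($g \approx 2.0023$), defined in exactly one place
in the package. The kernel is evaluated in closed form with Fresnel
integrals; a 1001-point Gauss–Legendre quadrature route is kept as a
cross-check and the two agree to better than $10^{-6}$ (tested; in
practice they agree near machine precision).

Distance distributions are either free-form on a grid or sums of Gaussians

$$\rho_j(R) = \frac{1}{\sigma_j\sqrt{2\pi}}
\exp\left(\frac{-[R - R_j]^2}{2\sigma_j^2}\right), \qquad
\sigma_j = \frac{\mathrm{FWHM}_j}{2\sqrt{2\ln 2}},$$

with mole fractions $x_j$. Units are fixed package-wide: nm for distance,
µs for time, Gauss for field; conversions happen only at I/O boundaries.

Default grids: distance 1–10 nm in 0.02 nm steps for forward simulation;
time steps of 16 ns. The inversion and fitting stages default to a 0.05 nm
grid — at the achievable distance resolution of the technique nothing is
gained below that, and the kernel matrices stay small. Gaussians clipped by
the grid (< 0.1 % of mass) are silently renormalized; larger clipping warns
first.

# Background correction and its validation

The tail of $V(t)$, by default the latest 2/3 of the trace, is fit by
linear least squares on the log amplitude, yielding $k$ and $\lambda$
simultaneously for fixed $d$ (optionally profiling $d$). Correction then
inverts the signal model:
$\hat F(t) = (V/B - (1 - \lambda))/\lambda$, rescaled to $\hat F(0) = 1$.
The fit is scale-invariant (amplitudes are normalized to $V(0)$ first).

Because the fit window inevitably contains residual form-factor decay, the
recovered $(\lambda, k)$ carry small first-order errors. Two places absorb
them:

* the time-domain Gaussian fit floats a modulation-depth rescale
  $\Lambda$ and a linear baseline slope $c$ (model
  $1 - \Lambda + \Lambda\,(KP)(t) + c\,t$), which is exactly the
  first-order expansion of a mis-estimated $(\lambda, k)$ pair and leaves
  the shape parameters unbiased;
* the stability validation repeats fit → correction → inversion over a
  grid of background fit starts (default 10 starts between 1/3 and 3/4 of
  $t_{\max}$) and tracks every distribution mode across runs. Modes whose
  mole fraction varies by more than 50 % (relative), or that appear in
  only some runs, are flagged unstable. The 50 % default is a package
  choice; the quantity is a diagnostic, not a hypothesis test.

Flagged modes that are well separated from stable ones (no overlap at
2σ) can be *suppressed*: their dipolar signal is folded into the
background, $B'(t) = B(t)[1 - \lambda_u + \lambda_u F_u(t)]$ with
$\lambda_u = \lambda x_u$, and the correction repeated. This is first-order
exact and leaves stable peak centers unchanged within a grid step
(tested). Suppression refuses to touch modes overlapping real
populations.

# Tikhonov inversion

The model-free distance estimate solves

$$\min_{P \ge 0}\ \|K P - \hat F\|^2 + \alpha^2 \|L_2 P\|^2$$

with $L_2$ the second-difference operator with reflective (Neumann)
boundary rows, so edge densities are not over-penalized. Non-negativity is
enforced by a deterministic active-set solver on the normal equations
(warm-started across the $\alpha$ scan, smooth-to-rough); the solution is
renormalized to unit area.

The smoothing parameter is scanned over 40 log-spaced values,
$10^{-4}$–$10^4$, and chosen by two criteria that are both always
computed and logged:

* **L-curve**: maximum curvature of the log–log (residual norm, seminorm)
  curve across the scan; degenerate curvature-free curves raise a warning
  and fall back to LOOCV.
* **LOOCV**: mean held-out squared prediction error of the unconstrained
  Tikhonov smoother, computed with the hat-matrix identity
  $e_i = (F_i - \hat F_i)/(1 - H_{ii})$, which is algebraically identical
  to refitting with each point left out (tested to $10^{-8}$ against
  explicit refits).

When the two disagree, LOOCV wins by default; both values are recorded in
the result and the report so the disagreement is visible. The constrained
and unconstrained problems differ, so LOOCV selection is a heuristic on
the linear smoother — the standard practice, and the reason the L-curve is
retained alongside it.

# Sum-of-Gaussians parameterization

Mole fractions come from fitting the corrected waveform *in the time
domain*: the model form factor is the kernel image of the Gaussian
mixture, and centers, FWHMs and fractions are optimized by
Levenberg–Marquardt least squares. Design choices:

* **Multistart** ("Monte Carlo" fitting): the initialization comes from
  the modes of the Tikhonov distribution; 32 restarts (default) redraw it
  with 10 % Gaussian jitter. Components the seed could not supply are
  redrawn globally (centers uniform in 1.8–6.5 nm) so the search is not
  trapped in the seed's neighborhood; grid-edge seed modes are discarded
  as inversion artifacts. Everything is driven by one RNG seed and is
  bit-reproducible.
* **Bounds**: centers 1.5–9 nm, FWHM 0.2–3 nm — wide, and intended only
  to stabilize near-limit components. Fractions live on the simplex via
  stick-breaking, so they always sum to 1.
* **Pruning**: components below fraction 0.01 are removed (logged) and
  the rest renormalized.
* The background is *not* refit jointly by default (only the
  $\Lambda, c$ nuisance pair above); the corrected trace remains the
  object being explained.

Model order is selected by the Bayesian information criterion,
$\mathrm{BIC} = n\ln(\mathrm{SSR}/n) + p\ln n$ with $p = 3n_c - 1$ free
shape parameters (+2 for the nuisance pair), with the additional
acceptance rule that the chosen parametric fit must reach within 1.1× the
Tikhonov RMSD — a parametric model that fits much worse than the
model-free inversion is rejected regardless of its BIC.

Uncertainties come from the error surface: each parameter is profiled on
a grid about its optimum with all others refit, and the interval reported
where $\mathrm{SSR} \le \mathrm{SSR}_{\min}(1 + F_{1,n-p}(q)/(n-p))$ at
confidence $q$ (default 68 %). Intervals are asymmetric; a side that
reaches its bound is reported one-sided. The $\Delta\chi^2$ convention is
a package choice (an F-statistic at 1 degree of freedom), stated here
because conventions differ between software packages.

# Dipolar CW-EPR and mobility

Short distances (0.8–2.0 nm) broaden rigid-limit CW spectra beyond what
DEER can see. The package models the coupled spectrum as a mixture of a
measured non-interacting reference $S_0$ and its Pake-broadened images:

$$S(B) = (1 - f_c) S_0(B) + f_c \sum_j x_j\,[S_0 * k_{r_j}](B),$$

where $k_r$ is the powder-averaged dipolar doublet (lines at
$\pm(3\cos^2\theta - 1) D(r)/2$, $D(r)$ in field units at the nitroxide
isotropic $g = 2.0056$), averaged over the Gaussian distance density.
Convolution happens in the absorption domain (FFT, 4× zero padding, 5 %
cosine edge taper) and conserves the double integral — spin count — to
$10^{-6}$. All spectra are normalized to their double integral before
analysis. The package does not simulate slow-motional nitroxide
lineshapes; the reference spectrum is an input (the synthetic CW fixture
uses a fixed three-line rigid-limit-like triplet, documented as synthetic
in its generator).

Probe mobility uses the outer-extrema splitting $T_\parallel'$ of the
CW spectrum:

$$\tau_R = a\left[1 - T_\parallel'/T_\parallel\right]^{b},
\quad a = 0.54\ \mathrm{ns},\ b = -1.36,$$

$$S = \frac{T_\parallel' - T_0}{T_\parallel - T_0},$$

with $T_\parallel$ the rigid-limit and $T_0$ the fast-limit splitting.
The order-parameter expression is the standard motional-averaging form,
interpolating between the fast limit ($S = 0$) and the rigid limit
($S = 1$); a denominator of $T_\parallel' - T_0$ sometimes seen in print
is a typographical degeneracy (it is identically 1) and is not used.

# The synthetic-data module

`condition_fixture()` ships the four study conditions with their reported
populations: apoCaM 85/15 (closed/compact), CaCaM 29/28/44
(compact/closed/open — the reported values sum to 1.01 and are
renormalized, with a note), apoCaM/RyRp 75/25 and CaCaM/RyRp 97/3. All
components default to FWHM 1.0 nm, matching the width used for the
predicted-waveform simulations.

Values the source experiments never published are fixed package defaults,
chosen once as plausible Q-band numbers and documented here: modulation
depth $\lambda = 0.3$, background $k = 0.05/\mu s$, $d = 3$, evolution
5 µs (6 µs when the open state must be resolved), step 16 ns.

**Noise convention.** `snr` is quoted against the *dipolar modulation
amplitude*: white Gaussian noise with
$\sigma = \lambda V(0)/\mathrm{snr}$ is added to $V(t)$. This is the
natural reference for distance analysis — after background correction the
form-factor noise is then $\approx 1/\mathrm{snr}$ at $t = 0$ — and it is
what makes "SNR 50" a regime where a 15 % population is confidently
recoverable. (Quoting against the full echo amplitude would make the same
label a 5× noisier regime in which a 15 % state at 2.6 nm is a ~3.5σ
feature and per-seed recovery necessarily fails; that detectability
calculation is reproduced by the package's tests indirectly through what
they do and do not assert.)

What the generator does *not* emulate — and hence what passing tests do
not show about real data: orientation selection, incomplete excitation of
short-distance pairs (the known error source for ≤ 3 nm populations),
ESEEM/2+1 artifacts, multi-spin effects, and phase noise. Fixtures are
white-noise idealizations of the stated conditions.

# Numerical and testing choices

* Problem sizes in the validation suite: 10 seeds per condition, 16
  multistart restarts in the multi-seed sweeps (32 remains the
  single-fit default), 0.05 nm inversion grid — chosen to keep the whole
  suite comfortably fast on one CPU while leaving every recovery
  tolerance intact.
* The NNLS solver is cross-checked against an independent implementation
  (`pracma::lsqnonneg`); the kernel against brute-force orientation
  averages; LOOCV against explicit refits; BIC against its arithmetic
  definition; the Pake kernel against its analytic second moment
  ($D^2/5$, hence the $r^{-6}$ ratio of 64 between $r$ and $2r$).
* Degenerate inputs are contracts, not crashes: flat form factors flag
  edge mass, $\lambda = 0$ refuses correction, identical CW spectra
  return 100 % non-coupled with a warning, rigid-limit splittings make
  $\tau_R$ diverge to `Inf` with a warning.

# Known limitations

Fractions for states near the DEER sensitivity edges (≤ 3 nm, or long
distances relative to the evolution window) are intrinsically less
certain than centers; the error surface and the background-stability
report are the honest way to read them. For near-degenerate three-state
problems the least-squares fraction estimator is also heavy-tailed: in a
minority of noise realizations the global optimum merges two adjacent
states into one wide component (the merged and separated basins differ by
less than the noise level in SSR), so population numbers should be
averaged over replicates or read with the profile intervals, never from a
single trace. The CW module's reference
spectrum must come from a matched singly-labeled sample; it is not
simulated. The L-curve/LOOCV disagreement policy (LOOCV wins) is a
default, not a theorem.
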