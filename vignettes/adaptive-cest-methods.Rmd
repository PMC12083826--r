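---
title: "Adaptive Bayesian design of CEST experiments: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Bayesian design of CEST experiments: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivecest)
```

# The problem

Chemical exchange saturation transfer (CEST) NMR reveals sparsely populated
("invisible") conformations of proteins: a weak radio-frequency field
saturates the spectrum at an offset `omega_rf`; when that offset hits the
resonance of a minor state B in slow exchange with the visible major state
A, saturation is transferred through exchange and the visible A peak loses
intensity.  A CEST profile therefore shows a large dip at the A resonance
and a small dip at the (otherwise undetectable) B resonance.

Each measured point of a profile is a full 2D spectrum, so measurement time
is the binding resource, and most of a conventional, evenly spaced offset
sweep is spent far from either dip where little is learned.  At low
signal-to-noise ratio, the problem compounds: repeated sampling of
informative conditions is needed, but which conditions are informative
depends on parameters — above all the minor-state shift `omega_b` — that
are unknown before the experiment.

This package implements a closed-loop answer: after every measurement,
re-estimate the per-residue exchange parameters by MCMC, score every
candidate irradiation condition by the mutual information between its
predicted outcome and the parameters, and measure next wherever that
expected information gain is largest.

# The forward model

Each residue is a two-state exchanging ^15^N spin described by seven
parameters: minor population `p_b`, exchange rate `k_ex` (s^-1^), minor
shift `omega_b` (Hz), longitudinal rate `r1` (shared by both states — CEST
data carry no information on a separate minor-state `r1`), transverse
rates `r2a`, `r2b` (s^-1^) and the basal intensity `i0`.  The major-state
shift `omega_a` is read off the spectrum and fixed.  A candidate condition
is the triple (`omega_rf`, `omega1`, `t_ex`): saturation offset, strength
and duration; the *reference* experiment (0, 0, 0) measures `i0` directly.

Magnetization evolves under the Bloch–McConnell equation dM/dt = L M for
M = (MxA, MyA, MzA, MxB, MyB, MzB), with per-state rotation about z by the
offset, nutation about x by the saturation field, relaxation, and exchange
coupling `k_ab = k_ex p_b`, `k_ba = k_ex (1 - p_b)`.  Because the prepared
^15^N polarization in a proton-enhanced experiment dwarfs the thermal
equilibrium, the thermal-recovery term is dropped (the
`bloch_mcconnell_matrix(m_eq=)` argument restores it if wanted); the
off-resonance intensity then decays as `i0 exp(-r1 t_ex)`, which is what
the experiment shows.

Three routes compute the intensity after saturation:

* **exact** — matrix exponential of `L t_ex` applied to the prepared
  magnetization (the package's oracle; used by the virtual spectrometer).
* **eigen** — the spin-locked-mode approximation
  `y = i0 A exp(-R1rho t_ex)`, with `R1rho` the negative real part of the
  eigenvalue of `L` belonging to the spin-locked mode, and `A` that mode's
  amplitude in the detected A-state z-magnetization.
* **fast** — the same quantity without a full eigendecomposition: a
  first-order rotating-frame rate (ground-state tilt with a
  Trott–Palmer-type exchange term) seeds a Rayleigh-quotient iteration,
  which converges to the spin-locked eigenvalue in a handful of 6×6
  solves; the left eigenvector, obtained by one inverse iteration on the
  transposed system, gives the amplitude `A` for free.

## Which eigenvalue is "R1rho"?

Writing the spin-locked start `n` (the unit vector along the A-state
effective field) in the eigenbasis, the locked-projection signal is
`g(T) = sum_j c_j exp(lambda_j T)` with amplitudes summing to exactly 1.
The package selects the mode whose amplitude is closest to unity — the
mode a spin-lock experiment actually reads out, since a dominant mode
must carry nearly all of the unit total, while `|c_j| > 1` values are
near-cancelling artifacts of the non-normal `L`.  A tempting
alternative, picking the eigenvector with the largest direct overlap
with `n`, is unstable: for slow exchange (`k_ex` comparable to the
relaxation rates) two real modes with well-separated eigenvalues can
both have overlap above 0.95 with `n` because eigenvectors of a
non-normal matrix need not be orthogonal, and the choice then flips on
sub-percent overlap differences.

The same physics limits *any* single-rate description: at prior-box
corners with `k_ex ~ R1rho` the locked-frame decay is irreducibly
biexponential with near-equal amplitudes.  The fast route therefore
computes its mode's amplitude and falls back to the full eigendecomposition
whenever that amplitude strays from unity (outside [0.9, 1.02] — about 2%
of prior-box-by-grid cases), and the decay-fit oracle in the test
suite only compares rates where the exact decay is single-exponential
(log-residual below 1e-3 on both an early and a late fitting window, with
consistent slopes).  Intensities — the quantity the likelihood actually
uses — remain accurate throughout: over prior-box draws crossed with the
standard offset grid, the fast intensity sits within 0.03 `i0` of the
exact propagation for well over 95% of conditions, with a median error
orders of magnitude below that.

## The amplitude factor

The textbook spin-lock projection uses `A = cos^2(theta_A)` with
`theta_A` the ground-state tilt angle.  That is the first-order expansion
of the exact one-mode amplitude in `p_b` and the exchange couplings; since
the left/right eigenvector pair is already available in both approximate
routes, the package uses the exact amplitude instead.  The two agree far
off resonance and the exact version markedly reduces the model error near
resonances, which matters because the likelihood treats the approximation
as exact.  Saturation times below 0.5 s violate the assumption that
transverse magnetization in the tilted frame has decayed, so approximate
methods warn below that floor and candidate grids start at 0.5 s.

# Inference

Priors are independent and uniform on either the natural or the log scale:
`p_b` [0, 0.1] linear, `k_ex` [5, 1000] s^-1^ log, `omega_b`
[-1000, 1000] Hz linear, `r1` [0.1, 10] s^-1^ log, `r2a/r1` [1, 100] log,
`r2b/r1` [1, 1000] log, `i0` [0.1, 10000] log.  The transverse rates are
parameterized as ratios to `r1` (as the box suggests) and reported as
absolute rates.  The noise SD `sigma` is a known input, estimated upstream
from the spectral background, never inferred.

Sampling is adaptive Metropolis with delayed rejection in the
transformed coordinates.  The kernel mixes three reversible components:
an adapted random walk, a second-stage delayed-rejection retry with a
five-fold smaller step whenever the first proposal is rejected (the
two-stage acceptance ratio preserves detailed balance), and, with 5%
probability, an independence proposal drawn uniformly from the prior box
whose acceptance ratio reduces to the likelihood ratio — the component
that lets a chain hop between well-separated minor-shift modes.
Proposals outside the box are rejected, which gives exact uniform-prior
semantics (no reflection).  During the first half of burn-in a
Robbins–Monro recursion drives a scalar step size towards ~28%
acceptance while the chain finds the posterior bulk; during the second
half the proposal covariance is learned from the chain (scaled by
2.38²/7 with a small diagonal jitter) and the scale re-tuned; both freeze
at the end of burn-in.  Learning the covariance only from the second
half matters: including the initial transient inflates the proposal and
collapses acceptance on concentrated posteriors.

Two further measures address the multimodal minor-shift posteriors that
low-SNR CEST data produce.  `sample_posterior(n_chains=)` pools several
independently started chains, protecting the credible intervals against
a single chain settling into one basin: on reference-only (unimodal)
data a single chain is statistically consistent with the nominal level
(the test suite measures 66.0% empirical coverage of the 68.3% interval
over 300 replicates, within three binomial standard deviations), while
on informative 44-point profiles pooling four chains is what keeps
coverage at its nominal level.  Inside the design loop, each iteration warm-starts its chain
from the previous iteration's last retained draw, which removes the
burn-in transient and keeps the short in-loop chains effective as the
posterior concentrates.

Two presets mirror the two uses: the in-loop preset (20,000 burn-in,
30,000 steps, thinning 50, hence 600 retained draws) keeps the
between-measurements turnaround short, and the long preset (100,000
burn-in, 1,000,000 steps) serves the detailed post-run analysis.  The MAP
reported by `summarize_posterior()` is the retained draw with the highest
unnormalized posterior density — reproducible, and consistent with how
such estimates are typically displayed — rather than a separate
optimization; credible intervals are central 68.3% marginal quantiles.

# The utility and its estimator

With residues a priori independent, the mutual information between the
next observation vector and all parameters is the sum over residues of
per-residue mutual informations, so each candidate `x` is scored by
`U(x) = sum_k w_k I_k(x)` (weights default to 1; a one-hot weight
refocuses the design on a single residue, and weights may switch mid-run).

For Gaussian noise the per-residue MI has the exact form
`H[predictive] - 0.5 log(2 pi e sigma^2)`, where the predictive density is
the equal-weight mixture of `N(f_s, sigma^2)` over posterior draws `s` and
`f_s` is the fast forward prediction.  The mixture entropy is computed by
Riemann sum on a uniform grid spanning the predictions ±6 `sigma`, refined
beyond the 1001-point default until the cell width is at most `sigma`/4 —
that keeps the quadrature mass within 1e-4 of 1 even for the very spread
predictions of an early, prior-like posterior, at negligible cost once the
posterior has concentrated.  Small negative estimates are clamped to
zero.  The reference condition is scored like any other: its predictions
`f_s = i0_s` vary across draws, so it is informative about `i0`.

Selection is arg-max with exact ties broken uniformly at random (seeded),
avoiding systematic grid-order bias.  After the next observation arrives,
the *realized* information gain is estimated by self-normalized importance
sampling over the same draws, `KL = sum w_s log(S w_s)` with
`w_s` proportional to `N(y_obs; f_s, sigma^2)`.  Its predictive average
equals the mutual information — the identity the test suite verifies both
for the estimators and in closed form on a linear-Gaussian toy — and the
gap between realized KL and MI flags surprising observations (noise
outliers or model misfit) iteration by iteration.

# The loop and the virtual spectrometer

`run_adaptive()` executes: measure (reference first), per-residue MCMC on
all accumulated data, utility over all candidates, arg-max selection;
repeat; then append a long-preset re-analysis.  The audit-trail invariant
— each measured condition equals the arg-max of the previous iteration's
stored utility table — is checked in the tests.  Repetition of a condition
is allowed and simply accumulates replicates in the likelihood, which is
the mechanism by which the design buys precision at low SNR.

The observation provider is an abstraction: the virtual spectrometer
(exact forward model plus Gaussian noise of known `sigma`) is one
provider; a function reading appended CSV rows can stand in for a real
acquisition pipeline.  Spectrometer control itself is out of scope.

The synthetic truth generator emulates a small single-domain protein with
one sparsely populated excited state: `p_b` ~ U[0.01, 0.05], `k_ex` ~
logU[20, 500] s^-1^, `omega_b - omega_a` ~ U[-800, 800] Hz, `r1` ~
U[0.8, 1.5] s^-1^, `r2a/r1` ~ U[5, 20], `r2b/r1` ~ U[10, 200], `i0` ~
U[5, 15], `omega_a` ~ U[-800, 800] Hz, and `sigma = i0/SNR` with SNR 20 —
deliberately narrower than the prior box, as a real protein is.  The
(`omega_a`, `omega_b`) pair is rejection-sampled until `omega_b` lies in
the prior box.  What the generator does *not* emulate: peak overlap and
intensity cross-talk, B1 inhomogeneity, temperature drift, non-Gaussian
or correlated noise, three-state exchange, and residue-correlated
(`p_b`, `k_ex`) — so passing tests demonstrate the machinery under the
stated noise model, not robustness to those real-data effects.

Scenario presets reproduce the standard study layouts: `A1` (one residue,
offsets every 5 Hz in ±1000 Hz, strengths 10/50 Hz, `t_ex` 0.5 s — 803
candidates, SNR 20, 200 iterations), `A2` (variable duration
{0.5, 0.75, 1} s at a single strength), `A3`/`A4` (70 residues, strengths
{6.3, 13, 26.2(, 50)} Hz, durations {0.5, 1} s, 192 iterations), and the
conventional comparators `C4` (63 offsets × 3 strengths + 3 references =
192 measurements at a 32.3-Hz step) and the restricted-offset variants
`C10`/`C11` on [0, 500] Hz.  Where a preset detail is not fixed by the
published layouts, the package makes one choice and keeps it: `A2` uses
25 Hz as its single mid-range strength, `A3`/`A4` reuse the 63-point
offset grid of `C4` for comparability, `C10` keeps the three `A4`
strengths, and `C11` trades strength diversity for offset density (189
offsets at 13 Hz).

# Why the most informative duration tracks 1/R1rho

During saturation the locked intensity decays as `i0 exp(-R1rho t)`.  For
known `i0` and Gaussian noise, the Fisher information about the rate from
a single measurement at time `t` is proportional to
`t^2 exp(-2 R1rho t)`, maximal exactly at `R1rho t = 1`
(`optimal_saturation_time()`).  In runs with the duration as a design
variable, the selected `t_ex` accordingly correlates with the inverse of
the current R1rho estimate — capped by the 0.5-s validity floor and the
candidate list.

# Problem sizes used by the tests

The test suite and the bundled checks run the full algorithms at reduced
problem sizes, chosen so the whole suite completes on a desk machine while
every statistical check retains power; the full-scale presets remain the
package defaults.  Specifically: chain presets of 1,500–8,000 burn-in /
2,000–16,000 steps, pooling up to four chains, instead of the in-loop and long presets; candidate
grids with 25–50-Hz offset steps (83–163 candidates) instead of 5-Hz
steps; design runs of 48–100 iterations with 1–3 residues and 3–5
replicate seeds; calibration over 30 single-residue replicates (210
residue–parameter pairs); and accuracy sweeps over 60–1,000 prior-box
draws crossed with the 802 non-reference members of the `A1` grid.

# Known limitations

* The forward model is strictly two-state; a third state is neither
  modelled nor searched for.
* The approximate intensity inherits the spin-lock projection's blind
  spot: strongly biexponential corners of parameter space (slow exchange
  with comparable rates) are represented by a single dominant mode.
  Intensity errors there remain small in absolute terms but are the main
  residual model error in the likelihood.
* `sigma` is assumed known and constant per residue; mis-specifying it
  miscalibrates both the posterior and the utility.
* The design is myopic (one measurement ahead) and discrete (a fixed
  candidate list); utility per unit measurement time is not modelled, so
  longer durations are not penalized for their longer acquisition.
* Global models sharing `p_b`/`k_ex` across residues are out of scope;
  each residue is estimated independently.
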