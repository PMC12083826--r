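# adaptivecest

Closed-loop Bayesian design of ¹⁵N chemical exchange saturation transfer
(CEST) NMR experiments.

CEST detects sparsely populated, directly invisible protein conformations:
a weak saturation pulse applied at offset ω_RF erodes the visible
major-state peak whenever it touches either the major-state resonance ω_A
or the minor-state resonance ω_B, so a profile of peak intensity against
offset shows a large dip at ω_A and a tell-tale small dip at ω_B.  Each
profile point is a full 2D spectrum, and before the experiment the most
important parameter — ω_B — is unknown, so evenly spaced offset sweeps
waste most of their measurement time.  This package closes the loop
instead: after every measurement it re-estimates each residue's two-state
exchange parameters

θ = (p_B, k_ex, ω_B, R₁, R₂A, R₂B, I₀)

by adaptive-Metropolis MCMC under the field's standard linear/log-uniform
priors, scores every candidate irradiation condition x = (ω_RF, ω₁, T_EX)
by the mutual information

U(x) = Σ_k I( p(ŷ_k) ; p(θ_k) ) = Σ_k { H[p(ŷ_k)] − ½ln(2πeσ²) },

between the predicted next observation and the parameters (the predictive
p(ŷ) is the equal-weight Gaussian mixture over posterior draws), and
measures next at the arg-max.  The forward model is the two-state
Bloch–McConnell equation; an exact matrix-exponential propagator serves as
oracle and virtual spectrometer, while the in-loop likelihood and utility
use a fast spin-locked-mode approximation y = I₀·A·exp(−R₁ρ·T_EX) whose
rate and amplitude are refined from a first-order rotating-frame seed by
Rayleigh-quotient iteration — accurate to the eigenvalue route everywhere
(it falls back to the full eigendecomposition where a single mode does not
dominate) at a fraction of the cost.

The package provides the building blocks (`bloch_mcconnell_matrix()`,
`propagate_exact()`, `r1rho_fast()`, `cest_intensity()`,
`sample_posterior()`, `mutual_information()`, `realized_kl()`,
`select_next_condition()`), the closed loop (`run_adaptive()`) with a
virtual spectrometer (`generate_virtual_protein()`, `virtual_observe()`),
conventional evenly spaced comparators (`conventional_schedule()`,
`run_conventional()`), named scenario presets (`scenario_config()`), CSV
interchange of observations/candidates/truths, and a command-line
launcher (`inst/cli/adaptive-cest.R`).

## Worked example

A one-residue virtual protein at signal-to-noise 20, a reduced candidate
grid (offsets every 25 Hz in ±1000 Hz, strengths 10 and 50 Hz, T_EX
0.5 s), and 40 design iterations with desk-scale chain lengths:

```r
library(adaptivecest)

truth <- generate_virtual_protein(1, seed = 3)
truth[, c("omega_a", "p_b", "k_ex", "omega_b", "r1", "i0", "sigma")]
#>     omega_a        p_b     k_ex   omega_b      r1       i0     sigma
#> 1 -531.1336 0.03408403 139.9383 -39.10732 1.06946 8.277343 0.4138672

cands <- build_candidate_grid(-1000, 1000, 25, c(10, 50), 0.5)
rec <- run_adaptive(truth, cands, n_iterations = 40, seed = 5,
                    loop_settings = mcmc_settings(burnin = 1500,
                                                  steps = 2000, thin = 4),
                    final_settings = mcmc_settings(burnin = 4000,
                                                   steps = 8000, thin = 10))
rec$final$summaries[[1]]
#>   parameter          map       ci_lo        ci_hi
#> 1       p_b   0.04600268   0.0370390   0.05318555
#> 2      k_ex  88.33987043  69.0176783 133.04601806
#> 3   omega_b -45.39687975 -48.1781327 -37.81266132
#> 4        r1   0.91220754   0.8282588   1.00476319
#> 5       r2a   9.48114639   7.9009011  10.96976241
#> 6       r2b 122.35579218  75.5299223 154.94790858
#> 7        i0   8.30108594   8.0744940   8.44938721
```

After 40 measurements the design has found the minor-state dip: the true
ω_B = −39.1 Hz lies inside its 68.3% credible interval [−48.2, −37.8] Hz,
which is ~10 Hz wide on a ±1000 Hz search range.  The exchange
parameters are localized around their true values (p_B 0.034, k_ex
140 s⁻¹); note that at the 68.3% level roughly one interval in three is
*expected* to just miss its truth, as `p_b` and `k_ex` do here — the
calibration of these intervals is itself verified in the test suite.
The utility of the selected condition decays as the posterior
concentrates — the per-iteration record keeps every utility table,
posterior summary and realized Kullback–Leibler divergence:

```r
round(sapply(rec$iterations[c(1, 5, 20, 40)],
             function(it) max(it$utility$mi_total_nat)), 4)
#> [1] 1.6144 0.7196 0.2228 0.1081
```

`save_run_record(rec, "run01/")` persists observations, utility tables
and summaries as plain CSV/JSON.  The same loop scales to the bundled
multi-residue scenarios, e.g. `scenario_config("A3")` (70 residues, 505
candidates, 192 iterations) against `scenario_config("C4")` (the matched
192-measurement conventional sweep).

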