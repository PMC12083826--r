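# Shared fixtures: prior-box draws, compact grids, reduced MCMC settings.
# All randomness is seeded inside each test; helpers only build objects.

PAR_NAMES <- c("p_b", "k_ex", "omega_b", "r1", "r2a", "r2b", "i0")

# n draws from the inference prior box, as the 8-column natural-scale
# matrix (absolute rates, omega_a last) used by the C++ sweep kernels
draw_prior_box <- function(n) {
  r1 <- exp(runif(n, log(0.1), log(10)))
  cbind(p_b = runif(n, 0, 0.1),
        k_ex = exp(runif(n, log(5), log(1000))),
        omega_b = runif(n, -1000, 1000),
        r1 = r1,
        r2a = r1 * exp(runif(n, log(1), log(100))),
        r2b = r1 * exp(runif(n, log(1), log(1000))),
        i0 = exp(runif(n, log(0.1), log(10000))),
        omega_a = runif(n, -800, 800))
}

prior_truth_row <- function() {
  d <- draw_prior_box(1)
  out <- data.frame(residue_id = "X01", omega_a = d[1, "omega_a"],
                    p_b = d[1, "p_b"], k_ex = d[1, "k_ex"],
                    omega_b = d[1, "omega_b"], r1 = d[1, "r1"],
                    r2a = d[1, "r2a"], r2b = d[1, "r2b"], i0 = d[1, "i0"])
  out$sigma <- out$i0 / 20
  class(out) <- c("spin_system_truth", "data.frame")
  out
}

row_to_model <- function(d, validate = TRUE) {
  residue_model(d[["p_b"]], d[["k_ex"]], d[["omega_b"]], d[["r1"]],
                d[["r2a"]], d[["r2b"]], d[["i0"]], d[["omega_a"]],
                validate = validate)
}

# the non-reference members of the standard single-residue candidate grid
a1_grid_matrix <- function(step = 5) {
  g <- build_candidate_grid(-1000, 1000, step, c(10, 50), 0.5)
  g <- g[g$t_ex_s > 0, ]
  cbind(g$omega_rf_hz, g$omega1_hz, g$t_ex_s)
}

# reduced-step presets for desk-scale chains (documented in the vignette)
quick_loop <- function() mcmc_settings(burnin = 1500, steps = 2000, thin = 4)
quick_final <- function() mcmc_settings(burnin = 4000, steps = 8000, thin = 10)

simulate_schedule_obs <- function(truth, schedule) {
  do.call(rbind, lapply(seq_len(nrow(schedule)), function(n)
    virtual_observe(truth, schedule[n, , drop = FALSE], n)))
}

# access to the compiled kernels for oracle-level checks
.ns <- asNamespace("adaptivecest")
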