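#' Build a candidate grid of saturation conditions
#'
#' Cartesian product of an inclusive offset grid with the given strengths
#' and durations, optionally preceded by the single reference condition
#' (0 Hz, 0 Hz, 0 s).  Ordering is deterministic: reference first, then
#' offset-major ascending, then strength, then duration.
#'
#' @param offset_lo,offset_hi,offset_step Offset grid in Hz (inclusive
#'   endpoints, `offset_step` > 0).
#' @param strengths Saturation strengths in Hz (non-empty).
#' @param durations Saturation durations in s (non-empty).
#' @param include_reference Add the reference member (default `TRUE`).
#' @return A data.frame of class `candidate_set` with columns
#'   `omega_rf_hz`, `omega1_hz`, `t_ex_s` and a logical `reference` column.
#' @examples
#' nrow(build_candidate_grid(-1000, 1000, 5, c(10, 50), 0.5))  # 803
#' @export
build_candidate_grid <- function(offset_lo, offset_hi, offset_step,
                                 strengths, durations = 0.5,
                                 include_reference = TRUE) {
  if (offset_lo > offset_hi) stop("invalid grid: offset_lo > offset_hi")
  if (offset_step <= 0) stop("invalid grid: offset_step must be > 0")
  if (length(strengths) == 0) stop("invalid grid: no strengths")
  if (length(durations) == 0) stop("invalid grid: no durations")
  if (any(strengths <= 0)) stop("strengths must be positive (the reference is added via include_reference)")
  if (any(durations <= 0)) stop("durations must be positive")
  offsets <- seq(offset_lo, offset_hi, by = offset_step)
  grid <- expand.grid(t_ex_s = as.numeric(durations),
                      omega1_hz = as.numeric(strengths),
                      omega_rf_hz = as.numeric(offsets),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$omega_rf_hz, grid$omega1_hz, grid$t_ex_s), ,
               drop = FALSE]
  grid <- grid[, c("omega_rf_hz", "omega1_hz", "t_ex_s")]
  grid$reference <- FALSE
  if (include_reference) {
    grid <- rbind(data.frame(omega_rf_hz = 0, omega1_hz = 0, t_ex_s = 0,
                             reference = TRUE), grid)
  }
  rownames(grid) <- NULL
  if (anyDuplicated(grid[, 1:3])) stop("invalid grid: duplicate conditions")
  class(grid) <- c("candidate_set", "data.frame")
  grid
}

#' Predictive density of the next observation at a candidate condition
#'
#' The posterior-predictive density of a future intensity under the
#' Gaussian noise model: an equal-weight Gaussian mixture with component
#' means f_s = cest_intensity(draw_s, cond, "fast") and common SD `sigma`,
#' discretized on a uniform grid spanning \[min f - 6 sigma,
#' max f + 6 sigma\].  The grid is refined beyond `grid_points` until the
#' cell width is at most sigma/4, which keeps the Riemann-sum mass within
#' 1e-4 of 1 for arbitrarily spread predictions.
#'
#' @param draws A `posterior_draws` object with at least 100 draws.
#' @param cond An [irr_condition()].
#' @param sigma Noise SD (> 0).
#' @param grid_points Minimum number of grid points (default 1001).
#' @return A list with `grid`, `density`, the component means `f`, and the
#'   Riemann `mass`.
#' @export
predictive_density <- function(draws, cond, sigma, grid_points = 1001) {
  check_draws(draws)
  if (sigma <= 0) stop("sigma must be positive (degenerate predictive density)")
  cnd <- as_condition(cond)
  f <- as.numeric(cpp_forward_draws(draws$draws, draws$omega_a, cnd$omega_rf,
                                    cnd$omega1, cnd$t_ex, 2L))
  lo <- min(f) - 6 * sigma
  hi <- max(f) + 6 * sigma
  G <- max(grid_points, ceiling((hi - lo) / (sigma / 4)) + 1)
  grid <- seq(lo, hi, length.out = G)
  dens <- rowMeans(vapply(f, function(m) stats::dnorm(grid, m, sigma),
                          numeric(G)))
  w <- rep(diff(grid)[1], G)
  w[c(1, G)] <- w[1] / 2
  list(grid = grid, density = dens, f = f, mass = sum(w * dens))
}

check_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (nrow(draws$draws) < 100)
    stop("utility computations need at least 100 posterior draws")
  invisible(draws)
}

#' Mutual information between the next observation and the parameters
#'
#' The expected information gain of measuring at `cond`, in nats:
#' I = H\[predictive mixture\] - (1/2) log(2 pi e sigma^2), computed by
#' Riemann sum over the discretized predictive density.  This is exact for
#' the Gaussian noise model because the conditional entropy of y given
#' theta is the noise entropy.  Small negative numerical estimates are
#' clamped to zero.  The reference condition is scored identically (its
#' predictions f_s = i0_s vary across draws, so it is informative about
#' the basal intensity).
#'
#' @inheritParams predictive_density
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(draws, cond, sigma, grid_points = 1001) {
  check_draws(draws)
  if (sigma <= 0) stop("sigma must be positive")
  cnd <- as_condition(cond)
  f <- as.numeric(cpp_forward_draws(draws$draws, draws$omega_a, cnd$omega_rf,
                                    cnd$omega1, cnd$t_ex, 2L))
  mi_from_predictions(f, sigma, grid_points)
}

#' Mutual information from precomputed predictions
#'
#' The estimator underlying [mutual_information()], exposed for models
#' whose forward predictions f_s are available directly (closed-form
#' checks, custom forward models).
#'
#' @param f Numeric vector of per-draw forward predictions.
#' @param sigma Noise SD (> 0).
#' @param grid_points Minimum grid size.
#' @return Mutual information in nats (>= 0).
#' @export
mi_from_predictions <- function(f, sigma, grid_points = 1001) {
  if (sigma <= 0) stop("sigma must be positive")
  cpp_mi_core(as.numeric(f), sigma, as.integer(grid_points))$mi
}

#' Total utility of every candidate condition
#'
#' Because the per-residue parameter blocks are a priori independent, the
#' mutual information between the joint observation vector and the joint
#' parameters is the sum over residues of the per-residue mutual
#' informations; an optional non-negative weight per residue refocuses the
#' utility (all-ones reproduces the plain sum, a one-hot weight targets a
#' single residue).
#'
#' @param draws_list List of `posterior_draws`, one per residue.
#' @param candidates A `candidate_set` (or condition data.frame).
#' @param sigma Noise SD, either a single value or one per residue.
#' @param weights Optional non-negative weights, length = number of
#'   residues (default all ones).
#' @param grid_points Minimum MI grid size.
#' @param iteration Optional iteration index stored on the result.
#' @return A data.frame of class `utility_table`: the candidate columns,
#'   `mi_total_nat`, and one `mi_residue_<id>_nat` column per residue.
#' @export
total_utility <- function(draws_list, candidates, sigma, weights = NULL,
                          grid_points = 1001, iteration = NA_integer_) {
  if (inherits(draws_list, "posterior_draws")) draws_list <- list(draws_list)
  K <- length(draws_list)
  stopifnot(K >= 1)
  sigma <- rep_len(sigma, K)
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K) stop("weights must have one entry per residue")
  if (any(weights < 0)) stop("weights must be non-negative")
  tab <- as_condition_table(candidates)
  cm <- cond_matrix(tab)
  per <- matrix(0, nrow(tab), K)
  ids <- character(K)
  for (k in seq_len(K)) {
    check_draws(draws_list[[k]])
    per[, k] <- as.numeric(cpp_mi_table(draws_list[[k]]$draws,
                                        draws_list[[k]]$omega_a, cm,
                                        sigma[k], as.integer(grid_points)))
    ids[k] <- as.character(draws_list[[k]]$residue_id)
  }
  out <- tab
  out$mi_total_nat <- as.numeric(per %*% weights)
  for (k in seq_len(K)) out[[paste0("mi_residue_", ids[k], "_nat")]] <- per[, k]
  attr(out, "iteration") <- iteration
  attr(out, "weights") <- weights
  class(out) <- c("utility_table", "data.frame")
  out
}

#' Select the next condition from a utility table
#'
#' Returns the candidate maximizing the total utility; exact ties are
#' broken uniformly at random using the caller's (seeded) RNG stream so
#' that grid order introduces no systematic bias.
#'
#' @param table A `utility_table` from [total_utility()].
#' @return The selected condition as a one-row data.frame (with its index
#'   in attribute `index`).
#' @export
select_next_condition <- function(table) {
  stopifnot(nrow(table) >= 1)
  u <- table$mi_total_nat
  tied <- which(u == max(u))
  pick <- if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
  out <- as_condition_table(table)[pick, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "index") <- pick
  out
}

#' Realized Kullback-Leibler divergence of one observation
#'
#' The information actually delivered by an observed intensity `y_obs`:
#' D_KL(p(theta | y_obs) || p(theta)), estimated by self-normalized
#' importance sampling over the current draws with Gaussian weights
#' w_s proportional to N(y_obs; f_s, sigma).  Its expectation over the
#' predictive distribution equals the mutual information, which is the
#' core diagnostic identity of the design loop.
#'
#' @inheritParams predictive_density
#' @param y_obs The observed intensity.
#' @return The KL estimate in nats (>= 0), with the importance-sampling
#'   effective sample size in attribute `ess`; a warning is raised when the
#'   ESS collapses (observation far outside every prediction).
#' @export
realized_kl <- function(draws, cond, y_obs, sigma) {
  check_draws(draws)
  if (sigma <= 0) stop("sigma must be positive")
  cnd <- as_condition(cond)
  f <- as.numeric(cpp_forward_draws(draws$draws, draws$omega_a, cnd$omega_rf,
                                    cnd$omega1, cnd$t_ex, 2L))
  res <- cpp_realized_kl(f, y_obs, sigma)
  if (res$ess < 10)
    warning(sprintf("realized KL effective sample size %.1f; estimate unreliable",
                    res$ess))
  structure(res$kl, ess = res$ess)
}

#' Write a utility table (or a list of them) to CSV
#'
#' Columns: `iteration`, `omega_rf_hz`, `omega1_hz`, `t_ex_s`,
#' `mi_total_nat`, and the per-residue `mi_residue_<id>_nat` columns.
#'
#' @param table A `utility_table`.
#' @param path Output file path.
#' @export
write_utility_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$reference <- NULL
  df <- cbind(iteration = attr(table, "iteration"), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
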