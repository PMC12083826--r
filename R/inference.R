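#' Prior specification for the seven residue parameters
#'
#' Independent uniform priors, each either linear or logarithmic
#' (log-uniform) in its natural coordinate.  The defaults are the standard
#' CEST analysis box: `p_b` \[0, 0.1\] linear, `k_ex` \[5, 1000\] s^-1 log,
#' `omega_b` \[-1000, 1000\] Hz linear, `r1` \[0.1, 10\] s^-1 log,
#' `r2a/r1` \[1, 100\] log, `r2b/r1` \[1, 1000\] log, `i0` \[0.1, 10000\]
#' log.  Note that the transverse rates are parameterized as ratios to `r1`
#' inside the sampler and reported as absolute rates in summaries.
#'
#' @param lower,upper Named numeric vectors overriding individual bounds;
#'   names among `p_b`, `k_ex`, `omega_b`, `r1`, `r2a_ratio`, `r2b_ratio`,
#'   `i0`.
#' @return A data.frame of class `prior_spec` with columns `parameter`,
#'   `lower`, `upper`, `scale`.
#' @examples
#' prior_spec()
#' prior_spec(upper = c(p_b = 0.05))
#' @export
prior_spec <- function(lower = NULL, upper = NULL) {
  spec <- data.frame(
    parameter = c("p_b", "k_ex", "omega_b", "r1", "r2a_ratio", "r2b_ratio", "i0"),
    lower = c(0, 5, -1000, 0.1, 1, 1, 0.1),
    upper = c(0.1, 1000, 1000, 10, 100, 1000, 10000),
    scale = c("linear", "logarithmic", "linear", "logarithmic",
              "logarithmic", "logarithmic", "logarithmic"),
    stringsAsFactors = FALSE
  )
  apply_override <- function(spec, vals, col) {
    if (is.null(vals)) return(spec)
    bad <- setdiff(names(vals), spec$parameter)
    if (length(bad)) stop("unknown prior parameter(s): ", paste(bad, collapse = ", "))
    spec[[col]][match(names(vals), spec$parameter)] <- as.numeric(vals)
    spec
  }
  spec <- apply_override(spec, lower, "lower")
  spec <- apply_override(spec, upper, "upper")
  if (any(spec$lower >= spec$upper))
    stop("prior lower bounds must be strictly below upper bounds")
  if (any(spec$scale == "logarithmic" & spec$lower <= 0))
    stop("logarithmic priors require a strictly positive lower bound")
  class(spec) <- c("prior_spec", "data.frame")
  spec
}

# transformed-coordinate bounds: identity for linear parameters, log for
# logarithmic ones
prior_bounds_transformed <- function(prior) {
  lo <- prior$lower
  hi <- prior$upper
  lg <- prior$scale == "logarithmic"
  lo[lg] <- log(lo[lg])
  hi[lg] <- log(hi[lg])
  list(lower = lo, upper = hi, log = lg)
}

# natural 7-vector (absolute rates) -> transformed coordinates
theta_to_u <- function(theta) {
  c(theta[1], log(theta[2]), theta[3], log(theta[4]),
    log(theta[5] / theta[4]), log(theta[6] / theta[4]), log(theta[7]))
}

u_to_theta <- function(u) {
  c(u[1], exp(u[2]), u[3], exp(u[4]), exp(u[4] + u[5]), exp(u[4] + u[6]),
    exp(u[7]))
}

#' Log prior density
#'
#' Unnormalized log density of the prior at a natural-scale parameter
#' vector.  Inside the box the prior is uniform in the transformed
#' coordinates, i.e. the natural-scale density carries a 1/value factor for
#' every logarithmic parameter (here 1/k_ex * 1/r1 * 1/r2a * 1/r2b * 1/i0,
#' from the ratio parameterization); outside the box the density is zero.
#'
#' @param theta Numeric 7-vector `(p_b, k_ex, omega_b, r1, r2a, r2b, i0)`
#'   on the natural scale with absolute transverse rates.
#' @param prior A [prior_spec()].
#' @return Log density (finite inside the box, `-Inf` outside).
#' @export
log_prior <- function(theta, prior = prior_spec()) {
  stopifnot(is.numeric(theta), length(theta) == 7L)
  if (!all(is.finite(theta))) return(-Inf)
  if (any(theta[c(2, 4, 5, 6, 7)] <= 0)) return(-Inf)
  u <- theta_to_u(theta)
  bt <- prior_bounds_transformed(prior)
  if (any(u < bt$lower | u > bt$upper)) return(-Inf)
  # |det du/dtheta| = 1/(k_ex * r1 * r2a * r2b * i0) for the log/ratio block
  -(log(theta[2]) + log(theta[4]) + log(theta[5]) + log(theta[6]) +
      log(theta[7]))
}

#' Gaussian log likelihood of accumulated observations for one residue
#'
#' Sum over observations of the normal log density of
#' `intensity - cest_intensity(theta, condition, method = "fast")` with
#' known noise SD `sigma`.  Reference observations (`t_ex` = 0) use the
#' exact identity y = i0.  Replicate observations at the same condition
#' accumulate.
#'
#' @inheritParams log_prior
#' @param observations Data.frame with columns `omega_rf_hz`, `omega1_hz`,
#'   `t_ex_s`, `intensity` (the package's observation-table format).
#' @param sigma Noise standard deviation (> 0), known, not inferred.
#' @param omega_a Known major-state shift of the residue, Hz.
#' @return Log likelihood; 0 for zero observations.
#' @export
log_likelihood <- function(theta, observations, sigma, omega_a) {
  stopifnot(is.numeric(theta), length(theta) == 7L)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  if (is.null(observations) || nrow(observations) == 0L) return(0)
  grp <- group_observations(observations)
  th8 <- c(theta, omega_a)
  f <- as.numeric(cpp_cest_curve(th8, grp$conds, 2L, 0))
  sum(-0.5 * grp$n * log(2 * pi * sigma^2) -
        (grp$sumy2 - 2 * f * grp$sumy + grp$n * f^2) / (2 * sigma^2))
}

# collapse observations to unique conditions with sufficient statistics
group_observations <- function(observations) {
  key <- paste(sprintf("%.17g", observations$omega_rf_hz),
               sprintf("%.17g", observations$omega1_hz),
               sprintf("%.17g", observations$t_ex_s))
  idx <- match(key, unique(key))
  first <- !duplicated(key)
  conds <- cbind(observations$omega_rf_hz[first],
                 observations$omega1_hz[first],
                 observations$t_ex_s[first])
  list(conds = conds,
       n = as.numeric(tabulate(idx, nbins = sum(first))),
       sumy = as.numeric(rowsum(observations$intensity, idx)[, 1]),
       sumy2 = as.numeric(rowsum(observations$intensity^2, idx)[, 1]))
}

#' MCMC settings presets
#'
#' `"loop"` is the in-loop preset used between measurements (20,000 burn-in
#' steps, 30,000 sampling steps, thinning 50, hence 600 retained draws);
#' `"long"` is the detailed post-run preset (100,000 burn-in, 1,000,000
#' sampling steps).
#'
#' @param preset `"loop"` or `"long"`, or `NULL` when giving explicit values.
#' @param burnin,steps,thin Explicit overrides.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(preset = c("loop", "long"), burnin = NULL,
                          steps = NULL, thin = NULL) {
  if (is.null(burnin) || is.null(steps) || is.null(thin)) {
    preset <- match.arg(preset)
    def <- switch(preset,
                  loop = list(burnin = 20000L, steps = 30000L, thin = 50L),
                  long = list(burnin = 100000L, steps = 1000000L, thin = 50L))
  } else {
    def <- list()
    preset <- "custom"
  }
  out <- list(burnin = as.integer(burnin %||% def$burnin),
              steps = as.integer(steps %||% def$steps),
              thin = as.integer(thin %||% def$thin),
              preset = preset)
  stopifnot(out$burnin >= 0, out$steps >= out$thin, out$thin >= 1)
  structure(out, class = "mcmc_settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample the per-residue posterior by adaptive Metropolis MCMC
#'
#' Random-walk Metropolis in the transformed coordinates (linear for
#' linear-prior parameters, log for logarithmic ones; transverse rates as
#' ratios to `r1`), with the proposal covariance adapted to the empirical
#' chain covariance during burn-in and frozen afterwards.  Proposals
#' outside the prior box are rejected, giving exact uniform-prior
#' semantics.  The chain is deterministic given the seed.
#'
#' @inheritParams log_likelihood
#' @param prior A [prior_spec()].
#' @param settings An [mcmc_settings()] object.
#' @param seed Integer seed; `NULL` continues the caller's RNG stream.
#' @param residue_id Identifier stored in the result.
#' @param init Optional natural-scale 7-vector starting point (e.g. a draw
#'   from the previous iteration's posterior in a sequential design loop);
#'   default is a random point in the prior box.  Warm starts remove the
#'   burn-in transient and keep the proposal adaptation effective when the
#'   posterior is already concentrated.
#' @param n_chains Number of independently started chains; their retained
#'   draws are pooled.  Multiple starts protect the credible intervals
#'   against a single chain settling into one basin of a multimodal
#'   minor-shift posterior.
#' @return An object of class `posterior_draws`: the retained draws (S x 7
#'   matrix on the natural scale, absolute rates), their log likelihoods,
#'   and sampler metadata.  A convergence warning is attached when the
#'   post-burn-in acceptance rate falls below 1%.
#' @export
sample_posterior <- function(observations, prior = prior_spec(), sigma = NULL,
                             omega_a, settings = mcmc_settings("loop"),
                             seed = NULL, residue_id = "residue",
                             init = NULL, n_chains = 1L) {
  if (is.null(sigma)) {
    if (!is.null(observations) && nrow(observations) > 0 &&
        "sigma" %in% names(observations)) {
      sg <- unique(observations$sigma)
      if (length(sg) != 1L)
        stop("observations carry multiple sigma values; pass sigma explicitly")
      sigma <- sg
    } else stop("sigma is required")
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  bt <- prior_bounds_transformed(prior)
  if (is.null(observations) || nrow(observations) == 0L) {
    grp <- list(conds = matrix(numeric(0), 0, 3), n = numeric(0),
                sumy = numeric(0), sumy2 = numeric(0))
  } else {
    grp <- group_observations(observations)
  }
  run_chain <- function() {
    if (is.null(init)) {
      init_u <- stats::runif(7, bt$lower, bt$upper)
    } else {
      stopifnot(length(init) == 7L)
      init_u <- pmin(pmax(theta_to_u(init), bt$lower), bt$upper)
    }
    cpp_sample_posterior(bt$lower, bt$upper, omega_a, grp$conds, grp$n,
                         grp$sumy, grp$sumy2, sigma,
                         settings$burnin, settings$steps, settings$thin,
                         init_u)
  }
  chains <- lapply(seq_len(n_chains), function(i) run_chain())
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  loglik <- unlist(lapply(chains, `[[`, "loglik"))
  arate <- mean(vapply(chains, `[[`, numeric(1), "acceptance_rate"))
  colnames(draws) <- c("p_b", "k_ex", "omega_b", "r1", "r2a", "r2b", "i0")
  conv_warning <- NULL
  if (is.finite(arate) && arate < 0.01) {
    conv_warning <- sprintf("acceptance rate %.3f%% below 1%%", 100 * arate)
    warning("possible non-convergence: ", conv_warning)
  }
  structure(list(residue_id = residue_id,
                 draws = draws,
                 loglik = as.numeric(loglik),
                 sigma = sigma,
                 omega_a = omega_a,
                 n_observations = if (is.null(observations)) 0L else nrow(observations),
                 meta = list(seed = seed, burnin = settings$burnin,
                             steps = settings$steps, thin = settings$thin,
                             n_chains = n_chains,
                             preset = settings$preset,
                             acceptance_rate = arate,
                             convergence_warning = conv_warning)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> residue %s: %d draws, acceptance %.1f%%\n",
              x$residue_id, nrow(x$draws), 100 * x$meta$acceptance_rate))
  invisible(x)
}

#' Posterior summary: MAP draw and 68.3% credible intervals
#'
#' The MAP is the retained draw with the highest unnormalized log posterior
#' (log prior + log likelihood); the credible interval is the central
#' marginal \[15.85%, 84.15%\] quantile interval per parameter, both on the
#' natural scale with absolute transverse rates.
#'
#' @param draws A `posterior_draws` object (at least 100 retained draws).
#' @param prior The [prior_spec()] used for the MAP density.
#' @return A data.frame of class `parameter_summary` with columns
#'   `parameter`, `map`, `ci_lo`, `ci_hi`.
#' @export
summarize_posterior <- function(draws, prior = prior_spec()) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (nrow(draws$draws) < 100)
    stop("need at least 100 retained draws to summarize")
  lp <- draws$loglik + apply(draws$draws, 1, log_prior, prior = prior)
  map_i <- which.max(lp)
  qs <- apply(draws$draws, 2, stats::quantile,
              probs = c(0.1585, 0.8415), names = FALSE)
  out <- data.frame(parameter = colnames(draws$draws),
                    map = as.numeric(draws$draws[map_i, ]),
                    ci_lo = qs[1, ], ci_hi = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("parameter_summary", "data.frame")
  out
}
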