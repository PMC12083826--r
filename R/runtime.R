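#' Virtual spectrometer: simulate one measurement
#'
#' Observes every residue of a synthetic truth under one condition:
#' y_k = exact Bloch-McConnell intensity + Gaussian noise with the
#' residue's sigma.  The reference condition yields i0 plus noise.  Uses
#' the caller's RNG stream (seed upstream for reproducibility).
#'
#' @param truth A `spin_system_truth` from [generate_virtual_protein()].
#' @param cond An [irr_condition()] or one-row condition data.frame.
#' @param iteration Iteration index recorded on the rows (1-based).
#' @return An observation data.frame (one row per residue) with columns
#'   `iteration`, `omega_rf_hz`, `omega1_hz`, `t_ex_s`, `residue_id`,
#'   `intensity`, `sigma`.
#' @export
virtual_observe <- function(truth, cond, iteration = 1L) {
  cnd <- as_condition(cond)
  K <- nrow(truth)
  y <- vapply(seq_len(K), function(k) {
    propagate_exact(truth_model(truth, k), cnd)
  }, numeric(1))
  y <- y + stats::rnorm(K, 0, truth$sigma)
  data.frame(iteration = as.integer(iteration),
             omega_rf_hz = cnd$omega_rf, omega1_hz = cnd$omega1,
             t_ex_s = cnd$t_ex, residue_id = truth$residue_id,
             intensity = y, sigma = truth$sigma,
             stringsAsFactors = FALSE)
}

draw_subseed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Run the adaptive CEST design loop
#'
#' Executes the closed loop: iteration 1 measures the reference; every
#' iteration then (i) observes all residues at the current condition,
#' (ii) samples each residue's posterior by MCMC from all accumulated
#' observations, (iii) scores every candidate by the (optionally weighted)
#' summed mutual information, and (iv) selects the arg-max candidate for
#' the next iteration, ties broken at random.  The same condition may be
#' selected repeatedly; replicate observations accumulate in the
#' likelihood.  After the last iteration a detailed re-analysis with
#' `final_settings` is appended.  The whole run is reproducible from
#' `seed`.
#'
#' @param truth A `spin_system_truth`, or an observation provider
#'   `function(cond, iteration)` returning an observation data.frame (one
#'   row per residue with `intensity` and `sigma`); a file-backed provider
#'   can stream real measurements.
#' @param candidates A `candidate_set`; must contain the reference.
#' @param prior A [prior_spec()].
#' @param n_iterations Number of 2D measurements (>= 1).
#' @param seed Integer seed for the whole run.
#' @param loop_settings [mcmc_settings()] used between iterations.
#' @param final_settings [mcmc_settings()] for the appended re-analysis
#'   (`NULL` to skip).
#' @param weights Per-residue utility weights: a numeric vector, or a
#'   `function(iteration)` returning one (mid-run utility switching).
#' @param grid_points Minimum MI quadrature grid size.
#' @param utility_draws If set, the utility is evaluated on this many
#'   evenly thinned posterior draws per residue (at least 100), trading a
#'   little Monte-Carlo precision of the MI surface for speed on large
#'   candidate sets.
#' @param progress Print one line per iteration.
#' @return A `run_record`: per-iteration conditions, utility tables,
#'   summaries and realized KL, the accumulated observations, and the
#'   final re-analysis.
#' @export
run_adaptive <- function(truth, candidates, prior = prior_spec(),
                         n_iterations, seed = 1L,
                         loop_settings = mcmc_settings("loop"),
                         final_settings = mcmc_settings("long"),
                         weights = NULL, grid_points = 1001,
                         utility_draws = NULL, progress = FALSE) {
  stopifnot(n_iterations >= 1)
  candidates <- as_candidate_set(candidates)
  ref_i <- which(candidates$t_ex_s == 0)
  if (length(ref_i) == 0)
    stop("candidate set lacks the reference condition (iteration 1 requires it)")
  observer <- make_observer(truth)
  set.seed(seed)

  cond <- candidates[ref_i[1], 1:3, drop = FALSE]
  obs <- NULL
  draws <- NULL
  iterations <- vector("list", n_iterations)
  for (n in seq_len(n_iterations)) {
    ob_n <- observer(cond, n)
    kl <- NULL
    if (!is.null(draws)) {
      kl <- vapply(seq_along(draws), function(k) {
        row <- ob_n[ob_n$residue_id == draws[[k]]$residue_id, ]
        as.numeric(suppressWarnings(
          realized_kl(draws[[k]], cond, row$intensity, row$sigma)))
      }, numeric(1))
      names(kl) <- vapply(draws, `[[`, "", "residue_id")
    }
    obs <- rbind(obs, ob_n)
    ids <- unique(obs$residue_id)
    sig <- obs$sigma[match(ids, obs$residue_id)]
    seeds_k <- vapply(ids, function(i) draw_subseed(), integer(1))
    prev_draws <- draws
    draws <- lapply(seq_along(ids), function(k) {
      # warm start from the previous iteration's last retained draw
      init <- NULL
      if (!is.null(prev_draws))
        init <- as.numeric(prev_draws[[k]]$draws[nrow(prev_draws[[k]]$draws), ])
      sample_posterior(obs[obs$residue_id == ids[k], ], prior,
                       sigma = sig[k], omega_a = obs$omega_a[match(ids[k], obs$residue_id)],
                       settings = loop_settings, seed = seeds_k[k],
                       residue_id = ids[k], init = init)
    })
    w_n <- resolve_weights(weights, n, length(ids))
    udraws <- draws
    if (!is.null(utility_draws))
      udraws <- lapply(draws, thin_draws, n_keep = utility_draws)
    utab <- total_utility(udraws, candidates, sig, weights = w_n,
                          grid_points = grid_points, iteration = n)
    nxt <- select_next_condition(utab)
    iterations[[n]] <- list(iteration = n, condition = cond,
                            utility = utab,
                            summaries = lapply(draws, summarize_posterior,
                                               prior = prior),
                            realized_kl = kl, next_condition = nxt,
                            mcmc_seeds = seeds_k)
    if (progress)
      message(sprintf("iteration %d: measured (%g, %g, %g); next (%g, %g, %g)",
                      n, cond$omega_rf_hz, cond$omega1_hz, cond$t_ex_s,
                      nxt$omega_rf_hz, nxt$omega1_hz, nxt$t_ex_s))
    cond <- nxt
  }

  final <- NULL
  if (!is.null(final_settings)) {
    ids <- unique(obs$residue_id)
    sig <- obs$sigma[match(ids, obs$residue_id)]
    fdraws <- lapply(seq_along(ids), function(k) {
      sample_posterior(obs[obs$residue_id == ids[k], ], prior,
                       sigma = sig[k], omega_a = obs$omega_a[match(ids[k], obs$residue_id)],
                       settings = final_settings, seed = draw_subseed(),
                       residue_id = ids[k])
    })
    final <- list(draws = fdraws,
                  summaries = lapply(fdraws, summarize_posterior,
                                     prior = prior))
  }
  structure(list(kind = "adaptive", seed = seed, observations = obs,
                 iterations = iterations, final = final,
                 candidates = candidates,
                 settings = list(loop = loop_settings,
                                 final = final_settings)),
            class = "run_record")
}

as_candidate_set <- function(x) {
  tab <- as_condition_table(x)
  tab$reference <- tab$t_ex_s == 0
  if (sum(tab$reference) > 1) stop("candidate set has more than one reference")
  if (anyDuplicated(tab[, 1:3])) stop("candidate set has duplicate conditions")
  class(tab) <- c("candidate_set", "data.frame")
  tab
}

resolve_weights <- function(weights, iteration, K) {
  if (is.null(weights)) return(rep(1, K))
  w <- if (is.function(weights)) weights(iteration) else weights
  rep_len(w, K)
}

# observation provider closure; carries a lookup for the known omega_a
make_observer <- function(truth) {
  if (is.function(truth)) {
    obs_fun <- truth
  } else {
    stopifnot(inherits(truth, "data.frame"))
    obs_fun <- function(cond, iteration) virtual_observe(truth, cond, iteration)
  }
  function(cond, iteration) {
    ob <- obs_fun(cond, iteration)
    if (!"omega_a" %in% names(ob)) {
      if (is.function(truth)) stop("observation provider must supply omega_a")
      ob$omega_a <- truth$omega_a[match(ob$residue_id, truth$residue_id)]
    }
    ob$omega_a_of <- NULL
    attr(ob, "row.names") <- seq_len(nrow(ob))
    ob
  }
}

#' Run a conventional (pre-determined) CEST schedule
#'
#' Observes every scheduled condition once, in order, then runs the
#' detailed per-residue MCMC re-analysis.  Produces the same `run_record`
#' shape as [run_adaptive()] for head-to-head precision comparisons under
#' a matched measurement budget.
#'
#' @inheritParams run_adaptive
#' @param schedule Ordered condition data.frame (see
#'   [conventional_schedule()]); must be non-empty.
#' @param settings [mcmc_settings()] for the analysis.
#' @return A `run_record`.
#' @export
run_conventional <- function(truth, schedule, prior = prior_spec(), seed = 1L,
                             settings = mcmc_settings("long")) {
  schedule <- as_condition_table(schedule)
  if (nrow(schedule) == 0) stop("empty schedule")
  observer <- make_observer(truth)
  set.seed(seed)
  obs <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(n) {
    observer(schedule[n, , drop = FALSE], n)
  }))
  ids <- unique(obs$residue_id)
  sig <- obs$sigma[match(ids, obs$residue_id)]
  fdraws <- lapply(seq_along(ids), function(k) {
    sample_posterior(obs[obs$residue_id == ids[k], ], prior, sigma = sig[k],
                     omega_a = obs$omega_a[match(ids[k], obs$residue_id)],
                     settings = settings, seed = draw_subseed(),
                     residue_id = ids[k])
  })
  structure(list(kind = "conventional", seed = seed, observations = obs,
                 iterations = list(), schedule = schedule,
                 final = list(draws = fdraws,
                              summaries = lapply(fdraws, summarize_posterior,
                                                 prior = prior)),
                 settings = list(final = settings)),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s run, %d observations of %d residue(s)\n",
              x$kind, nrow(x$observations),
              length(unique(x$observations$residue_id))))
  if (length(x$iterations))
    cat(sprintf("  %d design iterations; seed %d\n", length(x$iterations),
                x$seed))
  invisible(x)
}

#' Persist a run record as a directory of plain-text files
#'
#' Writes `observations.csv`, one `utility_iterNNN.csv` per design
#' iteration, `summaries.csv` (final re-analysis, columns `residue`,
#' `parameter`, `map`, `ci_lo`, `ci_hi`), and `run_meta.json` (seed,
#' settings).
#'
#' @param record A `run_record`.
#' @param dir Output directory (created if needed).
#' @export
save_run_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_observations(record$observations, file.path(dir, "observations.csv"))
  for (it in record$iterations)
    write_utility_csv(it$utility,
                      file.path(dir, sprintf("utility_iter%03d.csv",
                                             it$iteration)))
  if (!is.null(record$final)) {
    summ <- do.call(rbind, lapply(record$final$draws, function(d) {
      s <- summarize_posterior(d)
      cbind(residue = d$residue_id, as.data.frame(s))
    }))
    utils::write.csv(summ, file.path(dir, "summaries.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  meta <- list(kind = record$kind, seed = record$seed,
               settings = lapply(record$settings, function(s)
                 if (is.null(s)) NULL else unclass(s)))
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# deterministic, evenly spaced subset of retained draws
thin_draws <- function(draws, n_keep) {
  n_keep <- max(100L, as.integer(n_keep))
  S <- nrow(draws$draws)
  if (S <= n_keep) return(draws)
  idx <- unique(round(seq(1, S, length.out = n_keep)))
  out <- draws
  out$draws <- draws$draws[idx, , drop = FALSE]
  out$loglik <- draws$loglik[idx]
  out
}
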