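OBS_COLUMNS <- c("iteration", "omega_rf_hz", "omega1_hz", "t_ex_s",
                 "residue_id", "intensity", "sigma")

#' Read / write observation tables
#'
#' The package's interchange format for peak intensities: a CSV with
#' header `iteration, omega_rf_hz, omega1_hz, t_ex_s, residue_id,
#' intensity, sigma`.  Numbers are written with 17 significant digits so a
#' write/read round trip reproduces values exactly.  Malformed rows are
#' rejected with their line number.
#'
#' @param path File path.
#' @return `read_observations()`: a data.frame of observations (possibly
#'   empty).
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(OBS_COLUMNS, names(df))
  if (length(miss))
    stop("observation file missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, OBS_COLUMNS]
  num_cols <- setdiff(OBS_COLUMNS, "residue_id")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & nzchar(df[[cl]]))
    bad <- union(bad, which(is.na(df[[cl]]) | !nzchar(df[[cl]])))
    if (length(bad))
      stop(sprintf("non-numeric '%s' field at line %d of %s", cl,
                   bad[1] + 1L, path))
    df[[cl]] <- v
  }
  df$iteration <- as.integer(df$iteration)
  bad <- which(df$sigma <= 0)
  if (length(bad))
    stop(sprintf("sigma must be > 0 (line %d of %s)", bad[1] + 1L, path))
  bad <- which(df$iteration < 1)
  if (length(bad))
    stop(sprintf("iteration must be >= 1 (line %d of %s)", bad[1] + 1L, path))
  df
}

#' @rdname read_observations
#' @param observations An observation data.frame.
#' @export
write_observations <- function(observations, path) {
  df <- observations[, OBS_COLUMNS]
  for (cl in setdiff(OBS_COLUMNS, c("residue_id", "iteration")))
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write candidate-condition tables
#'
#' CSV with header `omega_rf_hz, omega1_hz, t_ex_s`.
#'
#' @param path File path.
#' @export
read_candidates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_candidate_set(df)
}

#' @rdname read_candidates
#' @param candidates A condition data.frame.
#' @export
write_candidates <- function(candidates, path) {
  df <- as_condition_table(candidates)
  for (cl in names(df)) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write synthetic truth tables
#'
#' CSV mirror of [generate_virtual_protein()] output.
#'
#' @param path File path.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_id", "omega_a", "p_b", "k_ex", "omega_b", "r1", "r2a",
            "r2b", "i0", "sigma")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("truth file missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("spin_system_truth", "data.frame")
  df
}

#' @rdname read_truth
#' @param truth A `spin_system_truth` data.frame.
#' @export
write_truth <- function(truth, path) {
  df <- as.data.frame(truth)
  num <- vapply(df, is.numeric, logical(1))
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' YAML (or JSON) configuration whose keys mirror the scenario fields:
#' either `scenario: <name>` to start from a named preset (see
#' [scenario_config()]), plus optional overrides among `offset_lo`,
#' `offset_hi`, `offset_step`, `strengths`, `durations`, `snr`,
#' `n_residues`, `omega_a` (list), `n_iterations`, `seed`, `truth`
#' (path to a truth CSV), and `mcmc: {loop: {burnin, steps, thin},
#' final: {...}}`.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return A `scenario_config` list.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- if (!is.null(cfg$scenario)) {
    scenario_config(cfg$scenario)
  } else {
    structure(list(kind = "adaptive", snr = 20,
                   mcmc = list(loop = mcmc_settings("loop"),
                               final = mcmc_settings("long"))),
              class = "scenario_config")
  }
  grid_keys <- c("offset_lo", "offset_hi", "offset_step", "strengths",
                 "durations")
  if (any(grid_keys %in% names(cfg))) {
    base$candidates <- build_candidate_grid(
      cfg$offset_lo %||% -1000, cfg$offset_hi %||% 1000,
      cfg$offset_step %||% 5, cfg$strengths %||% c(10, 50),
      cfg$durations %||% 0.5)
  }
  for (key in c("snr", "n_residues", "n_iterations", "seed", "omega_a",
                "truth"))
    if (!is.null(cfg[[key]])) base[[key]] <- cfg[[key]]
  for (slot in c("loop", "final")) {
    ms <- cfg$mcmc[[slot]]
    if (!is.null(ms))
      base$mcmc[[slot]] <- mcmc_settings(burnin = ms$burnin, steps = ms$steps,
                                         thin = ms$thin)
  }
  base
}
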