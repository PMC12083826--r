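#' Named simulation scenarios
#'
#' Preset configurations for the package's standard simulation studies.
#' Adaptive scenarios (candidate sets):
#' * `A1` -- 1 residue, offsets -1000..1000 Hz in 5-Hz steps, strengths
#'   10 and 50 Hz, `t_ex` 0.5 s, plus the reference: 803 candidates;
#'   SNR 20, 200 iterations.
#' * `A2` -- as A1 but a single mid-range strength (25 Hz) and variable
#'   duration `t_ex` in \{0.50, 0.75, 1.00\} s.
#' * `A3` -- 70 residues, 63 evenly spaced offsets in \[-1000, 1000\] Hz,
#'   strengths \{6.3, 13.0, 26.2, 50\} Hz, `t_ex` in \{0.5, 1.0\} s,
#'   192 iterations.
#' * `A4` -- as A3 without the 50-Hz strength.
#'
#' Conventional scenarios (fixed schedules):
#' * `C4` -- 63 evenly spaced offsets in \[-1000, 1000\] Hz (32.3-Hz step)
#'   x strengths \{6.3, 13.0, 26.2\} Hz at `t_ex` 0.5 s plus 3 references:
#'   192 measurements.
#' * `C10` -- as C4 with offsets restricted to \[0, 500\] Hz.
#' * `C11` -- 189 offsets in \[0, 500\] Hz x a single 13.0-Hz strength
#'   plus 3 references: 192 measurements.
#'
#' @param name Scenario name.
#' @return A list of class `scenario_config` with elements `name`, `kind`
#'   (`"adaptive"` or `"conventional"`), `candidates` or `schedule`,
#'   `n_residues`, `snr`, `n_iterations`, and `mcmc` presets.
#' @examples
#' nrow(scenario_config("A1")$candidates)  # 803
#' nrow(scenario_config("C4")$schedule)    # 192
#' @export
scenario_config <- function(name = c("A1", "A2", "A3", "A4", "C4", "C10", "C11")) {
  name <- match.arg(name)
  a_strengths <- c(6.3, 13.0, 26.2, 50)
  cfg <- switch(name,
    A1 = list(kind = "adaptive",
              candidates = build_candidate_grid(-1000, 1000, 5, c(10, 50), 0.5),
              n_residues = 1L, n_iterations = 200L),
    A2 = list(kind = "adaptive",
              candidates = build_candidate_grid(-1000, 1000, 5, 25,
                                                c(0.50, 0.75, 1.00)),
              n_residues = 1L, n_iterations = 200L),
    A3 = list(kind = "adaptive",
              candidates = build_candidate_grid(-1000, 1000, 2000 / 62,
                                                a_strengths, c(0.5, 1.0)),
              n_residues = 70L, n_iterations = 192L),
    A4 = list(kind = "adaptive",
              candidates = build_candidate_grid(-1000, 1000, 2000 / 62,
                                                a_strengths[1:3], c(0.5, 1.0)),
              n_residues = 70L, n_iterations = 192L),
    C4 = list(kind = "conventional",
              schedule = conventional_schedule(63, -1000, 1000,
                                               a_strengths[1:3], 0.5, 3),
              n_residues = 70L),
    C10 = list(kind = "conventional",
               schedule = conventional_schedule(63, 0, 500,
                                                a_strengths[1:3], 0.5, 3),
               n_residues = 70L),
    C11 = list(kind = "conventional",
               schedule = conventional_schedule(189, 0, 500, 13.0, 0.5, 3),
               n_residues = 70L)
  )
  cfg$name <- name
  cfg$snr <- 20
  cfg$mcmc <- list(loop = mcmc_settings("loop"), final = mcmc_settings("long"))
  class(cfg) <- "scenario_config"
  cfg
}

#' Conventional evenly spaced CEST schedule
#'
#' The fixed measurement list of a conventional CEST experiment:
#' `n_offsets` evenly spaced offsets (inclusive endpoints) crossed with
#' each strength at a fixed duration, preceded by `n_references` reference
#' measurements.  Total length is `n_offsets * length(strengths) +
#' n_references`.
#'
#' @param n_offsets Number of offsets (>= 2).
#' @param offset_lo,offset_hi Offset range in Hz.
#' @param strengths Saturation strengths in Hz.
#' @param t_ex Fixed saturation duration in s.
#' @param n_references Number of repeated reference measurements.
#' @return A data.frame of conditions (columns `omega_rf_hz`, `omega1_hz`,
#'   `t_ex_s`), references first, then strength-major offset-ascending.
#' @examples
#' nrow(conventional_schedule(63, -1000, 1000, c(6.3, 13, 26.2), 0.5, 3))  # 192
#' @export
conventional_schedule <- function(n_offsets, offset_lo, offset_hi, strengths,
                                  t_ex = 0.5, n_references = 3) {
  if (n_offsets < 2) stop("n_offsets must be >= 2")
  offsets <- seq(offset_lo, offset_hi, length.out = n_offsets)
  body <- expand.grid(omega_rf_hz = offsets, omega1_hz = as.numeric(strengths),
                      KEEP.OUT.ATTRS = FALSE)
  body <- body[order(body$omega1_hz, body$omega_rf_hz), , drop = FALSE]
  body$t_ex_s <- t_ex
  refs <- data.frame(omega_rf_hz = numeric(n_references),
                     omega1_hz = numeric(n_references),
                     t_ex_s = numeric(n_references))
  out <- rbind(refs, body[, c("omega_rf_hz", "omega1_hz", "t_ex_s")])
  rownames(out) <- NULL
  out
}
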