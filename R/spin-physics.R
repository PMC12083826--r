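#' Bloch-McConnell evolution matrix
#'
#' Builds the homogeneous part `L` and inhomogeneous term `C` of the
#' two-state Bloch-McConnell equation dM/dt = L M + C for the magnetization
#' vector M = (MxA, MyA, MzA, MxB, MyB, MzB) in the frame rotating at the
#' saturation frequency.  `L` contains per-state rotation about z by the
#' offset Omega = 2*pi*(nu_spin - nu_RF), nutation about x by
#' 2*pi*`omega1`, transverse/longitudinal relaxation, and the exchange
#' coupling k_ab = k_ex*p_b, k_ba = k_ex*(1 - p_b).
#'
#' `C` = r1 * m_eq * (0, 0, p_a, 0, 0, p_b) would restore a thermal
#' equilibrium of relative size `m_eq`.  In proton-enhanced 15N CEST the
#' prepared polarization dwarfs the thermal 15N equilibrium, so the
#' relaxation sink is the physically correct default (`m_eq = 0`): the
#' off-resonance intensity then decays as i0*exp(-r1*t_ex), as observed.
#'
#' @param model A [residue_model()].
#' @param cond An [irr_condition()] (its `t_ex` is not used here).
#' @param m_eq Thermal-equilibrium scale relative to the prepared
#'   polarization; default 0.
#' @return A list with the 6x6 matrix `L` and the length-6 vector `C`.
#' @export
bloch_mcconnell_matrix <- function(model, cond, m_eq = 0) {
  th <- as_theta8(model)
  cnd <- as_condition(cond)
  out <- cpp_bm_matrix(th, cnd$omega_rf, cnd$omega1, m_eq)
  lbl <- c("MxA", "MyA", "MzA", "MxB", "MyB", "MzB")
  dimnames(out$L) <- list(lbl, lbl)
  names(out$C) <- lbl
  out
}

#' Exact CEST intensity by matrix-exponential propagation
#'
#' Propagates the prepared magnetization (0, 0, p_a, 0, 0, p_b) under the
#' full Bloch-McConnell matrix for `t_ex` seconds and returns the A-state
#' longitudinal intensity normalized so that `t_ex` = 0 yields exactly `i0`.
#' This is the package's oracle forward model; the fast routes are tested
#' against it.
#'
#' @inheritParams bloch_mcconnell_matrix
#' @param cond An [irr_condition()].
#' @return Intensity in the units of `i0`.
#' @examples
#' m <- residue_model(0.05, 200, 300, 1, 10, 100, 10, 0)
#' propagate_exact(m, reference_condition())  # == i0
#' propagate_exact(m, irr_condition(300, 10, 0.5))
#' @export
propagate_exact <- function(model, cond, m_eq = 0) {
  th <- as_theta8(model)
  cnd <- as_condition(cond)
  as.numeric(cpp_cest_curve(th, cond_matrix(cnd), 0L, m_eq))
}

#' Rotating-frame relaxation rate from the Bloch-McConnell eigenvalue
#'
#' R1rho is the decay rate of the magnetization component spin-locked along
#' the A-state effective field.  It is read off as -Re(lambda) of the
#' eigenvalue of the homogeneous 6x6 matrix whose eigenvector has maximal
#' overlap with the A-state effective-field direction
#' (sin(theta_A), 0, cos(theta_A), 0, 0, 0), theta_A = atan2(omega1,
#' omega_a - omega_rf) in angular units.  Ties are broken towards the
#' non-oscillating (smallest |Im|), slowest (largest Re) mode.
#'
#' @inheritParams propagate_exact
#' @return Rate in s^-1 (positive).
#' @export
r1rho_eigenvalue <- function(model, cond) {
  cnd <- as_condition(cond)
  if (cnd$omega1 <= 0)
    stop("r1rho requires omega1 > 0 (no effective field without saturation)")
  cpp_r1rho(as_theta8(model), cnd$omega_rf, cnd$omega1, 1L)
}

#' Fast rotating-frame relaxation rate
#'
#' A cheap route to the same quantity as [r1rho_eigenvalue()]: a first-order
#' rotating-frame rate (ground-state tilt plus a Trott-Palmer-type exchange
#' term) seeds a Rayleigh-quotient iteration on the 6x6 matrix, which
#' converges to the spin-locked eigenvalue in a handful of 6x6 solves and
#' avoids the full eigendecomposition.  Safeguards (non-convergence, wrong
#' sign, loss of overlap with the effective-field direction) fall back to
#' the eigenvalue route, as do conditions outside the validated +/-5000 Hz
#' frequency range (with a warning).
#'
#' @inheritParams r1rho_eigenvalue
#' @return Rate in s^-1; contract: within 1% relative of
#'   [r1rho_eigenvalue()] over the standard prior box and candidate grids.
#' @export
r1rho_fast <- function(model, cond) {
  th <- as_theta8(model)
  cnd <- as_condition(cond)
  if (cnd$omega1 <= 0)
    stop("r1rho requires omega1 > 0 (no effective field without saturation)")
  if (abs(cnd$omega_rf) > 5000 || abs(th[8]) > 5000 || abs(th[3]) > 5000) {
    warning("condition outside the validated +/-5000 Hz range; ",
            "using the eigenvalue route")
    return(cpp_r1rho(th, cnd$omega_rf, cnd$omega1, 1L))
  }
  cpp_r1rho(th, cnd$omega_rf, cnd$omega1, 2L)
}

#' CEST intensity under one saturation condition
#'
#' The forward model of the design loop.  The reference condition returns
#' `i0` exactly for every method.  For `method = "eigen"` or `"fast"` the
#' intensity follows the spin-lock projection approximation
#' y = i0 * cos^2(theta_A) * exp(-R1rho * t_ex), with R1rho from the
#' corresponding rate routine; `method = "exact"` delegates to
#' [propagate_exact()].  The projection approximation assumes the
#' transverse magnetization in the tilted frame has decayed, so saturation
#' times in (0, 0.5) s trigger a validity warning for the approximate
#' methods.
#'
#' @inheritParams propagate_exact
#' @param method One of `"fast"`, `"eigen"`, `"exact"`.
#' @return Intensity in the units of `i0`.
#' @export
cest_intensity <- function(model, cond, method = c("fast", "eigen", "exact")) {
  method <- match.arg(method)
  cnd <- as_condition(cond)
  if (method != "exact" && cnd$t_ex > 0) {
    if (cnd$t_ex < 0.5)
      warning("t_ex below the 0.5 s validity floor of the spin-lock ",
              "projection approximation")
    if (cnd$omega1 <= 0)
      stop("approximate methods need omega1 > 0 when t_ex > 0")
  }
  code <- c(exact = 0L, eigen = 1L, fast = 2L)[[method]]
  as.numeric(cpp_cest_curve(as_theta8(model), cond_matrix(cnd), code, 0))
}

#' CEST profile over a set of conditions
#'
#' Vectorized [cest_intensity()] over the rows of a candidate table (the
#' simulated counterpart of a measured CEST profile).
#'
#' @inheritParams cest_intensity
#' @param conditions A candidate table (see [build_candidate_grid()]) or
#'   data.frame with columns `omega_rf_hz`, `omega1_hz`, `t_ex_s`.
#' @return The input table with an added `intensity` column.
#' @export
cest_profile <- function(model, conditions, method = c("fast", "eigen", "exact")) {
  method <- match.arg(method)
  tab <- as_condition_table(conditions)
  code <- c(exact = 0L, eigen = 1L, fast = 2L)[[method]]
  tab$intensity <- as.numeric(cpp_cest_curve(as_theta8(model),
                                             cond_matrix(tab), code, 0))
  tab
}
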