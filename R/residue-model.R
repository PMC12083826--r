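#' Per-residue two-state exchange model
#'
#' The seven inferred parameters of one residue's two-state (A <-> B)
#' exchange model plus the known major-state shift `omega_a`: minor-state
#' population `p_b`, exchange rate `k_ex` = kon + koff (s^-1), minor-state
#' shift `omega_b` (Hz), shared longitudinal rate `r1` (s^-1), transverse
#' rates `r2a` and `r2b` (s^-1), and the basal intensity `i0` measured at
#' `t_ex` = 0.  Both states share `r1`; CEST data carry no information on a
#' separate minor-state longitudinal rate.
#'
#' Parameters are validated against the standard prior box used throughout
#' the package: `p_b` in \[0, 0.1\], `k_ex` in \[5, 1000\] s^-1, `omega_b` in
#' \[-1000, 1000\] Hz, `r1` in \[0.1, 10\] s^-1, `r2a/r1` in \[1, 100\],
#' `r2b/r1` in \[1, 1000\], `i0` in \[0.1, 10000\].
#'
#' @param p_b Minor-state population (dimensionless).
#' @param k_ex Exchange rate kon + koff, s^-1.
#' @param omega_b Minor-state 15N shift, Hz.
#' @param r1 Longitudinal relaxation rate shared by both states, s^-1.
#' @param r2a,r2b Transverse relaxation rates of the major/minor state, s^-1.
#' @param i0 Basal intensity at zero saturation time, arbitrary units.
#' @param omega_a Known major-state shift, Hz (fixed, not inferred).
#' @param validate Check the prior-box invariants (default `TRUE`).
#' @return An object of class `residue_model`.
#' @examples
#' residue_model(p_b = 0.02, k_ex = 100, omega_b = 300, r1 = 1,
#'               r2a = 10, r2b = 50, i0 = 10, omega_a = -100)
#' @export
residue_model <- function(p_b, k_ex, omega_b, r1, r2a, r2b, i0, omega_a,
                          validate = TRUE) {
  th <- c(p_b = p_b, k_ex = k_ex, omega_b = omega_b, r1 = r1, r2a = r2a,
          r2b = r2b, i0 = i0, omega_a = omega_a)
  if (!all(is.finite(th))) stop("residue model parameters must be finite")
  if (validate) {
    if (p_b < 0 || p_b > 0.1) stop("p_b outside [0, 0.1]")
    if (k_ex < 5 || k_ex > 1000) stop("k_ex outside [5, 1000] s^-1")
    if (omega_b < -1000 || omega_b > 1000) stop("omega_b outside [-1000, 1000] Hz")
    if (r1 < 0.1 || r1 > 10) stop("r1 outside [0.1, 10] s^-1")
    if (r2a / r1 < 1 || r2a / r1 > 100) stop("r2a/r1 outside [1, 100]")
    if (r2b / r1 < 1 || r2b / r1 > 1000) stop("r2b/r1 outside [1, 1000]")
    if (i0 < 0.1 || i0 > 10000) stop("i0 outside [0.1, 10000]")
  }
  structure(as.list(th), class = "residue_model")
}

#' @export
print.residue_model <- function(x, ...) {
  cat("<residue_model>\n")
  cat(sprintf("  p_b = %.4g   k_ex = %.4g /s   omega_b = %.4g Hz\n",
              x$p_b, x$k_ex, x$omega_b))
  cat(sprintf("  r1 = %.4g /s  r2a = %.4g /s  r2b = %.4g /s  i0 = %.4g\n",
              x$r1, x$r2a, x$r2b, x$i0))
  cat(sprintf("  omega_a = %.4g Hz (known)\n", x$omega_a))
  invisible(x)
}

# 8-vector (p_b, k_ex, omega_b, r1, r2a, r2b, i0, omega_a) for the C++ core
as_theta8 <- function(model) {
  if (inherits(model, "residue_model"))
    return(as.numeric(unlist(model, use.names = FALSE)))
  if (is.numeric(model) && length(model) == 8L) return(as.numeric(model))
  stop("expected a residue_model or a numeric 8-vector")
}

# derived exchange rates; detailed balance p_a*k_ab == p_b*k_ba holds by
# construction
exchange_rates <- function(model) {
  m <- as_theta8(model)
  c(k_ab = m[2] * m[1], k_ba = m[2] * (1 - m[1]))
}
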