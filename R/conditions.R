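#' Saturation (irradiation) condition
#'
#' One candidate experimental condition of a CEST measurement: the offset of
#' the saturation pulse `omega_rf` (Hz), its strength `omega1` (Hz, the
#' nutation frequency nu1 = gamma*B1/2pi) and its duration `t_ex` (s).  The
#' reference experiment -- no saturation, returning the basal intensity --
#' is the condition (0 Hz, 0 Hz, 0 s).
#'
#' @param omega_rf Saturation offset in Hz (linear frequency).
#' @param omega1 Saturation strength in Hz; must be non-negative.
#' @param t_ex Saturation duration in seconds; must be non-negative.
#' @return An object of class `irr_condition`.
#' @examples
#' irr_condition(300, 10, 0.5)
#' is_reference(reference_condition())
#' @export
irr_condition <- function(omega_rf = 0, omega1 = 0, t_ex = 0) {
  stopifnot(is.numeric(omega_rf), is.numeric(omega1), is.numeric(t_ex),
            length(omega_rf) == 1L, length(omega1) == 1L, length(t_ex) == 1L)
  if (!all(is.finite(c(omega_rf, omega1, t_ex))))
    stop("irradiation condition fields must be finite")
  if (t_ex < 0) stop("t_ex must be >= 0")
  if (omega1 < 0) stop("omega1 must be >= 0")
  structure(list(omega_rf = omega_rf, omega1 = omega1, t_ex = t_ex),
            class = "irr_condition")
}

#' @rdname irr_condition
#' @export
reference_condition <- function() irr_condition(0, 0, 0)

#' @rdname irr_condition
#' @param x An `irr_condition` or one row of a candidate table.
#' @export
is_reference <- function(x) {
  x <- as_condition(x)
  x$t_ex == 0
}

#' @rdname irr_condition
#' @param a,b Conditions to compare; equal iff all three fields are equal.
#' @export
conditions_equal <- function(a, b) {
  a <- as_condition(a); b <- as_condition(b)
  a$omega_rf == b$omega_rf && a$omega1 == b$omega1 && a$t_ex == b$t_ex
}

#' @export
print.irr_condition <- function(x, ...) {
  cat(sprintf("<irr_condition> omega_rf = %g Hz, omega1 = %g Hz, t_ex = %g s%s\n",
              x$omega_rf, x$omega1, x$t_ex,
              if (is_reference(x)) " (reference)" else ""))
  invisible(x)
}

# coerce an irr_condition, a 1-row condition data.frame, or a length-3
# numeric to the canonical list form
as_condition <- function(x) {
  if (inherits(x, "irr_condition")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(irr_condition(x$omega_rf_hz, x$omega1_hz, x$t_ex_s))
  }
  if (is.numeric(x) && length(x) == 3L)
    return(irr_condition(x[[1]], x[[2]], x[[3]]))
  stop("cannot interpret object as an irradiation condition")
}

# canonical data.frame of conditions (columns omega_rf_hz, omega1_hz, t_ex_s)
as_condition_table <- function(x) {
  if (is.data.frame(x)) {
    need <- c("omega_rf_hz", "omega1_hz", "t_ex_s")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("condition table lacks column(s): ", paste(miss, collapse = ", "))
    return(x[, need, drop = FALSE])
  }
  cnd <- as_condition(x)
  data.frame(omega_rf_hz = cnd$omega_rf, omega1_hz = cnd$omega1,
             t_ex_s = cnd$t_ex)
}

cond_matrix <- function(x) {
  tab <- as_condition_table(x)
  matrix(c(tab$omega_rf_hz, tab$omega1_hz, tab$t_ex_s), ncol = 3L,
         dimnames = NULL)
}
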