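#' Generate a virtual protein (synthetic ground truth)
#'
#' Draws per-residue true exchange parameters for simulation studies.  The
#' generation ranges are deliberately narrower than the inference prior box
#' (every truth must lie strictly inside it) and emulate a small
#' single-domain protein with a sparsely populated excited state: defaults
#' are `p_b` ~ U\[0.01, 0.05\], `k_ex` ~ logU\[20, 500\] s^-1,
#' `omega_b - omega_a` ~ U\[-800, 800\] Hz, `r1` ~ U\[0.8, 1.5\] s^-1,
#' `r2a/r1` ~ U\[5, 20\], `r2b/r1` ~ U\[10, 200\], `i0` ~ U\[5, 15\], and
#' `omega_a` ~ U\[-800, 800\] Hz.  The (`omega_a`, `omega_b`) pair is
#' rejection-sampled until `omega_b` lies inside the prior box.  The noise
#' SD is derived per residue from the configured signal-to-noise ratio,
#' sigma = i0 / SNR.
#'
#' @param n_residues Number of residues K.
#' @param ranges Named list overriding generation ranges; entries among
#'   `p_b`, `k_ex`, `delta_omega`, `r1`, `r2a_ratio`, `r2b_ratio`, `i0`,
#'   each a length-2 numeric.
#' @param omega_a_range Range of the known major-state shifts, Hz.
#' @param snr Signal-to-noise ratio i0 / sigma (default 20).
#' @param seed Integer seed; `NULL` continues the caller's RNG stream.
#' @param prior The [prior_spec()] whose box the truth must respect.
#' @return A data.frame of class `spin_system_truth` with one row per
#'   residue: `residue_id`, `omega_a`, the seven model parameters
#'   (absolute rates), and `sigma`.
#' @examples
#' generate_virtual_protein(3, seed = 1)
#' @export
generate_virtual_protein <- function(n_residues, ranges = list(),
                                     omega_a_range = c(-800, 800), snr = 20,
                                     seed = NULL, prior = prior_spec()) {
  stopifnot(n_residues >= 1, snr > 0)
  if (!is.null(seed)) set.seed(seed)
  def <- list(p_b = c(0.01, 0.05), k_ex = c(20, 500),
              delta_omega = c(-800, 800), r1 = c(0.8, 1.5),
              r2a_ratio = c(5, 20), r2b_ratio = c(10, 200), i0 = c(5, 15))
  bad <- setdiff(names(ranges), names(def))
  if (length(bad)) stop("unknown generation range(s): ", paste(bad, collapse = ", "))
  def[names(ranges)] <- ranges
  # generation ranges must sit inside the prior box
  box <- function(p) {
    i <- match(p, prior$parameter)
    c(prior$lower[i], prior$upper[i])
  }
  chk <- function(rng, p) {
    b <- box(p)
    if (rng[1] < b[1] || rng[2] > b[2])
      stop("generation range for ", p, " outside the prior box")
  }
  chk(def$p_b, "p_b"); chk(def$k_ex, "k_ex"); chk(def$r1, "r1")
  chk(def$r2a_ratio, "r2a_ratio"); chk(def$r2b_ratio, "r2b_ratio")
  chk(def$i0, "i0")
  ob_box <- box("omega_b")

  runifr <- function(n, rng) stats::runif(n, rng[1], rng[2])
  logunif <- function(n, rng) exp(stats::runif(n, log(rng[1]), log(rng[2])))

  K <- n_residues
  omega_a <- numeric(K)
  omega_b <- numeric(K)
  for (k in seq_len(K)) {
    repeat {
      oa <- runifr(1, omega_a_range)
      ob <- oa + runifr(1, def$delta_omega)
      if (ob >= ob_box[1] && ob <= ob_box[2]) break
    }
    omega_a[k] <- oa
    omega_b[k] <- ob
  }
  r1 <- runifr(K, def$r1)
  i0 <- runifr(K, def$i0)
  out <- data.frame(
    residue_id = sprintf("X%02d", seq_len(K)),
    omega_a = omega_a,
    p_b = runifr(K, def$p_b),
    k_ex = logunif(K, def$k_ex),
    omega_b = omega_b,
    r1 = r1,
    r2a = r1 * runifr(K, def$r2a_ratio),
    r2b = r1 * runifr(K, def$r2b_ratio),
    i0 = i0,
    sigma = i0 / snr,
    stringsAsFactors = FALSE
  )
  attr(out, "snr") <- snr
  attr(out, "seed") <- seed
  class(out) <- c("spin_system_truth", "data.frame")
  out
}

truth_model <- function(truth, k) {
  residue_model(truth$p_b[k], truth$k_ex[k], truth$omega_b[k], truth$r1[k],
                truth$r2a[k], truth$r2b[k], truth$i0[k], truth$omega_a[k])
}
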