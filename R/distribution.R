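#' Micro rate constants of a two-compartment disposition model
#'
#' Given the central volume, steady-state volume, terminal ("area") volume
#' and clearance, solves for the tissue-distribution rates k2 (central to
#' peripheral), k3 (peripheral to central) and the elimination rate k4,
#' using the standard rearrangements: `k4 = Cl / Vc`, `beta = Cl / Vt`,
#' `Vss = Vc (1 + k2/k3)` and the characteristic-root identities
#' `alpha * beta = k3 * k4`, `alpha + beta = k2 + k3 + k4`.  With
#' `R = (Vss - Vc) / Vc` this gives the closed form
#' `k3 = (k4 - beta) / (k4/beta - (R + 1))`.
#'
#' @param v_central Central (initial dilution) volume (L).
#' @param v_ss Steady-state volume of distribution (L).
#' @param v_terminal Terminal-phase volume Cl/beta (L).
#' @param cl Clearance (L min^-1).
#' @return Named list with `k2`, `k3`, `k4`, `alpha`, `beta` (min^-1).
#' @export
#' @examples
#' derive_rate_constants(3, 70, 140, 0.0266)
derive_rate_constants <- function(v_central, v_ss, v_terminal, cl) {
  if (!(v_central > 0 && v_central < v_ss && v_ss < v_terminal))
    stop(sprintf(
      "volume ordering 0 < Vc < Vss < Vterminal violated (%.4g, %.4g, %.4g L)",
      v_central, v_ss, v_terminal), call. = FALSE)
  if (cl <= 0) stop("clearance must be > 0", call. = FALSE)
  k4 <- cl / v_central
  beta <- cl / v_terminal
  R <- (v_ss - v_central) / v_central
  denom <- k4 / beta - (R + 1)  # = (Vt - Vss)/Vc > 0
  k3 <- (k4 - beta) / denom
  if (!is.finite(k3) || k3 <= 0)
    stop("no positive solution for k3 (inconsistent volume ordering)",
         call. = FALSE)
  k2 <- R * k3
  alpha <- k3 * k4 / beta
  list(k2 = k2, k3 = k3, k4 = k4, alpha = alpha, beta = beta)
}

#' Construct one distribution-kinetics scenario
#'
#' @param scenario_id Label (e.g. `"i"`..`"v"` or `"custom"`).
#' @param v_central Central volume hypothesis (L).
#' @param v_terminal Terminal volume hypothesis (L).
#' @param compound A [compound()] providing Vss and Cl.
#' @param settings A [model_settings()] providing the body weight.
#' @return An object of class `distribution_scenario` containing the three
#'   volumes, clearance (L min^-1) and the derived rate constants.
#' @export
distribution_scenario <- function(scenario_id, v_central, v_terminal,
                                  compound, settings = model_settings()) {
  v_ss <- compound$vss_per_kg * settings$body_weight
  cl <- compound$cl_per_kg * settings$body_weight / 1000  # L/min
  if (v_central >= v_ss)
    stop(sprintf(
      "compound '%s': scenario %s has V_central (%.4g L) >= V_ss (%.4g L); model degenerate",
      compound$name, scenario_id, v_central, v_ss), call. = FALSE)
  k <- derive_rate_constants(v_central, v_ss, v_terminal, cl)
  sc <- c(list(scenario_id = scenario_id, v_central = v_central,
               v_ss = v_ss, v_terminal = v_terminal, cl = cl), k)
  class(sc) <- "distribution_scenario"
  sc
}

#' The five hypothetical distribution-kinetics scenarios for a compound
#'
#' Distribution kinetics are unknown at the virtual design stage, so each
#' compound is simulated under five (V_central, V_terminal) hypotheses
#' spanning plausible extremes: (i) Vc = 3.0 L (plasma volume),
#' Vt = 1.1 Vss; (ii) Vc = 0.5 Vss, Vt = 1.1 Vss; (iii) Vc = 3.0 L,
#' Vt = 2.0 Vss; (iv) Vc = 0.5 Vss, Vt = 2.0 Vss; (v) the midpoints of the
#' two Vc values and of the two Vt values.
#'
#' @param compound A [compound()].
#' @param settings A [model_settings()].
#' @return A list of five `distribution_scenario` objects named `i`..`v`.
#' @export
make_scenarios <- function(compound, settings = model_settings()) {
  v_ss <- compound$vss_per_kg * settings$body_weight
  vc_lo <- 3.0
  vc_hi <- 0.5 * v_ss
  vt_lo <- 1.1 * v_ss
  vt_hi <- 2.0 * v_ss
  specs <- list(
    i   = c(vc_lo, vt_lo),
    ii  = c(vc_hi, vt_lo),
    iii = c(vc_lo, vt_hi),
    iv  = c(vc_hi, vt_hi),
    v   = c((vc_lo + vc_hi) / 2, (vt_lo + vt_hi) / 2)
  )
  out <- lapply(names(specs), function(id) {
    distribution_scenario(id, specs[[id]][1], specs[[id]][2], compound,
                          settings)
  })
  names(out) <- names(specs)
  out
}

#' @export
print.distribution_scenario <- function(x, ...) {
  cat(sprintf(
    "<distribution_scenario %s> Vc %.4g | Vss %.4g | Vt %.4g L; k2 %.4g, k3 %.4g, k4 %.4g /min (alpha %.4g, beta %.4g)\n",
    x$scenario_id, x$v_central, x$v_ss, x$v_terminal, x$k2, x$k3, x$k4,
    x$alpha, x$beta))
  invisible(x)
}
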