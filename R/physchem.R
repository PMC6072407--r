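#' Fraction of a compound in its neutral form at a given pH
#'
#' Single-pKa Henderson-Hasselbalch form: a neutral compound is fully
#' neutral; a monoacid has fraction `1 / (1 + 10^(ph - pka))`; a monobase
#' `1 / (1 + 10^(pka - ph))`.  Multiprotic and zwitterionic species are not
#' supported.
#'
#' @param charge_type `"neutral"`, `"monoacid"` or `"monobase"`.
#' @param pka pKa (ignored for neutral compounds).
#' @param ph pH at which to evaluate.
#' @return Fraction neutral in (0, 1].
#' @export
#' @examples
#' fraction_neutral("monoacid", 4.26, 7.4)  # ~7.24e-4
fraction_neutral <- function(charge_type, pka, ph) {
  switch(charge_type,
    neutral = rep(1, length(ph)),
    monoacid = {
      if (any(is.na(pka))) stop("pKa required for a monoacid", call. = FALSE)
      1 / (1 + 10^(ph - pka))
    },
    monobase = {
      if (any(is.na(pka))) stop("pKa required for a monobase", call. = FALSE)
      1 / (1 + 10^(pka - ph))
    },
    stop(sprintf("charge type '%s' is not implemented (supported: %s)",
                 charge_type, paste(charge_types, collapse = "/")),
         call. = FALSE)
  )
}

#' Aqueous solubility corrected from pH 7.4 to pH 6.5
#'
#' Multiplies the measured pH 7.4 solubility by the ratio of the fraction
#' neutral at pH 7.4 to the fraction neutral at pH 6.5.  The product
#' solubility x fraction-neutral (the intrinsic, neutral-species
#' solubility) is therefore conserved across pH.  Monobases gain
#' solubility at the lower pH, monoacids lose it, neutrals are unchanged.
#'
#' @param compound A [compound()].
#' @return Solubility at pH 6.5 (M).
#' @export
solubility_at_ph65 <- function(compound) {
  ratio <- fraction_neutral(compound$charge_type, compound$pka, 7.4) /
    fraction_neutral(compound$charge_type, compound$pka, 6.5)
  compound$solubility_ph74 * ratio
}

# log10-log10 scaling of neutral-species Caco-2 membrane permeability to
# neutral-species human jejunal membrane permeability (32-compound
# calibration; r^2 = 0.88).  Constants fixed, not refit here.
PEFF_SLOPE <- 0.916
PEFF_INTERCEPT <- 1.579

#' Neutral-species human membrane permeability at pH 6.5 from Caco-2 data
#'
#' The apparent Caco-2 permeability is converted to the neutral-species
#' membrane permeability by dividing by the fraction neutral at pH 6.5
#' (pH-partition assumption), then scaled to the human neutral-species
#' membrane permeability through the fixed log-log calibration
#' `log10(Pm_human) = 0.916 log10(Pm_Caco2) + 1.579`.
#'
#' @param compound A [compound()].
#' @return Neutral-species human membrane permeability (cm s^-1).
#' @seealso [peff_human()] for the effective jejunal permeability.
#' @export
membrane_peff_human <- function(compound) {
  fn65 <- fraction_neutral(compound$charge_type, compound$pka, 6.5)
  if (fn65 <= 0)
    stop(sprintf("compound '%s': fraction neutral underflows to 0 at pH 6.5",
                 compound$name), call. = FALSE)
  pm_caco2_neutral <- compound$papp_caco2_ph65 / fn65
  10^(PEFF_SLOPE * log10(pm_caco2_neutral) + PEFF_INTERCEPT)
}

#' Effective human jejunal permeability at pH 6.5
#'
#' Membrane transport acts in series with diffusion across the aqueous
#' boundary layer lining the epithelium, so the effective jejunal
#' permeability combines the ionisation-weighted membrane permeability of
#' [membrane_peff_human()] with the boundary-layer permeability as
#' resistances in series:
#' `1/P_eff = 1/P_ABL + 1/(fn(6.5) * Pm_human_neutral)`.
#' Highly permeable compounds are therefore boundary-layer limited (the
#' effective permeability saturates at `p_abl_human`), while poorly
#' permeable compounds remain membrane limited.  Setting `p_abl_human` to
#' `Inf` disables the boundary layer and returns the bare
#' membrane-pathway permeability `fn(6.5) * Pm_human_neutral`.
#'
#' @param compound A [compound()].
#' @param settings A [model_settings()]; supplies `p_abl_human` (cm s^-1).
#' @return Effective human jejunal permeability at pH 6.5 (cm s^-1).
#' @export
peff_human <- function(compound, settings = model_settings()) {
  fn65 <- fraction_neutral(compound$charge_type, compound$pka, 6.5)
  membrane <- fn65 * membrane_peff_human(compound)
  1 / (1 / settings$p_abl_human + 1 / membrane)
}

#' Absorption rate constant from effective permeability
#'
#' For a uniform cylindrical intestinal segment the surface-to-volume
#' ratio is `2 / r` (the length cancels), amplified by the intestinal-fold
#' factor, so `k1 = (2 * amplification / r) * p_eff * 60` per minute with
#' `r` in cm and `p_eff` in cm/s.  With the default radius 1.25 cm and
#' amplification 2 this is `k1 = 192 * p_eff`.
#'
#' @param p_eff Effective permeability (cm s^-1).
#' @param settings A [model_settings()].
#' @return First-order absorption rate constant (min^-1).
#' @export
k1_from_peff <- function(p_eff, settings = model_settings()) {
  if (any(p_eff < 0)) stop("p_eff must be >= 0", call. = FALSE)
  if (settings$intestinal_radius <= 0)
    stop("intestinal radius must be > 0", call. = FALSE)
  (2 * settings$absorption_amplification / settings$intestinal_radius) *
    p_eff * 60
}

#' Fraction of absorbed drug escaping hepatic first-pass extraction
#'
#' Well-stirred estimate `F_h = 1 - Cl_b / Q_h`, with blood clearance taken
#' equal to plasma clearance (blood/plasma concentration ratio of 1) and
#' the whole-body clearance `cl_per_kg * body_weight`.
#'
#' @param cl_per_kg Plasma clearance (mL min^-1 kg^-1).
#' @param settings A [model_settings()].
#' @return F_h in (0, 1].
#' @export
fraction_escaping_first_pass <- function(cl_per_kg,
                                         settings = model_settings()) {
  cl_total <- cl_per_kg * settings$body_weight  # mL/min
  if (cl_total >= settings$q_h)
    stop(sprintf(
      "clearance %.4g mL/min meets or exceeds liver blood flow %.4g mL/min (F_h <= 0)",
      cl_total, settings$q_h), call. = FALSE)
  1 - cl_total / settings$q_h
}

#' All absorption-side derived parameters for a compound
#'
#' Bundles the pH 6.5 solubility, the saturated intestinal amount (mg) =
#' solubility (M) x molecular weight (g/mol) x intestinal volume (L) x
#' 1000, the scaled human effective permeability, the absorption rate
#' constant k1 and the hepatic first-pass fraction.
#'
#' @param compound A [compound()].
#' @param settings A [model_settings()].
#' @return An object of class `absorption_params`.
#' @export
absorption_params <- function(compound, settings = model_settings()) {
  s65 <- solubility_at_ph65(compound)
  peff <- peff_human(compound, settings)
  ap <- list(
    solubility_ph65 = s65,
    saturated_amount = s65 * compound$mol_weight * settings$v_intestinal *
      1000,
    p_eff_human_ph65 = peff,
    k1 = k1_from_peff(peff, settings),
    f_h = fraction_escaping_first_pass(compound$cl_per_kg, settings)
  )
  class(ap) <- "absorption_params"
  ap
}

#' @export
print.absorption_params <- function(x, ...) {
  cat(sprintf(
    "<absorption_params> S(pH6.5) %.3g M | saturated %.4g mg | Peff %.3g cm/s | k1 %.4g /min | F_h %.4g\n",
    x$solubility_ph65, x$saturated_amount, x$p_eff_human_ph65, x$k1, x$f_h))
  invisible(x)
}
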