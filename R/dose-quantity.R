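#' Sweep the dose list and build log-log dose-quantity curves
#'
#' Runs one repeat-dosing simulation per dose of the settings dose list
#' under one distribution-kinetics scenario, collects the steady-state
#' quantities, and returns one curve (log10 dose vs log10 quantity) per
#' quantity.  Evaluation is restricted to the final dosing interval, which
#' is all the steady-state quantities need.
#'
#' @param compound A [compound()].
#' @param scenario A [distribution_scenario()].
#' @param settings A [model_settings()].
#' @param quantities Character vector of quantity names to keep (default:
#'   everything [steady_state_quantities()] produces for this compound).
#' @return A named list of `dose_quantity_curve` objects, each a list with
#'   `quantity_name`, `log10_dose`, `log10_quantity`.
#' @export
run_dose_sweep <- function(compound, scenario, settings = model_settings(),
                           quantities = NULL) {
  ap <- absorption_params(compound, settings)
  t_last <- (settings$n_doses - 1) * settings$dose_interval
  grid <- build_time_grid(settings)
  times <- grid[grid >= t_last]
  doses <- settings$dose_list
  rows <- lapply(doses, function(d) {
    tr <- simulate_regimen(d, ap, scenario, settings, times = times)
    steady_state_quantities(tr, scenario, compound, settings)
  })
  qmat <- do.call(rbind, rows)
  keep <- if (is.null(quantities)) colnames(qmat) else {
    miss <- setdiff(quantities, colnames(qmat))
    if (length(miss) > 0)
      stop("quantities not available for this compound: ",
           paste(miss, collapse = ", "), call. = FALSE)
    quantities
  }
  out <- lapply(keep, function(qn) {
    curve <- list(quantity_name = qn,
                  log10_dose = log10(doses),
                  log10_quantity = log10(qmat[, qn]))
    class(curve) <- "dose_quantity_curve"
    curve
  })
  names(out) <- keep
  out
}

#' Estimate DQI and HLD from a dose-quantity curve (regression method)
#'
#' Fits ordinary least squares to the longest low-dose prefix of the curve
#' whose fitted log-log slope lies within `slope_tolerance` of 1; the DQI
#' is the intercept of that fit.  The maximum of the log10 quantities (the
#' plateau level, or the highest-dose value when no plateau is reached)
#' is then mapped back through the slope-1 line:
#' `HLD = log10(max_quantity) - DQI`.  The curve is flagged as plateaued
#' when the two highest doses differ by less than 0.001 in log10 quantity.
#'
#' @param curve A `dose_quantity_curve` from [run_dose_sweep()].
#' @param settings A [model_settings()] (for the slope tolerance).
#' @return A list: `dqi`, `hld`, `log10_max_quantity`, `n_linear_points`,
#'   `slope` (the fitted slope of the linear region), `plateau_reached`.
#' @export
estimate_dqi_hld <- function(curve, settings = model_settings()) {
  x <- curve$log10_dose
  y <- curve$log10_quantity
  n <- length(x)
  if (n < 2) stop("need at least two curve points", call. = FALSE)
  tol <- settings$slope_tolerance

  # slopes of every prefix in one pass via cumulative sums
  k <- seq_len(n)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x * x); sxy <- cumsum(x * y)
  denom <- k * sxx - sx^2
  slopes <- (k * sxy - sx * sy) / denom
  slopes[1] <- NA
  ok <- which(!is.na(slopes) & abs(slopes - 1) <= tol)
  if (length(ok) == 0)
    stop(sprintf(
      "no prefix of >= 2 points has slope within %g of 1: non-linear PK at all tested doses",
      tol), call. = FALSE)
  m <- max(ok)
  slope <- slopes[m]
  dqi <- (sy[m] - slope * sx[m]) / m

  log10_max <- max(y)
  hld <- log10_max - dqi  # slope treated as exactly 1 in the rearrangement
  plateau <- (y[n] - y[n - 1]) < 0.001
  list(dqi = dqi, hld = hld, log10_max_quantity = log10_max,
       n_linear_points = m, slope = slope, plateau_reached = plateau)
}

#' Fit the dose-quantity curve to a smooth saturation power function
#'
#' Nonlinear least squares of
#' `log10(quantity) = log10(max_quantity) - log10(1 + 10^(HLD - log10(dose)))`,
#' which reduces to the slope-1 line with intercept
#' `log10(max_quantity) - HLD` at low dose and to the plateau at high
#' dose; at `dose = 10^HLD` the curve sits `log10(2)` below the plateau.
#' Starting values come from the regression method; on non-convergence the
#' regression estimates are returned with a warning and the residuals of
#' the failed fit attached.
#'
#' @param curve A `dose_quantity_curve`.
#' @param settings A [model_settings()].
#' @return A list: `dqi`, `hld`, `log10_max_quantity`, `converged`.
#' @export
fit_power_curve <- function(curve, settings = model_settings()) {
  start <- estimate_dqi_hld(curve, settings)
  df <- data.frame(ld = curve$log10_dose, lq = curve$log10_quantity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lq ~ m - log10(1 + 10^(h - ld)), data = df,
      start = list(m = start$log10_max_quantity, h = start$hld),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("power-curve fit did not converge (", conditionMessage(fit),
            "); falling back to the regression estimates", call. = FALSE)
    return(list(dqi = start$dqi, hld = start$hld,
                log10_max_quantity = start$log10_max_quantity,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(dqi = unname(cf["m"] - cf["h"]), hld = unname(cf["h"]),
       log10_max_quantity = unname(cf["m"]), converged = TRUE)
}

#' Predicted quantity at a dose from DQI and HLD
#'
#' Below the highest linear dose the quantity is `dose * 10^DQI`; above
#' it, the prediction is capped at the maximum quantity
#' `10^(HLD + DQI)`.
#'
#' @param dqi Dose-quantity intercept (log10 units of the quantity).
#' @param hld Highest linear dose (log10 mg).
#' @param dose_mg Dose (mg), > 0.
#' @return Predicted quantity (linear scale).
#' @export
#' @examples
#' log10(quantity_at_dose(-2.30, 0.39, 50))  # capped: -1.91
quantity_at_dose <- function(dqi, hld, dose_mg) {
  if (any(dose_mg <= 0)) stop("dose must be > 0", call. = FALSE)
  ifelse(log10(dose_mg) <= hld, dose_mg * 10^dqi, 10^(hld + dqi))
}

#' @export
print.dose_quantity_curve <- function(x, ...) {
  cat(sprintf("<dose_quantity_curve> %s: %d points, log10(dose) %g .. %g\n",
              x$quantity_name, length(x$log10_dose), min(x$log10_dose),
              max(x$log10_dose)))
  invisible(x)
}
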