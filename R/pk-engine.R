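# Closed-form piecewise solution of the three-compartment oral model:
# compartment A (intestinal segment, saturable first-order/zero-order
# transfer, absorption restricted to a window after a gastric lag), feeding
# compartment B (central, site of elimination) which exchanges with
# compartment C (peripheral):
#   dB/dt = input(t) + k3*C - (k2 + k4)*B
#   dC/dt = k2*B - k3*C
# The disposition matrix M = [[-(k2+k4), k3], [k2, -k3]] has eigenvalues
# -alpha, -beta (alpha*beta = k3*k4, alpha+beta = k2+k3+k4), so exp(M t) and
# its convolutions with constant and exponential inputs have two-exponential
# closed forms.  Everything below is vectorised over time.

# exp(x) - style helpers with removable singularities --------------------

# (1 - exp(-a*d)) / a, with the a -> 0 limit d; vectorised over d
.int_exp <- function(a, d) {
  if (abs(a) < 1e-14) return(d)
  (1 - exp(-a * d)) / a
}

# int_0^d exp(-a*(d-s)) * exp(-k*s) ds = (exp(-k*d) - exp(-a*d)) / (a - k)
# with the a -> k limit d * exp(-a*d); vectorised over d
.conv_exp <- function(a, k, d) {
  if (abs(a - k) < 1e-12 * max(a, k, 1)) return(d * exp(-a * d))
  (exp(-k * d) - exp(-a * d)) / (a - k)
}

# Evaluate B and C at relative phase times d (vector), starting from state
# x0 = c(B0, C0), under input rate r(s) = c0 + c1 * exp(-k1 * s) into B.
.propagate <- function(d, x0, sc, c0 = 0, c1 = 0, k1 = 0) {
  a <- sc$alpha; b <- sc$beta
  m11 <- -(sc$k2 + sc$k4)
  dd <- b - a  # < 0, eigenvalue gap
  f1 <- exp(-a * d); f2 <- exp(-b * d)
  # exp(M d) entries
  e11 <- (f1 * (m11 + b) - f2 * (m11 + a)) / dd
  e12 <- sc$k3 * (f1 - f2) / dd
  e21 <- sc$k2 * (f1 - f2) / dd
  e22 <- (f1 * (-sc$k3 + b) - f2 * (-sc$k3 + a)) / dd
  B <- e11 * x0[1] + e12 * x0[2]
  C <- e21 * x0[1] + e22 * x0[2]
  if (c0 != 0) {
    g1 <- .int_exp(a, d)
    g2 <- .int_exp(b, d)
    B <- B + c0 * (g1 * (m11 + b) - g2 * (m11 + a)) / dd
    C <- C + c0 * sc$k2 * (g1 - g2) / dd
  }
  if (c1 != 0) {
    h1 <- .conv_exp(a, k1, d)
    h2 <- .conv_exp(b, k1, d)
    B <- B + c1 * (h1 * (m11 + b) - h2 * (m11 + a)) / dd
    C <- C + c1 * sc$k2 * (h1 - h2) / dd
  }
  cbind(B = B, C = C)
}

#' Dose event times of the repeat-dosing protocol
#'
#' @param settings A [model_settings()].
#' @return A data.frame with one row per dose: `index`, `t_i` (dose time),
#'   `t_iA` (start of the absorption window, after the gastric lag) and
#'   `t_iB` (end of the absorption window), all in minutes.
#' @export
dose_events <- function(settings = model_settings()) {
  i <- seq_len(settings$n_doses)
  t_i <- (i - 1) * settings$dose_interval
  data.frame(index = i,
             t_i = t_i,
             t_iA = t_i + settings$gastric_lag,
             t_iB = t_i + settings$gastric_lag + settings$absorption_window)
}

#' Time at which the intestinal compartment becomes unsaturated
#'
#' For a dose above the saturated amount, transfer out of the intestinal
#' compartment is zero-order at rate `k1 * saturated_amount` until the
#' remaining amount falls to the saturated amount, at
#' `(dose - saturated_amount) / (k1 * saturated_amount)` minutes after the
#' start of the window (or never within the window, for very large doses).
#'
#' @param dose_mg Dose (mg).
#' @param ap An [absorption_params()].
#' @return Minutes after the start of the absorption window, or `NA` when
#'   the dose does not saturate the compartment.
#' @export
unsaturation_delay <- function(dose_mg, ap) {
  if (dose_mg <= ap$saturated_amount) return(NA_real_)
  (dose_mg - ap$saturated_amount) / (ap$k1 * ap$saturated_amount)
}

# Amounts in A, B, C at times `rel` (minutes since the dose time t_i) for a
# single dose considered in isolation.
.dose_amounts <- function(rel, dose_mg, ap, sc, settings) {
  n <- length(rel)
  A <- numeric(n); B <- numeric(n); C <- numeric(n)
  if (dose_mg == 0 || n == 0) return(cbind(A = A, B = B, C = C))
  if (ap$k1 * ap$saturated_amount <= 0)
    stop("k1 * saturated_amount is zero with a positive dose: no absorption pathway",
         call. = FALSE)
  lag <- settings$gastric_lag
  win <- settings$absorption_window
  S <- ap$saturated_amount
  k1 <- ap$k1
  r0 <- ap$f_h * k1 * S  # zero-order input rate into B while saturated

  t_z <- if (dose_mg > S) min((dose_mg - S) / (k1 * S), win) else 0
  fo_len <- win - t_z                     # duration of the first-order phase
  A0f <- if (dose_mg > S) S else dose_mg  # amount in A when first-order starts

  # states at the phase boundaries
  x_z <- if (t_z > 0) .propagate(t_z, c(0, 0), sc, c0 = r0)[1, ] else c(0, 0)
  x_b <- if (fo_len > 0) {
    .propagate(fo_len, x_z, sc, c1 = ap$f_h * k1 * A0f, k1 = k1)[1, ]
  } else x_z

  tau <- rel - lag  # time since absorption start; < 0 before the bolus lands
  in_zero <- which(tau >= 0 & tau < t_z)
  in_fo <- which(tau >= t_z & tau < win)
  post <- which(tau >= win)

  if (length(in_zero) > 0) {
    d <- tau[in_zero]
    A[in_zero] <- dose_mg - k1 * S * d
    xc <- .propagate(d, c(0, 0), sc, c0 = r0)
    B[in_zero] <- xc[, "B"]; C[in_zero] <- xc[, "C"]
  }
  if (length(in_fo) > 0) {
    d <- tau[in_fo] - t_z
    A[in_fo] <- A0f * exp(-k1 * d)
    xc <- .propagate(d, x_z, sc, c1 = ap$f_h * k1 * A0f, k1 = k1)
    B[in_fo] <- xc[, "B"]; C[in_fo] <- xc[, "C"]
  }
  if (length(post) > 0) {
    d <- tau[post] - win
    # remaining compound in A is discarded at the end of the window
    xc <- .propagate(d, x_b, sc)
    B[post] <- xc[, "B"]; C[post] <- xc[, "C"]
  }
  cbind(A = A, B = B, C = C)
}

#' Evaluation time grid of a simulation
#'
#' The union of (a) the regular grid at `grid_step` intervals over the
#' whole simulation, (b) `n_random_timepoints` uniform-random times drawn
#' with the settings seed, and (c) all protocol-special times: the start,
#' every dose time, every absorption-window start and end, the end of the
#' simulation, and any caller-supplied extra times (e.g. unsaturation
#' times).  Sorted and de-duplicated; the same seed always yields the same
#' grid.
#'
#' @param settings A [model_settings()].
#' @param extra_times Additional times to include (min).
#' @return Numeric vector of times (min).
#' @export
build_time_grid <- function(settings = model_settings(), extra_times = NULL) {
  regular <- seq(0, settings$sim_length, by = settings$grid_step)
  random <- with_seed(settings$rng_seed,
                      stats::runif(settings$n_random_timepoints, 0,
                                   settings$sim_length))
  ev <- dose_events(settings)
  special <- c(0, ev$t_i, ev$t_iA, ev$t_iB, settings$sim_length, extra_times)
  sort(unique(c(regular, random, special)))
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.new_trace <- function(times, A, B, C, v_central) {
  tr <- data.frame(times = times, amount_A = A, amount_B = B, amount_C = C,
                   conc_central = B / v_central)
  class(tr) <- c("pk_trace", "data.frame")
  tr
}

#' Compartment amounts over time for one dose in isolation
#'
#' Piecewise-analytic solution for a single oral dose: nothing before the
#' bolus lands in the intestinal compartment; a zero-order transfer phase
#' at rate `k1 * saturated_amount` while the compartment is saturated
#' (doses above the saturated amount); a first-order phase at rate
#' `k1 * A(t)`; and, after the absorption window closes (remaining
#' intestinal compound discarded), free two-compartment disposition.  The
#' hepatic first-pass fraction scales the input flux into the central
#' compartment.
#'
#' @param dose_mg Dose (mg).
#' @param absorption_params An [absorption_params()].
#' @param scenario A [distribution_scenario()].
#' @param dose_event A single row of [dose_events()] (or a list with
#'   `t_i`).
#' @param times Absolute evaluation times (min); times before `t_i`
#'   evaluate to zero.
#' @param settings A [model_settings()].
#' @return A `pk_trace` data.frame: `times`, `amount_A`, `amount_B`,
#'   `amount_C` (mg) and `conc_central` (mg L^-1).
#' @export
single_dose_response <- function(dose_mg, absorption_params, scenario,
                                 dose_event, times,
                                 settings = model_settings()) {
  if (dose_mg < 0) stop("dose must be >= 0", call. = FALSE)
  rel <- times - dose_event$t_i
  x <- .dose_amounts(rel, dose_mg, absorption_params, scenario, settings)
  .new_trace(times, x[, "A"], x[, "B"], x[, "C"], scenario$v_central)
}

#' Sum per-dose traces on a shared grid (principle of superposition)
#'
#' @param traces A list of `pk_trace` objects on identical time grids.
#' @return A `pk_trace` with pointwise-summed amounts and concentration.
#' @export
superpose <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$times
  for (tr in traces[-1]) {
    if (length(tr$times) != length(t0) || any(tr$times != t0))
      stop("superpose: traces are not on the same time grid", call. = FALSE)
  }
  add <- function(field) Reduce(`+`, lapply(traces, `[[`, field))
  tr <- traces[[1]]
  out <- data.frame(times = t0,
                    amount_A = add("amount_A"),
                    amount_B = add("amount_B"),
                    amount_C = add("amount_C"),
                    conc_central = add("conc_central"))
  class(out) <- c("pk_trace", "data.frame")
  out
}

#' Superposed repeat-dosing trace
#'
#' Simulates every dose of the protocol in isolation and sums the
#' contributions at each evaluation time.  All doses share the dose size.
#' A single vectorised evaluation over the stacked relative times is used;
#' it is algebraically identical to calling [single_dose_response()] per
#' dose and [superpose()]-ing.
#'
#' @param dose_mg Dose given at each dosing time (mg).
#' @param absorption_params An [absorption_params()].
#' @param scenario A [distribution_scenario()].
#' @param settings A [model_settings()].
#' @param times Absolute evaluation times (min); defaults to the full
#'   [build_time_grid()].
#' @return A `pk_trace`.
#' @export
simulate_regimen <- function(dose_mg, absorption_params, scenario,
                             settings = model_settings(),
                             times = build_time_grid(settings)) {
  ev <- dose_events(settings)
  n <- length(times)
  rel <- rep(times, nrow(ev)) -
    rep(ev$t_i, each = n)  # stacked relative times, dose-major
  x <- .dose_amounts(rel, dose_mg, absorption_params, scenario, settings)
  dim_sum <- function(v) rowSums(matrix(v, nrow = n))
  .new_trace(times, dim_sum(x[, "A"]), dim_sum(x[, "B"]),
             dim_sum(x[, "C"]), scenario$v_central)
}

# Composite Simpson's rule on uniformly spaced samples y with step h;
# length(y) - 1 must be even.
simpson <- function(y, h) {
  n <- length(y) - 1
  if (n < 2 || n %% 2 != 0)
    stop("simpson: need an even, positive number of intervals",
         call. = FALSE)
  odd <- seq(2, n, by = 2)                              # weight-4 samples
  even <- if (n > 2) seq(3, n - 1, by = 2) else integer(0)  # weight-2
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[odd]) + 2 * sum(y[even]))
}

#' Steady-state exposure quantities over the final dosing interval
#'
#' Evaluated over the last dosing interval, where steady state is assumed
#' to have been reached: the maximum, minimum and average central
#' concentration, the central AUC (composite Simpson's rule on a uniform
#' sub-grid at the settings grid step, internally refined to an even
#' number of intervals), the peripheral analogues (peripheral
#' concentration uses the volume `v_ss - v_central`), and -- when plasma
#' protein binding is available -- the free-level variants obtained by
#' multiplying by the fraction unbound.
#'
#' @param trace A superposed `pk_trace` covering the final interval.
#' @param scenario The [distribution_scenario()] used.
#' @param compound The [compound()] simulated (for protein binding).
#' @param settings A [model_settings()].
#' @return Named numeric vector: `css_central_max`, `css_central_min`,
#'   `css_central_avg`, `auc_central`, the `_peripheral` analogues, and
#'   `free_`-prefixed variants when binding data exist.  Concentrations in
#'   mg L^-1, AUCs in mg min L^-1.
#' @export
steady_state_quantities <- function(trace, scenario, compound,
                                    settings = model_settings()) {
  t_last <- (settings$n_doses - 1) * settings$dose_interval
  t_end <- settings$sim_length
  if (min(trace$times) > t_last || max(trace$times) < t_end)
    stop("trace does not cover the final dosing interval", call. = FALSE)
  sel <- trace$times >= t_last & trace$times <= t_end
  conc_c <- trace$conc_central[sel]
  v_peri <- scenario$v_ss - scenario$v_central
  conc_p <- trace$amount_C[sel] / v_peri

  # uniform sub-grid for Simpson; refine if the interval count is odd
  step <- settings$grid_step
  n_int <- (t_end - t_last) / step
  if (n_int %% 1 != 0 || n_int %% 2 != 0) {
    step <- (t_end - t_last) / (2 * ceiling(n_int / 2))
  }
  sub <- seq(t_last, t_end, by = step)
  yc <- stats::approx(trace$times, trace$conc_central, xout = sub)$y
  yp <- stats::approx(trace$times, trace$amount_C, xout = sub)$y / v_peri
  auc_c <- simpson(yc, step)
  auc_p <- simpson(yp, step)

  interval <- t_end - t_last
  q <- c(css_central_max = max(conc_c),
         css_central_min = min(conc_c),
         css_central_avg = auc_c / interval,
         auc_central = auc_c,
         css_peripheral_max = max(conc_p),
         css_peripheral_min = min(conc_p),
         css_peripheral_avg = auc_p / interval,
         auc_peripheral = auc_p)
  if (!is.na(compound$ppb_percent_bound)) {
    fu <- (100 - compound$ppb_percent_bound) / 100
    free <- q * fu
    names(free) <- paste0("free_", names(q))
    q <- c(q, free)
  }
  q
}
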