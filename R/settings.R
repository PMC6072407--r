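#' Simulation protocol settings
#'
#' Every fixed constant of the simulation protocol, bundled in one object.
#' The defaults reproduce the standard protocol: a 0.08 L cylindrical
#' intestinal segment of radius 1.25 cm with a two-fold surface
#' amplification for intestinal folds, a 1 h gastric lag followed by a 4 h
#' absorption window, 14 twice-daily doses spanning 168 h, a 70 kg subject
#' with 1450 mL min^-1 liver blood flow, a 20-dose sweep from 1e-6 mg to
#' 10 g, a 15 min regular evaluation grid augmented by 336 random time
#' points, a +/-1e-4 slope tolerance for the linear-PK region, and 50
#' Gaussian input-error scenarios with SD 0.3 on the log10 scale.
#'
#' @param v_intestinal Intestinal fluid volume (L).
#' @param intestinal_radius Radius of the cylindrical intestinal segment (cm).
#' @param absorption_amplification Surface-area amplification factor
#'   accounting for intestinal folds (dimensionless).
#' @param gastric_lag Delay between dosing and arrival of the bolus in the
#'   intestinal compartment (min).
#' @param absorption_window Duration over which absorption is permitted
#'   (min); drug remaining in the intestinal compartment afterwards is
#'   discarded.
#' @param dose_interval Time between repeat doses (min).
#' @param n_doses Number of repeat doses.
#' @param sim_length Total simulated time (min); must equal
#'   `n_doses * dose_interval`.
#' @param body_weight Subject body weight (kg).
#' @param q_h Liver blood flow (mL min^-1).
#' @param p_abl_human Aqueous boundary-layer permeability of the human
#'   jejunum (cm s^-1), the ceiling of the effective permeability; `Inf`
#'   disables the boundary layer (see [peff_human()]).
#' @param dose_list Oral doses for the dose sweep (mg).
#' @param grid_step Spacing of the regular evaluation grid (min).
#' @param n_random_timepoints Number of additional uniform-random
#'   evaluation times.
#' @param rng_seed Integer seed for every stochastic element (random grid
#'   times, input-error draws).
#' @param slope_tolerance Half-width of the acceptance band around a
#'   log-log slope of 1 when selecting the linear-PK region.
#' @param error_sd_log10 Standard deviation (log10 scale) of the Gaussian
#'   input-error model for Vss and Cl.
#' @param n_error_scenarios Number of perturbed input scenarios (the
#'   original is always added as scenario 0).
#'
#' @return An object of class `model_settings` (a named list).
#' @seealso [load_settings()] to read overrides from a YAML/JSON file.
#' @export
#' @examples
#' s <- model_settings()
#' s$dose_interval  # 720 min, i.e. twice daily
model_settings <- function(v_intestinal = 0.08,
                           intestinal_radius = 1.25,
                           absorption_amplification = 2,
                           gastric_lag = 60,
                           absorption_window = 240,
                           dose_interval = 720,
                           n_doses = 14,
                           sim_length = n_doses * dose_interval,
                           body_weight = 70,
                           q_h = 1450,
                           p_abl_human = 4.6e-4,
                           dose_list = default_dose_list(),
                           grid_step = 15,
                           n_random_timepoints = 336,
                           rng_seed = 20180205L,
                           slope_tolerance = 1e-4,
                           error_sd_log10 = 0.3,
                           n_error_scenarios = 50) {
  s <- list(
    v_intestinal = v_intestinal,
    intestinal_radius = intestinal_radius,
    absorption_amplification = absorption_amplification,
    gastric_lag = gastric_lag,
    absorption_window = absorption_window,
    dose_interval = dose_interval,
    n_doses = n_doses,
    sim_length = sim_length,
    body_weight = body_weight,
    q_h = q_h,
    p_abl_human = p_abl_human,
    dose_list = dose_list,
    grid_step = grid_step,
    n_random_timepoints = n_random_timepoints,
    rng_seed = rng_seed,
    slope_tolerance = slope_tolerance,
    error_sd_log10 = error_sd_log10,
    n_error_scenarios = n_error_scenarios
  )
  class(s) <- "model_settings"
  validate_settings(s)
}

#' The 20 doses of the standard sweep (mg)
#'
#' @return Numeric vector of length 20.
#' @export
default_dose_list <- function() {
  c(0.000001, 0.000005, 0.00001, 0.00005, 0.0001, 0.001, 0.01, 0.1,
    1, 10, 25, 50, 75, 100, 250, 500, 1000, 2500, 5000, 10000)
}

validate_settings <- function(s) {
  stopifnot(inherits(s, "model_settings"))
  num_pos <- c("v_intestinal", "intestinal_radius", "absorption_amplification",
               "absorption_window", "dose_interval", "body_weight", "q_h",
               "p_abl_human", "grid_step")
  for (f in num_pos) {
    if (!is.numeric(s[[f]]) || length(s[[f]]) != 1L || is.na(s[[f]]) ||
        s[[f]] <= 0) {
      stop(sprintf("settings: '%s' must be a single positive number", f),
           call. = FALSE)
    }
  }
  if (!is.numeric(s$error_sd_log10) || s$error_sd_log10 < 0)
    stop("settings: 'error_sd_log10' must be >= 0", call. = FALSE)
  if (!is.numeric(s$gastric_lag) || s$gastric_lag < 0)
    stop("settings: 'gastric_lag' must be >= 0", call. = FALSE)
  if (!is.numeric(s$n_doses) || s$n_doses < 1 || s$n_doses %% 1 != 0)
    stop("settings: 'n_doses' must be a positive integer", call. = FALSE)
  if (!is.numeric(s$n_error_scenarios) || s$n_error_scenarios < 0)
    stop("settings: 'n_error_scenarios' must be >= 0", call. = FALSE)
  if (!is.numeric(s$slope_tolerance) || s$slope_tolerance <= 0)
    stop("settings: 'slope_tolerance' must be > 0", call. = FALSE)
  if (!isTRUE(all.equal(s$sim_length, s$n_doses * s$dose_interval)))
    stop("settings: 'sim_length' must equal n_doses * dose_interval",
         call. = FALSE)
  if (!is.numeric(s$dose_list) || length(s$dose_list) < 1 ||
      any(s$dose_list < 0))
    stop("settings: 'dose_list' must be non-negative doses (mg)",
         call. = FALSE)
  if (is.unsorted(s$dose_list, strictly = TRUE))
    stop("settings: 'dose_list' must be strictly increasing", call. = FALSE)
  s
}

#' Read simulation settings from a YAML or JSON file
#'
#' The file may contain any subset of the [model_settings()] keys; values
#' not given keep their protocol defaults.  An absent `path` returns the
#' defaults unchanged.  Unknown keys are an error, as are non-physical
#' values (negative durations or volumes).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL`.
#' @return A `model_settings` object.
#' @export
load_settings <- function(path = NULL) {
  if (is.null(path)) return(model_settings())
  if (!file.exists(path)) stop("settings file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(model_settings))
  known <- setdiff(known, "sim_length")  # derived unless given explicitly
  unknown <- setdiff(names(raw), c(known, "sim_length"))
  if (length(unknown) > 0)
    stop("settings: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_settings, raw)
}

#' @export
print.model_settings <- function(x, ...) {
  cat("Simulation protocol settings\n")
  cat(sprintf("  %d doses every %g min (%g h total), gastric lag %g min, window %g min\n",
              x$n_doses, x$dose_interval, x$sim_length / 60, x$gastric_lag,
              x$absorption_window))
  cat(sprintf("  V_intestinal %g L, r %g cm, amplification %g; BW %g kg, Q_h %g mL/min\n",
              x$v_intestinal, x$intestinal_radius, x$absorption_amplification,
              x$body_weight, x$q_h))
  cat(sprintf("  dose sweep: %d doses (%g .. %g mg); error SD(log10) %g x %d scenarios\n",
              length(x$dose_list), min(x$dose_list), max(x$dose_list),
              x$error_sd_log10, x$n_error_scenarios))
  invisible(x)
}
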