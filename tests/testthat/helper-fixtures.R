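# Small synthetic compounds and shared objects used across test files.

neutral_probe <- function(papp = 1e-5, sol = 1e-4, vss = 1, cl = 1,
                          ppb = NA_real_, mw = 300) {
  compound("probe", "neutral", NA, sol, papp, vss, cl, ppb, mw)
}

# a disposition scenario assembled directly from micro rate constants,
# bypassing the volume-based constructor (used for edge cases like k4 = 0)
raw_scenario <- function(k2, k3, k4, v_central, v_ss = NA, id = "raw") {
  disc <- sqrt((k2 + k3 + k4)^2 - 4 * k3 * k4)
  alpha <- ((k2 + k3 + k4) + disc) / 2
  beta <- ((k2 + k3 + k4) - disc) / 2
  sc <- list(scenario_id = id, v_central = v_central, v_ss = v_ss,
             v_terminal = NA, cl = k4 * v_central,
             k2 = k2, k3 = k3, k4 = k4, alpha = alpha, beta = beta)
  class(sc) <- "distribution_scenario"
  sc
}

fixture_compounds <- function() example_compounds()
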