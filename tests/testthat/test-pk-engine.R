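settings <- model_settings()
drugs <- fixture_compounds()

test_that("the evaluation grid combines regular, random and protocol times", {
  g <- build_time_grid(settings)
  regular <- seq(0, settings$sim_length, by = 15)
  expect_length(regular, 673)
  expect_true(all(regular %in% g))
  ev <- dose_events(settings)
  expect_true(all(c(ev$t_i, ev$t_iA, ev$t_iB) %in% g))
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_identical(g, build_time_grid(settings))  # same seed, same grid
  g2 <- build_time_grid(model_settings(rng_seed = 99L))
  expect_false(length(g) == length(g2) && all(g == g2))
  expect_true(123.456 %in% build_time_grid(settings, extra_times = 123.456))
})

test_that("dose events follow lag and window timing", {
  ev <- dose_events(settings)
  expect_equal(nrow(ev), 14)
  expect_equal(ev$t_i, (0:13) * 720)
  expect_equal(ev$t_iA - ev$t_i, rep(60, 14))
  expect_equal(ev$t_iB - ev$t_iA, rep(240, 14))
  ap <- absorption_params(drugs[["diazepam"]], settings)
  expect_true(is.na(unsaturation_delay(ap$saturated_amount / 2, ap)))
  d <- 10 * ap$saturated_amount
  expect_equal(unsaturation_delay(d, ap),
               (d - ap$saturated_amount) / (ap$k1 * ap$saturated_amount))
})

test_that("single-dose traces honour the absorption-phase structure", {
  dz <- drugs[["diazepam"]]
  ap <- absorption_params(dz, settings)
  sc <- make_scenarios(dz, settings)$i
  ev <- dose_events(settings)[1, ]
  times <- sort(unique(c(seq(0, 2000, by = 5), 60, 180, 300)))

  tr0 <- single_dose_response(0, ap, sc, ev, times, settings)
  expect_true(all(tr0$amount_A == 0 & tr0$amount_B == 0 & tr0$amount_C == 0))

  tr <- single_dose_response(10000, ap, sc, ev, times, settings)
  expect_true(all(tr$amount_A >= 0 & tr$amount_B >= 0 & tr$amount_C >= 0))
  # 10 g saturates the whole window: linear zero-order depletion of A
  expect_equal(tr$amount_A[tr$times == 180],
               10000 - ap$k1 * ap$saturated_amount * 120)
  after <- tr$times >= 60 & tr$times <= 300
  expect_true(all(diff(tr$amount_A[after]) <= 1e-9))
  expect_true(all(tr$amount_A[tr$times >= 300] == 0))
  expect_true(all(tr$amount_A[tr$times < 60] == 0))

  bad_ap <- ap; bad_ap$k1 <- 0
  expect_error(single_dose_response(1, bad_ap, sc, ev, times, settings),
               "no absorption pathway")
})

test_that("analytic solution matches the stiff ODE oracle across regimes", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(cp = "diazepam", scn = "i", dose = 1e-3),     # first-order only
    list(cp = "diazepam", scn = "iii", dose = 100),    # zero-order then first
    list(cp = "diazepam", scn = "i", dose = 10000),    # saturated full window
    list(cp = "chlorpromazine", scn = "ii", dose = 50),
    list(cp = "prazosin", scn = "v", dose = 10),
    list(cp = "furosemide", scn = "i", dose = 1)       # slow absorber
  )
  rel_times <- sort(unique(c(seq(0, 2000, by = 25), 60, 61, 90, 150, 299,
                             300, 301, 500)))
  ev <- dose_events(settings)[1, ]
  for (cs in cases) {
    cp <- drugs[[cs$cp]]
    ap <- absorption_params(cp, settings)
    sc <- make_scenarios(cp, settings)[[cs$scn]]
    tr <- single_dose_response(cs$dose, ap, sc, ev, rel_times, settings)
    orc <- ode_oracle(cs$dose, ap, sc, settings, rel_times)
    scale_b <- max(orc$B); scale_c <- max(orc$C)
    expect_lt(max(abs(tr$amount_B - orc$B)) / scale_b, 1e-6,
              label = paste("B mismatch:", cs$cp, cs$scn, cs$dose))
    expect_lt(max(abs(tr$amount_C - orc$C)) / scale_c, 1e-6,
              label = paste("C mismatch:", cs$cp, cs$scn, cs$dose))
  }
})

test_that("mass balance holds with elimination switched off", {
  # raw two-compartment scenario with k4 = 0 and no first-pass loss
  sc <- raw_scenario(k2 = 0.01, k3 = 0.005, k4 = 0, v_central = 10,
                     v_ss = 30)
  ap <- structure(list(solubility_ph65 = 1e-4, saturated_amount = 5,
                       p_eff_human_ph65 = 1e-4, k1 = 0.02, f_h = 1),
                  class = "absorption_params")
  ev <- dose_events(settings)[1, ]
  t_b <- 60 + 240

  # unsaturated dose: everything removed from A arrives in B + C
  tr <- single_dose_response(2, ap, sc, ev, c(t_b, 1000), settings)
  removed <- 2 * (1 - exp(-0.02 * 240))
  expect_equal(tr$amount_B[1] + tr$amount_C[1], removed, tolerance = 1e-10)
  # no elimination: B + C stays constant after the window
  expect_equal(tr$amount_B[2] + tr$amount_C[2], removed, tolerance = 1e-10)

  # saturating dose: zero-order stretch then first-order tail
  tr2 <- single_dose_response(20, ap, sc, ev, t_b, settings)
  t_z <- (20 - 5) / (0.02 * 5)
  removed2 <- 0.02 * 5 * t_z + 5 * (1 - exp(-0.02 * (240 - t_z)))
  expect_equal(tr2$amount_B + tr2$amount_C, removed2, tolerance = 1e-10)
})

test_that("eliminated plus remaining drug equals the absorbed input", {
  skip_if_not_installed("deSolve")
  dz <- drugs[["diazepam"]]
  ap <- absorption_params(dz, settings)
  sc <- make_scenarios(dz, settings)$i
  ev <- dose_events(settings)[1, ]
  t_end <- settings$sim_length
  absorbed <- ap$f_h * 1 * (1 - exp(-ap$k1 * 240))  # 1 mg, unsaturated

  # integrate k4 * B piecewise (B is smooth within each phase)
  seg_int <- function(lo, hi, n = 4000) {
    tt <- seq(lo, hi, length.out = 2 * n + 1)
    tr <- single_dose_response(1, ap, sc, ev, tt, settings)
    h <- (hi - lo) / (2 * n)
    y <- tr$amount_B
    h / 3 * (y[1] + y[2 * n + 1] + 4 * sum(y[seq(2, 2 * n, 2)]) +
               2 * sum(y[seq(3, 2 * n - 1, 2)]))
  }
  auc_b <- seg_int(60, 300) + seg_int(300, t_end)
  tr_end <- single_dose_response(1, ap, sc, ev, t_end, settings)
  recovered <- sc$k4 * auc_b + tr_end$amount_B + tr_end$amount_C
  expect_equal(recovered, absorbed, tolerance = 1e-6)
})

test_that("superposition is linear and matches the stacked regimen solver", {
  dz <- drugs[["diazepam"]]
  ap <- absorption_params(dz, settings)
  sc <- make_scenarios(dz, settings)$i
  ev <- dose_events(settings)
  times <- build_time_grid(settings)
  per_dose <- lapply(seq_len(nrow(ev)), function(i)
    single_dose_response(50, ap, sc, ev[i, ], times, settings))

  expect_equal(superpose(per_dose[1]), per_dose[[1]])
  total <- superpose(per_dose)
  for (tr in per_dose)
    expect_true(all(total$conc_central - tr$conc_central >= -1e-12))
  expect_equal(superpose(list(per_dose[[1]], per_dose[[1]]))$amount_B,
               2 * per_dose[[1]]$amount_B)

  reg <- simulate_regimen(50, ap, sc, settings, times)
  expect_equal(reg$amount_B, total$amount_B, tolerance = 1e-12)
  expect_equal(reg$conc_central, total$conc_central, tolerance = 1e-12)

  short <- per_dose[[1]][per_dose[[1]]$times < 5000, ]
  class(short) <- c("pk_trace", "data.frame")
  expect_error(superpose(list(per_dose[[1]], short)), "same time grid")
})

test_that("steady-state quantities reduce correctly for simple traces", {
  sc <- raw_scenario(0.01, 0.005, 0.001, v_central = 3, v_ss = 10)
  cp <- drugs[["diazepam"]]  # PPB 98.61
  times <- seq(0, 10080, by = 15)
  mk_trace <- function(conc, amount_C = 0) {
    tr <- data.frame(times = times, amount_A = 0, amount_B = conc * 3,
                     amount_C = amount_C, conc_central = conc)
    class(tr) <- c("pk_trace", "data.frame")
    tr
  }
  q <- steady_state_quantities(mk_trace(rep(2, length(times))), sc, cp,
                               settings)
  expect_equal(unname(q["auc_central"]), 2 * 720)
  expect_equal(unname(q["css_central_max"]), 2)
  expect_equal(unname(q["css_central_min"]), 2)
  expect_equal(unname(q["css_central_avg"]), 2)
  expect_equal(unname(q["free_css_central_max"]), 2 * (100 - 98.61) / 100)

  # Simpson's rule is exact for polynomials: conc rising linearly from the
  # start of the last interval integrates to 720^2 / 2
  ramp <- pmax(times - 9360, 0)
  q2 <- steady_state_quantities(mk_trace(ramp), sc, cp, settings)
  expect_equal(unname(q2["auc_central"]), 259200)
  expect_equal(unname(q2["css_central_max"]), 720)

  # peripheral concentrations use the peripheral volume Vss - Vc
  q3 <- steady_state_quantities(mk_trace(rep(1, length(times)),
                                         amount_C = 14), sc, cp, settings)
  expect_equal(unname(q3["css_peripheral_max"]), 14 / (10 - 3))
})

test_that("composite Simpson integration is exact for cubics", {
  x <- seq(0, 1, length.out = 9)
  expect_equal(dqihld:::simpson(x^3, diff(x)[1]), 0.25)
  expect_equal(dqihld:::simpson(x^2 - 2 * x + 5, diff(x)[1]), 1 / 3 - 1 + 5)
  expect_error(dqihld:::simpson(c(1, 2), 1), "even")
})

test_that("exposure is exactly proportional to dose below saturation", {
  dz <- drugs[["diazepam"]]
  ap <- absorption_params(dz, settings)
  sc <- make_scenarios(dz, settings)$ii
  t_last <- 13 * 720
  grid <- build_time_grid(settings)
  times <- grid[grid >= t_last]
  q1 <- steady_state_quantities(
    simulate_regimen(1e-4, ap, sc, settings, times), sc, dz, settings)
  q2 <- steady_state_quantities(
    simulate_regimen(1e-2, ap, sc, settings, times), sc, dz, settings)
  expect_equal(q2 / q1, rep(100, length(q1)), tolerance = 1e-10,
               ignore_attr = TRUE)
})
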