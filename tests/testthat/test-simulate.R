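test_that("with both defects closed the circulation balances to Qp/Qs = 1", {
  sim <- cached_sim("vsd_closed",
                    scenario_preset("vsd", closed_asd = TRUE,
                                    closed_vsd = TRUE))
  expect_true(sim$metrics$converged)
  expect_equal(sim$metrics$qp_qs, 1, tolerance = 1e-3)
  expect_equal(sim$metrics$mean_qasd_ml_s, 0)
  expect_equal(sim$metrics$mean_qvsd_ml_s, 0)
})

test_that("baseline scenarios converge to the expected shunt severities", {
  vsd <- cached_sim("vsd", scenario_preset("vsd"))
  asd_vsd <- cached_sim("asd_vsd", scenario_preset("asd_vsd"))
  expect_true(vsd$metrics$converged)
  expect_true(asd_vsd$metrics$converged)
  # post-tricuspid shunting is substantial at healthy pulmonary resistance
  expect_gt(vsd$metrics$qp_qs, 2)
  # adding the atrial communication increases total shunting
  expect_gt(asd_vsd$metrics$qp_qs, vsd$metrics$qp_qs)
})

test_that("steady-state flux identity Qp = Qs + mean shunt flow holds on every preset", {
  for (sc in c("vsd", "asd", "asd_vsd")) {
    met <- cached_sim(sc, scenario_preset(sc))$metrics
    expect_lt(abs(met$qp_ml_s - met$qs_ml_s - met$mean_qasd_ml_s -
                    met$mean_qvsd_ml_s),
              1e-3 * met$qs_ml_s)
  }
})

test_that("the returned cycle is periodic within the convergence tolerance", {
  traj <- cached_sim("vsd", scenario_preset("vsd"))$trajectory
  first <- as.numeric(traj[1, c("VLA", "VLV", "VRA", "VRV", "pARSYS")])
  last <- as.numeric(traj[nrow(traj), c("VLA", "VLV", "VRA", "VRV", "pARSYS")])
  expect_equal(first, last, tolerance = 5e-3)
})

test_that("halving the integrator tolerances leaves Qp/Qs unchanged to 0.1%", {
  for (sc in c("vsd", "asd", "asd_vsd")) {
    base <- cached_sim(sc, scenario_preset(sc))$metrics$qp_qs
    half <- cached_sim(paste0(sc, "_halved"), scenario_preset(sc),
                       sim_config(rel_tol = 5e-7, abs_tol = 5e-9))$metrics$qp_qs
    expect_lt(abs(base - half) / base, 1e-3)
  }
})

test_that("the limit-cycle flow ratio does not depend on the initial state", {
  m <- scenario_preset("asd")
  base <- cached_sim("asd", m)$metrics$qp_qs
  other <- cached_sim("asd_altstart", m,
                      sim_config(initial_state =
                        default_initial_state(m, p_arsys = 110, p_vensys = 9,
                                              p_arpul = 28, p_venpul = 14)))
  expect_true(other$metrics$converged)
  expect_lt(abs(base - other$metrics$qp_qs) / base, 2 * 1e-4)
})

test_that("dynamically measured systemic resistance matches the static resistor sum", {
  met <- cached_sim("vsd_closed",
                    scenario_preset("vsd", closed_asd = TRUE,
                                    closed_vsd = TRUE))$metrics
  expect_lt(abs(met$svr_dynamic_wu - met$svr_wu) / met$svr_wu, 0.05)
  expect_lt(abs(met$pvr_dynamic_wu - met$pvr_wu) / met$pvr_wu, 0.05)
})

test_that("cycle averages match a trapezoidal quadrature oracle", {
  tt <- seq(0, 0.8, length.out = 801)
  traj <- data.frame(time_s = tt, const = rep(3.7, 801),
                     sine = sin(2 * pi * tt / 0.8),
                     bump = exp(sin(2 * pi * tt / 0.8)))
  expect_equal(cycle_average(traj, "const"), 3.7)
  expect_equal(cycle_average(traj, "sine"), 0, tolerance = 1e-10)
  oracle <- stats::integrate(function(t) exp(sin(2 * pi * t / 0.8)),
                             0, 0.8, rel.tol = 1e-12)$value / 0.8
  expect_equal(cycle_average(traj, "bump"), oracle, tolerance = 1e-5)
  expect_error(cycle_average(traj, "nope"), "unknown signal")
})

test_that("Wood-unit conversion and pulmonary-resistance targeting are exact", {
  expect_equal(resistance_to_wood(0.06), 1)
  m <- scenario_preset("vsd")
  m19 <- set_pvr(m, 1.9)
  expect_equal(m19$compartments$ARPUL$R, 0.06 * 1.9 - 0.0105)
  expect_equal(m19$compartments$ARPUL$R, 0.104, tolerance = 5e-3)
  m82 <- set_pvr(m, 8.2)
  expect_equal(m82$compartments$ARPUL$R, 0.4815)
  expect_identical(m82$compartments$VENPUL$R, 0.0105)
  # idempotence: targeting the current static sum changes nothing
  cur <- resistance_to_wood(m$compartments$ARPUL$R + m$compartments$VENPUL$R)
  expect_equal(set_pvr(m, cur)$compartments$ARPUL$R, m$compartments$ARPUL$R)
  expect_error(set_pvr(m, 0.1), "target_wu")
})

test_that("a too-small cycle budget is reported as non-convergence", {
  expect_warning(
    sim <- simulate_steady_state(scenario_preset("vsd"),
                                 sim_config(max_cycles = 3)),
    "not reached")
  expect_false(sim$metrics$converged)
})

test_that("verbose simulations log the cycle count and residual", {
  expect_message(
    simulate_steady_state(scenario_preset("vsd", closed_asd = TRUE,
                                          closed_vsd = TRUE),
                          sim_config(verbose = TRUE)),
    "converged=TRUE after [0-9]+ cycles \\(residual")
})
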