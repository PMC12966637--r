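test_that("percent reduction is computed from unrounded endpoints", {
  expect_equal(percent_reduction(2.0, 1.6), 20)
  expect_equal(percent_reduction(3.3, 3.3), 0)
  expect_equal(percent_reduction(4.4, 2.0), 100 * 2.4 / 4.4)
  expect_equal(percent_reduction(1.5, 2.0), -100 / 3)
  expect_error(percent_reduction(0, 1), "first")
})

test_that("sweep specifications validate their grid and overrides", {
  expect_error(sweep_spec("vsd", "PVR_WU", grid = c(2, 5, 3)), "monotone")
  expect_error(sweep_spec("vsd", "EBRV", 0.01, 0.1,
                          overrides = list(FOO = 1)), "overrides")
  expect_error(sweep_spec("vsd", "PVR_WU"), "grid")
  s <- sweep_spec("vsd", "PVR_WU", 1.9, 8.2, n = 5)
  expect_equal(s$grid, seq(1.9, 8.2, length.out = 5))
})

test_that("a single-point sweep has zero percent reduction", {
  res <- cached_sweep("single_pt", sweep_spec("vsd", "PVR_WU", n = 1,
                                              grid = 1.9))
  expect_equal(res$percent_reduction, 0)
  expect_equal(res$qp_qs_first, res$qp_qs_last)
})

test_that("Qp/Qs falls monotonically along the PVR grid for post-tricuspid shunts", {
  for (sc in c("vsd", "asd_vsd")) {
    res <- cached_sweep(paste0(sc, "_pvr5"),
                        sweep_spec(sc, "PVR_WU", 1.9, 8.2, n = 5))
    expect_true(all(res$points$converged))
    expect_true(all(diff(res$points$qp_qs) < 1e-3))
  }
})

test_that("Qp/Qs falls monotonically along the elastance grid for the atrial shunt", {
  res <- cached_sweep("asd_ebrv5",
                      sweep_spec("asd", "EBRV", 0.0088, 0.28, n = 5,
                                 overrides = list(PVR_WU = 1.9)))
  expect_true(all(res$points$converged))
  expect_true(all(diff(res$points$qp_qs) < 1e-3))
})

test_that("effect sizes order by shunt level: PVR rules the VSD, elastance rules the ASD", {
  vsd_pvr <- endpoint_sweep("vsd", "PVR_WU", 1.9, 8.2)
  asd_pvr <- endpoint_sweep("asd", "PVR_WU", 1.9, 8.2)
  vsd_eb <- endpoint_sweep("vsd", "EBRV", 0.0088, 0.28)
  asd_eb <- endpoint_sweep("asd", "EBRV", 0.0088, 0.28,
                           overrides = list(PVR_WU = 1.9))
  expect_gt(vsd_pvr$percent_reduction, asd_pvr$percent_reduction)
  expect_gt(asd_eb$percent_reduction, vsd_eb$percent_reduction)
})

test_that("doubling PVR from 2 to 4 Wood units costs the VSD about one unit of Qp/Qs", {
  res <- endpoint_sweep("vsd", "PVR_WU", 2.0, 4.0)
  drop <- res$qp_qs_first - res$qp_qs_last
  expect_gt(drop, 0.5)
  expect_lt(drop, 1.5)
})

test_that("the dominant defect shapes the combined-scenario elastance response", {
  combined <- endpoint_sweep("asd_vsd", "EBRV", 0.0088, 0.28)
  asd_only <- endpoint_sweep("asd", "EBRV", 0.0088, 0.28,
                             overrides = list(PVR_WU = 1.9))
  # near-closing the ventricular defect recovers the isolated-ASD response
  tiny_vsd <- endpoint_sweep("asd_vsd", "EBRV", 0.0088, 0.28,
                             overrides = list(RVSD = 1e6, PVR_WU = 1.9))
  expect_lt(abs(tiny_vsd$percent_reduction - asd_only$percent_reduction), 5)
  # enlarging it (smaller resistance) mutes the elastance sensitivity
  large_vsd <- endpoint_sweep("asd_vsd", "EBRV", 0.0088, 0.28,
                              overrides = list(RVSD = 0.0024))
  expect_lt(large_vsd$percent_reduction, combined$percent_reduction)
  vsd_only <- endpoint_sweep("vsd", "EBRV", 0.0088, 0.28)
  expect_lt(abs(large_vsd$percent_reduction - vsd_only$percent_reduction),
            abs(combined$percent_reduction - vsd_only$percent_reduction))
})

test_that("a stiffened right ventricle flattens the relaxation-time response", {
  base <- endpoint_sweep("asd", "TRRV_FRAC", 0.30, 0.70,
                         overrides = list(PVR_WU = 1.9))
  stiff <- endpoint_sweep("asd", "TRRV_FRAC", 0.30, 0.70,
                          overrides = list(PVR_WU = 1.9, EBRV = 0.088))
  # absolute Qp/Qs span across the grid collapses when the ventricle is stiff
  span <- function(r) abs(r$qp_qs_first - r$qp_qs_last)
  expect_lt(span(stiff), span(base) / 5)
})

test_that("non-converged sweep points are flagged and the sweep continues", {
  res <- run_sweep(sweep_spec("vsd", "PVR_WU", n = 1, grid = 4.0),
                   sim_config(max_cycles = 3))
  expect_false(any(res$points$converged))
  expect_equal(nrow(res$points), 1L)
})

test_that("the panel table covers the requested scenario/parameter grid", {
  curves <- qpqs_parameter_curves(panels = c("D", "E"), n = 2)
  expect_setequal(unique(curves$panel), c("D", "E"))
  expect_true(all(curves$scenario[curves$panel == "D"] == "asd_vsd"))
  expect_true(all(curves$scenario[curves$panel == "E"] == "asd"))
  expect_equal(nrow(curves), 4L)
  expect_true(all(curves$converged))
})
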