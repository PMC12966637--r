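# Gold table: every shipped preset must reproduce the printed baseline
# parameterization bit-exact. Values are asserted with `==`-strict
# tolerance via expect_identical on the numeric literals.

.gold <- list(
  vsd = list(
    EA = c(LA = 0.2273, LV = 3.0391, RA = 0.0429, RV = 0.6683),
    EB = c(LA = 0.209, LV = 0.10, RA = 0.0636, RV = 0.07),
    R = c(ARSYS = 0.588, VENSYS = 0.352, ARPUL = 0.104, VENPUL = 0.0105),
    C = c(ARSYS = 0.96, VENSYS = 60.0, ARPUL = 5.0, VENPUL = 16.0),
    L = c(ARSYS = 5e-3, VENSYS = 5e-4, ARPUL = 5e-4, VENPUL = 5e-4),
    RASD = "closed", RVSD = 0.038),
  asd = list(
    EA = c(LA = 0.2273, LV = 2.44, RA = 0.0429, RV = 0.6683),
    EB = c(LA = 0.209, LV = 0.018, RA = 0.0636, RV = 0.0088),
    R = c(ARSYS = 0.699, VENSYS = 0.66, ARPUL = 0.290, VENPUL = 0.0105),
    C = c(ARSYS = 0.671, VENSYS = 60.0, ARPUL = 5.0, VENPUL = 16.0),
    L = c(ARSYS = 5e-3, VENSYS = 5e-4, ARPUL = 5e-4, VENPUL = 5e-4),
    RASD = 0.0031, RVSD = "closed"),
  asd_vsd = list(
    EA = c(LA = 0.2273, LV = 3.0391, RA = 0.0429, RV = 0.6683),
    EB = c(LA = 0.209, LV = 0.10, RA = 0.0636, RV = 0.07),
    R = c(ARSYS = 0.588, VENSYS = 0.352, ARPUL = 0.104, VENPUL = 0.0105),
    C = c(ARSYS = 0.96, VENSYS = 60.0, ARPUL = 5.0, VENPUL = 16.0),
    L = c(ARSYS = 5e-3, VENSYS = 5e-4, ARPUL = 5e-4, VENPUL = 5e-4),
    RASD = 0.0031, RVSD = 0.038))

# timing fractions of THB, shared by all three scenarios
.gold_timing <- list(
  LA = c(tC = 0.79, TC = 0.11, TR = 0.8),
  LV = c(tC = 0.0, TC = 0.35, TR = 0.4),
  RA = c(tC = 0.8, TC = 0.1, TR = 0.7),
  RV = c(tC = 0.0, TC = 0.3, TR = 0.4))

test_that("shipped presets reproduce the baseline parameter table bit-exact", {
  for (sc in names(.gold)) {
    m <- scenario_preset(sc)
    g <- .gold[[sc]]
    expect_identical(m$THB, 0.8)
    for (nm in names(m$chambers)) {
      expect_identical(m$chambers[[nm]]$EA, unname(g$EA[nm]))
      expect_identical(m$chambers[[nm]]$EB, unname(g$EB[nm]))
      expect_identical(m$chambers[[nm]]$V0, 0)
      tm <- .gold_timing[[nm]]
      expect_identical(m$chambers[[nm]]$tC, unname(tm["tC"]) * 0.8)
      expect_identical(m$chambers[[nm]]$TC, unname(tm["TC"]) * 0.8)
      expect_identical(m$chambers[[nm]]$TR, unname(tm["TR"]) * 0.8)
      # relaxation onset is contraction onset + duration by construction
      expect_identical(m$chambers[[nm]]$tR,
                       m$chambers[[nm]]$tC + m$chambers[[nm]]$TC)
    }
    for (vn in names(m$valves)) {
      expect_identical(m$valves[[vn]]$Rmin, 0.0075)
      expect_identical(m$valves[[vn]]$Rmax, 75006.2)
    }
    for (wn in names(m$compartments)) {
      expect_identical(m$compartments[[wn]]$R, unname(g$R[wn]))
      expect_identical(m$compartments[[wn]]$C, unname(g$C[wn]))
      expect_identical(m$compartments[[wn]]$L, unname(g$L[wn]))
    }
    expect_identical(m$shunts$RASD, g$RASD)
    expect_identical(m$shunts$RVSD, g$RVSD)
  }
})

test_that("closing defect branches through the preset interface works", {
  m <- scenario_preset("asd_vsd", closed_asd = TRUE)
  expect_identical(m$shunts$RASD, "closed")
  expect_identical(m$shunts$RVSD, 0.038)
  m <- scenario_preset("vsd", closed_vsd = TRUE)
  expect_identical(m$shunts$RVSD, "closed")
})

test_that("preset parsing rejects malformed model descriptions by field name", {
  spec <- yaml::read_yaml(preset_path("vsd"))
  bad <- spec
  bad$chambers$RV$EB <- NULL
  expect_error(shuntsim:::parse_model_spec(bad), "chambers.RV.EB")
  bad <- spec
  bad$valves$Rmax <- 1e-4
  expect_error(shuntsim:::parse_model_spec(bad), "Rmax")
  bad <- spec
  bad$compartments$VENPUL <- NULL
  expect_error(shuntsim:::parse_model_spec(bad), "compartments.VENPUL")
})
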