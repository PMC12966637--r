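#' @keywords internal
"_PACKAGE"

#' @useDynLib shuntsim
#' @importFrom stats setNames
#' @importFrom utils modifyList write.csv read.csv
NULL

.chamber_names <- c("LA", "LV", "RA", "RV")
.valve_names <- c("MV", "AV", "TV", "PV")
.compartment_names <- c("ARSYS", "VENSYS", "ARPUL", "VENPUL")
.state_names <- c("VLA", "VLV", "VRA", "VRV",
                  "pARSYS", "pVENSYS", "pARPUL", "pVENPUL",
                  "QARSYS", "QVENSYS", "QARPUL", "QVENPUL")
.derived_names <- c("QMV", "QAV", "QTV", "QPV", "QASD", "QVSD",
                    "pLA", "pLV", "pRA", "pRV")

.check <- function(ok, field, constraint) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid parameter `%s`: %s", field, constraint), call. = FALSE)
  }
}

.num1 <- function(x, field) {
  .check(is.numeric(x) && length(x) == 1L && is.finite(x), field,
         "must be a single finite number")
  as.numeric(x)
}

#' Time-varying elastance parameters for one cardiac chamber
#'
#' A chamber is a pressure generator p = E(t) (V - V0) whose elastance
#' oscillates between a passive floor `EB` and a systolic ceiling `EB + EA`.
#' Activation rises over `[tC, tC + TC]` and falls over `[tR, tR + TR]`,
#' both windows interpreted modulo the heartbeat period; by construction
#' `tR = tC + TC` (relaxation starts when contraction ends).
#'
#' @param EA Active (systolic) elastance amplitude, mmHg/mL (>= 0).
#' @param EB Passive (diastolic) elastance, mmHg/mL (> 0).
#' @param tC Contraction onset time, s (within one heartbeat period).
#' @param TC Contraction duration, s (> 0).
#' @param TR Relaxation duration, s (> 0); relaxation onset is `tC + TC`.
#' @param V0 Unstressed (rest) volume, mL (>= 0). Default 0: chamber pressure
#'   is then proportional to volume, which makes all flow ratios independent
#'   of the total blood volume placed in the circuit.
#' @param name Optional chamber label used in error messages.
#' @return An object of class `chamber_params`.
#' @export
chamber_params <- function(EA, EB, tC, TC, TR, V0 = 0, name = NULL) {
  pfx <- if (is.null(name)) "" else paste0(name, ".")
  EA <- .num1(EA, paste0(pfx, "EA")); EB <- .num1(EB, paste0(pfx, "EB"))
  tC <- .num1(tC, paste0(pfx, "tC")); TC <- .num1(TC, paste0(pfx, "TC"))
  TR <- .num1(TR, paste0(pfx, "TR")); V0 <- .num1(V0, paste0(pfx, "V0"))
  .check(EA >= 0, paste0(pfx, "EA"), "active elastance must be >= 0")
  .check(EB > 0, paste0(pfx, "EB"), "passive elastance must be > 0")
  .check(V0 >= 0, paste0(pfx, "V0"), "rest volume must be >= 0")
  .check(tC >= 0, paste0(pfx, "tC"), "contraction onset must be >= 0")
  .check(TC > 0, paste0(pfx, "TC"), "contraction duration must be > 0")
  .check(TR > 0, paste0(pfx, "TR"), "relaxation duration must be > 0")
  structure(list(EA = EA, EB = EB, V0 = V0,
                 tC = tC, TC = TC, tR = tC + TC, TR = TR),
            class = "chamber_params")
}

#' Diode-with-leak valve parameters
#'
#' Each valve is a pressure-gated resistor: resistance `Rmin` when the
#' transvalvular gradient is forward (open), `Rmax` when it is reverse
#' (closed, a small leak).
#'
#' @param Rmin Open-valve resistance, mmHg s/mL (> 0).
#' @param Rmax Closed-valve resistance, mmHg s/mL (> Rmin).
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(Rmin = 0.0075, Rmax = 75006.2) {
  Rmin <- .num1(Rmin, "Rmin"); Rmax <- .num1(Rmax, "Rmax")
  .check(Rmin > 0, "Rmin", "open-valve resistance must be > 0")
  .check(Rmax > Rmin, "Rmax", "closed-valve resistance must exceed Rmin")
  structure(list(Rmin = Rmin, Rmax = Rmax), class = "valve_params")
}

#' Windkessel (RLC) compartment parameters
#'
#' @param R Viscous resistance, mmHg s/mL (> 0).
#' @param C Compliance, mL/mmHg (> 0).
#' @param L Blood inertance, mmHg s^2/mL (> 0).
#' @param name Optional compartment label used in error messages.
#' @return An object of class `wk_params`.
#' @export
windkessel_params <- function(R, C, L, name = NULL) {
  pfx <- if (is.null(name)) "" else paste0(name, ".")
  R <- .num1(R, paste0(pfx, "R")); C <- .num1(C, paste0(pfx, "C"))
  L <- .num1(L, paste0(pfx, "L"))
  .check(R > 0, paste0(pfx, "R"), "resistance must be > 0")
  .check(C > 0, paste0(pfx, "C"), "compliance must be > 0")
  .check(L > 0, paste0(pfx, "L"), "inertance must be > 0")
  structure(list(R = R, C = C, L = L), class = "wk_params")
}

#' Septal-defect (shunt) branch parameters
#'
#' Each defect is a purely resistive branch between the left and right side
#' of the corresponding level (atrial or ventricular). `"closed"` means the
#' branch is absent (zero flow). Resistance is an inverse proxy for defect
#' size: a large defect has a small resistance.
#'
#' @param RASD Atrial defect resistance, mmHg s/mL (> 0), or `"closed"`.
#' @param RVSD Ventricular defect resistance, mmHg s/mL (> 0), or `"closed"`.
#' @return An object of class `shunt_params`.
#' @export
shunt_params <- function(RASD = "closed", RVSD = "closed") {
  chk <- function(x, field) {
    if (identical(x, "closed") || is.null(x)) return("closed")
    x <- .num1(x, field)
    .check(x > 0, field, 'defect resistance must be > 0 (or "closed")')
    x
  }
  structure(list(RASD = chk(RASD, "RASD"), RVSD = chk(RVSD, "RVSD")),
            class = "shunt_params")
}

#' Full circuit parameterization of the closed-loop shunt model
#'
#' Bundles the four chamber elastances, four valves, four Windkessel
#' compartments (systemic/pulmonary x arterial/venous), the optional shunt
#' branches and the heartbeat period into one validated object.
#'
#' @param THB Heartbeat period, s (> 0).
#' @param chambers Named list `LA`, `LV`, `RA`, `RV` of [chamber_params()].
#' @param valves Named list `MV`, `AV`, `TV`, `PV` of [valve_params()].
#' @param compartments Named list `ARSYS`, `VENSYS`, `ARPUL`, `VENPUL` of
#'   [windkessel_params()].
#' @param shunts A [shunt_params()] object.
#' @param name Optional scenario label.
#' @return An object of class `model_params`.
#' @seealso [scenario_preset()] for the shipped scenario parameterizations.
#' @export
model_params <- function(THB, chambers, valves, compartments,
                         shunts = shunt_params(), name = NULL) {
  THB <- .num1(THB, "THB")
  .check(THB > 0, "THB", "heartbeat period must be > 0")
  .check(is.list(chambers) && setequal(names(chambers), .chamber_names),
         "chambers", "must be a named list with elements LA, LV, RA, RV")
  .check(is.list(valves) && setequal(names(valves), .valve_names),
         "valves", "must be a named list with elements MV, AV, TV, PV")
  .check(is.list(compartments) &&
           setequal(names(compartments), .compartment_names),
         "compartments",
         "must be a named list with elements ARSYS, VENSYS, ARPUL, VENPUL")
  for (nm in .chamber_names) {
    .check(inherits(chambers[[nm]], "chamber_params"),
           paste0("chambers.", nm), "must be a chamber_params object")
    .check(chambers[[nm]]$tC < THB, paste0("chambers.", nm, ".tC"),
           "contraction onset must lie within one heartbeat period")
  }
  for (nm in .valve_names)
    .check(inherits(valves[[nm]], "valve_params"),
           paste0("valves.", nm), "must be a valve_params object")
  for (nm in .compartment_names)
    .check(inherits(compartments[[nm]], "wk_params"),
           paste0("compartments.", nm), "must be a windkessel_params object")
  .check(inherits(shunts, "shunt_params"), "shunts",
         "must be a shunt_params object")
  structure(list(THB = THB,
                 chambers = chambers[.chamber_names],
                 valves = valves[.valve_names],
                 compartments = compartments[.compartment_names],
                 shunts = shunts,
                 name = name),
            class = "model_params")
}

#' Flatten model parameters into the compiled-RHS parameter vector
#'
#' Layout (51 values, matching the compiled code): THB; chambers LA, LV, RA,
#' RV each as (EA, EB, V0, tC, TC, tR, TR); valves MV, AV, TV, PV each as
#' (Rmin, Rmax); compartments ARSYS, VENSYS, ARPUL, VENPUL each as (R, C, L);
#' RASD, RVSD with closed defects encoded as -1.
#'
#' @param m A [model_params()] object.
#' @return A numeric vector of length 51.
#' @keywords internal
#' @export
as_param_vector <- function(m) {
  stopifnot(inherits(m, "model_params"))
  shunt_num <- function(x) if (identical(x, "closed")) -1 else x
  c(m$THB,
    unlist(lapply(m$chambers, function(ch)
      c(ch$EA, ch$EB, ch$V0, ch$tC, ch$TC, ch$tR, ch$TR))),
    unlist(lapply(m$valves, function(v) c(v$Rmin, v$Rmax))),
    unlist(lapply(m$compartments, function(w) c(w$R, w$C, w$L))),
    shunt_num(m$shunts$RASD), shunt_num(m$shunts$RVSD),
    use.names = FALSE)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Closed-loop lumped-parameter circulation model\n")
  if (!is.null(x$name)) cat("  scenario:", x$name, "\n")
  cat(sprintf("  heartbeat period: %g s\n", x$THB))
  fmt_shunt <- function(r) if (identical(r, "closed")) "closed"
                           else sprintf("%g mmHg s/mL", r)
  cat("  ASD branch:", fmt_shunt(x$shunts$RASD),
      " VSD branch:", fmt_shunt(x$shunts$RVSD), "\n")
  cat(sprintf("  static SVR %.2f WU, PVR %.2f WU\n",
              resistance_to_wood(x$compartments$ARSYS$R +
                                 x$compartments$VENSYS$R),
              resistance_to_wood(x$compartments$ARPUL$R +
                                 x$compartments$VENPUL$R)))
  invisible(x)
}
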