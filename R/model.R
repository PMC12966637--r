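#' Chamber activation function
#'
#' Dimensionless periodic activation in \[0, 1\]: zero in the quiescent
#' phase, rising by a half-cosine ramp from 0 to 1 over
#' `[tC, tC + TC]` and falling back over `[tR, tR + TR]`, with both windows
#' interpreted modulo the heartbeat period (atrial relaxation windows
#' commonly wrap past the cycle end).
#'
#' @param t Time, s (vectorized).
#' @param ch A [chamber_params()] object.
#' @param THB Heartbeat period, s.
#' @return Numeric vector of activations in \[0, 1\].
#' @export
activation <- function(t, ch, THB) {
  stopifnot(inherits(ch, "chamber_params"), THB > 0)
  u <- (t - ch$tC) %% THB
  v <- (t - ch$tR) %% THB
  a <- numeric(length(t))
  rising <- u < ch$TC
  falling <- !rising & v < ch$TR
  a[rising] <- 0.5 * (1 - cos(pi * u[rising] / ch$TC))
  a[falling] <- 0.5 * (1 + cos(pi * v[falling] / ch$TR))
  a
}

#' Time-varying chamber elastance
#'
#' `E(t) = EB + EA * activation(t)`: the passive elastance plus the activated
#' fraction of the active elastance.
#'
#' @inheritParams activation
#' @return Elastance, mmHg/mL, in `[EB, EB + EA]`.
#' @export
elastance <- function(t, ch, THB) {
  ch$EB + ch$EA * activation(t, ch, THB)
}

#' Linear elastance pressure law
#'
#' Chambers are pressure generators: `p = E (V - V0)`.
#'
#' @param V Chamber volume, mL.
#' @param E Instantaneous elastance, mmHg/mL (> 0).
#' @param V0 Unstressed volume, mL.
#' @return Pressure, mmHg.
#' @export
chamber_pressure <- function(V, E, V0 = 0) {
  stopifnot(all(E > 0))
  E * (V - V0)
}

#' Valve flow (pressure-gated resistor)
#'
#' `Q = dp / Rmin` for a forward gradient, `Q = dp / Rmax` for a reverse
#' gradient; both branches vanish at `dp = 0`, so the law is continuous.
#' With the default resistances the reverse leak is ~1e7 times smaller than
#' forward flow at the same |gradient|.
#'
#' @param p_up Upstream pressure, mmHg.
#' @param p_down Downstream pressure, mmHg.
#' @param v A [valve_params()] object.
#' @return Flow, mL/s (positive forward).
#' @export
valve_flow <- function(p_up, p_down, v = valve_params()) {
  stopifnot(inherits(v, "valve_params"))
  dp <- p_up - p_down
  dp / ifelse(dp > 0, v$Rmin, v$Rmax)
}

#' Shunt flow across a septal defect
#'
#' Purely resistive branch; positive flow is left-to-right (the clinical
#' convention under which a left-to-right shunt gives Qp/Qs > 1).
#'
#' @param p_left Left-side pressure, mmHg.
#' @param p_right Right-side pressure, mmHg.
#' @param R Defect resistance, mmHg s/mL, or `"closed"` (zero flow).
#' @return Flow, mL/s.
#' @export
shunt_flow <- function(p_left, p_right, R) {
  if (identical(R, "closed")) return(rep(0, length(p_left)))
  stopifnot(is.numeric(R), R > 0)
  (p_left - p_right) / R
}

#' Right-hand side of the 12-state circuit ODE (reference implementation)
#'
#' Pure-R evaluation of the balance equations: chamber volume balances
#' (valve and shunt flows in/out), capacitor pressure balances
#' `C dp/dt = Qin - Qout`, and inductor flow balances
#' `L dQ/dt = p_up - p_down - R Q`, with the systemic venous compartment
#' discharging into the right atrium and the pulmonary venous compartment
#' into the left atrium. Time-critical integration uses the identical
#' compiled version; this function is the readable reference and is used
#' for diagnostics.
#'
#' @param t Time, s.
#' @param state Named numeric vector of the 12 state variables (order
#'   `VLA VLV VRA VRV pARSYS pVENSYS pARPUL pVENPUL QARSYS QVENSYS QARPUL
#'   QVENPUL`).
#' @param m A [model_params()] object.
#' @return A list with `dstate` (named derivative vector) and `derived`
#'   (named vector of valve flows, shunt flows and chamber pressures).
#' @export
circuit_rhs <- function(t, state, m) {
  stopifnot(inherits(m, "model_params"))
  if (!all(is.finite(state))) {
    bad <- .state_names[!is.finite(state)]
    stop(sprintf("non-finite state variable(s) %s at t = %g s",
                 paste(bad, collapse = ", "), t), call. = FALSE)
  }
  s <- setNames(as.numeric(state), .state_names)
  ch <- m$chambers
  p_ch <- vapply(.chamber_names, function(nm) {
    chamber_pressure(s[[paste0("V", nm)]],
                     elastance(t, ch[[nm]], m$THB), ch[[nm]]$V0)
  }, numeric(1))
  QMV <- valve_flow(p_ch[["LA"]], p_ch[["LV"]], m$valves$MV)
  QAV <- valve_flow(p_ch[["LV"]], s[["pARSYS"]], m$valves$AV)
  QTV <- valve_flow(p_ch[["RA"]], p_ch[["RV"]], m$valves$TV)
  QPV <- valve_flow(p_ch[["RV"]], s[["pARPUL"]], m$valves$PV)
  QASD <- shunt_flow(p_ch[["LA"]], p_ch[["RA"]], m$shunts$RASD)
  QVSD <- shunt_flow(p_ch[["LV"]], p_ch[["RV"]], m$shunts$RVSD)
  w <- m$compartments
  dstate <- c(
    VLA = s[["QVENPUL"]] - QMV - QASD,
    VLV = QMV - QAV - QVSD,
    VRA = s[["QVENSYS"]] - QTV + QASD,
    VRV = QTV - QPV + QVSD,
    pARSYS  = (QAV - s[["QARSYS"]]) / w$ARSYS$C,
    pVENSYS = (s[["QARSYS"]] - s[["QVENSYS"]]) / w$VENSYS$C,
    pARPUL  = (QPV - s[["QARPUL"]]) / w$ARPUL$C,
    pVENPUL = (s[["QARPUL"]] - s[["QVENPUL"]]) / w$VENPUL$C,
    QARSYS  = (s[["pARSYS"]] - s[["pVENSYS"]] - w$ARSYS$R * s[["QARSYS"]]) / w$ARSYS$L,
    QVENSYS = (s[["pVENSYS"]] - p_ch[["RA"]] - w$VENSYS$R * s[["QVENSYS"]]) / w$VENSYS$L,
    QARPUL  = (s[["pARPUL"]] - s[["pVENPUL"]] - w$ARPUL$R * s[["QARPUL"]]) / w$ARPUL$L,
    QVENPUL = (s[["pVENPUL"]] - p_ch[["LA"]] - w$VENPUL$R * s[["QVENPUL"]]) / w$VENPUL$L
  )
  derived <- c(QMV = QMV, QAV = QAV, QTV = QTV, QPV = QPV,
               QASD = QASD, QVSD = QVSD,
               pLA = p_ch[["LA"]], pLV = p_ch[["LV"]],
               pRA = p_ch[["RA"]], pRV = p_ch[["RV"]])
  list(dstate = dstate, derived = derived)
}

#' Closed-loop mass-conservation residual of the RHS
#'
#' The total blood volume `sum(V_chamber) + sum(C * p_compartment)` is an
#' invariant of the circuit, so the corresponding derivative sum must vanish
#' for every state. Returns the residual normalized by the largest
#' individual volume-rate term.
#'
#' @inheritParams circuit_rhs
#' @return Dimensionless residual (0 up to round-off).
#' @export
conservation_residual <- function(t, state, m) {
  d <- circuit_rhs(t, state, m)$dstate
  Cs <- vapply(m$compartments, `[[`, numeric(1), "C")
  terms <- c(d[1:4], Cs * d[5:8])
  sum(terms) / max(abs(terms), .Machine$double.eps)
}
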