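#' Simulation configuration
#'
#' Integrator and convergence settings for [simulate_steady_state()].
#' Defaults: a stiff-capable integrator (the valve law spans seven orders
#' of magnitude in resistance) at `rel_tol` 1e-6 / `abs_tol` 1e-8 with the
#' step bounded at 1 ms, 800 output samples per cycle, and a periodic
#' steady-state criterion that stops when the *estimated remaining drift*
#' of cycle-mean valve flows and end-diastolic volumes falls below
#' `convergence_tol` (the per-cycle change is extrapolated geometrically,
#' because the slow systemic venous time constant makes the raw per-cycle
#' change an under-estimate of the distance to the limit cycle).
#'
#' @param rel_tol,abs_tol Integrator relative/absolute tolerances (> 0).
#' @param max_step Maximum integrator step, s.
#' @param n_samples_per_cycle Output samples per heartbeat (>= 200).
#' @param max_cycles Maximum heartbeats to integrate (>= 2).
#' @param convergence_tol Relative threshold for the steady-state criterion.
#' @param initial_state `"default"` or a named 12-vector (see
#'   [default_initial_state()]).
#' @param engine `"compiled"` (C right-hand side) or `"r"` (reference R
#'   implementation; identical equations, much slower).
#' @param verbose Emit a convergence message per simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rel_tol = 1e-6, abs_tol = 1e-8, max_step = 1e-3,
                       n_samples_per_cycle = 800L, max_cycles = 200L,
                       convergence_tol = 1e-4, initial_state = "default",
                       engine = c("compiled", "r"), verbose = FALSE) {
  .check(rel_tol > 0 && abs_tol > 0, "rel_tol/abs_tol",
         "integrator tolerances must be > 0")
  .check(max_step > 0, "max_step", "must be > 0")
  .check(n_samples_per_cycle >= 200, "n_samples_per_cycle", "must be >= 200")
  .check(max_cycles >= 2, "max_cycles", "must be >= 2")
  .check(convergence_tol > 0, "convergence_tol", "must be > 0")
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 n_samples_per_cycle = as.integer(n_samples_per_cycle),
                 max_cycles = as.integer(max_cycles),
                 convergence_tol = convergence_tol,
                 initial_state = initial_state,
                 engine = match.arg(engine), verbose = isTRUE(verbose)),
            class = "sim_config")
}

#' Default physiological initial state
#'
#' Compartment pressures start at typical diastolic values (systemic
#' arterial 80, systemic venous 5, pulmonary arterial 15, pulmonary venous
#' 8 mmHg), compartment flows at zero, and chamber volumes such that the
#' passive chamber pressure matches the adjacent venous pressure. Because
#' the model is homogeneous in the state (rest volumes default to zero),
#' the flow *ratios* at the limit cycle do not depend on this choice.
#'
#' @param m A [model_params()] object.
#' @param p_arsys,p_vensys,p_arpul,p_venpul Starting compartment pressures,
#'   mmHg.
#' @return Named numeric 12-vector in the canonical state order.
#' @export
default_initial_state <- function(m, p_arsys = 80, p_vensys = 5,
                                  p_arpul = 15, p_venpul = 8) {
  ch <- m$chambers
  setNames(c(p_venpul / ch$LA$EB + ch$LA$V0,
             p_venpul / ch$LV$EB + ch$LV$V0,
             p_vensys / ch$RA$EB + ch$RA$V0,
             p_vensys / ch$RV$EB + ch$RV$V0,
             p_arsys, p_vensys, p_arpul, p_venpul,
             0, 0, 0, 0),
           .state_names)
}

.rhs_r_desolve <- function(t, y, m) {
  out <- circuit_rhs(t, y, m)
  list(out$dstate, out$derived)
}

.integrate_cycle <- function(y, t0, m, pv, cfg, n_samples) {
  times <- seq(t0, t0 + m$THB, length.out = n_samples + 1L)
  if (cfg$engine == "compiled") {
    sol <- deSolve::lsoda(y, times, func = "shunt_derivs", parms = pv,
                          dllname = "shuntsim", initfunc = "shunt_initmod",
                          nout = 10L, outnames = .derived_names,
                          rtol = cfg$rel_tol, atol = cfg$abs_tol,
                          hmax = cfg$max_step, maxsteps = 50000L)
  } else {
    sol <- deSolve::lsoda(y, times, func = .rhs_r_desolve, parms = m,
                          rtol = cfg$rel_tol, atol = cfg$abs_tol,
                          hmax = cfg$max_step, maxsteps = 50000L)
  }
  sol <- as.data.frame(sol)
  names(sol) <- c("time_s", .state_names, .derived_names)
  sol
}

#' Trapezoidal cycle average of a trajectory signal
#'
#' @param traj A `cycle_trajectory` data frame (one period).
#' @param signal_name Column to average (any state or derived signal).
#' @return The trapezoidal time integral of the signal divided by the
#'   period, in the signal's units.
#' @export
cycle_average <- function(traj, signal_name) {
  if (!signal_name %in% names(traj))
    stop(sprintf("unknown signal `%s`; available: %s", signal_name,
                 paste(setdiff(names(traj), "time_s"), collapse = ", ")),
         call. = FALSE)
  tt <- traj$time_s
  pracma::trapz(tt, traj[[signal_name]]) / (tt[length(tt)] - tt[1])
}

#' Convert a resistance to Wood units
#'
#' One Wood unit is 1 mmHg per L/min, i.e. 0.06 mmHg s/mL.
#'
#' @param R Resistance, mmHg s/mL (>= 0).
#' @return Resistance in Wood units.
#' @export
resistance_to_wood <- function(R) {
  stopifnot(all(R >= 0))
  R / 0.06
}

#' Set the total pulmonary vascular resistance in Wood units
#'
#' Returns a copy of the model with the pulmonary *arterial* resistance
#' adjusted so that the static pulmonary resistive sum
#' `RARPUL + RVENPUL` equals the target; the venous part is left unchanged.
#'
#' @param m A [model_params()] object.
#' @param target_wu Target total PVR, Wood units; must exceed the venous
#'   contribution so that the arterial resistance stays positive.
#' @return Modified [model_params()] object.
#' @export
set_pvr <- function(m, target_wu) {
  stopifnot(inherits(m, "model_params"))
  target <- 0.06 * .num1(target_wu, "target_wu")
  rven <- m$compartments$VENPUL$R
  .check(target > rven, "target_wu",
         sprintf(paste0("total pulmonary resistance %.4f mmHg s/mL must ",
                        "exceed the venous part %.4f"), target, rven))
  m$compartments$ARPUL$R <- target - rven
  m
}

.cycle_monitor <- function(traj) {
  n <- nrow(traj)
  c(qp = cycle_average(traj, "QPV"),
    qs = cycle_average(traj, "QAV"),
    VLA = traj$VLA[n], VLV = traj$VLV[n],
    VRA = traj$VRA[n], VRV = traj$VRV[n])
}

#' Integrate the circuit to its periodic steady state
#'
#' Integrates heartbeat by heartbeat from the initial state until the
#' cycle-mean pulmonary and aortic valve flows and the chamber
#' end-diastolic volumes settle onto the limit cycle (see [sim_config()]
#' for the stopping rule), then returns the last cycle and its
#' cycle-averaged hemodynamic metrics.
#'
#' @param m A [model_params()] object.
#' @param cfg A [sim_config()] object.
#' @return A list of class `shunt_sim` with elements `trajectory` (a
#'   `cycle_trajectory` data frame over one period: time, the 12 states,
#'   valve/shunt flows and chamber pressures) and `metrics` (a
#'   `cycle_metrics` list: cycle-mean pulmonary flow `qp_ml_s`, systemic
#'   flow `qs_ml_s`, their ratio `qp_qs`, mean shunt flows, mean
#'   compartment pressures, static and dynamically estimated SVR/PVR in
#'   Wood units, convergence diagnostics).
#' @examples
#' \donttest{
#' sim <- simulate_steady_state(scenario_preset("vsd"))
#' sim$metrics$qp_qs
#' }
#' @export
simulate_steady_state <- function(m, cfg = sim_config()) {
  stopifnot(inherits(m, "model_params"), inherits(cfg, "sim_config"))
  pv <- as_param_vector(m)
  y <- if (identical(cfg$initial_state, "default")) {
    default_initial_state(m)
  } else {
    .check(is.numeric(cfg$initial_state) && length(cfg$initial_state) == 12,
           "initial_state", 'must be "default" or a numeric 12-vector')
    setNames(as.numeric(cfg$initial_state), .state_names)
  }
  # coarse sampling while monitoring convergence; full resolution at the end
  n_monitor <- max(200L, cfg$n_samples_per_cycle %/% 4L)
  prev <- NULL; delta_prev <- NULL
  converged <- FALSE; residual <- NA_real_; cycle <- 0L
  traj <- NULL
  for (cycle in seq_len(cfg$max_cycles)) {
    t0 <- (cycle - 1L) * m$THB
    traj <- .integrate_cycle(y, t0, m, pv, cfg, n_monitor)
    last <- as.numeric(traj[nrow(traj), 1 + seq_along(.state_names)])
    if (!all(is.finite(last))) {
      bad <- .state_names[!is.finite(last)]
      stop(sprintf("integration diverged in cycle %d (t = %.3f s): non-finite %s",
                   cycle, traj$time_s[nrow(traj)],
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    y <- setNames(last, .state_names)
    mon <- .cycle_monitor(traj)
    if (!is.null(prev)) {
      delta <- abs(mon - prev) / pmax(abs(mon), 1e-12)
      dmax <- max(delta)
      # geometric extrapolation of the remaining distance to the limit cycle
      est <- dmax
      if (!is.null(delta_prev) && delta_prev > 0) {
        r <- min(dmax / delta_prev, 0.995)
        if (r > 0) est <- dmax * r / (1 - r)
      }
      residual <- max(dmax, est)
      delta_prev <- dmax
      if (residual < cfg$convergence_tol) { converged <- TRUE; break }
    }
    prev <- mon
  }
  if (!converged)
    warning(sprintf(paste0("periodic steady state not reached after %d ",
                           "cycles (residual %.2e > %.2e)"),
                    cfg$max_cycles, residual, cfg$convergence_tol),
            call. = FALSE)
  # final cycle at full output resolution, starting from the converged state
  t0 <- cycle * m$THB
  traj <- .integrate_cycle(y, t0, m, pv, cfg, cfg$n_samples_per_cycle)
  traj$time_s <- traj$time_s - t0
  class(traj) <- c("cycle_trajectory", "data.frame")
  attr(traj, "THB") <- m$THB
  vmin <- vapply(c("VLA", "VLV", "VRA", "VRV"), function(v) min(traj[[v]]),
                 numeric(1))
  if (any(vmin <= 0))
    warning(sprintf("non-physical chamber volume(s): min %s <= 0 mL",
                    paste(names(vmin)[vmin <= 0], collapse = ", ")),
            call. = FALSE)
  metrics <- .compute_metrics(traj, m, cycle, converged, residual)
  if (cfg$verbose)
    message(sprintf("[%s] converged=%s after %d cycles (residual %.2e), Qp/Qs=%.3f",
                    if (is.null(m$name)) "model" else m$name,
                    converged, cycle, residual, metrics$qp_qs))
  structure(list(trajectory = traj, metrics = metrics), class = "shunt_sim")
}

.compute_metrics <- function(traj, m, cycles, converged, residual) {
  qp <- cycle_average(traj, "QPV")
  qs <- cycle_average(traj, "QAV")
  mp <- vapply(paste0("p", .compartment_names), function(s)
    cycle_average(traj, s), numeric(1))
  mean_pLA <- cycle_average(traj, "pLA")
  mean_pRA <- cycle_average(traj, "pRA")
  svr <- m$compartments$ARSYS$R + m$compartments$VENSYS$R
  pvr <- m$compartments$ARPUL$R + m$compartments$VENPUL$R
  structure(list(
    qp_ml_s = qp,
    qs_ml_s = qs,
    qp_qs = qp / qs,
    mean_qasd_ml_s = cycle_average(traj, "QASD"),
    mean_qvsd_ml_s = cycle_average(traj, "QVSD"),
    mean_p_arsys_mmhg = mp[["pARSYS"]],
    mean_p_vensys_mmhg = mp[["pVENSYS"]],
    mean_p_arpul_mmhg = mp[["pARPUL"]],
    mean_p_venpul_mmhg = mp[["pVENPUL"]],
    svr_wu = resistance_to_wood(svr),
    pvr_wu = resistance_to_wood(pvr),
    svr_dynamic_wu = resistance_to_wood((mp[["pARSYS"]] - mean_pRA) / qs),
    pvr_dynamic_wu = resistance_to_wood((mp[["pARPUL"]] - mean_pLA) / qp),
    cycles_to_converge = cycles,
    converged = converged,
    convergence_residual = residual
  ), class = "cycle_metrics")
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat("Cycle-averaged hemodynamics at periodic steady state\n")
  cat(sprintf("  Qp %.1f mL/s, Qs %.1f mL/s, Qp/Qs %.3f\n",
              x$qp_ml_s, x$qs_ml_s, x$qp_qs))
  cat(sprintf("  mean shunt flow: ASD %.1f, VSD %.1f mL/s\n",
              x$mean_qasd_ml_s, x$mean_qvsd_ml_s))
  cat(sprintf("  static SVR %.2f WU (dynamic %.2f), static PVR %.2f WU (dynamic %.2f)\n",
              x$svr_wu, x$svr_dynamic_wu, x$pvr_wu, x$pvr_dynamic_wu))
  cat(sprintf("  converged: %s after %d cycles (residual %.2e)\n",
              x$converged, x$cycles_to_converge, x$convergence_residual))
  invisible(x)
}

#' @export
print.shunt_sim <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

#' Plot one steady-state cycle
#'
#' Convenience base-graphics view of chamber pressures and shunt flows over
#' the returned cycle.
#'
#' @param x A `cycle_trajectory` data frame.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @importFrom graphics matplot legend par
#' @export
plot.cycle_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  matplot(x$time_s, cbind(x$pLA, x$pLV, x$pRA, x$pRV, x$pARSYS),
          type = "l", lty = 1, xlab = "time [s]", ylab = "pressure [mmHg]",
          ...)
  legend("topright", c("pLA", "pLV", "pRA", "pRV", "pARSYS"),
         col = 1:5, lty = 1, cex = 0.7, bty = "n")
  matplot(x$time_s, cbind(x$QASD, x$QVSD), type = "l", lty = 1,
          xlab = "time [s]", ylab = "shunt flow [mL/s]")
  legend("topright", c("QASD", "QVSD"), col = 1:2, lty = 1, cex = 0.7,
         bty = "n")
  invisible(x)
}
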