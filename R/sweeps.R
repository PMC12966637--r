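.sweep_quantities <- c("PVR_WU", "EBRV", "TRRV_FRAC", "RASD", "RVSD")

#' Specify a one-parameter sweep
#'
#' Defines a sweep of a single hemodynamic quantity over a monotone grid,
#' all other parameters held at their scenario baseline. Supported
#' quantities: `PVR_WU` (total pulmonary vascular resistance in Wood units,
#' applied via [set_pvr()]), `EBRV` (right-ventricular passive elastance,
#' mmHg/mL), `TRRV_FRAC` (right-ventricular relaxation duration as a
#' fraction of the heartbeat period; the relaxation onset is unchanged),
#' `RASD` and `RVSD` (defect resistances, mmHg s/mL).
#'
#' @param preset Scenario name (see [scenario_preset()]) or a
#'   [model_params()] object.
#' @param varied One of `"PVR_WU"`, `"EBRV"`, `"TRRV_FRAC"`, `"RASD"`,
#'   `"RVSD"`.
#' @param from,to Grid endpoints (a single-point grid is allowed with
#'   `n = 1`).
#' @param n Number of evenly spaced grid points (default 9).
#' @param grid Explicit strictly monotone grid overriding `from`/`to`/`n`.
#' @param overrides Named list of fixed baseline overrides applied before
#'   the sweep, e.g. `list(EBRV = 0.088)` or `list(RVSD = 0.0024)`; allowed
#'   names are the sweep quantities.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(preset, varied, from = NULL, to = NULL, n = 9L,
                       grid = NULL, overrides = list()) {
  varied <- match.arg(varied, .sweep_quantities)
  if (is.null(grid)) {
    .check(!is.null(from) && !is.null(to), "grid",
           "either `grid` or both `from` and `to` are required")
    grid <- if (n == 1L) from else seq(from, to, length.out = n)
  }
  .check(is.numeric(grid) && length(grid) >= 1, "grid",
         "must be a numeric vector")
  if (length(grid) > 1)
    .check(all(diff(grid) > 0) || all(diff(grid) < 0), "grid",
           "must be strictly monotone")
  .check(all(names(overrides) %in% .sweep_quantities), "overrides",
         paste("names must be among", paste(.sweep_quantities, collapse = ", ")))
  structure(list(preset = preset, varied = varied, grid = grid,
                 overrides = overrides), class = "sweep_spec")
}

.apply_quantity <- function(m, quantity, value) {
  switch(quantity,
    PVR_WU = set_pvr(m, value),
    EBRV = { m$chambers$RV$EB <- .num1(value, "EBRV"); m },
    TRRV_FRAC = {
      .check(value > 0 && value < 1, "TRRV_FRAC",
             "relaxation fraction must lie in (0, 1)")
      m$chambers$RV$TR <- value * m$THB
      m
    },
    RASD = { m$shunts$RASD <- value; m },
    RVSD = { m$shunts$RVSD <- value; m })
}

#' Percent reduction between two sweep endpoints
#'
#' `100 (first - last) / first`, computed from unrounded endpoints.
#'
#' @param first,last Endpoint values; `first` must be positive.
#' @return Percent reduction (negative when the quantity increased).
#' @export
percent_reduction <- function(first, last) {
  .check(all(first > 0), "first", "must be > 0")
  100 * (first - last) / first
}

#' Run a one-parameter sweep to steady state
#'
#' One converged steady-state simulation per grid point; non-converged
#' points are flagged in the result and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param cfg A [sim_config()].
#' @return An object of class `sweep_result`: a list with `spec`, `points`
#'   (data frame with columns `grid_value`, `qp_qs`, `qp_ml_s`, `qs_ml_s`,
#'   `mean_qasd_ml_s`, `mean_qvsd_ml_s`, `converged`, `cycles`), `metrics`
#'   (list of full `cycle_metrics` per point), endpoint ratios
#'   `qp_qs_first` / `qp_qs_last` and `percent_reduction`.
#' @export
run_sweep <- function(spec, cfg = sim_config()) {
  stopifnot(inherits(spec, "sweep_spec"))
  base <- if (inherits(spec$preset, "model_params")) spec$preset
          else scenario_preset(spec$preset)
  for (nm in names(spec$overrides))
    base <- .apply_quantity(base, nm, spec$overrides[[nm]])
  metrics <- vector("list", length(spec$grid))
  for (i in seq_along(spec$grid)) {
    m <- .apply_quantity(base, spec$varied, spec$grid[i])
    sim <- withCallingHandlers(
      simulate_steady_state(m, cfg),
      warning = function(w) {
        if (grepl("periodic steady state", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    metrics[[i]] <- sim$metrics
  }
  points <- data.frame(
    grid_value = spec$grid,
    qp_qs = vapply(metrics, `[[`, numeric(1), "qp_qs"),
    qp_ml_s = vapply(metrics, `[[`, numeric(1), "qp_ml_s"),
    qs_ml_s = vapply(metrics, `[[`, numeric(1), "qs_ml_s"),
    mean_qasd_ml_s = vapply(metrics, `[[`, numeric(1), "mean_qasd_ml_s"),
    mean_qvsd_ml_s = vapply(metrics, `[[`, numeric(1), "mean_qvsd_ml_s"),
    converged = vapply(metrics, `[[`, logical(1), "converged"),
    cycles = vapply(metrics, `[[`, integer(1), "cycles_to_converge"))
  n <- nrow(points)
  structure(list(spec = spec, points = points, metrics = metrics,
                 qp_qs_first = points$qp_qs[1], qp_qs_last = points$qp_qs[n],
                 percent_reduction = percent_reduction(points$qp_qs[1],
                                                       points$qp_qs[n])),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  lab <- if (inherits(x$spec$preset, "model_params"))
    x$spec$preset$name else x$spec$preset
  cat(sprintf("Sweep of %s, scenario %s (%d points)\n",
              x$spec$varied, lab, nrow(x$points)))
  print(x$points[, c("grid_value", "qp_qs", "converged")], row.names = FALSE)
  cat(sprintf("Qp/Qs %.3f -> %.3f: %.1f%% reduction\n",
              x$qp_qs_first, x$qp_qs_last, x$percent_reduction))
  invisible(x)
}

.fig2_panels <- list(
  A = list(varied = "PVR_WU", from = 1.9, to = 8.2,
           scenarios = c("vsd", "asd", "asd_vsd"), overrides = list()),
  B = list(varied = "EBRV", from = 0.0088, to = 0.28,
           scenarios = c("vsd", "asd", "asd_vsd"), overrides = list()),
  C = list(varied = "TRRV_FRAC", from = 0.30, to = 0.70,
           scenarios = c("vsd", "asd", "asd_vsd"), overrides = list()),
  D = list(varied = "EBRV", from = 0.0088, to = 0.28,
           scenarios = "asd_vsd", overrides = list(RVSD = 0.0024)),
  E = list(varied = "TRRV_FRAC", from = 0.30, to = 0.70,
           scenarios = "asd", overrides = list(EBRV = 0.088))
)

#' Qp/Qs response curves across all sweep panels
#'
#' Reproduces the full set of parameter-response curves: panel A sweeps
#' total PVR (1.9-8.2 WU) for all three scenarios; panel B sweeps the
#' right-ventricular passive elastance EBRV (0.0088-0.28 mmHg/mL); panel C
#' sweeps the relaxation fraction TRRV/THB (0.30-0.70); panel D repeats the
#' EBRV sweep for the combined scenario with an enlarged ventricular defect
#' (RVSD = 0.0024 mmHg s/mL); panel E repeats the relaxation sweep for the
#' isolated-ASD scenario with a tenfold-stiffened right ventricle
#' (EBRV = 0.088 mmHg/mL).
#'
#' The isolated-ASD scenario is a special case: its printed pulmonary
#' arterial resistance implies a static PVR of about 5.0 Wood units, whereas
#' the healthy baseline the response curves start from is 1.9 WU. The
#' diastolic-function sweeps (EBRV, TRRV) for that scenario are therefore
#' taken with total PVR pinned to `asd_baseline_pvr_wu` (default 1.9 WU via
#' [set_pvr()]); set it to `NULL` to sweep at the raw preset value instead.
#'
#' @param cfg A [sim_config()].
#' @param panels Subset of `c("A","B","C","D","E")`.
#' @param n Grid points per curve (default 9).
#' @param asd_baseline_pvr_wu Total PVR, Wood units, at which the
#'   isolated-ASD EBRV/TRRV sweeps are run (`NULL` to disable).
#' @return A data frame with columns `panel`, `scenario`, `varied`,
#'   `grid_value`, `qp_qs`, `converged`.
#' @export
qpqs_parameter_curves <- function(cfg = sim_config(),
                                  panels = names(.fig2_panels), n = 9L,
                                  asd_baseline_pvr_wu = 1.9) {
  panels <- match.arg(panels, names(.fig2_panels), several.ok = TRUE)
  out <- list()
  for (p in panels) {
    pd <- .fig2_panels[[p]]
    for (sc in pd$scenarios) {
      ov <- pd$overrides
      if (sc == "asd" && pd$varied != "PVR_WU" &&
          !is.null(asd_baseline_pvr_wu))
        ov$PVR_WU <- asd_baseline_pvr_wu
      res <- run_sweep(sweep_spec(sc, pd$varied, pd$from, pd$to, n = n,
                                  overrides = ov), cfg)
      out[[length(out) + 1L]] <- data.frame(
        panel = p, scenario = sc, varied = pd$varied,
        grid_value = res$points$grid_value, qp_qs = res$points$qp_qs,
        converged = res$points$converged)
    }
  }
  do.call(rbind, out)
}

#' One steady-state cycle of each shunt-flow waveform
#'
#' Returns the atrial shunt flow of the isolated-ASD scenario and the
#' ventricular shunt flow of the isolated-VSD scenario over one converged
#' cycle, together with automated morphology checks: the global QVSD peak
#' must fall in the ventricular contraction/ejection window, and QASD must
#' show distinct local maxima in the ventricular-relaxation and
#' atrial-contraction windows.
#'
#' @param cfg A [sim_config()].
#' @return A list with `asd` and `vsd` (`cycle_trajectory` data frames)
#'   and `checks` (see [check_waveform_morphology()]).
#' @export
shunt_flow_waveforms <- function(cfg = sim_config()) {
  sim_asd <- simulate_steady_state(scenario_preset("asd"), cfg)
  sim_vsd <- simulate_steady_state(scenario_preset("vsd"), cfg)
  list(asd = sim_asd$trajectory, vsd = sim_vsd$trajectory,
       checks = check_waveform_morphology(sim_asd$trajectory,
                                          sim_vsd$trajectory,
                                          scenario_preset("vsd")))
}

.local_maxima <- function(t, x, min_prominence = 0.01) {
  n <- length(x)
  thr <- min_prominence * diff(range(x))
  idx <- which(diff(sign(diff(x))) == -2) + 1L
  idx <- idx[x[idx] > min(x) + thr]
  t[idx]
}

#' Automated shunt-waveform morphology checks
#'
#' @param traj_asd Steady-state cycle of the isolated-ASD scenario.
#' @param traj_vsd Steady-state cycle of the isolated-VSD scenario.
#' @param m Model parameters supplying the timing windows (any scenario
#'   with the shared Table of timings).
#' @return A list of logicals: `qvsd_peak_in_systole` (global QVSD maximum
#'   within `[tCLV, tRLV + TRLV/2]`), `qasd_peak_in_relaxation` and
#'   `qasd_peak_in_atrial_contraction` (local QASD maxima inside the
#'   ventricular relaxation and atrial contraction windows), and
#'   `qasd_two_major_peaks`.
#' @export
check_waveform_morphology <- function(traj_asd, traj_vsd, m) {
  lv <- m$chambers$LV; la <- m$chambers$LA; ra <- m$chambers$RA
  THB <- m$THB
  in_win <- function(t, a, b) any(t >= a & t <= b)
  t_peak_vsd <- traj_vsd$time_s[which.max(traj_vsd$QVSD)] %% THB
  systole <- c(lv$tC, lv$tR + lv$TR / 2)
  peaks_asd <- .local_maxima(traj_asd$time_s, traj_asd$QASD,
                             min_prominence = 0.05) %% THB
  relax_win <- c(lv$tR, lv$tR + lv$TR)
  atrial_win <- c(min(la$tC, ra$tC), max(la$tR, ra$tR))
  list(
    qvsd_peak_in_systole = t_peak_vsd >= systole[1] && t_peak_vsd <= systole[2],
    qasd_peak_in_relaxation = in_win(peaks_asd, relax_win[1], relax_win[2]),
    qasd_peak_in_atrial_contraction = in_win(peaks_asd, atrial_win[1],
                                             atrial_win[2]),
    qasd_two_major_peaks = length(peaks_asd) >= 2
  )
}
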