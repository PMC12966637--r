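#' Load and validate a run configuration
#'
#' A run configuration is a YAML file describing one simulation or sweep:
#'
#' ```yaml
#' preset: vsd            # or `model:` with a full inline description
#' closed_asd: false
#' closed_vsd: false
#' overrides: {pvr_wu: 2.5}     # optional fixed overrides
#' sim: {rel_tol: 1.0e-6, abs_tol: 1.0e-8, convergence_tol: 1.0e-4}
#' sweep: {varied: PVR_WU, from: 1.9, to: 8.2, points: 9}   # optional
#' output: {metrics: metrics.json, trajectory: traj.csv}
#' seed: null             # reserved; the core model is deterministic
#' log_level: info
#' ```
#'
#' Every model invariant is checked on load with an error naming the
#' offending field.
#'
#' @param path Path to the YAML configuration.
#' @return A validated list of class `run_config` with elements `model`
#'   ([model_params()]), `sim` ([sim_config()]), `sweep` ([sweep_spec()] or
#'   `NULL`), `output`, `seed`, `log_level`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  .check(!is.null(raw$preset) || !is.null(raw$model), "preset",
         "configuration needs either a `preset` name or an inline `model`")
  model <- if (!is.null(raw$model)) parse_model_spec(raw$model)
           else scenario_preset(raw$preset)
  if (isTRUE(raw$closed_asd)) model$shunts$RASD <- "closed"
  if (isTRUE(raw$closed_vsd)) model$shunts$RVSD <- "closed"
  ov <- raw$overrides
  if (!is.null(ov)) {
    map <- c(pvr_wu = "PVR_WU", ebrv = "EBRV", trrv_frac = "TRRV_FRAC",
             rasd = "RASD", rvsd = "RVSD")
    .check(all(names(ov) %in% names(map)), "overrides",
           paste("names must be among", paste(names(map), collapse = ", ")))
    for (nm in names(ov))
      model <- .apply_quantity(model, map[[nm]], ov[[nm]])
  }
  sim <- do.call(sim_config, if (is.null(raw$sim)) list() else raw$sim)
  sweep <- NULL
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    .check(!is.null(sw$varied), "sweep.varied", "field is required")
    sweep <- sweep_spec(model, sw$varied, from = sw$from, to = sw$to,
                        n = if (is.null(sw$points)) 9L else sw$points,
                        grid = sw$grid)
  }
  structure(list(model = model, sim = sim, sweep = sweep,
                 output = raw$output, seed = raw$seed,
                 log_level = if (is.null(raw$log_level)) "info"
                             else raw$log_level),
            class = "run_config")
}

#' Serialize model parameters to the preset list layout
#'
#' Inverse of the preset parser: timing is written back as fractions of the
#' heartbeat period, valves as the shared Rmin/Rmax pair.
#'
#' @param m A [model_params()] object.
#' @return A list suitable for [yaml::write_yaml()].
#' @keywords internal
model_to_spec <- function(m) {
  stopifnot(inherits(m, "model_params"))
  list(
    name = m$name,
    thb_s = m$THB,
    chambers = lapply(m$chambers, function(ch)
      list(EA = ch$EA, EB = ch$EB, V0 = ch$V0,
           tC_frac = ch$tC / m$THB, TC_frac = ch$TC / m$THB,
           TR_frac = ch$TR / m$THB)),
    valves = list(Rmin = m$valves$MV$Rmin, Rmax = m$valves$MV$Rmax),
    compartments = lapply(m$compartments, function(w)
      list(R = w$R, C = w$C, L = w$L)),
    shunts = list(RASD = m$shunts$RASD, RVSD = m$shunts$RVSD))
}

#' Save a run configuration to YAML
#'
#' Writes the model inline (so the file is self-contained) together with
#' the simulation settings and any sweep; [load_run_config()] on the
#' written file reproduces the configuration.
#'
#' @param cfg A `run_config` object from [load_run_config()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(model = model_to_spec(cfg$model),
              sim = cfg$sim[c("rel_tol", "abs_tol", "max_step",
                              "n_samples_per_cycle", "max_cycles",
                              "convergence_tol")],
              output = cfg$output, seed = cfg$seed,
              log_level = cfg$log_level)
  if (!is.null(cfg$sweep))
    out$sweep <- list(varied = cfg$sweep$varied,
                      grid = as.numeric(cfg$sweep$grid))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

.metrics_field_order <- c(
  "qp_ml_s", "qs_ml_s", "qp_qs", "mean_qasd_ml_s", "mean_qvsd_ml_s",
  "mean_p_arsys_mmhg", "mean_p_vensys_mmhg", "mean_p_arpul_mmhg",
  "mean_p_venpul_mmhg", "svr_wu", "pvr_wu", "svr_dynamic_wu",
  "pvr_dynamic_wu", "cycles_to_converge", "converged",
  "convergence_residual")

#' Write cycle metrics to JSON
#'
#' Fields carry their units in the name (`_ml_s`, `_mmhg`, `_wu`) and are
#' written in a fixed, deterministic order at full double precision, so a
#' read-back reproduces the metrics exactly.
#'
#' @param metrics A `cycle_metrics` object.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "cycle_metrics"))
  out <- metrics[.metrics_field_order]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read cycle metrics back from JSON
#'
#' @param path File written by [write_metrics()].
#' @return A `cycle_metrics` object.
#' @export
read_metrics <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cycles_to_converge <- as.integer(x$cycles_to_converge)
  structure(x[.metrics_field_order], class = "cycle_metrics")
}

#' Write a steady-state cycle trajectory to CSV
#'
#' RFC 4180 CSV with one header row: `time_s`, the 12 state variables, then
#' the derived valve/shunt flows and chamber pressures.
#'
#' @param traj A `cycle_trajectory` data frame.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
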