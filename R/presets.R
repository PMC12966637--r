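#' Parse a preset/inline model description into model parameters
#'
#' @param x A list with elements `thb_s`, `chambers`, `valves`,
#'   `compartments`, `shunts` as in the shipped preset YAML files.
#' @param name Scenario label.
#' @return A [model_params()] object.
#' @keywords internal
parse_model_spec <- function(x, name = x$name) {
  for (f in c("thb_s", "chambers", "valves", "compartments", "shunts"))
    .check(!is.null(x[[f]]), f, "field is required in a model description")
  THB <- .num1(x$thb_s, "thb_s")
  chambers <- lapply(setNames(.chamber_names, .chamber_names), function(nm) {
    c0 <- x$chambers[[nm]]
    .check(!is.null(c0), paste0("chambers.", nm), "chamber block is missing")
    for (f in c("EA", "EB", "tC_frac", "TC_frac", "TR_frac"))
      .check(!is.null(c0[[f]]), paste0("chambers.", nm, ".", f),
             "field is required")
    chamber_params(EA = c0$EA, EB = c0$EB,
                   tC = c0$tC_frac * THB, TC = c0$TC_frac * THB,
                   TR = c0$TR_frac * THB,
                   V0 = if (is.null(c0$V0)) 0 else c0$V0, name = nm)
  })
  v <- valve_params(Rmin = x$valves$Rmin, Rmax = x$valves$Rmax)
  valves <- setNames(rep(list(v), 4), .valve_names)
  compartments <- lapply(setNames(.compartment_names, .compartment_names),
                         function(nm) {
    w0 <- x$compartments[[nm]]
    .check(!is.null(w0), paste0("compartments.", nm),
           "compartment block is missing")
    windkessel_params(R = w0$R, C = w0$C, L = w0$L, name = nm)
  })
  model_params(THB = THB, chambers = chambers, valves = valves,
               compartments = compartments,
               shunts = shunt_params(RASD = x$shunts$RASD,
                                     RVSD = x$shunts$RVSD),
               name = name)
}

#' Load a shipped scenario preset
#'
#' Three scenario presets are shipped, one per defect configuration:
#' `"vsd"` (isolated ventricular septal defect, RVSD = 0.038 mmHg s/mL),
#' `"asd"` (isolated atrial septal defect, RASD = 0.0031 mmHg s/mL) and
#' `"asd_vsd"` (both defects). With both defects closed each scenario is a
#' physiological closed-loop circulation.
#'
#' @param name One of `"vsd"`, `"asd"`, `"asd_vsd"`.
#' @param closed_asd,closed_vsd Close the corresponding defect branch.
#' @return A [model_params()] object.
#' @examples
#' m <- scenario_preset("vsd")
#' m$shunts$RVSD
#' @export
scenario_preset <- function(name = c("vsd", "asd", "asd_vsd"),
                            closed_asd = FALSE, closed_vsd = FALSE) {
  name <- match.arg(gsub("-", "_", tolower(name)),
                    c("vsd", "asd", "asd_vsd"))
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "shuntsim", mustWork = TRUE)
  m <- parse_model_spec(yaml::read_yaml(path))
  if (closed_asd) m$shunts$RASD <- "closed"
  if (closed_vsd) m$shunts$RVSD <- "closed"
  m
}

#' Path to a shipped preset file
#'
#' @param name One of `"vsd"`, `"asd"`, `"asd_vsd"`.
#' @return Filesystem path to the YAML preset.
#' @export
preset_path <- function(name) {
  system.file("extdata", "presets", paste0(gsub("-", "_", tolower(name)),
                                           ".yaml"),
              package = "shuntsim", mustWork = TRUE)
}
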