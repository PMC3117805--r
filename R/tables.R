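# Scenario batteries and tabular outputs.

#' Run a battery of scenarios and tabulate the clinical indices
#'
#' One column per scenario x contractility combination, one row per
#' implemented hemodynamic index (gas-exchange quantities are outside the
#' scope of this model).
#'
#' @param dd_types diastolic-dysfunction types to run.
#' @param contractilities contractility settings to cross with `dd_types`.
#' @param params control parameter set.
#' @param ... passed to [run_scenario()].
#' @return Data frame of indices; scenario labels as columns.
#' @export
scenario_table <- function(dd_types = c("control", "IR", "R", "PN"),
                           contractilities = c("normal", "increased"),
                           params = default_parameters(), ...) {
  cols <- list()
  for (dd in dd_types) for (ct in contractilities) {
    sim <- run_scenario(dd, ct, "fixed", params = params,
                        keep = "window", ...)
    s <- sim$summary
    cols[[paste(dd, ct, sep = ".")]] <- c(
      LVEDP = s$LVEDP, MSAP = s$MSAP, CVP = s$CVP, HR = s$HR, CO = s$CO,
      LVSV = s$LVSV, LVEF = s$LVEF, LVET = s$LVET,
      RVSV = s$RVSV, RVEF = s$RVEF, RVET = s$RVET,
      mitral_EA = s$mitral$EA, mitral_DT = s$mitral$DT,
      tricuspid_EA = s$tricuspid$EA,
      DS_central = s$DS_central, DS_pulmonary = s$DS_pulmonary,
      P_PAp = s$P_PAp, P_PAd = s$P_PAd, P_PA = s$P_PA, P_PC = s$P_PC,
      P_PV = s$P_PV, V_PA = s$V_PA, V_PC = s$V_PC, V_PV = s$V_PV,
      F_b = s$F_b, F_HRv = s$F_HRv, F_HRs = s$F_HRs, F_con = s$F_con,
      F_vaso = s$F_vaso)
  }
  as.data.frame(cols)
}

#' Respiratory-variation report
#'
#' Runs each scenario under sinusoidal pleural forcing and reports the
#' percent respiratory variation of the transvalvular flows and the
#' ventricular/pulmonary volumes.
#'
#' @param dd_types scenarios to run (normal contractility).
#' @param params control parameter set.
#' @param ... passed to [run_scenario()].
#' @return Data frame: one row per signal, one column per scenario.
#' @export
respiration_table <- function(dd_types = c("control", "IR", "R", "PN"),
                              params = default_parameters(), ...) {
  cols <- lapply(dd_types, function(dd) {
    sim <- run_scenario(dd, "normal", "sinusoid", params = params,
                        keep = "window", ...)
    sim$summary$resp_variation
  })
  names(cols) <- dd_types
  as.data.frame(cols)
}

#' Write the outputs of one scenario run to disk
#'
#' Writes the trajectory as CSV (one column per signal) and the clinical
#' summary as JSON, with scenario metadata for provenance.
#'
#' @param sim an `lvdd_sim` object.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_scenario_outputs <- function(sim, prefix) {
  csv <- paste0(prefix, "_trajectory.csv")
  js <- paste0(prefix, "_summary.json")
  utils::write.csv(sim$trajectory, csv, row.names = FALSE)
  meta <- list(scenario = unclass(sim$scenario), converged = sim$converged,
               clamp = sim$clamp, version = "1",
               summary = .summary_to_json(sim$summary))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, js))
}

.summary_to_json <- function(s) {
  s <- unclass(s)
  s$mitral <- unclass(s$mitral)
  s$tricuspid <- unclass(s$tricuspid)
  if (!is.null(s$resp_variation)) s$resp_variation <- as.list(s$resp_variation)
  s
}
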