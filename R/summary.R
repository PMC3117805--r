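# Consolidated per-scenario clinical summary.

#' Hemodynamic summary of a simulated trajectory
#'
#' Computes the full set of clinical indices over the analysis window (the
#' final five beats in fixed pleural mode, or the final complete
#' respiratory cycle under sinusoidal pleural forcing): ventricular
#' performance (EF, SV, CO, EDP, ET), mean pressures (MSAP from proximal
#' aortic, CVP from vena caval pressure), transvalvular inflow patterns,
#' venous D/S ratios, pulmonary means, and (sinusoid mode) respiratory
#' variation of the principal flows and volumes.
#'
#' @param traj trajectory data frame.
#' @param beats beat table.
#' @param params the parameter set used for the run (atrial timing is
#'   needed for the venous windows).
#' @param pleural "fixed" or "sinusoid".
#' @return A list of class `hemodynamic_summary`.
#' @export
hemodynamic_summary <- function(traj, beats, params,
                                pleural = c("fixed", "sinusoid")) {
  pleural <- match.arg(pleural)
  vi <- ventricular_indices(traj, beats)
  mit <- inflow_pattern(traj, "mitral", beats)
  tri <- inflow_pattern(traj, "tricuspid", beats)
  dsc <- venous_ds_ratio(traj, "central", beats, atrial = params$atrial)
  dsp <- venous_ds_ratio(traj, "pulmonary", beats, atrial = params$atrial)
  ib <- .analysis_beats(beats, traj, 5)
  t0 <- beats$onset[ib[1]]
  t1 <- beats$onset[ib[length(ib)]] + beats$period[ib[length(ib)]]
  if (pleural == "sinusoid") { t1 <- max(traj$time); t0 <- t1 - 7 }
  w <- traj$time >= t0 & traj$time <= t1
  avg <- function(col) mean(traj[[col]][w])
  out <- list(
    HR = vi$HR, CO = vi$CO,
    LVSV = vi$LV$SV, RVSV = vi$RV$SV,
    LVEF = vi$LV$EF, RVEF = vi$RV$EF,
    LVEDV = vi$LV$EDV, RVEDV = vi$RV$EDV,
    LVEDP = vi$LV$EDP, RVEDP = vi$RV$EDP,
    LVET = vi$LV$ET, RVET = vi$RV$ET,
    MSAP = avg("P_AOp"), CVP = avg("P_VC"),
    mitral = mit, tricuspid = tri,
    DS_central = dsc$DS, DS_pulmonary = dsp$DS,
    P_PAp = avg("P_PAp"), P_PAd = avg("P_PAd"), P_PA = avg("P_PA"),
    P_PC = avg("P_PC"), P_PV = avg("P_PV"),
    V_PAp = avg("V_PAp"), V_PAd = avg("V_PAd"), V_PA = avg("V_PA"),
    V_PC = avg("V_PC"), V_PV = avg("V_PV"),
    F_b = avg("F_b"), F_HRv = avg("F_HRv"), F_HRs = avg("F_HRs"),
    F_con = avg("F_con"), F_vaso = avg("F_vaso")
  )
  if (pleural == "sinusoid") {
    sigs <- c("Q_TC", "Q_M", "V_RV", "V_PAp", "V_PA", "V_PAd", "V_PC",
              "V_PV", "V_LV")
    out$resp_variation <- vapply(sigs, function(s) {
      respiratory_variation(traj, s, beats,
                            peak = if (s %in% c("Q_TC", "Q_M")) "early"
                                   else "max")
    }, numeric(1))
  }
  class(out) <- "hemodynamic_summary"
  out
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("HR %.1f bpm | CO %.2f l/min | MSAP %.1f | CVP %.1f mmHg\n",
              x$HR, x$CO, x$MSAP, x$CVP))
  cat(sprintf("LV: SV %.1f ml EF %.2f EDP %.1f mmHg ET %.2f s\n",
              x$LVSV, x$LVEF, x$LVEDP, x$LVET))
  cat(sprintf("RV: SV %.1f ml EF %.2f EDP %.1f mmHg ET %.2f s\n",
              x$RVSV, x$RVEF, x$RVEDP, x$RVET))
  cat(sprintf("Mitral E/A %.2f DT %.0f ms | Tricuspid E/A %.2f\n",
              x$mitral$EA, 1000 * x$mitral$DT, x$tricuspid$EA))
  cat(sprintf("D/S central %.2f pulmonary %.2f | P_PC %.1f mmHg\n",
              x$DS_central, x$DS_pulmonary, x$P_PC))
  if (!is.null(x$resp_variation)) {
    cat("Respiratory variation (%):\n")
    print(round(x$resp_variation, 1))
  }
  invisible(x)
}
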