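# Simulation engine: pleural forcing, the adaptive Cash-Karp integrator,
# scenario runs to periodic steady state, and the `lvdd_sim` result class.

#' Pleural pressure waveform
#'
#' Fixed mode holds pleural pressure at -5 mmHg; sinusoid mode oscillates
#' between -2 and -6 mmHg with a 7 s respiratory period.
#'
#' @param t time (s).
#' @param mode "fixed" or "sinusoid".
#' @return Pressure (mmHg).
#' @export
pleural_pressure <- function(t, mode = c("fixed", "sinusoid")) {
  mode <- match.arg(mode)
  stopifnot(all(t >= 0))
  if (mode == "fixed") rep(-5, length(t))
  else -4 - 2 * cos(2 * pi * t / 7)
}

#' Adaptive Cash-Karp RK4(5) integration
#'
#' Embedded 5th-order Runge-Kutta with the Cash-Karp tableau; step
#' acceptance on a mixed absolute/relative error norm.  This is the same
#' stepper that drives the cardiovascular model, exposed over an arbitrary
#' R right-hand side for verification against closed-form problems.
#'
#' @param f function `(t, y) -> dy/dt`.
#' @param y0 initial state (numeric vector).
#' @param t_span `c(t0, t1)`.
#' @param rtol,atol relative/absolute tolerances.
#' @param hmax maximal step size.
#' @return List with `t` (accepted times), `y` (state matrix, one row per
#'   accepted step) and `n_steps`.
#' @export
integrate_cash_karp <- function(f, y0, t_span, rtol = 1e-6, atol = 1e-6,
                                hmax = diff(t_span)) {
  stopifnot(length(t_span) == 2, diff(t_span) > 0, rtol > 0, atol > 0)
  cpp_ck_integrate(function(t, y) as.numeric(f(t, y)), as.numeric(y0),
                   t_span[1], t_span[2], rtol, atol, hmax)
}

#' Run one scenario to periodic steady state
#'
#' Applies the diastolic-dysfunction scenario to the control parameter set,
#' integrates the closed loop from the default initial state, detects the
#' periodic steady state (relative per-beat change of stroke volume and
#' mean arterial pressure below the configured tolerance across three
#' consecutive beats), and computes the clinical summary over the final
#' five beats (fixed pleural mode) or the final full respiratory cycle
#' (sinusoid mode).
#'
#' @param dd_type,contractility,pleural scenario selectors, see
#'   [scenario_config()].
#' @param params control parameter set (default [default_parameters()]).
#' @param scenario a ready-made `scenario_config` (overrides the selector
#'   arguments).
#' @param duration simulation length (s).
#' @param dt_report output grid spacing (s).
#' @param rtol,atol solver tolerances.
#' @param clamp neural clamping: "none", "con" (freeze contractility
#'   feedback at control), "hr" (freeze heart-rate efferents), or "all".
#' @param init optional initial state vector.
#' @param keep "all" retains the full trajectory, "window" only the
#'   analysis window (saves memory in batch runs).
#' @return An object of class `lvdd_sim` with elements `trajectory`
#'   (data frame), `beats`, `summary` (see [hemodynamic_summary()]),
#'   `converged`, `scenario`, `params`, and solver statistics.
#' @export
run_scenario <- function(dd_type = "control", contractility = "normal",
                         pleural = "fixed", params = default_parameters(),
                         scenario = NULL, duration = NULL, dt_report = 0.001,
                         rtol = 1e-6, atol = 1e-6, clamp = "none",
                         init = NULL, keep = c("all", "window")) {
  keep <- match.arg(keep)
  if (is.null(scenario))
    scenario <- scenario_config(dd_type, contractility, pleural,
                                duration = duration)
  else if (!is.null(duration)) scenario$duration <- duration
  sp <- apply_scenario(params, scenario)
  bad <- validate_parameters(sp)
  if (length(bad)) stop("invalid parameters: ", paste(bad, collapse = "; "))
  if (is.null(init)) init <- initial_state(sp)
  period0 <- heart_period(init["F_HRv"], init["F_HRs"], sp$neural)$period

  raw <- cpp_simulate(.flatten_params(sp, clamp), unname(init), 0, period0,
                      scenario$duration, dt_report,
                      ifelse(scenario$pleural == "fixed", 0L, 1L),
                      rtol, atol)
  n <- raw$n_rec
  traj <- as.data.frame(raw$traj[seq_len(n), , drop = FALSE])
  names(traj) <- c("time", .state_names, .aux_names)
  beats <- data.frame(onset = raw$beat_onsets, period = raw$beat_periods)
  beats <- beats[beats$onset + beats$period <= traj$time[n] + 1e-9, ,
                 drop = FALSE]

  bs <- .beat_stats(traj, beats)
  conv <- if (scenario$pleural == "fixed")
    .steady_converged(bs, scenario$steady_state_tol)
  else .steady_converged_cycles(bs, scenario$steady_state_tol)
  summ <- hemodynamic_summary(traj, beats, params = sp,
                              pleural = scenario$pleural)

  if (keep == "window") {
    t0 <- if (scenario$pleural == "fixed") {
      k <- nrow(beats); beats$onset[max(1, k - 5)]
    } else traj$time[n] - 14
    traj <- traj[traj$time >= t0 - 1e-9, , drop = FALSE]
  }
  structure(list(trajectory = traj, beats = beats, beat_stats = bs,
                 summary = summ, converged = conv, scenario = scenario,
                 params = sp, clamp = clamp,
                 solver = list(n_steps = raw$n_steps,
                               n_reject = raw$n_reject,
                               spt_iter_mean = raw$spt_iter_mean,
                               spt_fallbacks = raw$spt_fallbacks)),
            class = "lvdd_sim")
}

# per-beat stroke volume (LV) and mean arterial pressure
.beat_stats <- function(traj, beats) {
  n <- nrow(beats)
  sv <- msap <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- traj$time >= beats$onset[i] - 1e-9 &
         traj$time <= beats$onset[i] + beats$period[i] + 1e-9
    vl <- traj$V_LV[w]
    sv[i] <- max(vl) - min(vl)
    msap[i] <- mean(traj$P_AOp[w])
  }
  data.frame(onset = beats$onset, period = beats$period, SV = sv,
             MSAP = msap)
}

.steady_converged <- function(bs, tol) {
  n <- nrow(bs)
  if (n < 4) return(FALSE)
  i <- (n - 2):n
  rel <- function(x) max(abs(diff(x)) / pmax(abs(x[-length(x)]), 1e-9))
  rel(bs$SV[i]) < tol && rel(bs$MSAP[i]) < tol
}

# sinusoid mode: compare per-respiratory-cycle means of the beat statistics
# over the final two blocks of two complete 7 s cycles (two-cycle blocks
# average out the varying number of beats per cycle)
.steady_converged_cycles <- function(bs, tol, resp_period = 7) {
  Tend <- max(bs$onset + bs$period)
  if (Tend < 5 * resp_period) return(FALSE)
  m <- function(k) {  # k-th two-cycle block counted from the end
    hi <- Tend - 2 * (k - 1) * resp_period
    w <- bs$onset >= hi - 2 * resp_period & bs$onset < hi
    c(mean(bs$SV[w]), mean(bs$MSAP[w]))
  }
  a <- m(1); b <- m(2)
  all(abs(a - b) / pmax(abs(b), 1e-9) < 2 * tol)
}

#' @export
print.lvdd_sim <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("<lvdd_sim> scenario %s / %s contractility / %s pleural\n",
              sc$dd_type, sc$contractility, sc$pleural))
  cat(sprintf("  %d beats over %.1f s, steady state %s\n",
              nrow(x$beats), max(x$trajectory$time),
              if (x$converged) "reached" else "NOT reached"))
  s <- x$summary
  cat(sprintf("  HR %.1f bpm  CO %.2f l/min  LVEF %.2f  LVEDP %.1f mmHg  MSAP %.1f mmHg\n",
              s$HR, s$CO, s$LVEF, s$LVEDP, s$MSAP))
  invisible(x)
}

#' @export
summary.lvdd_sim <- function(object, ...) {
  object$summary
}

#' @export
coef.lvdd_sim <- function(object, ...) {
  w <- object$params$walls
  c(E_LV_ES = w$LVF$E_ES, E_RV_ES = w$RVF$E_ES, E_SPT_ES = w$SPT$E_ES,
    lambda_LV = w$LVF$lambda, lambda_RV = w$RVF$lambda,
    lambda_SPT = w$SPT$lambda)
}

#' Plot simulated waveforms or pressure-volume loops
#'
#' @param x an `lvdd_sim` object.
#' @param what "waveforms" (ventricular pressures and transvalvular flows
#'   over the final beats) or "pv" (LV and RV pressure-volume loops).
#' @param beats number of final beats to show.
#' @param ... ignored.
#' @export
plot.lvdd_sim <- function(x, what = c("waveforms", "pv"), beats = 3, ...) {
  what <- match.arg(what)
  tr <- x$trajectory
  nb <- nrow(x$beats)
  t0 <- x$beats$onset[max(1, nb - beats + 1)]
  w <- tr$time >= t0
  if (what == "waveforms") {
    op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(tr$time[w], tr$P_LV[w], type = "l", xlab = "time (s)",
                   ylab = "P (mmHg)", col = "firebrick")
    graphics::lines(tr$time[w], tr$P_AOp[w], col = "grey40")
    graphics::lines(tr$time[w], tr$P_LA[w], col = "steelblue")
    graphics::legend("topright", c("LV", "AO", "LA"), lty = 1, bty = "n",
                     col = c("firebrick", "grey40", "steelblue"))
    graphics::plot(tr$time[w], tr$Q_M[w], type = "l", xlab = "time (s)",
                   ylab = "Q_M (ml/s)")
    graphics::plot(tr$time[w], tr$Q_TC[w], type = "l", xlab = "time (s)",
                   ylab = "Q_TC (ml/s)")
  } else {
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(tr$V_RV[w], tr$P_RV[w], type = "l", xlab = "V_RV (ml)",
                   ylab = "P_RV (mmHg)")
    graphics::plot(tr$V_LV[w], tr$P_LV[w], type = "l", xlab = "V_LV (ml)",
                   ylab = "P_LV (mmHg)")
  }
  invisible(x)
}
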