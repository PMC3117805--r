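# Clinical waveform indices extracted from simulated (or synthetic)
# trajectories: valve events, ventricular performance, transvalvular inflow
# patterns (E/A, DT, IVRT, PFR, RFF/AFF), venous D/S ratios, respiratory
# variation, and P-V loop analysis.  All extractors are pure functions of
# the trajectory.

.resolve_traj <- function(x, beats) {
  if (inherits(x, "lvdd_sim")) list(traj = x$trajectory, beats = x$beats)
  else list(traj = x, beats = beats)
}

.trapz <- function(t, y) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Detect valve opening/closing events
#'
#' An event is a transition of valve flow across a 0.1 ml/s threshold.
#'
#' @param x an `lvdd_sim` object or trajectory data frame.
#' @param beats beat table (required if `x` is a data frame).
#' @param threshold flow threshold (ml/s).
#' @return Data frame with columns `valve`, `event` ("open"/"close"),
#'   `time`.
#' @export
detect_valve_events <- function(x, beats = NULL, threshold = 0.1) {
  rt <- .resolve_traj(x, beats)
  traj <- rt$traj
  cols <- c(mitral = "Q_M", tricuspid = "Q_TC", aortic = "Q_AO",
            pulmonic = "Q_PAV")
  out <- list()
  for (v in names(cols)) {
    q <- traj[[cols[v]]]
    if (is.null(q)) next
    above <- q > threshold
    d <- diff(above)
    io <- which(d == 1) + 1
    ic <- which(d == -1) + 1
    if (length(io))
      out[[paste0(v, "_o")]] <- data.frame(valve = v, event = "open",
                                           time = traj$time[io])
    if (length(ic))
      out[[paste0(v, "_c")]] <- data.frame(valve = v, event = "close",
                                           time = traj$time[ic])
  }
  if (!length(out))
    return(data.frame(valve = character(), event = character(),
                      time = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$time), ]
}

# indices of the last `n` complete beats
.analysis_beats <- function(beats, traj, n = 5) {
  ok <- which(beats$onset + beats$period <= max(traj$time) + 1e-9)
  utils::tail(ok, n)
}

#' Ventricular performance indices
#'
#' Per-beat end-diastolic/end-systolic volumes, stroke volume, ejection
#' fraction, cardiac output and ejection time, averaged over the analysis
#' beats.  EDP is the chamber pressure at end diastole (volume maximum).
#'
#' @param x an `lvdd_sim` or trajectory data frame.
#' @param beats beat table if `x` is a data frame.
#' @param n_beats number of final complete beats to analyze.
#' @return List with per-ventricle `EDV`, `ESV`, `SV`, `EF`, `EDP`, `ET`
#'   (s), plus `HR` (bpm) and `CO` (l/min, from the LV).
#' @export
ventricular_indices <- function(x, beats = NULL, n_beats = 5) {
  rt <- .resolve_traj(x, beats)
  traj <- rt$traj; bt <- rt$beats
  ib <- .analysis_beats(bt, traj, n_beats)
  ev <- detect_valve_events(traj, bt)
  res <- list()
  for (side in c("LV", "RV")) {
    vcol <- paste0("V_", side); pcol <- paste0("P_", side)
    outlet <- if (side == "LV") "aortic" else "pulmonic"
    edv <- esv <- edp <- et <- rep(NA_real_, length(ib))
    for (k in seq_along(ib)) {
      i <- ib[k]
      w <- traj$time >= bt$onset[i] - 1e-9 &
           traj$time <= bt$onset[i] + bt$period[i] + 1e-9
      vv <- traj[[vcol]][w]; tt <- traj$time[w]
      edv[k] <- max(vv); esv[k] <- min(vv)
      edp[k] <- traj[[pcol]][w][which.max(vv)]
      op <- ev$time[ev$valve == outlet & ev$event == "open" &
                    ev$time >= tt[1] & ev$time <= tt[length(tt)]]
      cl <- ev$time[ev$valve == outlet & ev$event == "close" &
                    ev$time >= tt[1] & ev$time <= tt[length(tt)]]
      if (length(op) && length(cl)) {
        cl2 <- cl[cl > op[1]]
        if (length(cl2)) et[k] <- cl2[1] - op[1]
      }
    }
    res[[side]] <- list(EDV = mean(edv), ESV = mean(esv),
                        SV = mean(edv - esv),
                        EF = mean((edv - esv) / edv),
                        EDP = mean(edp), ET = mean(et, na.rm = TRUE))
  }
  hr <- 60 / mean(bt$period[ib])
  res$HR <- hr
  res$CO <- res$LV$SV * hr / 1000
  res
}

# local maxima of a flow segment (simple neighbor comparison with a small
# amplitude floor to skip numerical ripple)
.find_peaks <- function(t, q, floor_frac = 0.05) {
  n <- length(q)
  if (n < 3) return(integer(0))
  floor_val <- floor_frac * max(q)
  idx <- which(q[2:(n - 1)] > q[1:(n - 2)] & q[2:(n - 1)] >= q[3:n]) + 1
  idx <- idx[q[idx] > floor_val]
  # merge plateaus / ripples closer than 30 ms, keeping the taller peak
  if (length(idx) > 1) {
    keep <- idx[1]
    for (i in idx[-1]) {
      if (t[i] - t[keep[length(keep)]] < 0.03) {
        if (q[i] > q[keep[length(keep)]]) keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    idx <- keep
  }
  idx
}

#' Transvalvular inflow pattern
#'
#' Extracts the early (E) and atrial (A) filling waves of mitral or
#' tricuspid flow: peak amplitudes, E/A ratio, deceleration time (linear
#' least-squares extrapolation of the 70 to 30 percent descending limb of
#' the E wave to zero flow), isovolumic relaxation time (outlet-valve
#' closure to inlet-valve opening), peak filling rate and the rapid/atrial
#' filling fractions (window boundary at the inter-wave flow minimum).
#' Fused (monophasic) inflow reports `A = NA` and `EA = NA`.
#'
#' @param x an `lvdd_sim` or trajectory data frame.
#' @param valve "mitral" or "tricuspid".
#' @param beats beat table if `x` is a data frame.
#' @param n_beats number of final beats to average.
#' @return List with `E`, `A`, `EA`, `DT` (s), `IVRT` (s), `PFR` (ml/s),
#'   `RFF`, `AFF`.
#' @export
inflow_pattern <- function(x, valve = c("mitral", "tricuspid"),
                           beats = NULL, n_beats = 5) {
  valve <- match.arg(valve)
  rt <- .resolve_traj(x, beats)
  traj <- rt$traj; bt <- rt$beats
  qcol <- if (valve == "mitral") "Q_M" else "Q_TC"
  outlet <- if (valve == "mitral") "aortic" else "pulmonic"
  ev <- detect_valve_events(traj, bt)
  ib <- .analysis_beats(bt, traj, n_beats)
  acc <- list(E = c(), A = c(), EA = c(), DT = c(), IVRT = c(), PFR = c(),
              RFF = c(), AFF = c())
  for (i in ib) {
    t0 <- bt$onset[i]; t1 <- t0 + bt$period[i]
    op <- ev$time[ev$valve == valve & ev$event == "open" &
                  ev$time >= t0 & ev$time < t1]
    if (!length(op)) next
    top <- op[1]
    cl <- ev$time[ev$valve == valve & ev$event == "close" & ev$time > top]
    tcl <- if (length(cl)) cl[1] else t1 + 0.1
    w <- traj$time >= top & traj$time <= tcl
    tt <- traj$time[w]; qq <- traj[[qcol]][w]
    if (length(tt) < 5) next
    pk <- .find_peaks(tt, qq)
    if (!length(pk)) next
    E <- qq[pk[1]]; tE <- tt[pk[1]]
    fused <- length(pk) < 2
    A <- if (fused) NA_real_ else qq[pk[length(pk)]]
    # deceleration time from the E-wave descending limb
    after <- which(tt > tE)
    stop_idx <- if (fused) length(tt) else {
      # descend only until the inter-wave minimum
      seg <- pk[1]:pk[length(pk)]
      seg[which.min(qq[seg])]
    }
    dsc <- after[after <= stop_idx]
    lim <- dsc[qq[dsc] <= 0.7 * E & qq[dsc] >= 0.3 * E]
    DT <- NA_real_
    if (length(lim) >= 3) {
      fit <- stats::lsfit(tt[lim], qq[lim])
      sl <- fit$coefficients[2]
      if (is.finite(sl) && sl < 0) {
        tzero <- -fit$coefficients[1] / sl
        DT <- unname(tzero - tE)
      }
    }
    # IVRT: outlet valve closure before inflow onset
    ocl <- ev$time[ev$valve == outlet & ev$event == "close" & ev$time < top]
    IVRT <- if (length(ocl)) top - ocl[length(ocl)] else NA_real_
    PFR <- E
    total <- .trapz(tt, qq)
    if (fused) {
      RFF <- NA_real_; AFF <- NA_real_
    } else {
      bnd <- stop_idx
      RFF <- .trapz(tt[1:bnd], qq[1:bnd]) / total
      AFF <- .trapz(tt[bnd:length(tt)], qq[bnd:length(tt)]) / total
    }
    acc$E <- c(acc$E, E); acc$A <- c(acc$A, A)
    acc$EA <- c(acc$EA, if (fused) NA_real_ else E / A)
    acc$DT <- c(acc$DT, DT); acc$IVRT <- c(acc$IVRT, IVRT)
    acc$PFR <- c(acc$PFR, PFR); acc$RFF <- c(acc$RFF, RFF)
    acc$AFF <- c(acc$AFF, AFF)
  }
  if (!length(acc$E))
    return(list(E = NA_real_, A = NA_real_, EA = NA_real_, DT = NA_real_,
                IVRT = NA_real_, PFR = NA_real_, RFF = NA_real_,
                AFF = NA_real_))
  lapply(acc, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

#' Venous inflow D/S flow-volume ratio
#'
#' Splits central venous (vena caval) or pulmonary venous inflow into the
#' systolic (S: AV-valve closure to opening), diastolic (D: opening to
#' atrial activation onset) and atrial-reversal (AR: atrial onset to the
#' next closure) windows, integrates each by the trapezoid rule, and
#' returns the D/S volume ratio.
#'
#' @param x an `lvdd_sim` or trajectory data frame.
#' @param side "central" (vena caval flow, tricuspid windows) or
#'   "pulmonary" (pulmonary venous flow, mitral windows).
#' @param beats beat table if `x` is a data frame.
#' @param atrial atrial activation spec (list with `B`, `offset`), used to
#'   place the atrial-contraction onset.
#' @param n_beats number of final beats to average.
#' @return List with mean `S`, `D`, `AR` volumes (ml) and `DS` ratio.
#' @export
venous_ds_ratio <- function(x, side = c("central", "pulmonary"),
                            beats = NULL,
                            atrial = list(B = 0.05, offset = 0.14),
                            n_beats = 5) {
  side <- match.arg(side)
  rt <- .resolve_traj(x, beats)
  traj <- rt$traj; bt <- rt$beats
  if (inherits(x, "lvdd_sim")) atrial <- x$params$atrial
  qcol <- if (side == "central") "Q_VC" else "Q_PV"
  av <- if (side == "central") "tricuspid" else "mitral"
  ev <- detect_valve_events(traj, bt)
  ib <- .analysis_beats(bt, traj, n_beats)
  S <- D <- AR <- c()
  for (i in ib) {
    t0 <- bt$onset[i]; t1 <- t0 + bt$period[i]
    cl <- ev$time[ev$valve == av & ev$event == "close" &
                  ev$time >= t0 - 0.2 & ev$time < t0 + 0.5 * bt$period[i]]
    op <- ev$time[ev$valve == av & ev$event == "open" &
                  ev$time >= t0 & ev$time < t1]
    if (!length(cl) || !length(op)) next
    tcl <- cl[1]; top <- op[op > tcl][1]
    if (is.na(top)) next
    t_atr <- t0 + bt$period[i] - atrial$offset - 2 * atrial$B
    ncl <- ev$time[ev$valve == av & ev$event == "close" & ev$time > top]
    tnc <- if (length(ncl)) ncl[1] else t1
    if (t_atr <= top || tnc <= t_atr) next
    win <- function(a, b) {
      w <- traj$time >= a & traj$time <= b
      .trapz(traj$time[w], traj[[qcol]][w])
    }
    S <- c(S, win(tcl, top)); D <- c(D, win(top, t_atr))
    AR <- c(AR, win(t_atr, tnc))
  }
  if (!length(S)) return(list(S = NA_real_, D = NA_real_, AR = NA_real_,
                              DS = NA_real_))
  list(S = mean(S), D = mean(D), AR = mean(AR), DS = mean(D) / mean(S))
}

#' Percent respiratory variation of a signal
#'
#' Collects a per-beat peak of the signal over the final complete
#' respiratory cycle and returns `100 * (max - min) / max`.  For volumes
#' and pressures the per-beat maximum is used; for transvalvular inflows
#' (`peak = "early"`) the early-diastolic (E-wave) peak is tracked, since
#' the atrial wave is driven by atrial contraction and is largely
#' insensitive to pleural pressure.
#'
#' @param x an `lvdd_sim` or trajectory data frame.
#' @param signal trajectory column name (e.g. "Q_TC", "Q_M", "V_RV").
#' @param beats beat table if `x` is a data frame.
#' @param resp_period respiratory period (s).
#' @param peak "max" (per-beat maximum) or "early" (first diastolic flow
#'   peak after AV-valve opening; requires `signal` to be "Q_M" or "Q_TC").
#' @return Percent variation.
#' @export
respiratory_variation <- function(x, signal, beats = NULL,
                                  resp_period = 7,
                                  peak = c("max", "early")) {
  peak <- match.arg(peak)
  rt <- .resolve_traj(x, beats)
  traj <- rt$traj; bt <- rt$beats
  Tend <- max(traj$time)
  sel <- which(bt$onset >= Tend - resp_period - 1e-9 &
               bt$onset < Tend - 1e-9)
  if (length(sel) < 4)
    warning("fewer than 4 beats in the respiratory cycle")
  if (peak == "max") {
    peaks <- vapply(sel, function(i) {
      w <- traj$time >= bt$onset[i] &
           traj$time <= min(bt$onset[i] + bt$period[i], Tend)
      max(traj[[signal]][w])
    }, numeric(1))
  } else {
    av <- if (signal == "Q_M") "mitral" else "tricuspid"
    ev <- detect_valve_events(traj, bt)
    peaks <- c()
    for (i in sel) {
      t0 <- bt$onset[i]; t1 <- t0 + bt$period[i]
      op <- ev$time[ev$valve == av & ev$event == "open" &
                    ev$time >= t0 & ev$time < t1]
      if (!length(op)) next
      cl <- ev$time[ev$valve == av & ev$event == "close" &
                    ev$time > op[1]]
      tcl <- if (length(cl)) min(cl[1], Tend) else min(t1, Tend)
      w <- traj$time >= op[1] & traj$time <= tcl
      q <- traj[[signal]][w]
      pk <- .find_peaks(traj$time[w], q)
      peaks <- c(peaks, if (length(pk)) q[pk[1]] else max(q))
    }
  }
  100 * (max(peaks) - min(peaks)) / max(peaks)
}

#' Ventricular pressure-volume loop
#'
#' Returns the ordered (V, P) loop of the chamber for each analysis beat
#' and its area (stroke work) by the shoelace formula.
#'
#' @param x an `lvdd_sim` or trajectory data frame.
#' @param chamber "LV" or "RV".
#' @param beats beat table if `x` is a data frame.
#' @param n_beats number of final beats.
#' @return List of per-beat lists with `V`, `P`, `area` (mmHg ml).
#' @export
pv_loop <- function(x, chamber = c("LV", "RV"), beats = NULL, n_beats = 1) {
  chamber <- match.arg(chamber)
  rt <- .resolve_traj(x, beats)
  traj <- rt$traj; bt <- rt$beats
  ib <- .analysis_beats(bt, traj, n_beats)
  vcol <- paste0("V_", chamber); pcol <- paste0("P_", chamber)
  lapply(ib, function(i) {
    w <- traj$time >= bt$onset[i] - 1e-9 &
         traj$time <= bt$onset[i] + bt$period[i] + 1e-9
    V <- traj[[vcol]][w]; P <- traj[[pcol]][w]
    n <- length(V)
    j <- c(2:n, 1)
    area <- abs(sum(V * P[j] - V[j] * P)) / 2
    list(V = V, P = P, area = area)
  })
}

#' Synthetic trajectory fixture with known indices
#'
#' Builds flow/volume traces from closed-form primitives (rectangles,
#' triangles with prescribed descending slope, Gaussian pulses) so each
#' extractor can be verified against an analytic answer without running
#' the simulator.  The E wave descends linearly from its peak at slope
#' `-E/DT`, so the deceleration-time extrapolation recovers `DT` exactly;
#' venous S and D waves are rectangles with prescribed areas.
#'
#' @param E,A mitral E/A peak flows (ml/s).
#' @param DT deceleration time (s).
#' @param EDV,ESV end-diastolic/systolic LV volume (ml).
#' @param S_vol,D_vol venous systolic/diastolic wave volumes (ml).
#' @param period beat period (s).
#' @param n_beats number of beats.
#' @param dt sampling interval (s).
#' @param beat_scale optional per-beat amplitude multipliers (length
#'   `n_beats`), emulating respiratory modulation.
#' @return An object usable by the extractors (class `lvdd_sim` subset
#'   with `trajectory` and `beats`).
#' @export
make_fixture_trace <- function(E = 80, A = 60, DT = 0.2, EDV = 120,
                               ESV = 50, S_vol = 30, D_vol = 30,
                               period = 1, n_beats = 3, dt = 0.001,
                               beat_scale = NULL) {
  if (is.null(beat_scale)) beat_scale <- rep(1, n_beats)
  stopifnot(length(beat_scale) == n_beats)
  tmax <- n_beats * period
  time <- seq(0, tmax, by = dt)
  n <- length(time)
  Q_M <- Q_AO <- Q_TC <- Q_PAV <- Q_VC <- Q_PVv <- numeric(n)
  # the final grid point (phase exactly 1 of the last beat) is end-diastole
  V_LV <- rep(EDV, n)
  P_LV <- rep(10, n)
  # beat-local schedule (fractions of the period):
  ej0 <- 0.06; ej1 <- 0.34         # ejection (outlet valve open)
  mo <- 0.46                       # inflow (AV valve) opens
  a0 <- 0.80; a1 <- 0.97           # atrial wave
  SV <- EDV - ESV
  for (b in seq_len(n_beats)) {
    t0 <- (b - 1) * period
    ph <- (time - t0) / period
    inb <- ph >= 0 & ph < 1
    p <- ph[inb]
    sc <- beat_scale[b]
    qa <- ifelse(p >= ej0 & p < ej1, SV / ((ej1 - ej0) * period), 0)
    # E wave: fast linear rise over 60 ms, then linear descent at -E/DT
    tE <- (mo + 0.06) * period
    eseg <- numeric(length(p))
    rise <- p >= mo & p < mo + 0.06
    eseg[rise] <- E * (p[rise] - mo) / 0.06
    desc <- p >= mo + 0.06
    val <- E * (1 - (p[desc] * period - tE) / DT)
    eseg[desc] <- pmax(0, val)
    # A wave: symmetric triangle
    aseg <- numeric(length(p))
    am <- (a0 + a1) / 2
    inA <- p >= a0 & p < a1
    aseg[inA] <- A * (1 - abs(p[inA] - am) / ((a1 - a0) / 2))
    # small pedestal keeps the AV valve "open" between the E and A waves
    ped <- ifelse(p >= mo & p < a0 + 0.01, 2, 0)
    qm <- pmax(eseg, aseg, ped) * sc
    qs <- ifelse(p >= 0.05 & p < 0.35, S_vol / (0.3 * period), 0)
    qd <- ifelse(p >= mo & p < mo + 0.25, D_vol / (0.25 * period), 0)
    Q_M[inb] <- qm
    Q_TC[inb] <- qm
    Q_AO[inb] <- qa
    Q_PAV[inb] <- qa
    Q_VC[inb] <- (qs + qd) * sc
    Q_PVv[inb] <- qs + qd
    # LV volume: linear ejection, then refill proportional to inflow volume
    vv <- numeric(length(p))
    vv[p < ej0] <- EDV
    eject <- p >= ej0 & p < ej1
    vv[eject] <- EDV - SV * (p[eject] - ej0) / (ej1 - ej0)
    after <- p >= ej1
    cumin <- cumsum(qm) * dt
    fillv <- cumin - ifelse(any(eject), cumin[max(which(eject))], 0)
    tot <- max(fillv[after], 1e-9)
    vv[after] <- ESV + SV * pmax(0, fillv[after]) / tot
    V_LV[inb] <- vv
    P_LV[inb] <- ifelse(p >= ej0 & p < ej1, 100, 10)
  }
  traj <- data.frame(time = time, V_LV = V_LV, V_RV = V_LV, P_LV = P_LV,
                     P_RV = P_LV, P_AOp = 95, P_VC = 3,
                     Q_M = Q_M, Q_TC = Q_TC, Q_AO = Q_AO, Q_PAV = Q_PAV,
                     Q_VC = Q_VC, Q_PV = Q_PVv)
  beats <- data.frame(onset = (seq_len(n_beats) - 1) * period,
                      period = period)
  structure(list(trajectory = traj, beats = beats,
                 params = list(atrial = list(B = 0.02,
                                             offset = (1 - (a0 + a1) / 2)))),
            class = "lvdd_sim")
}
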