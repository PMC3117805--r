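# Shared, memoized scenario runs (each steady-state run takes a few seconds;
# several tests interrogate the same scenarios).

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(dd, ct = "normal", pleural = "fixed",
                       clamp = "none") {
  key <- paste(dd, ct, pleural, clamp, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    dur <- if (pleural == "fixed") 70 else 91
    .sim_cache[[key]] <- run_scenario(dd, ct, pleural, duration = dur,
                                      clamp = clamp, keep = "window")
  }
  .sim_cache[[key]]
}

# bisection oracle for the septal volume: root of g(V) = V - W(V) where W is
# the activation-weighted inverse of the septal P-V law evaluated at the
# trans-septal pressure.  Independent R implementation of the defining
# equations (the engine uses damped fixed-point iteration in C++).
septal_bisect_oracle <- function(V_LV, V_RV, e_LVF, e_RVF, e_SPT, params,
                                 alpha = 1, lo = -60, hi = 80,
                                 tol = 1e-9) {
  w <- params$walls
  wallp <- function(e, V, wl) {
    e * alpha * wl$E_ES * (V - wl$V_d) +
      (1 - e) * wl$P_0 * expm1(wl$lambda * (V - wl$V_0))
  }
  g <- function(V) {
    Ps <- wallp(e_LVF, V_LV - V, w$LVF) - wallp(e_RVF, V_RV + V, w$RVF)
    Vsys <- w$SPT$V_d + Ps / (alpha * w$SPT$E_ES)
    Vdia <- w$SPT$V_0 +
      sign(Ps) * log1p(abs(Ps) / w$SPT$P_0) / w$SPT$lambda
    V - (e_SPT * Vsys + (1 - e_SPT) * Vdia)
  }
  while (g(lo) > 0) lo <- lo - 60
  while (g(hi) < 0) hi <- hi + 80
  uniroot(g, c(lo, hi), tol = tol)$root
}
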