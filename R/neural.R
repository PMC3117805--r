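# Baroreflex: arterial-pressure sensing, affine efferent maps identified
# from the printed steady-state operating points, first-order low-pass
# filtering, and chronotropic/inotropic/vasomotor effectors.

#' Baroreceptor discharge frequency
#'
#' Affine-saturating map of (low-pass filtered) mean systemic arterial
#' pressure to the normalized discharge frequency:
#' `F_b = clip(a*MSAP + b, 0, 1)`.
#'
#' @param MSAP_filtered filtered arterial pressure (mmHg).
#' @param neural neural parameter list (see [default_parameters()]).
#' @return `F_b` in `[0, 1]`.
#' @export
baroreceptor_discharge <- function(MSAP_filtered,
                                   neural = default_parameters()$neural) {
  stopifnot(all(MSAP_filtered > 0))
  pmin(1, pmax(0, neural$ab * MSAP_filtered + neural$bb))
}

#' Efferent limb targets
#'
#' Affine maps of the baroreceptor frequency to the four efferent limbs:
#' the sympathetic limbs (`F_HRs`, `F_con`, `F_vaso`) decrease in `F_b`,
#' the vagal limb (`F_HRv`) increases; all clipped to `[0, 1]`.
#'
#' @param F_b baroreceptor frequency in `[0, 1]`.
#' @param neural neural parameter list.
#' @return Named vector with `F_HRv`, `F_HRs`, `F_con`, `F_vaso`.
#' @export
efferent_targets <- function(F_b, neural = default_parameters()$neural) {
  stopifnot(all(F_b >= 0), all(F_b <= 1))
  v <- neural$intercepts + neural$slopes * F_b
  stats::setNames(pmin(1, pmax(0, v)),
                  c("F_HRv", "F_HRs", "F_con", "F_vaso"))
}

#' First-order low-pass update
#'
#' Exact exponential relaxation toward the target over a step `dt`:
#' `x + (target - x) * (1 - exp(-dt/tau))`.
#'
#' @param current,target current and target values.
#' @param tau time constant (s).
#' @param dt time step (s).
#' @return Updated value.
#' @export
low_pass_update <- function(current, target, tau, dt) {
  stopifnot(tau > 0)
  current + (target - current) * (1 - exp(-dt / tau))
}

#' Heart rate / beat period from the efferent limbs
#'
#' Linear chronotropic map `HR = h0 + hs*F_HRs + hv*F_HRv` (coefficients
#' identified by least squares from the printed operating points), clipped
#' to a physiological band.  The beat period is sampled at each beat onset.
#'
#' @param F_HRv,F_HRs vagal and sympathetic efferent frequencies.
#' @param neural neural parameter list.
#' @return List with `HR` (bpm) and `period` (s).
#' @export
heart_period <- function(F_HRv, F_HRs, neural = default_parameters()$neural) {
  stopifnot(all(F_HRv >= 0), all(F_HRv <= 1),
            all(F_HRs >= 0), all(F_HRs <= 1))
  hr <- neural$h0 + neural$hs * F_HRs + neural$hv * F_HRv
  hr <- pmin(neural$hr_max, pmax(neural$hr_min, hr))
  list(HR = hr, period = 60 / hr)
}

#' Neural contractility factor
#'
#' `alpha(F_con) = max(1, 1 + k_alpha * (F_con - F_con_ref))`, applied to
#' the end-systolic elastances of the LV free wall, RV free wall and
#' septum.
#'
#' @param F_con contractility efferent frequency in `[0, 1]`.
#' @param neural neural parameter list.
#' @return `alpha >= 1`.
#' @export
contractility_gain <- function(F_con, neural = default_parameters()$neural) {
  stopifnot(all(F_con >= 0), all(F_con <= 1))
  pmax(1, 1 + neural$k_alpha * (F_con - neural$F_con_ref))
}
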