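# Wall, chamber, septal, atrial and pericardial pressure laws.
#
# Systole: linear end-systolic P-V relation P = alpha * E_ES * (V - V_d).
# Diastole: exponential passive relation P = P_0 * (exp(lambda*(V - V_0)) - 1).
# The instantaneous wall pressure blends the two with the activation weight.

#' End-systolic wall pressure
#'
#' Linear end-systolic pressure-volume relation `alpha * E_ES * (V - V_d)`,
#' where `alpha >= 1` is the neural contractility factor.
#'
#' @param V wall volume (ml).
#' @param wall list with `E_ES` (mmHg/ml) and `V_d` (ml).
#' @param alpha dimensionless contractility factor (>= 1).
#' @return Pressure (mmHg).
#' @export
end_systolic_pressure <- function(V, wall, alpha = 1) {
  stopifnot(alpha >= 1)
  alpha * wall$E_ES * (V - wall$V_d)
}

#' End-diastolic (passive) wall pressure
#'
#' Exponential end-diastolic pressure-volume relation
#' `P_0 * (exp(lambda * (V - V_0)) - 1)`: zero at `V = V_0`, strictly
#' increasing in `V`.
#'
#' @param V wall volume (ml).
#' @param wall list with `P_0` (mmHg), `lambda` (1/ml), `V_0` (ml).
#' @return Pressure (mmHg).
#' @export
end_diastolic_pressure <- function(V, wall) {
  x <- wall$lambda * (V - wall$V_0)
  x <- pmin(x, 700)
  wall$P_0 * expm1(x)
}

#' Instantaneous free-wall pressure
#'
#' Activation-weighted sum of the systolic and diastolic laws:
#' `e * P_ES + (1 - e) * P_ED`.
#'
#' @param e activation weight in `[0, 1]`.
#' @param P_ES,P_ED end-systolic and end-diastolic pressures (mmHg).
#' @return Pressure (mmHg).
#' @export
free_wall_pressure <- function(e, P_ES, P_ED) {
  stopifnot(all(e >= 0), all(e <= 1))
  e * P_ES + (1 - e) * P_ED
}

#' Pericardial pressure
#'
#' Exponential constraint in total heart volume referenced to pleural
#' pressure: `P_PERI0 * (exp(lambda_PERI * (V_heart - V_PERI0)) - 1) + P_PL`.
#' Heart volume includes the pericardial fluid volume.
#'
#' @param V_heart total intrapericardial volume (ml).
#' @param P_PL pleural pressure (mmHg).
#' @param peri list with `P_0`, `lambda`, `V_0`.
#' @return Pressure (mmHg).
#' @export
pericardial_pressure <- function(V_heart, P_PL, peri) {
  stopifnot(all(V_heart > 0))
  peri$P_0 * expm1(pmin(peri$lambda * (V_heart - peri$V_0), 700)) + P_PL
}

#' Atrial chamber pressure
#'
#' Same weighted systolic/diastolic form as the ventricular free walls;
#' absolute pressure adds the pericardial pressure.
#'
#' @param V atrial volume (ml).
#' @param e_atrium atrial activation weight.
#' @param wall atrial wall parameters.
#' @param P_PERI pericardial pressure (mmHg).
#' @return Absolute chamber pressure (mmHg).
#' @export
atrial_pressure <- function(V, e_atrium, wall, P_PERI) {
  free_wall_pressure(e_atrium,
                     end_systolic_pressure(V, wall),
                     end_diastolic_pressure(V, wall)) + P_PERI
}

#' Instantaneous wall elastance
#'
#' Local `dP/dV` of the activation-weighted wall law:
#' `e * alpha * E_ES + (1 - e) * lambda * P_0 * exp(lambda * (V - V_0))`.
#'
#' @param e activation weight.
#' @param V wall volume (ml).
#' @param wall wall parameters.
#' @param alpha contractility factor.
#' @return Elastance (mmHg/ml).
#' @export
instantaneous_elastance <- function(e, V, wall, alpha = 1) {
  stopifnot(all(e >= 0), all(e <= 1), alpha >= 1)
  e * alpha * wall$E_ES +
    (1 - e) * wall$lambda * wall$P_0 * exp(pmin(wall$lambda * (V - wall$V_0), 700))
}

#' Solve the septal volume by damped fixed-point iteration
#'
#' Given chamber volumes and the three ventricular activation weights, finds
#' the septal volume `V_SPT` at which the septal P-V law (weighted inverse of
#' its systolic and diastolic branches, sign-mirrored for leftward bulging)
#' is consistent with the trans-septal pressure difference
#' `P_SPT = P_LVF(V_LV - V_SPT) - P_RVF(V_RV + V_SPT)`.  Positive septal
#' volume means the septum bulges into the right ventricle.  Iteration uses
#' damping 0.5 and falls back to a bracketing bisection when the fixed point
#' does not contract; a final Newton polish makes the result independent of
#' the starting value.
#'
#' @param V_LV,V_RV chamber volumes (ml).
#' @param e_LVF,e_RVF,e_SPT activation weights.
#' @param params an `hcrs_params` object.
#' @param alpha contractility factor applied to all three ventricular walls.
#' @param V_SPT_init starting value (ml).
#' @param tol convergence tolerance on the fixed-point update (ml).
#' @param max_iter iteration cap before the bisection fallback.
#' @return List with `V_SPT`, free-wall and trans-septal pressures,
#'   `iterations` and `fallback`.
#' @export
solve_septal_volume <- function(V_LV, V_RV, e_LVF, e_RVF, e_SPT, params,
                                alpha = 1, V_SPT_init = 0, tol = 1e-6,
                                max_iter = 100) {
  stopifnot(V_LV > 0, V_RV > 0)
  cpp_septal_solve(V_LV, V_RV, e_LVF, e_RVF, e_SPT,
                   .flatten_params(params), alpha, V_SPT_init, 0.5, tol,
                   max_iter)
}

#' Ventricular pressures at a given state
#'
#' Runs the septal solve and assembles absolute chamber pressures
#' (`P_LV = P_LVF + P_PERI`, `P_RV = P_RVF + P_PERI`).
#'
#' @inheritParams solve_septal_volume
#' @param V_LA,V_RA atrial volumes (ml), needed for the pericardial volume.
#' @param P_PL pleural pressure (mmHg).
#' @return List with chamber, free-wall, trans-septal and pericardial
#'   pressures and the septal volume.
#' @export
ventricular_pressures <- function(V_LV, V_RV, V_LA, V_RA, e_LVF, e_RVF,
                                  e_SPT, params, alpha = 1, P_PL = -5,
                                  V_SPT_init = 0) {
  s <- solve_septal_volume(V_LV, V_RV, e_LVF, e_RVF, e_SPT, params,
                           alpha = alpha, V_SPT_init = V_SPT_init)
  Vh <- V_LV + V_RV + V_LA + V_RA + params$pericardium$V_fluid
  pp <- pericardial_pressure(Vh, P_PL, params$pericardium)
  list(P_LVF = s$P_LVF, P_RVF = s$P_RVF,
       P_LV = s$P_LVF + pp, P_RV = s$P_RVF + pp,
       P_SPT = s$P_SPT, V_SPT = s$V_SPT, P_PERI = pp,
       iterations = s$iterations)
}
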