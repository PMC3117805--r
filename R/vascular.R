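# Elemental laws of the circulation network and the R-level surface over
# the compiled right-hand side.

#' Vascular compartment pressure
#'
#' Linear compliance element: `P = (V - V_un)/C + P_ext`.
#'
#' @param V compartment volume (ml).
#' @param comp list (or one-row data frame) with `C` (ml/mmHg) and `V_un`
#'   (ml).
#' @param P_ext external reference pressure (pleural for thoracic
#'   compartments, body pressure otherwise; mmHg).
#' @return Pressure (mmHg).
#' @export
compartment_pressure <- function(V, comp, P_ext = 0) {
  stopifnot(all(V >= 0))
  (V - comp$V_un) / comp$C + P_ext
}

#' Diode valve flow
#'
#' `max(0, (P_up - P_down)/R_open)`: unidirectional resistive flow,
#' continuous at zero pressure difference.
#'
#' @param P_up,P_down upstream/downstream pressures (mmHg).
#' @param valve list with `R_open` (mmHg s/ml).
#' @return Flow (ml/s).
#' @export
valve_flow <- function(P_up, P_down, valve) {
  pmax(0, (P_up - P_down) / valve$R_open)
}

#' Time derivative of an inertial flow
#'
#' `dQ/dt = (P_up - P_down - R*Q)/L` for segments carrying blood inertance.
#'
#' @param Q current flow (ml/s).
#' @param P_up,P_down boundary pressures (mmHg).
#' @param R series resistance (mmHg s/ml).
#' @param L inertance (mmHg s^2/ml).
#' @return Flow derivative (ml/s^2).
#' @export
inertial_flow_derivative <- function(Q, P_up, P_down, R, L) {
  stopifnot(L > 0)
  (P_up - P_down - R * Q) / L
}

#' Full model state derivative
#'
#' Evaluates the complete right-hand side: activations at the cardiac
#' phase, septal solve, chamber/compartment pressures, all flows, and the
#' neural limb dynamics.  Pure function of `(t, state)` given the
#' parameters.
#'
#' @param state named state vector as produced by [initial_state()].
#' @param params an `hcrs_params` object.
#' @param t absolute time (s), used only for the pleural waveform.
#' @param phase time since beat onset (s).
#' @param period current beat period (s).
#' @param pleural "fixed" or "sinusoid".
#' @param clamp neural clamping: "none", "con", "hr", or "all".
#' @param V_SPT_init starting value for the septal solve (ml).
#' @return List with `deriv` (named state derivative) and `aux` (named
#'   pressures, flows, activations).
#' @export
model_derivatives <- function(state, params, t = 0, phase = 0,
                              period = 60 / 55.2,
                              pleural = c("fixed", "sinusoid"),
                              clamp = "none", V_SPT_init = 0) {
  pleural <- match.arg(pleural)
  out <- cpp_rhs(.flatten_params(params, clamp), unname(state), phase,
                 period, t, ifelse(pleural == "fixed", 0L, 1L), V_SPT_init)
  names(out$deriv) <- .state_names
  names(out$aux) <- .aux_names
  out
}

.state_names <- c("V_LV", "V_RV", "V_LA", "V_RA",
                  "V_AOp", "V_AOd", "V_SA", "V_SAd", "V_SC", "V_SVL",
                  "V_SV", "V_VC", "V_PAp", "V_PAd", "V_PA", "V_PC", "V_PV",
                  "Q_AOp", "Q_AOd", "Q_PAd",
                  "msap_f", "F_HRv", "F_HRs", "F_con", "F_vaso")

.aux_names <- c("P_LV", "P_RV", "P_LA", "P_RA", "P_PERI", "P_SPT", "V_SPT",
                "P_AOp", "P_AOd", "P_SA", "P_SAd", "P_SC", "P_SVL", "P_SV",
                "P_VC", "P_PAp", "P_PAd", "P_PA", "P_PC", "P_PV", "P_PL",
                "Q_M", "Q_AO", "Q_TC", "Q_PAV", "Q_RA", "Q_LA", "Q_COR",
                "Q_CRB", "Q_SA", "Q_SC", "Q_SVL", "Q_SV", "Q_VC", "Q_PAr",
                "Q_PC", "Q_PV", "Q_PS",
                "e_LVF", "e_RVF", "e_SPT", "e_A", "alpha", "F_b",
                "spt_iters", "HR_target", "phase", "period")
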