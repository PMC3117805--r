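# Model parameters: printed constants, scenario perturbations, validation,
# and YAML (de)serialization.

# Gaussian coefficients of the ventricular/septal activation function.
# Columns are the seven terms; the IR variant alters A6, A7 and B7 only.
.gauss_control <- list(
  A = c(0.282, 0.075, 0.384, 0.205, 0.37, 0.516, 0.15),
  B = c(0.043, 0.030, 0.050, 0.040, 0.08, 0.060, 0.04),
  C = c(0.110, 0.165, 0.220, 0.300, 0.35, 0.395, 0.405)
)
.gauss_ir <- list(A6 = 0.37, A7 = 0.249, B7 = 0.35)

# Steady-state baroreflex operating points used to identify the affine
# neural maps (mean systemic arterial pressure, discharge frequencies and
# heart rate in the control and three diastolic-dysfunction states).
.baro_points <- data.frame(
  MSAP  = c(96.6, 91.5, 89.0, 84.9),
  F_b   = c(0.41, 0.39, 0.38, 0.36),
  F_HRv = c(0.54, 0.51, 0.50, 0.47),
  F_HRs = c(0.28, 0.33, 0.35, 0.39),
  F_con = c(0.40, 0.45, 0.49, 0.53),
  F_vaso = c(0.54, 0.62, 0.64, 0.70),
  HR    = c(55.2, 60.2, 63.8, 68.2)
)

.vasc_names <- c("AOp", "AOd", "SA", "SAd", "SC", "SVL", "SV", "VC",
                 "PAp", "PAd", "PA", "PC", "PV")

#' Identify the affine baroreflex maps from the printed operating points
#'
#' Fits, by ordinary least squares over the four steady-state operating
#' points, (i) the baroreceptor discharge map F_b(MSAP), (ii) the four
#' efferent limb maps F_x(F_b), and (iii) the linear chronotropic map
#' HR(F_HRs, F_HRv).
#'
#' @return A list with elements `ab`, `bb` (baroreceptor slope/intercept),
#'   `slopes`, `intercepts` (named per limb), and `h0`, `hs`, `hv`
#'   (chronotropic coefficients).
#' @export
fit_neural_maps <- function() {
  pts <- .baro_points
  fb <- stats::lsfit(pts$MSAP, pts$F_b)
  limbs <- c("F_HRv", "F_HRs", "F_con", "F_vaso")
  sl <- ic <- numeric(4)
  names(sl) <- names(ic) <- limbs
  for (i in seq_along(limbs)) {
    f <- stats::lsfit(pts$F_b, pts[[limbs[i]]])
    ic[i] <- f$coefficients[1]
    sl[i] <- f$coefficients[2]
  }
  h <- stats::lsfit(cbind(pts$F_HRs, pts$F_HRv), pts$HR)
  list(ab = unname(fb$coefficients[2]), bb = unname(fb$coefficients[1]),
       slopes = sl, intercepts = ic,
       h0 = unname(h$coefficients[1]), hs = unname(h$coefficients[2]),
       hv = unname(h$coefficients[3]))
}

#' Default (control) model parameters
#'
#' Returns the full control parameter set: end-systolic elastances and
#' passive stiffness of the five contractile walls, the seven-term Gaussian
#' activation functions (normalized to unit peak), the pericardial law, all
#' vascular resistances/compliances/inertances, valve resistances,
#' coronary/cerebral shunts, and the baroreflex maps identified from the
#' steady-state operating points.
#'
#' Unstressed volumes are not part of the printed tables; they are chosen so
#' that the control steady state carries the documented pulmonary blood
#' distribution (about 201 ml in the pulmonary arterial bed, 95 ml in the
#' capillaries and 227 ml in the veins) at a total blood volume of 5000 ml.
#'
#' @return An object of class `hcrs_params`.
#' @examples
#' p <- default_parameters()
#' p$valves["mitral", "R_open"]      # 0.007 mmHg s/ml
#' p$walls$LVF$E_ES                  # 3.5 mmHg/ml
#' @export
default_parameters <- function() {
  g <- .gauss_control
  vent_act <- function(wall_id) {
    normalize_activation(activation_spec(g$A, g$B, g$C, wall_id = wall_id))
  }
  nm <- fit_neural_maps()
  p <- list(
    walls = list(
      LVF = list(E_ES = 3.5, V_d = 1, P_0 = 2, lambda = 0.025, V_0 = 1),
      RVF = list(E_ES = 0.34, V_d = 3, P_0 = 1, lambda = 0.01, V_0 = 3),
      SPT = list(E_ES = 40, V_d = 0, P_0 = 1.11, lambda = 0.05, V_0 = 0),
      LA  = list(E_ES = 2.5, V_d = 7, P_0 = 2, lambda = 0.1, V_0 = 40),
      RA  = list(E_ES = 0.34, V_d = 3, P_0 = 1, lambda = 0.1, V_0 = 30)
    ),
    activations = list(LVF = vent_act("LVF"), RVF = vent_act("RVF"),
                       SPT = vent_act("SPT")),
    # one Gaussian pulse per atrium, peaking `offset` s before cycle end;
    # per-atrium gains scale the normalized pulse inside the chamber laws
    atrial = list(B = 0.06, offset = 0.04,
                  amplitude_LA = 0.55, amplitude_RA = 0.7),
    # slack volume calibrated so the control end-diastolic pericardial
    # pressure sits at about -2.5 mmHg, the operating point implied by the
    # chamber volume/pressure tables
    pericardium = list(P_0 = 0.5, lambda = 0.005, V_0 = 30, V_fluid = 6),
    compartments = data.frame(
      name = .vasc_names,
      C = c(2.4, 0.43, 0.092, 0.069, 0.8, 0.6, 37.5, 4.0,
            0.69, 0.64, 6.0, 2.1, 7.3),
      V_un = c(51, 60, 50, 80, 200, 150, 2900, 120,
               7.8, 9.6, 97.9, 66.5, 132.7),
      R_out = c(0.015, 0.015, 0.35, 0.4, 0.2, 0.2, 0.026, 0.01,
                0.002, 0.01, 0.08, 0.008, 0.01),
      L_out = c(0.0055, 0.0031, NA, NA, NA, NA, NA, NA,
                0.00008, NA, NA, NA, NA),
      external = c("pleural", "body", "body", "body", "body", "body",
                   "body", "pleural", "pleural", "pleural", "pleural",
                   "pleural", "pleural"),
      stringsAsFactors = FALSE
    ),
    valves = data.frame(
      name = c("mitral", "tricuspid", "aortic", "pulmonic"),
      R_open = c(0.007, 0.0028, 0.005, 0.002),
      row.names = c("mitral", "tricuspid", "aortic", "pulmonic"),
      stringsAsFactors = FALSE
    ),
    shunts = list(R_COR = 35, R_CRB = 16, R_PS = 4.0),
    neural = c(nm, list(
      tau_symp = 2, tau_vagal = 0.5, tau_msap = 2,
      k_alpha = 3.6, F_con_ref = 0.40, F_vaso_ref = 0.54,
      k_R = 12, k_V = 0,
      hr_min = 30, hr_max = 180,
      hr_ref_v = 0.54, hr_ref_s = 0.28,
      K_f = 1.2
    )),
    total_blood_volume = 5000,
    pleural_mode = "fixed"
  )
  class(p) <- "hcrs_params"
  p
}

#' Scenario configuration
#'
#' @param dd_type one of "control", "IR" (impaired relaxation),
#'   "R" (restrictive), "PN" (pseudo-normal = IR + R), "R_NSPT"
#'   (restrictive with normal septal stiffness).
#' @param contractility "normal" or "increased" (LV and septal end-systolic
#'   elastance scaled by 1.6).
#' @param pleural "fixed" (-5 mmHg) or "sinusoid" (-2 to -6 mmHg, 7 s period).
#' @param duration simulation length in seconds (default depends on pleural
#'   mode).
#' @param steady_state_tol maximal relative per-beat change in stroke volume
#'   and arterial pressure considered converged.
#' @export
scenario_config <- function(dd_type = c("control", "IR", "R", "PN", "R_NSPT"),
                            contractility = c("normal", "increased"),
                            pleural = c("fixed", "sinusoid"),
                            duration = NULL,
                            steady_state_tol = 0.005) {
  dd_type <- match.arg(dd_type)
  contractility <- match.arg(contractility)
  pleural <- match.arg(pleural)
  if (is.null(duration)) duration <- if (pleural == "fixed") 90 else 91
  stopifnot(duration > 0, steady_state_tol > 0)
  structure(list(dd_type = dd_type, contractility = contractility,
                 pleural = pleural, duration = duration,
                 steady_state_tol = steady_state_tol),
            class = "scenario_config")
}

#' Apply a diastolic-dysfunction scenario to a parameter set
#'
#' Returns a modified copy; the input is untouched.  The impaired-relaxation
#' (IR) pattern alters the last two Gaussian terms of the LV free-wall and
#' septal activation functions (A6 = 0.37, A7 = 0.249, B7 = 0.35 s) and
#' renormalizes them to unit peak.  The restrictive (R) pattern doubles the
#' passive diastolic stiffness of the LV free wall (0.025 to 0.05/ml) and
#' septum (0.05 to 0.1/ml).  Pseudo-normalization (PN) applies both; R_NSPT
#' stiffens the LV free wall only.  Increased contractility scales the LV
#' and septal end-systolic elastances by 1.6 (3.5 to 5.6 and 40 to 64
#' mmHg/ml).
#'
#' @param params an `hcrs_params` object (control values).
#' @param scenario a `scenario_config`.
#' @return A new `hcrs_params` object.
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "hcrs_params"),
            inherits(scenario, "scenario_config"))
  p <- params
  dd <- scenario$dd_type
  if (!dd %in% c("control", "IR", "R", "PN", "R_NSPT"))
    stop("unknown scenario tag: ", dd)
  ir <- dd %in% c("IR", "PN")
  restr <- dd %in% c("R", "PN", "R_NSPT")
  if (ir) {
    for (w in c("LVF", "SPT")) {
      spec <- p$activations[[w]]
      spec$A[6] <- .gauss_ir$A6
      spec$A[7] <- .gauss_ir$A7
      spec$B[7] <- .gauss_ir$B7
      p$activations[[w]] <- normalize_activation(spec)
    }
  }
  if (restr) {
    p$walls$LVF$lambda <- 0.05
    if (dd != "R_NSPT") p$walls$SPT$lambda <- 0.1
  }
  if (scenario$contractility == "increased") {
    p$walls$LVF$E_ES <- 1.6 * 3.5
    p$walls$SPT$E_ES <- 1.6 * 40
  }
  p$pleural_mode <- scenario$pleural
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of every component (positive elastances,
#' stiffness, compliances and resistances; activation weights normalized to
#' unit peak) and reports violations without raising.
#'
#' @param params an `hcrs_params` object.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  for (w in names(params$walls)) {
    wall <- params$walls[[w]]
    if (!(wall$E_ES > 0)) v <- c(v, sprintf("wall %s: E_ES must be > 0", w))
    if (!(wall$lambda > 0)) v <- c(v, sprintf("wall %s: lambda must be > 0", w))
    if (!(wall$P_0 > 0)) v <- c(v, sprintf("wall %s: P_0 must be > 0", w))
  }
  for (w in names(params$activations)) {
    spec <- params$activations[[w]]
    if (any(spec$B <= 0)) v <- c(v, sprintf("activation %s: B must be > 0", w))
    if (any(spec$A < 0)) v <- c(v, sprintf("activation %s: A must be >= 0", w))
    if (any(spec$C < 0)) v <- c(v, sprintf("activation %s: C must be >= 0", w))
    pk <- activation_peak(spec)
    if (abs(pk - 1) > 1e-3)
      v <- c(v, sprintf("activation %s: normalized peak %.4f outside [0.999, 1.001]",
                        w, pk))
  }
  peri <- params$pericardium
  if (any(unlist(peri) <= 0)) v <- c(v, "pericardium: all parameters must be > 0")
  comp <- params$compartments
  bad <- comp$C <= 0
  if (any(bad)) v <- c(v, sprintf("compartment %s: compliance must be > 0",
                                  comp$name[bad]))
  bad <- comp$R_out <= 0
  if (any(bad)) v <- c(v, sprintf("compartment %s: outflow resistance must be > 0",
                                  comp$name[bad]))
  bad <- comp$V_un < 0
  if (any(bad)) v <- c(v, sprintf("compartment %s: unstressed volume must be >= 0",
                                  comp$name[bad]))
  if (any(params$valves$R_open <= 0))
    v <- c(v, "valves: R_open must be > 0")
  if (!(params$total_blood_volume > 0))
    v <- c(v, "total_blood_volume must be > 0")
  v
}

# flatten to the representation the C++ engine reads
.flatten_params <- function(params, clamp = "none") {
  comp <- params$compartments
  act_flat <- function(a) list(A = a$A, B = a$B, C = a$C, scale = a$scale)
  resist <- c(
    R_M = params$valves["mitral", "R_open"],
    R_TC = params$valves["tricuspid", "R_open"],
    R_AOp = params$valves["aortic", "R_open"],
    R_PAp = params$valves["pulmonic", "R_open"],
    R_AOd = comp$R_out[comp$name == "AOp"],
    R_SA = comp$R_out[comp$name == "AOd"],
    R_SAd = comp$R_out[comp$name == "SA"],
    R_SC = comp$R_out[comp$name == "SAd"],
    R_SVL = comp$R_out[comp$name == "SC"],
    R_SV = comp$R_out[comp$name == "SVL"],
    R_VC = comp$R_out[comp$name == "SV"],
    R_RA = comp$R_out[comp$name == "VC"],
    R_PAd = comp$R_out[comp$name == "PAp"],
    R_PA = comp$R_out[comp$name == "PAd"],
    R_PC = comp$R_out[comp$name == "PA"],
    R_PV = comp$R_out[comp$name == "PC"],
    R_LA = comp$R_out[comp$name == "PV"],
    R_PS = params$shunts$R_PS,
    R_COR = params$shunts$R_COR,
    R_CRB = params$shunts$R_CRB
  )
  list(
    walls = params$walls,
    activations = lapply(params$activations, act_flat),
    atrial = params$atrial,
    pericardium = params$pericardium,
    resist = resist,
    compl = comp$C,
    vun = comp$V_un,
    inert = c(L_AOp = comp$L_out[comp$name == "AOp"],
              L_AOd = comp$L_out[comp$name == "AOd"],
              L_PA = comp$L_out[comp$name == "PAp"]),
    neural = params$neural,
    clamp_con = as.integer(clamp %in% c("con", "all")),
    clamp_hr = as.integer(clamp %in% c("hr", "all"))
  )
}

#' Default initial state for a simulation
#'
#' Chamber and compartment volumes are distributed near the control
#' operating point; the systemic venous reservoir absorbs the residual so
#' the state carries exactly the configured total blood volume.  Neural
#' limbs start at their control steady values.
#'
#' @param params an `hcrs_params` object.
#' @return Named numeric state vector.
#' @export
initial_state <- function(params) {
  comp <- params$compartments
  v <- c(V_LV = 120, V_RV = 140, V_LA = 60, V_RA = 50,
         V_AOp = 295, V_AOd = 101, V_SA = 58.7, V_SAd = 84.6,
         V_SC = 228.8, V_SVL = 162, V_SV = 0, V_VC = 149.6,
         V_PAp = 20.4, V_PAd = 21.1, V_PA = 201.1, V_PC = 94.9,
         V_PV = 226.9)
  v["V_SV"] <- params$total_blood_volume - sum(v)
  if (v["V_SV"] < 0) stop("total blood volume too small for default state")
  c(v, Q_AOp = 0, Q_AOd = 0, Q_PAd = 0,
    msap_f = 96.6, F_HRv = 0.54, F_HRs = 0.28, F_con = 0.40, F_vaso = 0.54)
}

#' Write parameters to a YAML configuration file
#' @param params an `hcrs_params` object.
#' @param path output file.
#' @export
write_parameters <- function(params, path) {
  ser <- unclass(params)
  ser$compartments <- as.list(ser$compartments)
  ser$valves <- as.list(ser$valves[c("name", "R_open")])
  ser$activations <- lapply(ser$activations, unclass)
  yaml::write_yaml(ser, path, precision = 22)
  invisible(path)
}

#' Read parameters from a YAML configuration file
#' @param path file written by [write_parameters()].
#' @return An `hcrs_params` object.
#' @export
read_parameters <- function(path) {
  ser <- yaml::read_yaml(path)
  ser$compartments <- as.data.frame(ser$compartments,
                                    stringsAsFactors = FALSE)
  ser$compartments$L_out <- as.numeric(ser$compartments$L_out)
  ser$valves <- data.frame(ser$valves, row.names = ser$valves$name,
                           stringsAsFactors = FALSE)
  ser$activations <- lapply(ser$activations, function(a) {
    a$A <- as.numeric(a$A); a$B <- as.numeric(a$B); a$C <- as.numeric(a$C)
    structure(a, class = "activation_spec")
  })
  # the YAML writer drops vector names under explicit precision; the limb
  # order is fixed
  limbs <- c("F_HRv", "F_HRs", "F_con", "F_vaso")
  ser$neural$slopes <- stats::setNames(unlist(ser$neural$slopes), limbs)
  ser$neural$intercepts <- stats::setNames(unlist(ser$neural$intercepts),
                                           limbs)
  structure(ser, class = "hcrs_params")
}
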