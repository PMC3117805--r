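# Gaussian-sum activation functions e_x(t) driving time-varying wall
# mechanics.  The kernel is the standard Gaussian g(u) = exp(-u^2/2)
# (width B is one standard deviation); the alternative 1/e-half-width
# convention exp(-u^2) would be a one-line change here.

#' Construct an activation specification
#'
#' @param A,B,C amplitudes (dimensionless), widths (s) and center offsets (s)
#'   of the Gaussian terms.
#' @param scale normalization scale applied to the sum.
#' @param wall_id which wall this function drives ("LVF", "RVF", "SPT",
#'   "LA", "RA").
#' @return An `activation_spec` object.
#' @export
activation_spec <- function(A, B, C, scale = 1,
                            wall_id = c("LVF", "RVF", "SPT", "LA", "RA")) {
  wall_id <- match.arg(wall_id)
  stopifnot(length(A) == length(B), length(B) == length(C),
            all(B > 0), all(A >= 0), all(C >= 0))
  structure(list(A = A, B = B, C = C, scale = scale, wall_id = wall_id),
            class = "activation_spec")
}

#' Evaluate an activation function
#'
#' Computes `scale * sum_i A_i exp(-((t - C_i)/B_i)^2)`, clipped to `[0, 1]`.
#'
#' @param t_cycle time since beat onset (s); may be a vector.
#' @param spec an `activation_spec`.
#' @return Activation weight(s) in `[0, 1]`.
#' @export
activation_value <- function(t_cycle, spec) {
  if (any(t_cycle < 0)) stop("t_cycle must be non-negative")
  v <- vapply(t_cycle, function(t) {
    sum(spec$A * exp(-0.5 * ((t - spec$C) / spec$B)^2))
  }, numeric(1))
  pmin(1, pmax(0, spec$scale * v))
}

# unclipped peak of the scaled sum over one cycle (dense grid + local refine)
activation_peak <- function(spec, t_max = 1.5) {
  tg <- seq(0, t_max, by = 1e-4)
  raw <- vapply(tg, function(t)
    sum(spec$A * exp(-0.5 * ((t - spec$C) / spec$B)^2)), numeric(1))
  i <- which.max(raw)
  lo <- max(0, tg[i] - 2e-4); hi <- min(t_max, tg[i] + 2e-4)
  opt <- stats::optimize(function(t) {
    sum(spec$A * exp(-0.5 * ((t - spec$C) / spec$B)^2))
  }, c(lo, hi), maximum = TRUE)
  spec$scale * max(raw[i], opt$objective)
}

#' Normalize an activation function to unit peak
#'
#' Sets the normalization scale so the maximum over one cycle equals 1.
#' Idempotent; linear in the amplitudes.
#'
#' @param spec an `activation_spec`.
#' @return The spec with updated `scale`.
#' @export
normalize_activation <- function(spec) {
  if (all(spec$A == 0)) stop("cannot normalize an all-zero activation")
  raw_peak <- activation_peak(activation_spec(spec$A, spec$B, spec$C,
                                              scale = 1,
                                              wall_id = spec$wall_id))
  spec$scale <- 1 / raw_peak
  spec
}

#' Atrial activation pulse
#'
#' A single normalized Gaussian placed late in the cycle (peak `offset`
#' seconds before the end of the beat) modelling atrial systole.
#'
#' @param t_cycle time since beat onset (s).
#' @param period current beat period (s).
#' @param atrial_spec list with elements `B` (width, s) and `offset`
#'   (s before cycle end).
#' @return Activation weight(s) in `[0, 1]`.
#' @export
atrial_activation <- function(t_cycle, period,
                              atrial_spec = list(B = 0.05, offset = 0.04)) {
  if (any(t_cycle < 0)) stop("t_cycle must be non-negative")
  center <- period - atrial_spec$offset
  # wrap term: relaxation of the previous cycle's pulse continues past the
  # beat boundary
  exp(-((t_cycle - center) / atrial_spec$B)^2) +
    exp(-((t_cycle + atrial_spec$offset) / atrial_spec$B)^2)
}
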