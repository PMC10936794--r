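#' Breath-cycle timing
#'
#' @param t_insp Inspiratory duration, s (> 0).
#' @param t_exp Expiratory duration, s (> 0).
#' @return An object of class \code{breath_timing} with fields \code{t_insp},
#'   \code{t_exp}, \code{T_resp = t_insp + t_exp} and the I:E ratio.
#' @export
#' @examples
#' breath_timing(t_insp = 1.6, t_exp = 2.4) # I:E = 1:1.5, T_resp = 4 s
breath_timing <- function(t_insp = 1.6, t_exp = 2.4) {
  if (t_insp <= 0) stop("'t_insp' must be > 0", call. = FALSE)
  if (t_exp <= 0) stop("'t_exp' must be > 0", call. = FALSE)
  structure(list(t_insp = t_insp, t_exp = t_exp, T_resp = t_insp + t_exp,
                 ie_ratio = t_insp / t_exp),
            class = "breath_timing")
}

#' Volume-controlled reference parameters
#'
#' @param gamma Inspiratory flow, ml/s (> 0).
#' @param VT Tidal volume, ml (> 0).
#' @return An object of class \code{volume_reference}.
#' @export
volume_reference <- function(gamma, VT) {
  if (gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  if (VT <= 0) stop("'VT' must be > 0", call. = FALSE)
  structure(list(gamma = gamma, VT = VT), class = "volume_reference")
}

#' Pressure-mode reference parameters (CPAP or PAV)
#'
#' CPAP holds a constant set pressure; PAV delivers PEEP plus a gain-scaled
#' surrogate of the patient's inspiratory effort (a half-sine over the
#' inspiratory window). The surrogate is a package convention whose role is
#' to produce distinguishable mode signatures, not clinical fidelity.
#'
#' @param mode "CPAP" or "PAV".
#' @param target Set pressure, cm H2O; must exceed PEEP. The shipped study
#'   levels are 20 and 40.
#' @param PEEP Positive end-expiratory pressure, cm H2O (>= 0).
#' @param pav_gain Dimensionless assist gain in [0, 1); PAV only.
#' @param effort_amplitude Peak simulated patient effort, cm H2O; PAV only.
#' @return An object of class \code{pressure_reference}.
#' @export
#' @examples
#' pressure_reference("CPAP", target = 20)
#' pressure_reference("PAV", target = 20, pav_gain = 0.6, effort_amplitude = 10)
pressure_reference <- function(mode = c("CPAP", "PAV"), target = 20, PEEP = 5,
                               pav_gain = NULL, effort_amplitude = NULL) {
  mode <- match.arg(mode)
  if (PEEP < 0) stop("'PEEP' must be >= 0", call. = FALSE)
  if (target <= PEEP) stop("'target' must exceed PEEP", call. = FALSE)
  if (mode == "PAV") {
    if (is.null(pav_gain) || is.null(effort_amplitude)) {
      stop("PAV requires 'pav_gain' and 'effort_amplitude'", call. = FALSE)
    }
    if (pav_gain < 0 || pav_gain >= 1) {
      stop("'pav_gain' must lie in [0, 1)", call. = FALSE)
    }
    if (effort_amplitude < 0) {
      stop("'effort_amplitude' must be >= 0", call. = FALSE)
    }
  }
  structure(list(mode = mode, target = target, PEEP = PEEP,
                 pav_gain = pav_gain, effort_amplitude = effort_amplitude),
            class = "pressure_reference")
}

# Within-cycle time, convention t_cycle in [0, T_resp): the cycle boundary
# belongs to the next cycle.
cycle_time <- function(t, timing) t %% timing$T_resp

#' Volume-controlled flow reference
#'
#' The inspiratory flow set-point: \code{gamma} while both
#' \code{gamma * t_cycle < VT} and \code{0 < t_cycle < t_insp} hold (strict
#' inequalities), 0 otherwise, with \code{t_cycle} the within-cycle time
#' \code{t mod T_resp}.
#'
#' @param t Time, s (vectorized; taken modulo the cycle period).
#' @param ref A \code{\link{volume_reference}}.
#' @param timing A \code{\link{breath_timing}}.
#' @return Flow in ml/s, same length as \code{t}.
#' @export
#' @examples
#' tm <- breath_timing(2, 2)
#' flow_reference(1, volume_reference(gamma = 5, VT = 500), tm)   # 5
#' flow_reference(2, volume_reference(gamma = 5, VT = 500), tm)   # 0 (t = t_insp)
flow_reference <- function(t, ref, timing) {
  stopifnot(inherits(ref, "volume_reference"), inherits(timing, "breath_timing"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  tc <- cycle_time(t, timing)
  on <- (ref$gamma * tc < ref$VT) & (tc > 0) & (tc < timing$t_insp)
  ifelse(on, ref$gamma, 0)
}

#' Pressure reference waveform (CPAP or PAV)
#'
#' CPAP: the constant set pressure at every t. PAV:
#' \code{PEEP + pav_gain * effort_amplitude * sin(pi * t_cycle / t_insp)}
#' during inspiration and PEEP during expiration; never below PEEP.
#'
#' @param t Time, s (vectorized).
#' @param ref A \code{\link{pressure_reference}}.
#' @param timing A \code{\link{breath_timing}}.
#' @return Pressure in cm H2O, same length as \code{t}.
#' @export
pressure_waveform <- function(t, ref, timing) {
  stopifnot(inherits(ref, "pressure_reference"),
            inherits(timing, "breath_timing"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  if (ref$mode == "CPAP") return(rep(ref$target, length(t)))
  tc <- cycle_time(t, timing)
  effort <- ifelse(tc < timing$t_insp,
                   sin(pi * tc / timing$t_insp), 0)
  pmax(ref$PEEP + ref$pav_gain * ref$effort_amplitude * effort, ref$PEEP)
}

#' Evaluate any reference at given times
#'
#' Dispatch helper: volume references produce flow (ml/s), pressure
#' references produce pressure (cm H2O).
#'
#' @param t Time, s.
#' @param ref A \code{volume_reference} or \code{pressure_reference}.
#' @param timing A \code{\link{breath_timing}}.
#' @return Numeric reference series.
#' @export
reference_at <- function(t, ref, timing) {
  if (inherits(ref, "volume_reference")) {
    flow_reference(t, ref, timing)
  } else if (inherits(ref, "pressure_reference")) {
    pressure_waveform(t, ref, timing)
  } else {
    stop("unknown reference type", call. = FALSE)
  }
}
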