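#' Ventilator-patient model parameters
#'
#' Physical parameters of the lumped single-compartment ventilator-patient
#' circuit. Units are fixed package-wide: pressure in cm H2O, volume in ml,
#' flow in ml/s, time in s.
#'
#' @param Cc Pulmonary compliance, ml/cm H2O. Must be > 0.
#' @param C2 Load-reservoir compliance, ml/cm H2O. Must be >= 0.
#' @param R2c Load-branch resistance, cm H2O/(ml/s). Must be > 0.
#' @param Rc Patient airway resistance, cm H2O/(ml/s). Must be > 0.
#' @param Rv2min Minimum valve resistance, cm H2O/(ml/s).
#' @param T_resp Breathing-cycle period, s. Must be > 0.
#' @param PEEP Positive end-expiratory pressure, cm H2O. Must be >= 0.
#' @param circuit_info Optional free-form list describing the remaining
#'   pneumatic circuit elements (valves, sources, auxiliary resistances).
#'   Carried for documentation only; never used in simulation.
#'
#' @return An object of class \code{plant_params}.
#' @export
#' @examples
#' plant_params() # reference values for an adult patient circuit
plant_params <- function(Cc = 0.075, C2 = 0.465, R2c = 0.377, Rc = 0.377,
                         Rv2min = 1.062e-4, T_resp = 4, PEEP = 5,
                         circuit_info = NULL) {
  for (nm in c("Cc", "R2c", "Rc", "T_resp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("plant parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (C2 < 0) stop("plant parameter 'C2' must be >= 0", call. = FALSE)
  if (PEEP < 0) stop("plant parameter 'PEEP' must be >= 0", call. = FALSE)
  structure(list(Cc = Cc, C2 = C2, R2c = R2c, Rc = Rc, Rv2min = Rv2min,
                 T_resp = T_resp, PEEP = PEEP, circuit_info = circuit_info),
            class = "plant_params")
}

#' Assemble the first-order-plus-dead-time ventilator transfer function
#'
#' Builds the lumped plant G(s) = b0 / (a1 s + a0) * exp(-delay * s) relating
#' delivered volume rate to output air flow. Two assemblies are available:
#'
#' \describe{
#'   \item{symbolic}{from the physical parameters:
#'     \code{b0 = Cc}, \code{a1 = Cc * C2 * R2c}, \code{a0 = Cc + C2}.}
#'   \item{canonical (default)}{the fixed reference plant
#'     \code{b0 = 0.07425}, \code{a1 = 0.022}, \code{a0 = 0.54}, the
#'     calibrated coefficient set used for all shipped scenarios.}
#' }
#'
#' The two assemblies agree on the denominator constant \code{a0} at the
#' reference parameter values but not on \code{b0} or \code{a1}; when the
#' canonical plant is requested a warning records the mismatch rather than
#' silently reconciling it.
#'
#' @param params A \code{\link{plant_params}} object.
#' @param use_canonical Logical; if \code{TRUE} (default) return the canonical
#'   coefficient set, otherwise assemble symbolically from \code{params}.
#' @param delay Transport delay, s. Defaults to \code{0.45 * T_resp}. May be
#'   set to 0 for delay-free studies.
#'
#' @return An object of class \code{fod_plant} with fields \code{b0},
#'   \code{a1}, \code{a0}, \code{delay}, \code{dc_gain} and \code{tau}
#'   (lag time constant \code{a1/a0}).
#' @export
#' @examples
#' assemble_transfer_function(plant_params(), use_canonical = FALSE)$a0 # 0.54
#' canonical_plant(delay = 0)$dc_gain                                  # 0.1375
assemble_transfer_function <- function(params = plant_params(),
                                       use_canonical = TRUE,
                                       delay = 0.45 * params$T_resp) {
  stopifnot(inherits(params, "plant_params"))
  if (delay < 0) stop("'delay' must be >= 0", call. = FALSE)
  if (use_canonical) {
    b0 <- 0.07425; a1 <- 0.022; a0 <- 0.54
    sym_b0 <- params$Cc
    sym_a1 <- params$Cc * params$C2 * params$R2c
    if (abs(sym_b0 - b0) > 1e-12 || abs(sym_a1 - a1) > 1e-12) {
      warning(sprintf(paste0(
        "canonical plant coefficients (b0 = %.5f, a1 = %.3f) are not ",
        "reproduced by symbolic assembly from the physical parameters ",
        "(Cc = %.5f, Cc*C2*R2c = %.5f); using the canonical set verbatim"),
        b0, a1, sym_b0, sym_a1), call. = FALSE)
    }
  } else {
    b0 <- params$Cc
    a1 <- params$Cc * params$C2 * params$R2c
    a0 <- params$Cc + params$C2
  }
  new_fod_plant(b0 = b0, a1 = a1, a0 = a0, delay = delay)
}

#' Construct a first-order-plus-dead-time plant from raw coefficients
#'
#' @param b0 Numerator constant (> 0).
#' @param a1 Lag coefficient, s-units (> 0).
#' @param a0 Denominator constant (> 0).
#' @param delay Transport delay, s (>= 0).
#' @return An object of class \code{fod_plant}.
#' @export
new_fod_plant <- function(b0, a1, a0, delay = 0) {
  stopifnot(is.numeric(b0), is.numeric(a1), is.numeric(a0), is.numeric(delay))
  if (b0 <= 0) stop("'b0' must be > 0", call. = FALSE)
  if (a1 <= 0) stop("'a1' must be > 0", call. = FALSE)
  if (a0 <= 0) stop("'a0' must be > 0", call. = FALSE)
  if (delay < 0) stop("'delay' must be >= 0", call. = FALSE)
  dc <- b0 / a0
  if (!is.finite(dc) || dc <= 0) stop("dc gain must be finite and positive",
                                      call. = FALSE)
  structure(list(b0 = b0, a1 = a1, a0 = a0, delay = delay,
                 dc_gain = dc, tau = a1 / a0),
            class = "fod_plant")
}

#' The canonical reference plant
#'
#' Convenience wrapper returning the fixed coefficient set
#' b0 = 0.07425, a1 = 0.022, a0 = 0.54 without the symbolic-mismatch warning.
#'
#' @param T_resp Breathing-cycle period used to default the delay, s.
#' @param delay Transport delay, s; default \code{0.45 * T_resp}.
#' @return An object of class \code{fod_plant}.
#' @export
canonical_plant <- function(T_resp = 4, delay = 0.45 * T_resp) {
  new_fod_plant(b0 = 0.07425, a1 = 0.022, a0 = 0.54, delay = delay)
}

#' @export
print.fod_plant <- function(x, ...) {
  cat(sprintf("First-order-plus-dead-time plant: %.5g / (%.5g s + %.5g)",
              x$b0, x$a1, x$a0))
  if (x$delay > 0) cat(sprintf(" * exp(-%.3g s)", x$delay))
  cat(sprintf("\n  dc gain %.5g, lag time constant %.5g s\n",
              x$dc_gain, x$tau))
  invisible(x)
}

# Stateful one-pole simulator used by step_response() and the closed-loop
# engine. Exact zero-order-hold discretization:
#   y[k+1] = phi * y[k] + (1 - phi) * dc_gain * u[k - d]
# with phi = exp(-a0*dt/a1) and d the delay rounded to whole samples
# (ring buffer, so y is identically y0 for t < delay).
plant_state_new <- function(plant, dt, y0 = 0) {
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (dt >= plant$tau) {
    stop(sprintf(paste0("sample interval dt = %g is not smaller than the ",
                        "plant lag time constant %g s; choose a smaller dt"),
         dt, plant$tau), call. = FALSE)
  }
  d_samp <- as.integer(round(plant$delay / dt))
  if (d_samp > 0 && abs(d_samp * dt - plant$delay) > 1e-12) {
    message(sprintf("transport delay %.6g s rounded to %d samples (%.6g s)",
                    plant$delay, d_samp, d_samp * dt))
  }
  list(phi = exp(-plant$a0 * dt / plant$a1), gain = plant$dc_gain,
       y = y0, buf = rep(0, max(d_samp, 1L)), d = d_samp, ptr = 1L)
}

# Advance one sample with input u; returns updated state. state$y is the
# output at the *new* sample instant.
plant_state_step <- function(state, u) {
  if (state$d > 0L) {
    u_eff <- state$buf[state$ptr]
    state$buf[state$ptr] <- u
    state$ptr <- if (state$ptr == state$d) 1L else state$ptr + 1L
  } else {
    u_eff <- u
  }
  state$y <- state$phi * state$y + (1 - state$phi) * state$gain * u_eff
  state
}

#' Open-loop step response of a plant
#'
#' Simulates the response to a constant input of given amplitude applied from
#' t = 0, using the exact zero-order-hold update and an integer-sample delay
#' buffer. The output is the initial value for all t < delay.
#'
#' @param plant A \code{fod_plant}.
#' @param amplitude Input level (constant for t >= 0).
#' @param dt Sample interval, s; must be smaller than the plant lag
#'   time constant \code{a1/a0}.
#' @param horizon Simulation length, s (>= dt).
#' @return A \code{trajectory} object (see \code{\link{trajectory}}) with the
#'   input recorded in the \code{control} column and the reference column set
#'   to the amplitude.
#' @export
#' @examples
#' tr <- step_response(canonical_plant(delay = 0), amplitude = 1,
#'                     dt = 0.001, horizon = 0.5)
#' tail(tr$output, 1) # ~ dc gain 0.1375
step_response <- function(plant, amplitude = 1, dt = 0.001, horizon = 1) {
  stopifnot(inherits(plant, "fod_plant"))
  if (horizon < dt) stop("'horizon' must be >= dt", call. = FALSE)
  n <- as.integer(floor(horizon / dt + 1e-9)) + 1L
  st <- plant_state_new(plant, dt)
  y <- numeric(n)
  for (k in 2:n) {
    st <- plant_state_step(st, amplitude)
    y[k] <- st$y
  }
  trajectory(dt = dt, reference = rep(amplitude, n), output = y,
             control = rep(amplitude, n))
}

#' Uniformly sampled closed- or open-loop trajectory
#'
#' Carrier for per-breath (time, reference, output, control) series.
#'
#' @param dt Sample interval, s (> 0).
#' @param reference,output,control Numeric series of one common length.
#' @param t Optional time stamps; defaults to \code{(0:(n-1)) * dt}.
#' @return An object of class \code{trajectory} (also a data.frame with
#'   columns \code{t, reference, output, control}).
#' @export
trajectory <- function(dt, reference, output, control,
                       t = (seq_along(reference) - 1) * dt) {
  n <- length(reference)
  if (length(output) != n || length(control) != n || length(t) != n) {
    stop("trajectory series must share one length", call. = FALSE)
  }
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (n > 1 && any(diff(t) <= 0)) {
    stop("time stamps must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(t = t, reference = reference, output = output,
                    control = control)
  attr(out, "dt") <- dt
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Write a trajectory as CSV
#'
#' Fixed column order \code{t,reference,output,control} with a header row.
#'
#' @param x A \code{trajectory}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  utils::write.csv(as.data.frame(x)[, c("t", "reference", "output", "control")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read plant parameters from a flat key-value config file
#'
#' Keys match the physical symbol names (\code{Cc, C2, R2c, Rc, Rv2min,
#' T_resp, PEEP}); unknown keys are collected into \code{circuit_info}.
#'
#' @param path Path to a YAML (flat key: value) file.
#' @return A \code{plant_params} object.
#' @export
read_plant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("Cc", "C2", "R2c", "Rc", "Rv2min", "T_resp", "PEEP")
  extra <- cfg[setdiff(names(cfg), known)]
  args <- cfg[intersect(names(cfg), known)]
  args$circuit_info <- if (length(extra)) extra else NULL
  do.call(plant_params, args)
}
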