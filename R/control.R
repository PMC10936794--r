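#' PID controller gains and limits
#'
#' Discrete PID with backward-Euler integral and derivative (derivative on
#' error), actuation clamped to \code{[u_min, u_max]} with the integrator
#' frozen while clamped (anti-windup).
#'
#' Defaults come from internal-model tuning of the canonical plant with the
#' closed-loop time constant set equal to the plant lag: for a plant
#' K/(tau s + 1) this gives Kp = 1/K and Ki = Kp/tau, Kd = 0.
#'
#' @param Kp Proportional gain (>= 0).
#' @param Ki Integral gain, 1/s (>= 0).
#' @param Kd Derivative gain, s (>= 0).
#' @param dt Controller sample interval, s (> 0).
#' @param u_min,u_max Actuation clamps, \code{u_min < u_max}.
#' @return An object of class \code{pid_gains}.
#' @export
#' @examples
#' pid_gains() # IMC defaults for the canonical plant
pid_gains <- function(Kp = NULL, Ki = NULL, Kd = 0, dt = 0.002,
                      u_min = -1000, u_max = 1000) {
  if (is.null(Kp) || is.null(Ki)) {
    p <- canonical_plant(delay = 0)
    if (is.null(Kp)) Kp <- 1 / p$dc_gain      # = a0/b0
    if (is.null(Ki)) Ki <- Kp / p$tau         # = Kp * a0/a1
  }
  if (Kp < 0 || Ki < 0 || Kd < 0) {
    stop("PID gains must be >= 0", call. = FALSE)
  }
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (u_min >= u_max) stop("'u_min' must be < u_max", call. = FALSE)
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd, dt = dt,
                 u_min = u_min, u_max = u_max),
            class = "pid_gains")
}

#' Initialize PID controller state
#'
#' @param gains A \code{\link{pid_gains}} object.
#' @return A list with zeroed integrator and previous-error memory.
#' @export
pid_state_new <- function(gains) {
  stopifnot(inherits(gains, "pid_gains"))
  list(integ = 0, e_prev = 0, first = TRUE)
}

#' One PID update
#'
#' u = Kp e + Ki * (accumulated error * dt) + Kd * backward-difference
#' derivative, clamped to the actuation limits. The integrator does not
#' accumulate on samples where the unclamped output exceeds the limits.
#'
#' @param error Current error sample (finite).
#' @param state Controller state from \code{\link{pid_state_new}} or a
#'   previous call.
#' @param gains A \code{\link{pid_gains}} object.
#' @return A list with \code{u} (clamped control value) and \code{state}.
#' @export
#' @examples
#' g <- pid_gains(Kp = 2, Ki = 0, Kd = 0)
#' pid_step(1.5, pid_state_new(g), g)$u # 3
pid_step <- function(error, state, gains) {
  if (!is.finite(error)) stop("non-finite error input", call. = FALSE)
  deriv <- if (state$first) 0 else (error - state$e_prev) / gains$dt
  integ_try <- state$integ + error * gains$dt
  u_raw <- gains$Kp * error + gains$Ki * integ_try + gains$Kd * deriv
  if (u_raw > gains$u_max || u_raw < gains$u_min) {
    # anti-windup: keep the old integrator, recompute, clamp
    u_raw <- gains$Kp * error + gains$Ki * state$integ + gains$Kd * deriv
    u <- min(max(u_raw, gains$u_min), gains$u_max)
  } else {
    state$integ <- integ_try
    u <- u_raw
  }
  state$e_prev <- error
  state$first <- FALSE
  list(u = u, state = state)
}

#' Internal-model (IMC) PID tuning for a first-order-plus-dead-time plant
#'
#' The standard IMC-PI rule: Kp = tau / (K (lambda + theta)), Ki = Kp / tau,
#' Kd = 0, with K the DC gain, tau the lag time constant, theta the
#' transport delay and lambda the desired closed-loop time constant.
#' The default lambda = max(tau, theta) targets the plant lag on delay-free
#' plants (reducing to Kp = 1/K, Ki = Kp/tau) and backs off to the dead
#' time on delay-dominant plants, the usual robustness guideline.
#'
#' @param plant A \code{fod_plant}.
#' @param dt Controller sample interval, s.
#' @param lambda Closed-loop time constant, s (default
#'   \code{max(plant$tau, plant$delay)}).
#' @param u_min,u_max Actuation clamps. The default floor of 0 reflects a
#'   one-way delivery valve: the ventilator cannot draw flow back.
#' @return A \code{\link{pid_gains}} object.
#' @export
#' @examples
#' imc_pid_gains(canonical_plant(delay = 0)) # Kp = 1/0.1375
imc_pid_gains <- function(plant, dt = 0.002,
                          lambda = max(plant$tau, plant$delay),
                          u_min = 0, u_max = 1000) {
  stopifnot(inherits(plant, "fod_plant"))
  Kp <- plant$tau / (plant$dc_gain * (lambda + plant$delay))
  pid_gains(Kp = Kp, Ki = Kp / plant$tau, Kd = 0, dt = dt,
            u_min = u_min, u_max = u_max)
}

#' ILC configuration
#'
#' Settings for the iteration-domain learning update
#' u_{i+1} = Q[u_i + L e_i] (+ C e_{i+1}), where Q is a zero-phase low-pass,
#' L a scalar learning gain scaled by the plant's inverse DC gain, and C the
#' within-cycle PID feedback ("current-cycle feedback").
#'
#' @param q_cutoff Q-filter cutoff, rad/s; \code{NULL} defaults to the plant
#'   cutoff a0/a1 at design time.
#' @param l_gain Scalar learning gain; the realized L is
#'   \code{l_gain / dc_gain}, so \code{|1 - L K| = |1 - l_gain| < 1} for
#'   l_gain in (0, 2). Default 0.8.
#' @param n_iterations Breath cycles to learn over (>= 1).
#' @param use_current_cycle Enable the PID feedback term C (default TRUE).
#' @return An object of class \code{ilc_config}.
#' @export
ilc_config <- function(q_cutoff = NULL, l_gain = 0.8, n_iterations = 10,
                       use_current_cycle = TRUE) {
  if (!is.null(q_cutoff) && q_cutoff <= 0) {
    stop("'q_cutoff' must be > 0", call. = FALSE)
  }
  if (!is.finite(l_gain)) stop("'l_gain' must be finite", call. = FALSE)
  if (n_iterations < 1) stop("'n_iterations' must be >= 1", call. = FALSE)
  structure(list(q_cutoff = q_cutoff, l_gain = l_gain,
                 n_iterations = as.integer(n_iterations),
                 use_current_cycle = isTRUE(use_current_cycle)),
            class = "ilc_config")
}

# Zero-phase first-order low-pass: one forward and one backward pass of the
# exponential smoother y[k] = alpha u[k] + (1-alpha) y[k-1] with
# alpha = dt*wc/(1 + dt*wc) (backward-Euler pole). Reflection padding at the
# edges suppresses start-up transients. DC gain is exactly 1.
zero_phase_lowpass <- function(x, cutoff, dt, pad = NULL) {
  n <- length(x)
  if (!is.finite(cutoff)) return(x)   # infinite cutoff: identity filter
  if (n < 2) return(x)
  alpha <- dt * cutoff / (1 + dt * cutoff)
  if (is.null(pad)) pad <- min(n - 1L, max(8L, ceiling(3 / (cutoff * dt))))
  xe <- c(2 * x[1] - x[seq(pad + 1L, 2L)],           # reflect left
          x,
          2 * x[n] - x[seq(n - 1L, n - pad)])        # reflect right
  smooth1 <- function(v) {
    y <- v
    for (k in 2:length(v)) y[k] <- alpha * v[k] + (1 - alpha) * y[k - 1]
    y
  }
  y <- rev(smooth1(rev(smooth1(xe))))
  y[seq(pad + 1L, pad + n)]
}

#' Design the ILC Q and L filters from the plant cutoff
#'
#' The plant cutoff is omega_c = a0/a1 (rad/s). Q is realized as a zero-phase
#' (forward-backward) first-order low-pass at \code{q_cutoff} (default
#' omega_c); L is the scalar \code{l_gain / dc_gain} (optionally followed by
#' the same low-pass). Also returns the frequency-domain contraction
#' estimate sup_w |Q(jw) (1 - L G(jw))|; learning contracts when it is < 1.
#'
#' @param plant A \code{fod_plant}.
#' @param cfg An \code{\link{ilc_config}}.
#' @param dt Sample interval the filters will run at, s.
#' @return An object of class \code{ilc_filters}: fields \code{q_cutoff},
#'   \code{l_scalar}, \code{dt}, \code{contraction}, and the closures
#'   \code{Q(x)} and \code{L(e)} operating on whole stored cycles.
#' @export
#' @examples
#' design_filters(canonical_plant(delay = 0), ilc_config(), dt = 0.002)$contraction
design_filters <- function(plant, cfg = ilc_config(), dt = 0.002) {
  stopifnot(inherits(plant, "fod_plant"), inherits(cfg, "ilc_config"))
  omega_c <- plant$a0 / plant$a1
  qc <- if (is.null(cfg$q_cutoff)) omega_c else cfg$q_cutoff
  l_scalar <- cfg$l_gain / plant$dc_gain
  # Contraction estimate over a log grid up to the Nyquist rate. The
  # learning term is advanced by the transport delay before filtering
  # (see ilc_update), which cancels the plant's delay phase in the lifted
  # domain, so the effective loop uses the delay-free response.
  w <- exp(seq(log(1e-3), log(pi / dt), length.out = 400))
  G <- plant$b0 / (1i * w * plant$a1 + plant$a0)
  Qmag <- 1 / (1 + (w / qc)^2)        # zero-phase: |H|^2 of the one-pass filter
  contraction <- max(Qmag * Mod(1 - l_scalar * G))
  if (contraction >= 1) {
    warning(sprintf(
      "ILC contraction estimate %.3f >= 1: learning may diverge", contraction),
      call. = FALSE)
  }
  structure(list(
    q_cutoff = qc, l_scalar = l_scalar, dt = dt,
    plant_cutoff = omega_c, contraction = contraction,
    delay_samples = as.integer(round(plant$delay / dt)),
    Q = function(x) zero_phase_lowpass(x, qc, dt),
    L = function(e) l_scalar * e
  ), class = "ilc_filters")
}

#' Per-cycle iteration memory
#'
#' Stores the control and error series of the most recent breath cycle.
#'
#' @param u Control series of one full cycle.
#' @param e Error series, same length and dt as \code{u}.
#' @param cycle_index Which breath cycle the series belong to.
#' @return An object of class \code{iteration_memory} including the cycle
#'   RMS error.
#' @export
iteration_memory <- function(u, e, cycle_index = 1L) {
  if (length(u) != length(e)) {
    stop(sprintf("stored control (%d) and error (%d) series differ in length",
                 length(u), length(e)), call. = FALSE)
  }
  structure(list(cycle_index = as.integer(cycle_index), u = u, e = e,
                 rms_error = sqrt(mean(e^2))),
            class = "iteration_memory")
}

#' Iteration-domain ILC update
#'
#' Computes the feedforward series for the next breath cycle:
#' \code{u_{i+1} = Q[u_i + L e_i]}, with the learning term advanced by the
#' plant transport delay (in samples) so the correction lands where the
#' error it addresses was caused. The current-cycle PID term C runs online
#' inside the next cycle (see \code{\link{run_scenario}}); when a
#' \code{current_error} series is supplied here it is added through the PID
#' law sample-by-sample, reproducing the offline form of the combined
#' update. Output is clamped to the PID actuation limits.
#'
#' @param memory An \code{\link{iteration_memory}} for cycle i.
#' @param filters An \code{ilc_filters} object from
#'   \code{\link{design_filters}}.
#' @param pid A \code{\link{pid_gains}} object (supplies the clamps and,
#'   when \code{current_error} is given, the C law).
#' @param current_error Optional e_{i+1} series (same length as the stored
#'   cycle) for the offline combined update; \code{NULL} (default) returns
#'   the pure feedforward.
#' @return Numeric control series u_{i+1}.
#' @export
ilc_update <- function(memory, filters, pid, current_error = NULL) {
  stopifnot(inherits(memory, "iteration_memory"),
            inherits(filters, "ilc_filters"),
            inherits(pid, "pid_gains"))
  n <- length(memory$u)
  if (!is.null(current_error) && length(current_error) != n) {
    stop(sprintf(
      "current-cycle error length %d does not match stored cycle length %d",
      length(current_error), n), call. = FALSE)
  }
  learn <- filters$L(memory$e)
  d <- filters$delay_samples
  if (d > 0 && d < n) {
    learn <- c(learn[(d + 1):n], rep(learn[n], d))  # advance by the dead time
  }
  u_next <- filters$Q(memory$u + learn)
  if (!is.null(current_error)) {
    st <- pid_state_new(pid)
    cterm <- numeric(n)
    for (k in seq_len(n)) {
      res <- pid_step(current_error[k], st, pid)
      cterm[k] <- res$u
      st <- res$state
    }
    u_next <- u_next + cterm
  }
  pmin(pmax(u_next, pid$u_min), pid$u_max)
}
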