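#' Multi-breath closed-loop scenario
#'
#' Bundles the plant, breath timing, reference, controller choice and
#' simulation settings for a repeated-breath run.
#'
#' @param reference A \code{\link{volume_reference}} (flow tracking) or
#'   \code{\link{pressure_reference}} (pressure tracking).
#' @param controller One of \code{"none"}, \code{"PID"}, \code{"ILC-PID"}.
#'   \code{"none"} feeds the reference straight into the plant input.
#' @param plant A \code{fod_plant}; default is the canonical plant without
#'   transport delay (the shipped "paper-style" scenarios; see the methods
#'   vignette for the rationale).
#' @param timing A \code{\link{breath_timing}}.
#' @param n_cycles Number of breath cycles (>= 1).
#' @param dt Sample interval, s.
#' @param pid A \code{\link{pid_gains}}; default is IMC tuning on the
#'   scenario's plant (\code{\link{imc_pid_gains}}). Also supplies the
#'   actuation clamps for ILC-PID.
#' @param ilc An \code{\link{ilc_config}} (ILC-PID only).
#' @param disturbance Standard deviation of additive Gaussian output noise;
#'   0 (default) disables it.
#' @param seed Integer seed for the disturbance draws.
#' @param pid_persistent Keep PID state across cycle boundaries instead of
#'   resetting at each cycle start (default FALSE).
#' @return An object of class \code{breath_scenario}.
#' @export
#' @examples
#' s <- breath_scenario(pressure_reference("CPAP", target = 20),
#'                      controller = "PID", n_cycles = 3)
breath_scenario <- function(reference,
                            controller = c("PID", "ILC-PID", "none"),
                            plant = canonical_plant(delay = 0),
                            timing = breath_timing(),
                            n_cycles = 10, dt = 0.002,
                            pid = imc_pid_gains(plant, dt = dt),
                            ilc = ilc_config(),
                            disturbance = 0, seed = 1L,
                            pid_persistent = FALSE) {
  controller <- match.arg(controller)
  stopifnot(inherits(plant, "fod_plant"), inherits(timing, "breath_timing"))
  if (n_cycles < 1) stop("'n_cycles' must be >= 1", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (disturbance < 0) stop("'disturbance' must be >= 0", call. = FALSE)
  structure(list(reference = reference, controller = controller,
                 plant = plant, timing = timing,
                 n_cycles = as.integer(n_cycles), dt = dt,
                 pid = pid, ilc = ilc, disturbance = disturbance,
                 seed = as.integer(seed),
                 pid_persistent = isTRUE(pid_persistent)),
            class = "breath_scenario")
}

#' Shipped default scenarios
#'
#' Four "paper-style" reference scenarios used throughout the package's
#' examples and tests. They assert orderings and saturation behaviour, not
#' any particular printed endpoint:
#' \describe{
#'   \item{cpap20}{CPAP pressure tracking at 20 cm H2O, delay-free
#'     canonical plant.}
#'   \item{pav20}{PAV pressure tracking (PEEP 5, assist gain 0.6, effort
#'     amplitude 10 cm H2O), delay-free canonical plant.}
#'   \item{volume_tracking}{Feasible volume-controlled breath (inspiratory
#'     flow 100 ml/s, tidal volume 120 ml), delay-free canonical plant:
#'     the monotone-learning showcase.}
#'   \item{volume_increasing}{Actuation-limited volume scenario (commanded
#'     flow 300 ml/s exceeds what the clamped actuation can deliver) on the
#'     canonical plant with a 0.2 s transport delay: reactive PID ramps up
#'     late every breath, while the learned feedforward saturates from the
#'     start of inspiration, so ILC-PID delivers the larger tidal volume.}
#' }
#'
#' @param controller Controller to attach to each scenario.
#' @param n_cycles Breath count per scenario.
#' @return Named list of \code{\link{breath_scenario}} objects.
#' @export
#' @examples
#' names(default_scenarios())
default_scenarios <- function(controller = "ILC-PID", n_cycles = 10) {
  timing <- breath_timing(t_insp = 1.6, t_exp = 2.4)
  p0 <- canonical_plant(delay = 0)
  pd <- canonical_plant(delay = 0.2)
  list(
    cpap20 = breath_scenario(
      pressure_reference("CPAP", target = 20), controller = controller,
      plant = p0, timing = timing, n_cycles = n_cycles),
    pav20 = breath_scenario(
      pressure_reference("PAV", target = 20, PEEP = 5, pav_gain = 0.6,
                         effort_amplitude = 10),
      controller = controller, plant = p0, timing = timing,
      n_cycles = n_cycles),
    volume_tracking = breath_scenario(
      volume_reference(gamma = 100, VT = 120), controller = controller,
      plant = p0, timing = timing, n_cycles = n_cycles),
    volume_increasing = breath_scenario(
      volume_reference(gamma = 300, VT = 450), controller = controller,
      plant = pd, timing = timing, n_cycles = n_cycles,
      pid = imc_pid_gains(pd, dt = 0.002, u_min = 0, u_max = 1000))
  )
}

#' Run a multi-breath closed-loop simulation
#'
#' Simulates \code{n_cycles} breaths of the configured loop. With
#' \code{controller = "ILC-PID"} the iteration memory carries across cycles:
#' between breaths the stored cycle is refined by the iteration-domain
#' update \code{u_ff <- Q[u_i + L e_i]} (see \code{\link{ilc_update}}), and
#' within the next breath the PID term adds current-cycle feedback when
#' enabled. Volume scenarios track flow; delivered volume is the running
#' integral of the plant's flow output, reset at each cycle start.
#'
#' @param s A \code{\link{breath_scenario}}.
#' @return An object of class \code{scenario_result}: \code{trajectories}
#'   (one \code{\link{trajectory}} per cycle), \code{rms_error},
#'   \code{max_error}, \code{peak_output} and (volume scenarios)
#'   \code{peak_volume} per cycle, \code{contraction} (ILC-PID), and the
#'   scenario.
#' @export
#' @examples
#' res <- run_scenario(breath_scenario(pressure_reference("CPAP", target = 20),
#'                                     controller = "PID", n_cycles = 2))
#' res$rms_error
run_scenario <- function(s) {
  stopifnot(inherits(s, "breath_scenario"))
  n_s <- as.integer(round(s$timing$T_resp / s$dt))
  if (n_s < 2) stop("cycle period too short for the chosen dt", call. = FALSE)
  is_volume <- inherits(s$reference, "volume_reference")
  ref_bound <- if (is_volume) s$reference$gamma else s$reference$target
  filters <- NULL
  u_ff <- rep(0, n_s)
  if (s$controller == "ILC-PID") {
    filters <- design_filters(s$plant, s$ilc, dt = s$dt)
  }
  noise <- NULL
  if (s$disturbance > 0) {
    set.seed(s$seed)
    noise <- matrix(stats::rnorm(n_s * s$n_cycles, sd = s$disturbance),
                    nrow = n_s)
  }
  st <- plant_state_new(s$plant, s$dt)
  pid_st <- pid_state_new(s$pid)
  trajectories <- vector("list", s$n_cycles)
  rms_error <- max_error <- peak_output <- peak_volume <- numeric(s$n_cycles)
  for (cyc in seq_len(s$n_cycles)) {
    if (!s$pid_persistent) pid_st <- pid_state_new(s$pid)
    t0 <- (cyc - 1) * s$timing$T_resp
    tt <- t0 + (seq_len(n_s) - 1) * s$dt
    ref <- reference_at(tt, s$reference, s$timing)
    y <- u <- e <- numeric(n_s)
    vol <- 0
    vmax <- 0
    for (k in seq_len(n_s)) {
      yk <- st$y
      if (!is.null(noise)) yk <- yk + noise[k, cyc]
      y[k] <- yk
      e[k] <- ref[k] - yk
      uk <- switch(s$controller,
        "none" = ref[k],
        "PID" = {
          res <- pid_step(e[k], pid_st, s$pid); pid_st <- res$state; res$u
        },
        "ILC-PID" = {
          fb <- 0
          if (s$ilc$use_current_cycle) {
            res <- pid_step(e[k], pid_st, s$pid); pid_st <- res$state
            fb <- res$u
          }
          u_ff[k] + fb
        })
      uk <- min(max(uk, s$pid$u_min), s$pid$u_max)
      u[k] <- uk
      st <- plant_state_step(st, uk)
      if (is_volume) {
        vol <- vol + yk * s$dt
        if (vol > vmax) vmax <- vol
      }
      if (abs(yk) > 10 * max(abs(ref_bound), 1)) {
        stop(sprintf("simulation diverged in cycle %d (|output| = %.3g)",
                     cyc, abs(yk)), call. = FALSE)
      }
    }
    trajectories[[cyc]] <- trajectory(dt = s$dt, reference = ref,
                                      output = y, control = u, t = tt)
    rms_error[cyc] <- sqrt(mean(e^2))
    max_error[cyc] <- max(abs(e))
    peak_output[cyc] <- max(abs(y))
    if (is_volume) peak_volume[cyc] <- vmax
    if (s$controller == "ILC-PID" && cyc < s$n_cycles) {
      u_ff <- ilc_update(iteration_memory(u_ff, e, cyc), filters, s$pid)
    }
  }
  structure(list(trajectories = trajectories, rms_error = rms_error,
                 max_error = max_error, peak_output = peak_output,
                 peak_volume = if (is_volume) peak_volume else NULL,
                 contraction = if (!is.null(filters)) filters$contraction
                               else NULL,
                 scenario = s),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("%s scenario, %d cycles @ dt = %g s (%s)\n",
              if (inherits(s$reference, "volume_reference")) "Volume"
              else s$reference$mode,
              s$n_cycles, s$dt, s$controller))
  cat(sprintf("  RMS error: first cycle %.4g, final cycle %.4g\n",
              x$rms_error[1], x$rms_error[s$n_cycles]))
  if (!is.null(x$peak_volume)) {
    cat(sprintf("  peak delivered volume, final cycle: %.4g ml\n",
                x$peak_volume[s$n_cycles]))
  }
  invisible(x)
}

#' Per-iteration learning diagnostics
#'
#' @param result A \code{scenario_result}.
#' @return A data.frame with columns \code{iteration, rms_error, max_error,
#'   contraction_estimate}, one row per breath cycle.
#' @export
iteration_diagnostics <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  data.frame(iteration = seq_along(result$rms_error),
             rms_error = result$rms_error,
             max_error = result$max_error,
             contraction_estimate =
               if (is.null(result$contraction)) NA_real_
               else result$contraction)
}

#' Run one scenario under both PID and ILC-PID
#'
#' Runs the identical scenario (same plant, gains, seed) under each
#' controller and tabulates final-cycle tracking statistics, optionally
#' including the uncontrolled loop.
#'
#' @param s A \code{\link{breath_scenario}}; its \code{controller} field is
#'   overridden per run.
#' @param include_none Also run with the reference fed straight through
#'   (default TRUE).
#' @return An object of class \code{controller_comparison}: \code{results}
#'   (named list of \code{scenario_result}) and \code{summary} (one row per
#'   controller: final RMS and max error, peak output, settling time to 2%).
#' @export
compare_controllers <- function(s, include_none = TRUE) {
  stopifnot(inherits(s, "breath_scenario"))
  ctrls <- c(if (include_none) "none", "PID", "ILC-PID")
  results <- lapply(ctrls, function(ctrl) {
    s2 <- s
    s2$controller <- ctrl
    run_scenario(s2)
  })
  names(results) <- ctrls
  summary <- do.call(rbind, lapply(ctrls, function(ctrl) {
    r <- results[[ctrl]]
    nfin <- length(r$rms_error)
    tr <- r$trajectories[[nfin]]
    err <- abs(tr$reference - tr$output)
    band <- 0.02 * max(abs(tr$reference))
    inside <- rev(cumprod(rev(err <= band)))  # 1 where settled to the end
    settle <- if (inside[1] == 1) 0 else {
      idx <- which(inside == 1)
      if (length(idx)) (idx[1] - 1) * s$dt else NA_real_
    }
    data.frame(controller = ctrl,
               final_rms = r$rms_error[nfin],
               final_max_error = r$max_error[nfin],
               peak_output = r$peak_output[nfin],
               peak_volume = if (is.null(r$peak_volume)) NA_real_
                             else r$peak_volume[nfin],
               settling_time = settle,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, summary = summary),
            class = "controller_comparison")
}

#' @export
print.controller_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
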