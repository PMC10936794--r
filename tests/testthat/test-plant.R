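test_that("symbolic assembly follows the compliance/resistance composition", {
  p <- plant_params(Cc = 0.075, C2 = 0.465, R2c = 0.377)
  g <- assemble_transfer_function(p, use_canonical = FALSE, delay = 0)
  expect_equal(g$b0, 0.075)
  expect_equal(g$a1, 0.075 * 0.465 * 0.377)
  expect_equal(g$a0, 0.54)
  expect_equal(g$dc_gain, 0.075 / 0.54)
})

test_that("canonical plant uses the fixed coefficient set and warns about the mismatch", {
  expect_warning(
    g <- assemble_transfer_function(plant_params(), use_canonical = TRUE,
                                    delay = 0),
    "not reproduced by symbolic assembly")
  expect_equal(g$b0, 0.07425)
  expect_equal(g$a1, 0.022)
  expect_equal(g$a0, 0.54)
  expect_equal(g$dc_gain, 0.07425 / 0.54)
  expect_equal(canonical_plant(T_resp = 4)$delay, 1.8)
})

test_that("degenerate physical parameters are rejected by name", {
  expect_error(plant_params(Cc = 0), "'Cc'")
  expect_error(plant_params(R2c = -1), "'R2c'")
  expect_error(plant_params(T_resp = 0), "'T_resp'")
  expect_error(new_fod_plant(b0 = 1, a1 = 0, a0 = 1), "'a1'")
})

test_that("symbolic assembly is homogeneous in the compliances", {
  for (c_scale in c(0.5, 2, 10)) {
    base <- assemble_transfer_function(
      plant_params(Cc = 0.075, C2 = 0.465), use_canonical = FALSE, delay = 0)
    scaled <- assemble_transfer_function(
      plant_params(Cc = 0.075 * c_scale, C2 = 0.465 * c_scale),
      use_canonical = FALSE, delay = 0)
    expect_equal(scaled$a0, c_scale * base$a0)
    expect_equal(scaled$dc_gain, base$dc_gain) # Cc/(Cc + C2) is scale-free
  }
})

test_that("delay-free step response matches the analytic first-order solution", {
  p <- canonical_plant(delay = 0)
  tr <- step_response(p, amplitude = 2, dt = 1e-4, horizon = 0.4)
  analytic <- 2 * p$dc_gain * (1 - exp(-p$a0 * tr$t / p$a1))
  expect_lt(max(abs(tr$output - analytic)), 1e-6)
  expect_equal(tr$output[1], 0)                       # zero initial state
  final <- utils::tail(tr$output, 1)
  expect_lt(abs(final - 2 * p$dc_gain) / (2 * p$dc_gain), 1e-3)
})

test_that("discretization error on a smoothly varying input halves with dt", {
  p <- new_fod_plant(b0 = 1, a1 = 0.2, a0 = 1, delay = 0)
  w <- 5
  sim_err <- function(dt) {
    n <- as.integer(round(1 / dt))
    st <- ventilab:::plant_state_new(p, dt)
    y <- numeric(n + 1)
    for (k in seq_len(n)) {
      st <- ventilab:::plant_state_step(st, sin(w * (k - 1) * dt))
      y[k + 1] <- st$y
    }
    t <- (0:n) * dt
    max(abs(y - analytic_sine_response(t, p$dc_gain, p$tau, w)))
  }
  e1 <- sim_err(2e-3)
  e2 <- sim_err(1e-3)
  expect_lt(e2 / e1, 0.6)   # first-order convergence: halving dt halves error
})

test_that("transport delay is an exact sample buffer", {
  p <- new_fod_plant(b0 = 1, a1 = 0.1, a0 = 1, delay = 0.05)
  tr <- step_response(p, amplitude = 1, dt = 0.01, horizon = 0.3)
  expect_true(all(tr$output[tr$t <= 0.05] == 0))
  expect_true(all(tr$output[tr$t > 0.06] > 0))
})

test_that("too-coarse sampling is rejected with a resolution error", {
  p <- canonical_plant(delay = 0)  # lag time constant ~0.0407 s
  expect_error(step_response(p, dt = 0.05, horizon = 1), "smaller dt")
})

test_that("trajectories enforce shared lengths and round-trip through CSV", {
  expect_error(trajectory(0.1, 1:3, 1:2, 1:3), "share one length")
  tr <- trajectory(0.1, c(1, 1), c(0, 0.5), c(2, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("t", "reference", "output", "control"))
  expect_equal(back$output, c(0, 0.5))
})

test_that("plant config files round-trip the physical parameters", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("Cc: 0.075", "C2: 0.465", "R2c: 0.377", "T_resp: 4",
               "PEEP: 5", "Rv1: extra"), path)
  p <- read_plant_config(path)
  expect_equal(p$Cc, 0.075)
  expect_equal(p$circuit_info$Rv1, "extra")
  expect_equal(assemble_transfer_function(p, use_canonical = FALSE)$a0, 0.54)
})
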