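test_that("the growth rate follows the stated form with clamped drive", {
  p <- adaptation_params(tau = 1, delta = 1, csa_max = 2)
  # threshold and saturation zeros
  expect_equal(csa_rate(1, 0.2, p), 0)
  expect_equal(csa_rate(1, 0.1, p), 0)
  expect_equal(csa_rate(2, 0.9, p), 0)
  # hand evaluation: tau=1, delta=1, csa_max=2, csa=1, F=0.5 -> 0.3
  expect_equal(csa_rate(1, 0.5, p), 0.3, tolerance = 1e-12)
  expect_error(csa_rate(2.5, 0.5, p), "csa_max")
})

test_that("constant-force growth matches the separable closed form", {
  p <- adaptation_params(tau = 200, delta = 1, csa_max = 1.2)
  prof <- tibble::tibble(time = seq(0, 2, length.out = 41),
                         f_quad_norm = rep(0.6, 41))
  sim <- simulate_growth(prof, p, n_reps = 50, n_out = 400)
  # closed form of the separable ODE at constant F
  k <- p$delta * (0.6 - p$f0) / (p$tau * (p$csa_max - 1))
  analytic <- p$csa_max - (p$csa_max - 1) * exp(-k * sim$time)
  expect_lt(max(abs(sim$csa - analytic)), 1e-6)
  # sub-threshold profile never grows
  prof0 <- tibble::tibble(time = seq(0, 2, length.out = 41),
                          f_quad_norm = rep(0.15, 41))
  sim0 <- simulate_growth(prof0, p, n_reps = 100)
  expect_true(all(sim0$csa == 1))
  # csa never exceeds the ceiling
  simx <- simulate_growth(prof, p, n_reps = 5000, n_out = 50)
  expect_true(all(simx$csa <= p$csa_max + 1e-9))
  expect_error(simulate_growth(tibble::tibble(time = c(0, 1), f_quad_norm = c(1, NA)),
                               p, 10), "non-finite")
})

test_that("repetitions to target agree with direct simulation", {
  p <- adaptation_params(tau = 150, delta = 1, csa_max = 1.2)
  prof <- tibble::tibble(time = seq(0, 0.5, length.out = 26),
                         f_quad_norm = 0.3 + 0.3 * sin(pi * seq(0, 1, length.out = 26)))
  r <- reps_to_target(prof, p, target = 1.0337)
  expect_true(r$feasible)
  # the ODE integrated for exactly r$reps repetitions reaches the target,
  # and one repetition fewer does not
  end_of <- function(n) tail(simulate_growth(prof, p, n_reps = n, n_out = 5)$csa, 1)
  expect_gte(end_of(r$reps) + 1e-7, 1.0337)
  expect_lt(end_of(r$reps - 1L), 1.0337)
  # trivial and infeasible cases
  expect_equal(reps_to_target(prof, p, target = 1)$reps, 0L)
  sub <- tibble::tibble(time = c(0, 1), f_quad_norm = c(0.1, 0.1))
  rs <- reps_to_target(sub, p)
  expect_false(rs$feasible)
  expect_equal(rs$reps, Inf)
})

test_that("stronger loading never needs more repetitions", {
  p <- adaptation_params(tau = 150, delta = 1, csa_max = 1.2)
  base <- tibble::tibble(time = seq(0, 0.5, length.out = 26),
                         f_quad_norm = 0.25 + 0.2 * sin(pi * seq(0, 1, length.out = 26)))
  for (scale in c(1.1, 1.3, 1.8, 2.5)) {
    hi <- base; hi$f_quad_norm <- base$f_quad_norm * scale
    expect_lte(reps_to_target(hi, p)$reps, reps_to_target(base, p)$reps)
  }
  # doubling the gain halves the repetitions in the constant-force case
  pc <- adaptation_params(tau = 150, delta = 1, csa_max = 1.2)
  pc2 <- adaptation_params(tau = 150, delta = 2, csa_max = 1.2)
  cst <- tibble::tibble(time = c(0, 1), f_quad_norm = c(0.7, 0.7))
  r1 <- reps_to_target(cst, pc)$reps
  r2 <- reps_to_target(cst, pc2)$reps
  expect_lte(abs(r2 - ceiling(r1 / 2)), 1)
})

test_that("set arithmetic reproduces the printed schedule mapping", {
  expect_equal(reps_to_schedule(252), 7L)
  expect_equal(reps_to_schedule(0), 0L)
  expect_equal(reps_to_schedule(1426), 40L)
  expect_equal(reps_to_schedule(1025), 29L)
})

test_that("calibration round-trips through the simulator", {
  p <- calibrate_adaptation(reps_at_reference = 108, reference_force = 0.75,
                            rep_duration = 3)
  ref <- tibble::tibble(time = c(0, 3), f_quad_norm = c(0.75, 0.75))
  r <- reps_to_target(ref, p, target = 1.0337)
  expect_equal(r$reps, 108L)
  # deterministic
  p2 <- calibrate_adaptation(108, 0.75, 3)
  expect_identical(p$tau, p2$tau)
  # scaling the reference repetitions scales the fitted rate constant
  p3 <- calibrate_adaptation(216, 0.75, 3)
  expect_equal(p3$tau / p$tau, 2, tolerance = 1e-9)
  expect_error(calibrate_adaptation(reference_force = 0.1), "unreachable")
  expect_error(calibrate_adaptation(target_increase = 0.5), "ceiling")
})
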