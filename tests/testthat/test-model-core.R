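test_that("muscle curves are normalised at the isometric optimum", {
  cv <- eval_muscle_curves(1, 0, 0)
  expect_equal(cv$f_act_fl, 1, tolerance = 1e-12)
  expect_equal(cv$f_v, 1, tolerance = 1e-12)
  expect_equal(cv$f_pas, 0, tolerance = 1e-12)
  expect_equal(cv$f_tendon, 0, tolerance = 1e-12)
  expect_error(eval_muscle_curves(c(1, NA)), "non-finite")
  expect_error(eval_muscle_curves(-0.2), "positive")
})

test_that("tendon stiffness calibration yields slope 35 at 4% strain", {
  cr <- calibrate_tendon_stiffness(muscle_curves(), 35, 0.04)
  f <- function(s) eval_muscle_curves(1, 0, s, cr)$f_tendon
  h <- 1e-6
  slope <- (f(0.04 + h) - f(0.04 - h)) / (2 * h)
  expect_equal(slope, 35, tolerance = 1e-6)
  # tendon force is zero at zero strain for any calibrated stiffness
  expect_equal(f(0), 0, tolerance = 1e-12)
})

test_that("calibrated stiffness is monotone in the target gradient", {
  cr35 <- calibrate_tendon_stiffness(muscle_curves(), 35, 0.04)
  cr70 <- calibrate_tendon_stiffness(muscle_curves(), 70, 0.04)
  expect_gt(cr70$kT, cr35$kT)
  # independent bisection oracle for the same root
  slope_at <- function(kT) {
    cr <- muscle_curves(kT = kT)
    f <- function(s) eval_muscle_curves(1, 0, s, cr)$f_tendon
    (f(0.04 + 1e-7) - f(0.04 - 1e-7)) / 2e-7
  }
  lo <- 1; hi <- 500
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (slope_at(mid) < 70) lo <- mid else hi <- mid
  }
  expect_equal(cr70$kT, (lo + hi) / 2, tolerance = 1e-6)
  expect_error(calibrate_tendon_stiffness(target_strain = 0), "slack point")
  expect_error(calibrate_tendon_stiffness(target_gradient = 35, interval = c(400, 500)),
               "bracket")
})

test_that("passive and tendon curves are twice continuously differentiable", {
  cr <- calibrate_tendon_stiffness()
  fp <- function(x) eval_muscle_curves(x, 0, 0, cr)$f_pas
  ft <- function(s) eval_muscle_curves(1, 0, s, cr)$f_tendon
  for (x in c(0.7, 1.0, 1.3)) expect_c2(fp, x)
  for (s in c(-0.01, 0.0, 0.02, 0.05)) expect_c2(ft, s)
})

test_that("hill equilibrium residual vanishes at constructed balance points", {
  m <- the_model()
  mtu <- as.list(m$mtus[3, ])
  cr <- m$curves
  # isometric balance: fibre at optimum, no velocities
  penn <- mtu$pennation_opt
  ft <- cos(penn) * (1 + 0)  # f_act(1)*f_v(0)*a + f_pas(1) with a = 1
  c2 <- 1 - log(cr$c3 / cr$c1) / cr$kT
  ltn <- c2 + log((ft + cr$c3) / cr$c1) / cr$kT
  lmt <- ltn * mtu$l_slack + mtu$l_opt * cos(penn)
  expect_equal(hill_equilibrium_residual(1, lmt, 0, ft, 0, mtu, cr), 0,
               tolerance = 1e-12)
  # zero activation, unloaded tendon, fibre at optimum (zero passive force)
  lmt0 <- mtu$l_slack + mtu$l_opt * cos(penn)
  expect_equal(hill_equilibrium_residual(0, lmt0, 0, 0, 0, mtu, cr), 0,
               tolerance = 1e-12)
})

test_that("hill residual matches an independent re-derivation at random states", {
  m <- the_model()
  cr <- m$curves
  set.seed(42)
  for (i in 1:20) {
    j <- sample(nrow(m$mtus), 1)
    mtu <- as.list(m$mtus[j, ])
    a <- runif(1); ft <- runif(1, 0, 1.5); dft <- runif(1, -5, 5)
    lmt <- mtu$l_slack + mtu$l_opt * runif(1, 0.6, 1.3)
    vmt <- runif(1, -0.3, 0.3)
    got <- hill_equilibrium_residual(a, lmt, vmt, ft, dft, mtu, cr)
    # re-derivation from first principles, written independently
    kT <- cr$kT; c1 <- cr$c1; c3 <- cr$c3
    lt <- (1 - log(c3 / c1) / kT + log((ft + c3) / c1) / kT) * mtu$l_slack
    h <- mtu$l_opt * sin(mtu$pennation_opt)
    w <- lmt - lt
    lm <- sqrt(w^2 + h^2)
    vt <- dft * mtu$l_slack / (kT * (ft + c3))
    vm <- (vmt - vt) * (w / lm)
    lmn <- lm / mtu$l_opt
    vmn <- vm / (10 * mtu$l_opt)
    cv <- eval_muscle_curves(lmn, vmn, 0, cr)
    want <- ft - (w / lm) * (a * cv$f_act_fl * cv$f_v + cv$f_pas + cr$beta * vmn)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("activation-rate envelope matches brute-force excitation sweep", {
  t_a <- 0.015; t_d <- 0.06
  # first-order model: da = (e - a)/t_a when e > a else (e - a)/t_d
  rate <- function(e, a) ifelse(e > a, (e - a) / t_a, (e - a) / t_d)
  es <- seq(0, 1, length.out = 401)
  for (a in c(0, 0.25, 0.5, 0.9, 1)) {
    rates <- rate(es, a)
    for (da in seq(-20, 70, length.out = 41)) {
      g <- activation_rate_constraints(a, da, t_a, t_d)
      feas_env <- g$g_act <= 1e-9 & g$g_deact <= 1e-9
      feas_brute <- da <= max(rates) + 1e-9 && da >= min(rates) - 1e-9
      expect_equal(feas_env, feas_brute)
    }
  }
  g <- activation_rate_constraints(0.5, 0)
  expect_true(all(g <= 0))
  g <- activation_rate_constraints(1, 1)
  expect_gt(g$g_act, 0)
})

test_that("contact force has the no-contact, stiffness-scaling and C2 properties", {
  m <- the_model()
  # clear of the ground
  expect_lt(contact_force(-0.05, 0, 0, 2e6, 1, m)$normal, 1e-3)
  expect_lt(contact_force(-0.05, -1, 0.5, 1e7, 2, m)$normal, 1e-3)
  # deep-contact stiffness ratio
  f1 <- contact_force(0.005, 0, 0, 1e6, 1, m)$normal
  f2 <- contact_force(0.005, 0, 0, 2e6, 1, m)$normal
  expect_equal(f2 / f1, 2, tolerance = 1e-6)
  # smooth at the contact boundary
  fn <- function(d) contact_force(d, 0, 0, 2e6, 1, m)$normal
  # the smoothing scale is eps_d = 1e-4 m, so probe below it
  expect_c2(fn, 0, steps = c(1e-5, 2e-6, 1e-6))
  # non-negative and monotone in penetration at fixed velocity
  d <- seq(-0.02, 0.02, length.out = 200)
  f <- contact_force(d, 0.1, 0, 2e6, 1, m)$normal
  expect_true(all(f >= 0))
  expect_true(all(diff(f) > -1e-9))
})

test_that("body-weight support force replicates the gravity conditions", {
  m <- the_model()
  expect_equal(bwss_force(1, m), 0)
  expect_equal(bwss_force(0.5, m), 0.5 * 79.9 * 9.81, tolerance = 1e-10)
  expect_equal(bwss_force(0.17, m), 0.83 * 79.9 * 9.81, tolerance = 1e-10)
  # about 392 N and 651 N for this participant mass
  expect_equal(bwss_force(0.5, m), 392, tolerance = 0.01)
  expect_equal(bwss_force(0.17, m), 651, tolerance = 0.01)
  expect_error(bwss_force(0, m), "g_level")
  expect_error(bwss_force(1.2, m), "g_level")
})

test_that("static standing pose yields zero pelvis residuals", {
  m <- the_model()
  nq <- length(m$coordinates)
  q <- rep(0, nq); q[2] <- 1.0
  com <- centre_of_mass(m, q)
  W <- m$total_mass * m$gravity
  # full support: GRF = body weight applied under the centre of mass
  tau <- inverse_dynamics(m, q, rep(0, nq), rep(0, nq),
                          grf = c(0, W), cop = com$x)
  expect_equal(tau$pelvis_tx, 0, tolerance = 1e-9)
  expect_equal(tau$pelvis_ty, 0, tolerance = 1e-9)
  expect_equal(tau$pelvis_tilt, 0, tolerance = 1e-9)
  # half support plus body-weight support at the pelvis centre of mass
  bw <- bwss_force(0.5, m)
  fk <- forward_kinematics(m, q)
  pel_x <- fk$cx[1, "pelvis"]
  cop <- (W * com$x - bw * pel_x) / (W - bw)
  tau2 <- inverse_dynamics(m, q, rep(0, nq), rep(0, nq),
                           grf = c(0, W - bw), cop = cop, bwss = bw)
  expect_equal(tau2$pelvis_tx, 0, tolerance = 1e-9)
  expect_equal(tau2$pelvis_ty, 0, tolerance = 1e-9)
  expect_equal(tau2$pelvis_tilt, 0, tolerance = 1e-6)
})

test_that("inverse dynamics satisfies the energy-rate identity", {
  m <- the_model()
  times <- seq(0, 0.5, by = 1e-4)
  tr <- smooth_traj(m, times, amp = 0.15)
  tau <- as.matrix(inverse_dynamics(m, tr$q, tr$qd, tr$qdd))
  # mechanical energy from forward kinematics
  energy <- function(i) {
    fk <- forward_kinematics(m, tr$q[i, , drop = FALSE], tr$qd[i, , drop = FALSE],
                             tr$qdd[i, , drop = FALSE])
    ke <- sum(0.5 * m$segments$mass * (fk$cvx[1, ]^2 + fk$cvy[1, ]^2) +
                0.5 * m$segments$inertia_zz * fk$omega[1, ]^2)
    pe <- sum(m$segments$mass * m$gravity * fk$cy[1, ])
    ke + pe
  }
  idx <- seq(100, length(times) - 100, by = 400)
  for (i in idx) {
    p_gen <- sum(tau[i, ] * tr$qd[i, ])
    dE <- (energy(i + 1) - energy(i - 1)) / (2e-4)
    expect_equal(p_gen, dE, tolerance = 1e-4 * max(1, abs(dE)))
  }
})

test_that("inverse dynamics of a forward-simulated motion recovers the torques", {
  m <- the_model()
  nq <- length(m$coordinates)
  q0 <- c(0, 1.0, 0, 0, 0.4, -0.8, 0.2)
  qd0 <- rep(0, nq)
  tau_fun <- function(t) c(0, 0, 0, 5 * sin(2 * pi * t), 20 * cos(2 * pi * t),
                           -15 * sin(2 * pi * t), 8 * cos(4 * pi * t))
  deriv <- function(t, y, p) {
    q <- y[1:nq]; qd <- y[nq + 1:nq]
    mm <- mass_matrix(m, q, qd)
    tau <- tau_fun(t)
    tau[1:3] <- mm$bias[1:3]  # root follows whatever residual-free motion results
    qdd <- solve(mm$M, tau - mm$bias)
    list(c(qd, qdd))
  }
  times <- seq(0, 0.25, by = 0.005)
  sol <- deSolve::ode(c(q0, qd0), times, deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  q <- sol[, 1 + 1:nq]; qd <- sol[, 1 + nq + 1:nq]
  qdd <- t(vapply(seq_along(times), function(i) {
    mm <- mass_matrix(m, q[i, ], qd[i, ])
    tau <- tau_fun(times[i]); tau[1:3] <- mm$bias[1:3]
    solve(mm$M, tau - mm$bias)
  }, numeric(nq)))
  tau_id <- as.matrix(inverse_dynamics(m, q, qd, qdd))
  tau_ref <- t(vapply(times, tau_fun, numeric(nq)))
  expect_lt(max(abs(tau_id[, 4:7] - tau_ref[, 4:7])), 1e-6)
})

test_that("torque actuator step response reaches 63.2% at the 35 ms delay", {
  resp <- torque_actuator_response(1, times = c(0, 0.035), a0 = 0, delay = 0.035)
  expect_equal(resp$a_tau[2], 1 - exp(-1), tolerance = 0.01 * (1 - exp(-1)))
})

test_that("model satisfies its structural invariants", {
  m <- the_model()
  expect_equal(m$total_mass, sum(m$segments$mass))
  expect_equal(m$total_mass, 79.9, tolerance = 1e-9)
  expect_gte(length(m$coordinates), 6)
  expect_true(all(m$segments$mass > 0))
  expect_true(all(m$segments$inertia_zz > 0))
  expect_true(all(m$mtus$f_max_iso > 0))
  expect_true(all(m$mtus$v_max == 10))
  expect_true(all(m$mtus$pv > 0 & m$mtus$pv <= 100))
  quad <- c("rectus_femoris", "vastus_lateralis", "vastus_intermedius",
            "vastus_medialis")
  expect_lte(sum(m$mtus$pv[m$mtus$name %in% quad]), 100)
  expect_true(all(m$mtus$l_slack > 0))
  expect_true(all(lengths(hopsim:::muscle_spanned_coords(m)) >= 1))
  expect_equal(m$contact$radius, 0.02)
})
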