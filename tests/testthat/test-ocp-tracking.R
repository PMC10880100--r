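# Deterministic, fast checks of the OCP building blocks. The full tracking
# experiment (solves across gravity conditions) lives in the acceptance
# suite; here a short ballistic-flight problem provides exact oracles.

test_that("scale factors reproduce the work-based derivation", {
  sf <- derive_scale_factors(2, 0.02, 9.81)
  expect_equal(sf$s_tau, 28.6)                    # 1 J over 2 degrees, 3 s.f.
  expect_equal(unname(sf$s_grf["vertical"]), 50)  # 1 J over 0.02 m
  expect_equal(unname(sf$s_grf["horizontal"]), 5.1)  # 50 / 9.81 to 2 s.f.
  expect_equal(signif(50 / 9.81, 2), 5.1)
})

test_that("effort cost integrates volume-weighted squared activations", {
  time <- seq(0, 1, length.out = 101)
  a <- matrix(0, 101, 2)
  expect_equal(effort_cost(time, a, pv = c(10, 5)), 0)
  a[, 1] <- 1
  expect_equal(effort_cost(time, a, pv = c(10, 5), w2 = 1), 10, tolerance = 1e-12)
  # linear in the volume fraction
  expect_equal(effort_cost(time, a, pv = c(20, 5)), 20, tolerance = 1e-12)
})

test_that("tracking cost matches hand-integrated scaled errors", {
  time <- seq(0, 1, length.out = 201)
  zero <- matrix(0, 201, 1)
  sf <- derive_scale_factors()
  # perfect tracking
  expect_equal(tracking_cost(time, list(q_rot = zero), list(q_rot = zero)), 0)
  # constant 2 degree error on one angle for 1 s at w2 = 1 integrates to 1
  err <- matrix(2 * pi / 180, 201, 1)
  expect_equal(tracking_cost(time, list(q_rot = err), list(q_rot = zero)),
               1, tolerance = 1e-12)
  # constant one-scale-unit moment error for 1 s at w3 = 10 integrates to 10
  merr <- matrix(sf$s_tau, 201, 1)
  expect_equal(tracking_cost(time, list(njm = merr), list(njm = zero)),
               10, tolerance = 1e-12)
  expect_error(tracking_cost(time, list(q_rot = zero),
                             list(q_rot = zero[1:100, , drop = FALSE])),
               "mismatch")
})

test_that("control cost scales by bounds and the reserve scale", {
  time <- seq(0, 1, length.out = 101)
  zero <- matrix(0, 101, 1)
  expect_equal(control_cost(time, qdd = zero, tau_res = zero), 0)
  # reserve of 2 N m at s_res = 2 and w2 = 1 integrates to 1
  expect_equal(control_cost(time, tau_res = zero + 2), 1, tolerance = 1e-12)
  # acceleration at its bound contributes w2 * 1
  expect_equal(control_cost(time, qdd = zero + 30, s_qdd = 30), 1,
               tolerance = 1e-12)
})

# ballistic-flight tracking data: all contact forces are (numerically) zero,
# the root coordinates are exact global polynomials of degree <= 3, and all
# joint angles are constant, so an exactly feasible point of the transcribed
# NLP can be written down in closed form
flight_tracking <- function(model, n_mesh = 10) {
  g0 <- model$gravity
  tgrid <- seq(0, 0.12, length.out = n_mesh + 1)
  nq <- length(model$coordinates)
  q <- matrix(0, n_mesh + 1, nq, dimnames = list(NULL, model$coordinates))
  q[, "pelvis_tx"] <- 0.05 * tgrid
  q[, "pelvis_ty"] <- 1.4 + 0.5 * tgrid - 0.5 * g0 * tgrid^2
  q[, "hip"] <- 0.4; q[, "knee"] <- -0.8; q[, "ankle"] <- 0.2
  qd <- matrix(0, n_mesh + 1, nq)
  qd[, 1] <- 0.05; qd[, 2] <- 0.5 - g0 * tgrid
  qdd <- matrix(0, n_mesh + 1, nq)
  qdd[, 2] <- -g0
  grf <- matrix(0, n_mesh + 1, 2, dimnames = list(NULL, c("grf_x", "grf_y")))
  id <- compute_net_joint_moments(model, q, qd, qdd, grf, rep(0, n_mesh + 1), 0)
  structure(list(time = tgrid, q = q, qd = qd, qdd = qdd, grf = grf,
                 cop = rep(0, n_mesh + 1), bwss = rep(0, n_mesh + 1),
                 njm = id$njm, residuals = id$residuals,
                 touchdown_times = c(0, 0.12), mass = model$total_mass,
                 g_level = 1),
            class = "hop_tracking")
}

# an exactly feasible design vector for the flight problem
flight_feasible_z <- function(nlp) {
  m <- nlp$model
  lay <- nlp$layout
  tr <- nlp$tracking
  g0 <- m$gravity
  x <- (nlp$ctr + nlp$scl * 0)  # start from centres
  x <- ifelse(is.finite(x), x, 0)
  cr <- m$curves
  # constant muscle state: pick a mid-range tendon force and invert the Hill
  # balance for the activation at the (constant) posture
  qrow <- tr$q[1, ]
  ev <- eval_mtu(m, matrix(qrow, 1), matrix(0, 1, lay$nq), warn_domain = FALSE)
  ft0 <- numeric(lay$nm); a0 <- numeric(lay$nm)
  c2 <- 1 - log(cr$c3 / cr$c1) / cr$kT
  for (j in seq_len(lay$nm)) {
    mtu <- as.list(m$mtus[j, ])
    ft <- 0.2
    ltn <- c2 + log((ft + cr$c3) / cr$c1) / cr$kT
    lmp <- ev$length[1, j] - ltn * mtu$l_slack
    h <- mtu$l_opt * sin(mtu$pennation_opt)
    lm <- sqrt(lmp^2 + h^2)
    cosp <- lmp / lm
    cv <- eval_muscle_curves(lm / mtu$l_opt, 0, 0, cr)
    a <- (ft / cosp - cv$f_pas) / cv$f_act_fl
    if (a < 0.01 || a > 0.99) { ft <- 0; a <- 0 }  # degenerate posture guard
    ft0[j] <- ft; a0[j] <- a
  }
  mus_mom <- numeric(lay$nq)
  for (j in seq_len(lay$nm)) {
    p <- m$polynomials[[j]]
    for (k in seq_along(p$coords)) {
      mus_mom[p$coords[k]] <- mus_mom[p$coords[k]] +
        ev$moment_arms[[j]][1, k] * ft0[j] * m$mtus$f_max_iso[j]
    }
  }
  # in free flight every joint row of the inverse dynamics vanishes exactly
  for (node in 0:(lay$n_nodes - 1)) {
    tn <- nlp$node_t[node + 1]
    x[lay$idx_x(node, lay$s_q)] <- c(0.05 * tn, 1.4 + 0.5 * tn - 0.5 * g0 * tn^2,
                                     0, 0, 0.4, -0.8, 0.2)
    x[lay$idx_x(node, lay$s_qd)] <- c(0.05, 0.5 - g0 * tn, 0, 0, 0, 0, 0)
    x[lay$idx_x(node, lay$s_am)] <- a0
    x[lay$idx_x(node, lay$s_ft)] <- ft0
    x[lay$idx_x(node, lay$s_atau)] <- 0
  }
  for (cn in seq_len(lay$K * lay$d)) {
    x[lay$idx_v(cn, lay$v_qdd)] <- c(0, -g0, 0, 0, 0, 0, 0)
    x[lay$idx_v(cn, lay$v_da)] <- 0
    x[lay$idx_v(cn, lay$v_dft)] <- 0
    x[lay$idx_v(cn, lay$v_etau)] <- 0
  }
  mdc <- muscle_driven_coords(m)
  for (k in seq_len(lay$K)) {
    x[lay$idx_u(k, lay$u_grf)] <- 0
    # reserves cancel the (purely muscular) joint moments
    x[lay$idx_u(k, lay$u_res)] <- -mus_mom[match(mdc, m$coordinates)]
  }
  x[lay$off_p + seq_len(lay$npar)] <- c(6, 2, t(as.matrix(m$spheres[, c("x", "y")])))
  nlp$to_z(x)
}

test_that("the transcription has the closed-form variable count", {
  m <- the_model()
  td <- flight_tracking(m, n_mesh = 10)
  cfg <- ocp_config(n_mesh = 10)
  nlp <- transcribe(m, td, cfg)
  nq <- 7; nm <- 10; nta <- 1; K <- 10; d <- 3
  nx <- 2 * nq + 2 * nm + nta
  nv <- nq + 2 * nm + nta
  expect_equal(nlp$layout$N,
               (1 + K * d) * nx + K * d * nv + K * (2 + 3) + 6)
  expect_equal(nrow(nlp$A), K * d * nx)
  expect_equal(nrow(nlp$G), 2 * nm * K)
})

test_that("variable scaling round-trips exactly", {
  m <- the_model()
  td <- flight_tracking(m)
  nlp <- transcribe(m, td, ocp_config(n_mesh = 10))
  set.seed(11)
  z <- runif(nlp$layout$N, -1, 1)
  expect_equal(nlp$to_z(nlp$to_x(z)), z, tolerance = 1e-12)
})

test_that("a feasible ballistic trajectory satisfies every constraint", {
  m <- the_model()
  td <- flight_tracking(m, n_mesh = 10)
  nlp <- transcribe(m, td, ocp_config(n_mesh = 10))
  z <- flight_feasible_z(nlp)
  expect_lt(max(abs(nlp$A %*% z - nlp$bA)), 1e-6)
  p <- nlp$eval_path(z)
  expect_lt(max(abs(p$C)), 1e-6)
  expect_lt(max(as.numeric(nlp$G %*% z - nlp$bG)), 1e-9)
})

test_that("initial guesses follow the stated construction", {
  m <- the_model()
  td <- flight_tracking(m, n_mesh = 10)
  nlp <- transcribe(m, td, ocp_config(n_mesh = 10))
  g <- make_initial_guesses(nlp)
  lay <- nlp$layout
  x <- nlp$to_x(g$data_informed)
  # kinematic channels copy the experimental data exactly
  for (node in c(0, 5, 30)) {
    tn <- nlp$node_t[node + 1]
    expect_equal(unname(x[lay$idx_x(node, lay$s_q[2])]),
                 1.4 + 0.5 * tn - 0.5 * m$gravity * tn^2, tolerance = 1e-9)
  }
  # remaining states at their lower bounds
  expect_true(all(x[lay$idx_x(3, lay$s_am)] == 0))
  expect_true(all(x[lay$idx_x(3, lay$s_ft)] == 0))
  # both guesses share the stated contact parameter values
  for (gz in g) {
    xp <- nlp$to_x(gz)[lay$off_p + 1:2]
    expect_equal(unname(xp[1]), 6)   # log10 of 1e6 N/m^2
    expect_equal(unname(xp[2]), 2)   # 2 s/m
  }
  expect_true(all(g$cold >= nlp$zlb - 1e-12 & g$cold <= nlp$zub + 1e-12))
})

test_that("the cost decomposition sums to the objective's quadratic value", {
  m <- the_model()
  td <- flight_tracking(m, n_mesh = 10)
  nlp <- transcribe(m, td, ocp_config(n_mesh = 10))
  z <- flight_feasible_z(nlp)
  ct <- hopsim:::nlp_cost_terms(nlp, z)
  expect_equal(ct$total, ct$J_effort + ct$J_tracking + ct$J_control,
               tolerance = 1e-12)
  obj <- hopsim:::nlp_objective(nlp, z)
  expect_equal(ct$total, obj$f, tolerance = 0.05 * max(1, abs(obj$f)))
})

test_that("solving the flight problem converges and stays near the data", {
  m <- the_model()
  td <- flight_tracking(m, n_mesh = 10)
  sol <- solve_tracking(m, td, ocp_config(n_mesh = 10, max_outer = 25),
                        guesses = "data_informed")
  expect_equal(sol$status, "converged")
  expect_lt(max(abs(sol$q - td$q)[, 3:7]) * 180 / pi, 1)
  expect_lt(max(abs(sol$tau_res)), 5)
})

test_that("solutions are invariant to the variable scaling", {
  m <- the_model()
  td <- flight_tracking(m, n_mesh = 6)
  cfg_on <- ocp_config(n_mesh = 6, max_outer = 25)
  cfg_off <- ocp_config(n_mesh = 6, max_outer = 25, scale_vars = FALSE)
  s_on <- solve_tracking(m, td, cfg_on, guesses = "data_informed")
  s_off <- solve_tracking(m, td, cfg_off, guesses = "data_informed")
  expect_equal(s_on$cost$total, s_off$cost$total,
               tolerance = 1e-4 * max(1, abs(s_on$cost$total)))
})
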