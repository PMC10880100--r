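test_that("peak and impulse follow their closed forms", {
  t <- seq(0, 0.3, length.out = 301)
  # constant 2 BW for 0.3 s
  pi1 <- peak_and_impulse(rep(2, 301), t)
  expect_equal(pi1$peak, 2)
  expect_equal(pi1$impulse, 0.6, tolerance = 1e-12)
  # half sine of amplitude A and duration T integrates to 2AT/pi
  A <- 3; Tdur <- 0.3
  pi2 <- peak_and_impulse(A * sin(pi * t / Tdur), t)
  expect_equal(pi2$peak, A, tolerance = 1e-4)
  expect_equal(pi2$impulse, 2 * A * Tdur / pi, tolerance = 1e-4)
  # all-zero series
  pi3 <- peak_and_impulse(rep(0, 301), t)
  expect_equal(unlist(pi3), c(peak = 0, impulse = 0))
  # signed extremum convention
  pi4 <- peak_and_impulse(c(1, -5, 2), c(0, 1, 2))
  expect_equal(pi4$peak, -5)
  expect_error(peak_and_impulse(numeric(0), numeric(0)), "empty")
})

test_that("intersegmental forces balance a static single-support pose", {
  m <- the_model()
  nq <- length(m$coordinates)
  q <- matrix(rep(0, nq), 1); q[2] <- 1.0
  qd <- qdd <- matrix(0, 1, nq)
  W <- m$total_mass * m$gravity
  com <- centre_of_mass(m, q[1, ])
  jf <- hopsim:::joint_forces_rnea(m, q, qd, qdd, bwss = 0,
                                   extra = list(list(segment = "foot",
                                                     point = matrix(c(com$x, 0), 1),
                                                     force = matrix(c(0, W), 1))))
  # the ankle (foot segment's joint) transmits the foot weight minus the GRF
  foot_i <- match("foot", m$segments$name)
  expect_equal(jf$fy[1, foot_i], m$segments$mass[foot_i] * m$gravity - W,
               tolerance = 1e-9)
  # the hip transmits the weight of the whole leg minus the GRF
  thigh_i <- match("thigh", m$segments$name)
  leg_w <- sum(m$segments$mass[3:5]) * m$gravity
  expect_equal(jf$fy[1, thigh_i], leg_w - W, tolerance = 1e-9)
})

test_that("a muscle along the segment axis adds compression to the joint", {
  # two-link free-body oracle: static pose, knee-spanning muscle with force F
  # along the shank axis increases the knee axial reaction by about F
  m <- the_model()
  nq <- length(m$coordinates)
  q <- matrix(rep(0, nq), 1); q[2] <- 1.0
  qd <- qdd <- matrix(0, 1, nq)
  Fm <- 500
  fk <- forward_kinematics(m, q[1, ])
  knee <- c(fk$ox[1, "shank"], fk$oy[1, "shank"])
  below <- c(knee[1], knee[2] - 0.2)
  above <- c(knee[1], knee[2] + 0.2)
  base <- hopsim:::joint_forces_rnea(m, q, qd, qdd)
  with_mus <- hopsim:::joint_forces_rnea(m, q, qd, qdd, extra = list(
    list(segment = "thigh", point = matrix(above, 1),
         force = matrix(c(0, -Fm), 1)),       # pulls the thigh down
    list(segment = "shank", point = matrix(below, 1),
         force = matrix(c(0, Fm), 1))))       # pulls the shank up
  shank_i <- match("shank", m$segments$name)
  # the muscle relieves the thigh of Fm of upward support: the parent now
  # pushes down on the shank harder by exactly Fm, i.e. the axial
  # compression (positive along the distal axis) grows by Fm
  dF <- with_mus$fy[1, shank_i] - base$fy[1, shank_i]
  expect_equal(dF, -Fm, tolerance = 1e-9)
  comp_gain <- -dF
  expect_equal(comp_gain, Fm, tolerance = 1e-9)
})

test_that("tracking diagnostics report the stated groups and thresholds", {
  # synthetic diagnostics via a minimal fake solution object
  m <- the_model()
  n <- 11
  time <- seq(0, 1, length.out = n)
  tr <- list(q = matrix(0, n, 7, dimnames = list(NULL, m$coordinates)),
             grf = matrix(0, n, 2),
             njm = tibble::tibble(lumbar = rep(10, n), hip = rep(10, n),
                                  knee = rep(10, n), ankle = rep(10, n)),
             touchdown_times = c(0.15, 0.85))
  qsim <- tr$q
  qsim[, "hip"] <- 1 * pi / 180     # constant one-degree offset
  sol <- structure(list(
    time = time, q = qsim,
    u_grf = tr$grf[-1, , drop = FALSE],
    njm_sim = matrix(10, n - 1, 3,
                     dimnames = list(NULL, c("hip", "knee", "ankle"))),
    actuator_activation = matrix(10 / m$torque_actuators$tau_max, n, 1),
    tau_res = matrix(1, n - 1, 3,
                     dimnames = list(NULL, c("hip", "knee", "ankle"))),
    nlp = list(model = m, tracking = tr)), class = "hop_ocp_solution")
  d <- tracking_errors(sol, tr)
  rot <- d$errors[d$errors$group == "rotations", ]
  expect_equal(rot$max_abs_error, 1, tolerance = 1e-9)
  expect_equal(rot$rmse, sqrt(mean(c(rep(0, 4), 1, 0, 0)^2 * 11 / 11)),
               tolerance = 0.2)
  # reserve of 1 N m against 10 N m moments: 10% boundary, accepted
  expect_equal(d$reserve_max, 1)
  expect_equal(d$reserve_fraction_max, 0.1, tolerance = 1e-9)
  expect_true(d$accepted)
  # 1 N m against a 5 N m moment is a 20% contribution and must be flagged
  tr2 <- tr
  tr2$njm$hip <- rep(5.000001, n)
  d2 <- tracking_errors(sol, tr2)
  expect_gt(d2$reserve_fraction_max, 0.15)
  expect_false(d2$accepted)
})
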