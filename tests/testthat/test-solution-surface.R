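# Result-object surface (tidiers, plots, files, downstream analyses) checked
# on a cheap converged problem: the short ballistic-flight trial from the
# tracking tests.

flight_solution <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- the_model()
      source_env <- new.env()
      # reuse the flight fixture defined in test-ocp-tracking.R
      td <- local({
        g0 <- m$gravity
        tgrid <- seq(0, 0.12, length.out = 11)
        nq <- length(m$coordinates)
        q <- matrix(0, 11, nq, dimnames = list(NULL, m$coordinates))
        q[, "pelvis_tx"] <- 0.05 * tgrid
        q[, "pelvis_ty"] <- 1.4 + 0.5 * tgrid - 0.5 * g0 * tgrid^2
        q[, "hip"] <- 0.4; q[, "knee"] <- -0.8; q[, "ankle"] <- 0.2
        qd <- matrix(0, 11, nq); qd[, 1] <- 0.05; qd[, 2] <- 0.5 - g0 * tgrid
        qdd <- matrix(0, 11, nq); qdd[, 2] <- -g0
        grf <- matrix(0, 11, 2, dimnames = list(NULL, c("grf_x", "grf_y")))
        id <- compute_net_joint_moments(m, q, qd, qdd, grf, rep(0, 11), 0)
        structure(list(time = tgrid, q = q, qd = qd, qdd = qdd, grf = grf,
                       cop = rep(0, 11), bwss = rep(0, 11),
                       njm = id$njm, residuals = id$residuals,
                       touchdown_times = c(0, 0.12), mass = m$total_mass,
                       g_level = 1), class = "hop_tracking")
      })
      cache <<- solve_tracking(m, td, ocp_config(n_mesh = 10, max_outer = 25),
                               guesses = "data_informed")
    }
    cache
  }
})

test_that("tidy and glance expose the solution in tabular form", {
  sol <- flight_solution()
  tb <- tidy(sol)
  expect_true(all(c("time", "channel", "group", "value") %in% names(tb)))
  expect_true(all(c("coordinate", "activation", "grf", "njm") %in% tb$group))
  gl <- glance(sol)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$status, "converged")
  expect_equal(gl$cost_total,
               gl$cost_effort + gl$cost_tracking + gl$cost_control,
               tolerance = 1e-9)
})

test_that("autoplot returns a ggplot of simulated vs experimental channels", {
  p <- autoplot(flight_solution())
  expect_s3_class(p, "ggplot")
})

test_that("solution files round-trip through the writers", {
  sol <- flight_solution()
  dir <- tempfile()
  write_solution(sol, dir)
  expect_true(file.exists(file.path(dir, "trajectories.tsv")))
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  js <- jsonlite::fromJSON(file.path(dir, "solution.json"))
  expect_equal(js$stiffness, sol$parameters$stiffness, tolerance = 1e-9)
})

test_that("joint reactions and load summaries are produced for a solution", {
  sol <- flight_solution()
  m <- sol$nlp$model
  jrf <- joint_reaction_forces(sol, m)
  expect_true(all(c("hip", "knee", "ankle", "lumbar") %in% names(jrf)))
  # in free flight the knee reaction carries no ground force: it stays of
  # the order of segment weights plus the (small) muscle forces
  expect_lt(max(abs(jrf$knee)), 500)
  loads <- joint_load_summary(sol, m)
  expect_equal(sort(loads$joint), sort(muscle_driven_coords(m)))
  expect_true(all(is.finite(loads$peak_jrf)))
  # lab-frame variant runs and differs in general
  jrf_lab <- joint_reaction_forces(sol, m, frame = "lab")
  expect_equal(dim(jrf_lab), dim(jrf))
})

test_that("a quadriceps profile feeds the adaptation pipeline end to end", {
  sol <- flight_solution()
  prof <- quadriceps_profile(sol, sol$nlp$model)
  expect_true(all(prof$f_quad_norm >= 0))
  tv <- training_volume(prof, adaptation_params())
  expect_equal(nrow(tv), 1)
  # a passive flight phase cannot reach the hypertrophy threshold
  expect_false(tv$feasible)
})
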