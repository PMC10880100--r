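test_that("training pose sampling is deterministic and covers the ranges", {
  ranges <- list(hip = c(-0.5, 1.2), knee = c(-1.8, 0.3), ankle = c(-1, 0.8))
  p1 <- sample_training_poses(ranges, n = 1000, seed = 7)
  p2 <- sample_training_poses(ranges, n = 1000, seed = 7)
  expect_identical(p1, p2)
  for (cn in names(ranges)) {
    x <- p1[[cn]]
    expect_true(all(x >= ranges[[cn]][1] & x <= ranges[[cn]][2]))
    spread <- diff(range(x)) / diff(ranges[[cn]])
    expect_gte(spread, 0.9)
  }
  expect_error(sample_training_poses(ranges, n = 10, min_n = 30), "at least 30")
})

test_that("polynomial fit recovers a polynomial reference exactly", {
  # reference length that is itself a polynomial of the model class
  expo <- hopsim:::monomial_exponents(2, 3)
  set.seed(3)
  coef_true <- rnorm(nrow(expo), sd = 0.01)
  q <- as.matrix(sample_training_poses(list(a = c(-1, 1), b = c(-1, 1)),
                                       n = 400, seed = 11))
  X <- hopsim:::monomial_basis(q, expo)
  L <- X %*% coef_true
  cf <- qr.coef(qr(X), L)
  expect_lt(max(abs(X %*% cf - L)), 1e-12)
  expect_equal(as.numeric(cf), coef_true, tolerance = 1e-9)
})

test_that("fitted moment arms agree with the exact geometry on held-out poses", {
  m <- the_model()
  held <- sample_training_poses(m$rom, n = 200, seed = 99)
  Q <- matrix(0, 200, length(m$coordinates),
              dimnames = list(NULL, m$coordinates))
  for (cn in names(m$rom)) Q[, cn] <- held[[cn]]
  ev <- eval_mtu(m, Q, warn_domain = FALSE)
  # lengths match the exact via-point geometry
  Lref <- mtu_length_reference(m, Q)
  expect_lt(max(abs(ev$length - Lref)), 3e-3)
  # moment arms match central differences of the exact length
  arms_ref <- mtu_moment_arm_reference(m, Q, m$coordinates[4:7])
  for (j in seq_along(m$polynomials)) {
    p <- m$polynomials[[j]]
    ref <- arms_ref[[p$mtu_name]][, match(p$coord_names, m$coordinates[4:7]), drop = FALSE]
    expect_lt(max(abs(ev$moment_arms[[p$mtu_name]] - ref)), 1e-2)
  }
})

test_that("held-out error is non-increasing with polynomial degree", {
  m2 <- fit_mtu_polynomials(the_model(), degree = 2, tol = 0.05)
  m4 <- fit_mtu_polynomials(the_model(), degree = 4, tol = 0.05)
  held <- sample_training_poses(m2$rom, n = 300, seed = 123)
  Q <- matrix(0, 300, length(m2$coordinates),
              dimnames = list(NULL, m2$coordinates))
  for (cn in names(m2$rom)) Q[, cn] <- held[[cn]]
  Lref <- mtu_length_reference(m2, Q)
  e2 <- max(abs(eval_mtu(m2, Q, warn_domain = FALSE)$length - Lref))
  e4 <- max(abs(eval_mtu(m4, Q, warn_domain = FALSE)$length - Lref))
  expect_lte(e4, e2 + 1e-12)
})

test_that("eval_mtu velocities follow the chain rule", {
  m <- the_model()
  nq <- length(m$coordinates)
  # zero velocity
  q <- c(0, 1, 0, 0, 0.3, -0.6, 0.1)
  ev0 <- eval_mtu(m, q, rep(0, nq))
  expect_true(all(ev0$velocity == 0))
  # single-coordinate muscle: velocity / qd = -moment arm
  qd <- rep(0, nq); qd[coord <- match("ankle", m$coordinates)] <- 0.7
  ev1 <- eval_mtu(m, q, qd)
  r_sol <- ev1$moment_arms[["soleus"]][1, 1]
  expect_equal(unname(ev1$velocity[1, "soleus"] / 0.7), unname(-r_sol), tolerance = 1e-12)
  # random state: velocity equals d(length)/dt along a trajectory
  set.seed(5)
  qr_ <- q + rnorm(nq, sd = 0.1); qdr <- rnorm(nq, sd = 0.5)
  h <- 1e-6
  Lp <- eval_mtu(m, qr_ + h * qdr, warn_domain = FALSE)$length
  Lm <- eval_mtu(m, qr_ - h * qdr, warn_domain = FALSE)$length
  evr <- eval_mtu(m, qr_, qdr, warn_domain = FALSE)
  expect_equal(as.numeric(evr$velocity), as.numeric((Lp - Lm) / (2 * h)),
               tolerance = 1e-6)
})

test_that("moment arm / length-derivative identity is exact for the polynomials", {
  m <- the_model()
  set.seed(8)
  q <- c(0, 1, 0, 0.1, 0.5, -0.9, 0.3)
  h <- 1e-7
  for (j in seq_along(m$polynomials)) {
    p <- m$polynomials[[j]]
    for (k in seq_along(p$coords)) {
      qp <- q; qp[p$coords[k]] <- qp[p$coords[k]] + h
      qm <- q; qm[p$coords[k]] <- qm[p$coords[k]] - h
      dL <- unname((eval_mtu(m, qp)$length[1, j] - eval_mtu(m, qm)$length[1, j]) / (2 * h))
      r <- eval_mtu(m, q)$moment_arms[[j]][1, k]
      expect_equal(r, -dL, tolerance = 1e-6)
    }
  }
})

test_that("fitted lengths are strictly positive over the fit domain", {
  m <- the_model()
  held <- sample_training_poses(m$rom, n = 500, seed = 17)
  Q <- matrix(0, 500, length(m$coordinates),
              dimnames = list(NULL, m$coordinates))
  for (cn in names(m$rom)) Q[, cn] <- held[[cn]]
  ev <- eval_mtu(m, Q, warn_domain = FALSE)
  expect_true(all(ev$length > 0))
})
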