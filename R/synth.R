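#' Synthetic-experiment configuration
#'
#' Defines the conditions of the emulated hopping study: five gravity levels,
#' metronome-paced hopping at about 2 Hz, per-condition ground-contact times,
#' and additive measurement noise. Defaults reproduce the study conditions:
#' contact times rise from 0.27-0.29 s in deep hypogravity to 0.34 s at 1 g,
#' the participant is 79.9 kg / 1.82 m, and noise is 0.5 degrees on joint
#' angles (2 mm on pelvis translations) and 5 N on force channels.
#'
#' @param g_levels gravity conditions (fractions of 1 g).
#' @param hop_frequency hopping frequency (Hz).
#' @param contact_times named per-condition ground contact times (s).
#' @param n_trials trials per condition.
#' @param noise_kin_deg kinematic noise SD (degrees; translations use
#'   `noise_kin_deg / 250` metres).
#' @param noise_force_n force-channel noise SD (N).
#' @param mass,height participant anthropometrics.
#' @param rate_kin,rate_force sampling rates (Hz).
#' @param stiffness,damping true foot-ground contact parameters used to
#'   synthesise the ground reaction forces.
#' @param crouch_depth baseline stance crouch modulation of the joint bumps.
#' @param seed base seed; every trial derives its own stream from it.
#' @return A list of class `hop_synth_config`.
#' @export
synth_config <- function(g_levels = c(0.17, 0.25, 0.37, 0.50, 1.0),
                         hop_frequency = 2,
                         contact_times = c(`0.17` = 0.29, `0.25` = 0.27,
                                           `0.37` = 0.28, `0.5` = 0.32,
                                           `1` = 0.34),
                         n_trials = 5,
                         noise_kin_deg = 0.5,
                         noise_force_n = 5,
                         mass = 79.9, height = 1.82,
                         rate_kin = 200, rate_force = 2000,
                         stiffness = 2e6, damping = 0.2,
                         crouch_depth = 1.0,
                         seed = 1) {
  structure(list(g_levels = g_levels, hop_frequency = hop_frequency,
                 contact_times = contact_times, n_trials = n_trials,
                 noise_kin_deg = noise_kin_deg, noise_force_n = noise_force_n,
                 mass = mass, height = height,
                 rate_kin = rate_kin, rate_force = rate_force,
                 stiffness = stiffness, damping = damping,
                 crouch_depth = crouch_depth, seed = seed),
            class = "hop_synth_config")
}

condition_contact_time <- function(config, g_level) {
  key <- as.character(g_level)
  if (key %in% names(config$contact_times)) return(config$contact_times[[key]])
  gk <- as.numeric(names(config$contact_times))
  approx(gk, as.numeric(config$contact_times), xout = g_level, rule = 2)$y
}

# periodic helpers on a uniform cycle grid ----------------------------------
periodic_derivative <- function(x, dt) {
  n <- length(x)
  (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / (2 * dt)
}
periodic_cumint <- function(x, dt) {
  # trapezoidal antiderivative starting at 0
  n <- length(x)
  c(0, cumsum((x[-n] + x[-1]) / 2 * dt))[1:n]
}

#' Reference hopping motion for one gravity condition
#'
#' Template-based periodic single-leg hopping: raised-cosine flexion bumps on
#' the joint angles during stance (ankle-dominant in hypogravity, with hip
#' and knee excursion growing towards 1 g), constant limb posture in flight,
#' plus two consistency passes that make the motion dynamically tractable:
#' a hip correction keeping the whole-body centre of mass above the planted
#' ankle, and an iterative vertical pass that adjusts the pelvis path until
#' the vertical acceleration of the centre of mass pointwise matches the
#' contact-model ground reaction force plus body-weight support minus body
#' weight.
#'
#' @param model a [hop_model()].
#' @param config a [synth_config()].
#' @param g_level gravity condition.
#' @param trial trial index (small deterministic amplitude jitter per trial).
#' @return List with the cycle grid `phase` (s), coordinate matrix `q_cycle`,
#'   contact/cycle timing, the achieved GRF, and consistency diagnostics.
#' @export
generate_reference_motion <- function(model, config, g_level, trial = 1) {
  g0 <- model$gravity
  m <- model$total_mass
  f <- config$hop_frequency
  Tc <- 1 / f
  tc <- condition_contact_time(config, g_level)
  if (tc >= Tc) stop(sprintf("infeasible timing: contact time %.3f s >= period %.3f s", tc, Tc))
  bw <- bwss_force(g_level, model)
  seed <- config$seed * 10000 + round(g_level * 100) * 10 + trial
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  jit <- function() 1 + 0.03 * rnorm(1)

  dt <- 1 / config$rate_force
  phase <- seq(0, Tc - dt, by = dt)
  n <- length(phase)
  stance <- phase < tc
  b <- ifelse(stance, sin(pi * phase / tc)^2, 0)
  cd <- config$crouch_depth
  ge <- max(0, (g_level - 0.5) / 0.5)
  amp <- list(
    lumbar = 0.02 * jit(),
    hip   = cd * (0.05 + 0.03 * g_level + 0.25 * ge) * jit(),
    knee  = cd * (0.10 + 0.08 * g_level + 0.45 * ge) * jit()
  )
  base <- c(lumbar = 0, hip = 0.25, knee = -0.45)
  # forefoot hopping: the foot keeps a constant, slightly plantarflexed world
  # pitch, so only the toe sphere bears load and the contact point does not
  # sweep under the foot; the ankle dorsiflexion pattern then emerges from
  # the hip and knee flexion (and grows with gravity, as the hip/knee bumps
  # do), rather than being templated separately
  foot_pitch <- -0.2
  nq <- length(model$coordinates)
  Q <- matrix(0, n, nq, dimnames = list(NULL, model$coordinates))
  Q[, "lumbar"] <- base["lumbar"] + amp$lumbar * b
  Q[, "hip"]   <- base["hip"] + amp$hip * b
  Q[, "knee"]  <- base["knee"] - amp$knee * b
  Q[, "ankle"] <- foot_pitch - Q[, "hip"] - Q[, "knee"]

  # --- ground reaction force profile and centre-of-mass path --------------
  # The vertical GRF is prescribed as a raised-cosine pulse over stance,
  # scaled so that its impulse exactly balances the effective (offloaded)
  # weight over one cycle. Double integration of the resulting com
  # acceleration gives a periodic com height path that is pointwise
  # consistent with the prescribed force by construction.
  A <- 2 * g_level * m * g0 * Tc / tc
  grf_req <- ifelse(stance, A * sin(pi * phase / tc)^2, 0)
  grf_req <- grf_req * (g_level * m * g0 * Tc) / (sum(grf_req) * dt)
  acc <- (grf_req + bw - m * g0) / m
  acc <- acc - mean(acc)
  v_com <- periodic_cumint(acc, dt); v_com <- v_com - mean(v_com)
  y_rel <- periodic_cumint(v_com, dt)

  blob <- model_blob_bare(model)
  zero <- matrix(0, n, nq)
  wseg <- model$segments$mass / m
  foot_i <- segment_index(model, "foot")
  sph <- as.matrix(model$spheres[, c("x", "y")])
  radius <- model$contact$radius
  cpars <- model$contact
  offsets <- function(Q) {
    fk <- cpp_forward_kinematics(blob, Q, zero, zero)
    kin <- cpp_sphere_kinematics(blob, Q, zero, sph)
    list(com_x = as.numeric(fk$cx %*% wseg),
         com_y = as.numeric(fk$cy %*% wseg),
         sph_y = kin$cy, sph_x = kin$cx,
         ankle_x = fk$ox[, foot_i])
  }
  off0 <- offsets(Q)
  # anchor: lowest sphere just touches the ground at touchdown (phase 0)
  y_com <- y_rel - y_rel[1] + (radius - min(off0$sph_y[1, ])) + off0$com_y[1]
  toe_i <- which.max(model$spheres$x)
  u_target <- 0                      # com directly above the loaded toe sphere

  # --- per-sample corrections ----------------------------------------------
  # Two alternating 1-D solves per sample: a hip correction swings the leg so
  # the whole-body com stays above the loaded toe sphere (near-linear
  # geometry, Newton),
  # and a knee correction places the foot at the depth where the contact
  # model reproduces the prescribed GRF (total contact force is monotone in
  # knee extension, so safeguarded bisection always converges). The passes
  # contract because the hip's effect on foot height and the knee's effect on
  # the com offset are both weak relative to the primary levers. In flight
  # the corrections are blended smoothly between the stance boundary values.
  knee_i <- coord_index(model, "knee")
  hip_i <- coord_index(model, "hip")
  ankle_i <- coord_index(model, "ankle")
  solve_mask <- stance & grf_req > 1
  i_first <- which(solve_mask)[1]
  i_last <- tail(which(solve_mask), 1)
  gap_idx <- c((i_last + 1):n, seq_len(max(i_first - 1, 0)))
  blend_gap <- function(dvec) {
    # C1 cubic Hermite across the flight arc: matches the values and slopes
    # of the stance solution at both boundaries, so the joint trajectories
    # carry no velocity kinks into the inverse dynamics
    ng <- length(gap_idx)
    p0 <- dvec[i_last]; p1 <- dvec[i_first]
    m0 <- (dvec[i_last] - dvec[i_last - 1])           # per-sample slope
    m1 <- (dvec[i_first + 1] - dvec[i_first])
    x <- seq_len(ng) / (ng + 1)
    h00 <- 2 * x^3 - 3 * x^2 + 1
    h10 <- x^3 - 2 * x^2 + x
    h01 <- -2 * x^3 + 3 * x^2
    h11 <- x^3 - x^2
    dvec[gap_idx] <- h00 * p0 + h10 * (ng + 1) * m0 + h01 * p1 + h11 * (ng + 1) * m1
    dvec
  }
  build_q <- function(d_kn, d_hp) {
    Qt <- Q
    Qt[, knee_i] <- Qt[, knee_i] + d_kn
    Qt[, hip_i] <- Qt[, hip_i] + d_hp
    # counter-rotate the ankle so the corrections translate the foot without
    # pitching it: keeps the contact force monotone in knee extension
    Qt[, ankle_i] <- Qt[, ankle_i] - d_kn - d_hp
    Qt
  }
  fy_tot <- function(off, sphd_prev) {
    pel <- y_com - off$com_y
    tot <- 0
    for (s in seq_len(nrow(sph))) {
      pen <- radius - (pel + off$sph_y[, s])
      tot <- tot + cpp_contact_force(pen, sphd_prev[, s], rep(0, n),
                                     config$stiffness, config$damping,
                                     cpars$mu, cpars$v0, cpars$eps_d,
                                     cpars$eps_f)$normal
    }
    tot
  }
  lumbar_i <- coord_index(model, "lumbar")
  lumbar0 <- Q[, lumbar_i]
  run_inner <- function(lumb_corr) {
    # rebuild the template with the current lumbar (torso) path; the lumbar
    # joint does not enter the leg chain, so the contact solves below are
    # unaffected except through the (small) com shift, and the ankle column
    # keeps the foot pitch fixed in the world frame
    Q[, lumbar_i] <- lumbar0 + lumb_corr
    Q[, ankle_i] <- foot_pitch - Q[, 3] - Q[, hip_i] - Q[, knee_i]
    Q <<- Q
    d_kn <- rep(0, n); d_hp <- rep(0, n)
    sphd <- matrix(0, n, nrow(sph))
    Qt <- Q; QDt <- zero; kin <- NULL
    for (pass in 1:8) {
      # (a) hip: Newton on the com-over-toe residual
      for (nw in 1:6) {
        off <- offsets(build_q(d_kn, d_hp))
        gap <- off$com_x - off$sph_x[, toe_i] - u_target
        if (max(abs(gap)) < 1e-10) break
        offh <- offsets(build_q(d_kn, d_hp + 1e-6))
        slope <- (offh$com_x - offh$sph_x[, toe_i] - (gap + u_target)) / 1e-6
        d_hp <- d_hp - pmin(pmax(gap / slope, -0.2), 0.2)
      }
      # (b) knee: bisection on the monotone force-depth relation
      lo <- rep(-0.8, n); hi <- rep(0.6, n)
      for (bi in 1:40) {
        mid <- (lo + hi) / 2
        Fm <- fy_tot(offsets(build_q(mid, d_hp)), sphd)
        high <- Fm > grf_req
        hi[high] <- mid[high]; lo[!high] <- mid[!high]
      }
      d_kn[solve_mask] <- ((lo + hi) / 2)[solve_mask]
      d_kn <- blend_gap(d_kn)
      # refresh kinematics and penetration velocities for the damping term
      Qt <- build_q(d_kn, d_hp)
      off <- offsets(Qt)
      Qt[, 2] <- y_com - off$com_y
      Qt[, 1] <- -off$com_x
      QDt <- zero
      for (j in seq_len(nq)) QDt[, j] <- periodic_derivative(Qt[, j], dt)
      kin <- cpp_sphere_kinematics(blob, Qt, QDt, sph)
      # under-relaxed update, clamped to physical stance-phase speeds, keeps
      # the damping-term feedback contractive
      sphd <- 0.5 * sphd + 0.5 * pmin(pmax(kin$penetration_velocity, -2), 2)
    }
    fx <- fy <- matrix(0, n, nrow(sph))
    for (s in seq_len(nrow(sph))) {
      fr <- cpp_contact_force(kin$penetration[, s], kin$penetration_velocity[, s],
                              kin$slip_velocity[, s],
                              config$stiffness, config$damping,
                              cpars$mu, cpars$v0, cpars$eps_d, cpars$eps_f)
      fx[, s] <- fr$tangential; fy[, s] <- fr$normal
    }
    list(Q = Qt, QD = QDt, kin = kin, fx = fx, fy = fy,
         com_y = off$com_y)
  }

  # --- outer angular-momentum pass -----------------------------------------
  # The remaining systematic inconsistency is the angular-momentum (pelvis
  # tilt row) residual. A Newton update on the lumbar (torso counter-swing)
  # path removes it: the tilt-row moment responds to an added lumbar
  # acceleration through the corresponding joint-space mass-matrix entry,
  # and the lumbar joint does not disturb the foot-contact solves.
  lumb_corr <- rep(0, n)
  inner <- NULL
  res_tilt <- NULL
  n_outer <- 8
  for (outer in seq_len(n_outer)) {
    inner <- run_inner(lumb_corr)
    QDDt <- apply(inner$QD, 2, periodic_derivative, dt = dt)
    extras <- lapply(seq_len(nrow(sph)), function(s) {
      list(segment = "foot",
           point = cbind(inner$kin$cx[, s], inner$kin$cy[, s]),
           force = cbind(inner$fx[, s], inner$fy[, s]))
    })
    tau <- as.matrix(inverse_dynamics(model, inner$Q, inner$QD, QDDt,
                                      bwss = bw, extra = extras))
    res_tilt <- tau[, 3]
    if (outer == n_outer || max(abs(res_tilt)) < 5) break
    elum <- rep(0, nq); elum[lumbar_i] <- 1
    tau1 <- cpp_inverse_dynamics(blob, inner$Q, zero,
                                 matrix(rep(elum, each = n), n, nq),
                                 integer(0), list(), list(), list())
    tau0 <- cpp_inverse_dynamics(blob, inner$Q, zero, zero,
                                 integer(0), list(), list(), list())
    M34 <- tau1[, 3] - tau0[, 3]
    alpha_corr <- -res_tilt / M34
    alpha_corr <- alpha_corr - mean(alpha_corr)
    vtc <- periodic_cumint(alpha_corr, dt); vtc <- vtc - mean(vtc)
    dtc <- periodic_cumint(vtc, dt); dtc <- dtc - mean(dtc)
    lumb_corr <- lumb_corr + 0.7 * dtc
  }
  Qf <- inner$Q; QDf <- inner$QD; kin <- inner$kin

  grf_y <- rowSums(inner$fy)
  grf_x <- rowSums(inner$fx)
  imp <- sum(grf_y + bw - m * g0) * dt
  if (abs(imp) > 0.02 * m * g0 * Tc) {
    stop(sprintf("impulse balance not achieved: residual %.2f N s over the cycle", imp))
  }
  com_y_path <- Qf[, 2] + inner$com_y
  resid <- max(abs(m * periodic_derivative(periodic_derivative(com_y_path, dt), dt) -
                     (grf_y + bw - m * g0)))
  copx <- rowSums(inner$fy * kin$cx) / ifelse(grf_y > 1, grf_y, NA)
  list(phase = phase, q_cycle = Qf, qd_cycle = QDf,
       grf_x = grf_x, grf_y = grf_y, cop_x = copx,
       contact_time = tc, period = Tc, bwss = bw,
       vertical_residual = resid,
       tilt_residual = max(abs(res_tilt)), seed = seed)
}

#' Generate one synthetic trial for a gravity condition
#'
#' Tiles the periodic reference motion into a trial containing two
#' touchdowns plus handling margins, samples kinematics and forces at their
#' respective rates, and adds the configured measurement noise. The ground
#' reaction force is the contact-model force along the motion, so the trial
#' is (up to noise and a small tilt imbalance) dynamically consistent.
#'
#' @param model a [hop_model()].
#' @param config a [synth_config()].
#' @param g_level gravity condition (must be in `config$g_levels` range).
#' @param trial trial index.
#' @return A [raw_trial()]; attributes `truth` records the generating
#'   contact parameters and timing.
#' @export
generate_condition_trial <- function(model, config, g_level, trial = 1) {
  ref <- generate_reference_motion(model, config, g_level, trial)
  Tc <- ref$period
  t_td1 <- 0.55                       # trial starts and ends in flight
  t_end <- t_td1 + 2 * Tc + 0.35
  state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed((ref$seed + 5000) %% .Machine$integer.max)

  cyc_fun <- function(x) {
    # periodic interpolant over the cycle
    ph <- c(ref$phase, Tc)
    xx <- c(x, x[1])
    sf <- splinefun(ph, xx, method = "periodic")
    function(t) sf((t - t_td1) %% Tc)
  }
  t_kin <- seq(0, t_end, by = 1 / config$rate_kin)
  t_frc <- seq(0, t_end, by = 1 / config$rate_force)
  nq <- ncol(ref$q_cycle)
  kin <- tibble::tibble(time = t_kin)
  sd_rot <- config$noise_kin_deg * pi / 180
  sd_tr <- config$noise_kin_deg / 250
  for (j in seq_len(nq)) {
    cn <- colnames(ref$q_cycle)[j]
    v <- cyc_fun(ref$q_cycle[, j])(t_kin)
    sdj <- if (cn %in% c("pelvis_tx", "pelvis_ty")) sd_tr else sd_rot
    kin[[cn]] <- v + rnorm(length(t_kin), sd = sdj)
  }
  copf <- {
    cop <- ref$cop_x
    ok <- !is.na(cop)
    # hold the last stance value through flight (masked out on use anyway)
    sf <- approxfun(ref$phase[ok], cop[ok], rule = 2)
    function(t) sf((t - t_td1) %% Tc)
  }
  grf_y <- cyc_fun(ref$grf_y)(t_frc)
  frc <- tibble::tibble(
    time = t_frc,
    grf_x = cyc_fun(ref$grf_x)(t_frc) + rnorm(length(t_frc), sd = config$noise_force_n),
    grf_y = grf_y + rnorm(length(t_frc), sd = config$noise_force_n),
    cop_x = ifelse(grf_y > 10, copf(t_frc), NA),
    bwss = ref$bwss + rnorm(length(t_frc), sd = config$noise_force_n / 2)
  )
  out <- raw_trial(kin, frc, mass = config$mass, g_level = g_level,
                   rate_kin = config$rate_kin, rate_force = config$rate_force)
  attr(out, "truth") <- list(stiffness = config$stiffness,
                             damping = config$damping,
                             contact_time = ref$contact_time,
                             period = ref$period, t_td1 = t_td1,
                             vertical_residual = ref$vertical_residual)
  out
}

#' Generate the full synthetic experiment
#'
#' @param model a [hop_model()].
#' @param config a [synth_config()].
#' @param out_dir optional directory: trials are also written as
#'   tab-delimited files `trial_g<level>_<k>_{kinematics,forces}.tsv`.
#' @return Tibble with `g_level`, `trial`, `stem` (if written) and the trial
#'   objects in a list column.
#' @export
generate_trials <- function(model, config = synth_config(), out_dir = NULL) {
  grid <- expand.grid(trial = seq_len(config$n_trials),
                      g_level = config$g_levels)
  trials <- purrr::map2(grid$g_level, grid$trial,
                        function(g, k) generate_condition_trial(model, config, g, k))
  stems <- rep(NA_character_, nrow(grid))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stems <- file.path(out_dir, sprintf("trial_g%03d_%d",
                                        round(100 * grid$g_level), grid$trial))
    purrr::walk2(trials, stems, write_trial)
  }
  tibble::tibble(g_level = grid$g_level, trial = grid$trial,
                 stem = stems, raw = trials)
}

#' Tracking data straight from a reference motion
#'
#' Builds OCP-ready tracking data directly from the generator's periodic
#' reference cycle, bypassing sampling, noise and filtering: the kinematic
#' derivatives are the exact periodic derivatives, the GRF is the
#' contact-model force, and the net joint moments follow by inverse
#' dynamics. The result is dynamically consistent up to the generator's own
#' residuals, which makes it the natural input for self-consistency
#' (inverse-crime) experiments such as contact-parameter recovery.
#'
#' @param model a [hop_model()].
#' @param config a [synth_config()] (use zero noise for a clean experiment).
#' @param g_level gravity condition.
#' @param trial trial index.
#' @param n_mesh mesh intervals of the output grid.
#' @return A `hop_tracking` object covering one cycle plus the standard
#'   0.15 s margins (wrapping the periodic cycle).
#' @export
tracking_from_reference <- function(model, config, g_level, trial = 1,
                                    n_mesh = 50) {
  ref <- generate_reference_motion(model, config, g_level, trial)
  Tc <- ref$period
  dt <- diff(ref$phase[1:2])
  # grid spanning [td - 0.15, td + Tc + 0.15] by periodic extension
  tgrid <- seq(-0.15, Tc + 0.15, length.out = n_mesh + 1)
  idx_of <- function(t) {
    ph <- t %% Tc
    round(ph / dt) %% length(ref$phase) + 1
  }
  ii <- vapply(tgrid, idx_of, numeric(1))
  nq <- ncol(ref$q_cycle)
  q <- ref$q_cycle[ii, , drop = FALSE]
  qd <- ref$qd_cycle[ii, , drop = FALSE]
  qdd <- apply(ref$qd_cycle, 2, periodic_derivative, dt = dt)[ii, , drop = FALSE]
  colnames(q) <- colnames(qd) <- colnames(qdd) <- model$coordinates
  grf <- cbind(grf_x = ref$grf_x[ii], grf_y = ref$grf_y[ii])
  cop <- ref$cop_x
  okc <- !is.na(cop)
  copf <- approxfun(ref$phase[okc], cop[okc], rule = 2)
  cop_g <- copf(tgrid %% Tc)
  bw <- rep(ref$bwss, length(tgrid))
  id <- compute_net_joint_moments(model, q, qd, qdd, grf, cop_g, bw)
  structure(list(time = tgrid + 0.15, q = q, qd = qd, qdd = qdd,
                 grf = grf, cop = cop_g, bwss = bw,
                 njm = id$njm, residuals = id$residuals,
                 touchdown_times = c(0.15, 0.15 + Tc),
                 mass = config$mass, g_level = g_level),
            class = "hop_tracking")
}
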