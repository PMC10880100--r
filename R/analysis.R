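#' Joint reaction forces of a tracking solution
#'
#' Reaction force transmitted across each joint, including the muscle
#' contributions: every muscle's tendon force is applied to the model as a
#' pair of point forces at its end attachments (directed along the path),
#' the contact and body-weight-support forces are applied externally, and a
#' recursive Newton-Euler pass returns the net force each parent segment
#' applies to its child. The reported component is the force along the child
#' segment's long axis (compression positive), which for the knee is the
#' force applied to the tibia by the femur; a `frame = "lab"` switch reports
#' the lab-frame vertical component instead.
#'
#' @param solution a `hop_ocp_solution`.
#' @param model the [hop_model()] used to build it.
#' @param frame `"segment"` (axial force in the child frame, default) or
#'   `"lab"` (world-vertical component).
#' @param tol refuse solutions whose pelvis residual feasibility is above
#'   this (dynamically inconsistent solutions give meaningless reactions).
#' @return tibble: `time`, one column per articulated joint (N, compression
#'   positive).
#' @export
joint_reaction_forces <- function(solution, model, frame = c("segment", "lab"),
                                  tol = 1e-3) {
  frame <- match.arg(frame)
  if (solution$feasibility > tol) {
    stop(sprintf(paste0("solution feasibility %.2e exceeds %.0e: pelvis ",
                        "residuals are not zero, reactions would be invalid"),
                 solution$feasibility, tol))
  }
  nlp <- solution$nlp
  lay <- nlp$layout
  uz <- nlp$unpack(hopsim_solution_z(solution))
  # mesh points 1..K (controls exist there)
  Xm <- uz$X[nlp$mesh_nodes + 1, , drop = FALSE]
  q <- Xm[, lay$s_q, drop = FALSE]
  qd <- Xm[, lay$s_qd, drop = FALSE]
  qdd <- uz$V[nlp$mesh_cn, lay$v_qdd, drop = FALSE]
  ft <- Xm[, lay$s_ft, drop = FALSE]
  par <- nlp$nat_par(uz$par)
  nt <- nrow(q)
  blob <- model_blob_bare(model)
  fk <- cpp_forward_kinematics(blob, q, qd, qdd)
  # contact forces at the optimised sphere positions
  spos <- matrix(par[-(1:2)], ncol = 2, byrow = TRUE)
  sph <- sphere_contact_forces(model, q, qd, stiffness = par[1],
                               damping = par[2], spheres = spos)
  extra <- list()
  for (s in seq_len(nrow(spos))) {
    extra[[length(extra) + 1]] <- list(
      segment = "foot", point = cbind(sph$cx[, s], sph$cy[, s]),
      force = cbind(sph$force_x[, s], sph$force_y[, s]))
  }
  # muscle forces as point-force pairs at the path end attachments
  pathpts <- muscle_endpoint_world(model, fk)
  for (j in seq_len(nrow(model$mtus))) {
    Ften <- ft[, j] * model$mtus$f_max_iso[j]
    o <- pathpts[[j]]$origin; i <- pathpts[[j]]$insertion
    dvec <- cbind(i$x - o$x, i$y - o$y)
    dlen <- sqrt(rowSums(dvec^2))
    u <- dvec / dlen
    extra[[length(extra) + 1]] <- list(
      segment = pathpts[[j]]$origin_segment,
      point = cbind(o$x, o$y), force = cbind(Ften * u[, 1], Ften * u[, 2]))
    extra[[length(extra) + 1]] <- list(
      segment = pathpts[[j]]$insertion_segment,
      point = cbind(i$x, i$y), force = cbind(-Ften * u[, 1], -Ften * u[, 2]))
  }
  jf <- joint_forces_rnea(model, q, qd, qdd,
                          bwss = rep(nlp$bw, nt), extra = extra)
  out <- tibble::tibble(time = solution$time[-1])
  seg <- model$segments
  for (i in which(!is.na(seg$parent))) {
    jn <- seg$parent_joint[i]
    fx <- jf$fx[, i]; fy <- jf$fy[, i]
    if (frame == "lab") {
      comp <- fy
    } else {
      # child long axis points from the joint towards the distal end
      # (local -y for limb segments, +y for the torso): compression is the
      # force component pulling the child towards the joint
      axis_sign <- if (seg$name[i] == "torso") 1 else -1
      th <- fk$theta[, i]
      ax <- -sin(th) * axis_sign; ay <- cos(th) * axis_sign
      comp <- fx * ax + fy * ay
    }
    out[[jn]] <- comp
  }
  out
}

# world positions of each muscle's first and last via point
muscle_endpoint_world <- function(model, fk) {
  lapply(model$paths, function(p) {
    first <- p[1, ]; last <- p[nrow(p), ]
    w <- function(pt) {
      si <- segment_index(model, pt$segment)
      th <- fk$theta[, si]
      list(x = fk$ox[, si] + cos(th) * pt$x - sin(th) * pt$y,
           y = fk$oy[, si] + sin(th) * pt$x + cos(th) * pt$y)
    }
    list(origin = w(first), insertion = w(last),
         origin_segment = first$segment, insertion_segment = last$segment)
  })
}

# recursive Newton-Euler pass that also returns the intersegmental joint
# forces (force applied by the parent on each segment, world frame)
joint_forces_rnea <- function(model, q, qd, qdd, bwss = 0, extra = list()) {
  nt <- nrow(q)
  blob <- model_blob_bare(model)
  fk <- cpp_forward_kinematics(blob, q, qd, qdd)
  seg <- model$segments
  nseg <- nrow(seg)
  g0 <- model$gravity
  # net external force on each segment (world), per time
  ex_fx <- ex_fy <- matrix(0, nt, nseg)
  ex_nz <- matrix(0, nt, nseg)          # about segment joint origin
  add_force <- function(si, px, py, fx, fy) {
    ex_fx[, si] <<- ex_fx[, si] + fx
    ex_fy[, si] <<- ex_fy[, si] + fy
    ex_nz[, si] <<- ex_nz[, si] + (px - fk$ox[, si]) * fy - (py - fk$oy[, si]) * fx
  }
  if (any(bwss != 0)) {
    th <- fk$theta[, 1]
    cx <- fk$ox[, 1] + cos(th) * seg$com_x[1] - sin(th) * seg$com_y[1]
    cy <- fk$oy[, 1] + sin(th) * seg$com_x[1] + cos(th) * seg$com_y[1]
    add_force(1, cx, cy, 0, rep_len(bwss, nt))
  }
  for (e in extra) {
    add_force(segment_index(model, e$segment), e$point[, 1], e$point[, 2],
              e$force[, 1], e$force[, 2])
  }
  fx <- fy <- nz <- matrix(0, nt, nseg)
  for (i in nseg:1) {
    Fx <- seg$mass[i] * fk$cax[, i] - ex_fx[, i]
    Fy <- seg$mass[i] * (fk$cay[, i] + g0) - ex_fy[, i]
    Nz <- seg$inertia_zz[i] * fk$alpha[, i] +
      (fk$cx[, i] - fk$ox[, i]) * seg$mass[i] * (fk$cay[, i] + g0) -
      (fk$cy[, i] - fk$oy[, i]) * seg$mass[i] * fk$cax[, i] - ex_nz[, i]
    fx[, i] <- fx[, i] + Fx; fy[, i] <- fy[, i] + Fy; nz[, i] <- nz[, i] + Nz
    pi_ <- match(seg$parent[i], seg$name)
    if (!is.na(pi_)) {
      fx[, pi_] <- fx[, pi_] + fx[, i]
      fy[, pi_] <- fy[, pi_] + fy[, i]
      nz[, pi_] <- nz[, pi_] + nz[, i] +
        (fk$ox[, i] - fk$ox[, pi_]) * fy[, i] -
        (fk$oy[, i] - fk$oy[, pi_]) * fx[, i]
    }
  }
  list(fx = fx, fy = fy, nz = nz)
}

#' Peak and impulse of a time series
#'
#' @param series values over one hopping cycle.
#' @param time matching time grid (s).
#' @return tibble with `peak` (signed extremum: the value of largest
#'   magnitude) and `impulse` (trapezoidal time integral).
#' @export
peak_and_impulse <- function(series, time) {
  if (!length(series)) stop("empty series")
  stopifnot(length(series) == length(time))
  peak <- series[which.max(abs(series))]
  tibble::tibble(peak = peak, impulse = trapz_integral(time, series))
}

#' Tracking diagnostics and reserve-actuator acceptance
#'
#' Maximum and root-mean-square errors between the simulated and
#' experimental channels, grouped as rotations (deg), translations (m), GRF
#' (body weight) and net joint moments (N m/kg), plus the reserve-actuator
#' contribution: a solution is acceptable when no reserve exceeds 5 N m nor
#' 10% of the corresponding net joint moment.
#'
#' @param solution a `hop_ocp_solution`.
#' @param tracking the tracking data it was fitted to (defaults to the one
#'   stored in the solution).
#' @return list of class `hop_tracking_diagnostics`: `errors` tibble (per
#'   channel group), `reserve_max`, `reserve_fraction_max`, `accepted`.
#' @export
tracking_errors <- function(solution, tracking = solution$nlp$tracking) {
  model <- solution$nlp$model
  bw1g <- model$total_mass * model$gravity
  rot <- which(model$coord_type == "rotation")
  trn <- which(model$coord_type == "translation")
  qerr <- solution$q - tracking$q
  grf_err <- solution$u_grf - tracking$grf[-1, , drop = FALSE]
  mus_cols <- match(muscle_driven_coords(model), colnames(tracking$njm))
  act_cols <- match(model$torque_actuators$coordinate, colnames(tracking$njm))
  njm_exp <- as.matrix(tracking$njm)[-1, , drop = FALSE]
  njm_sim_all <- cbind(solution$njm_sim,
                       sweep(solution$actuator_activation[-1, , drop = FALSE], 2,
                             model$torque_actuators$tau_max, `*`))
  colnames(njm_sim_all) <- c(colnames(solution$njm_sim),
                             model$torque_actuators$coordinate)
  njm_err <- njm_sim_all[, colnames(njm_exp)] - njm_exp
  grp <- function(name, e, unit) {
    tibble::tibble(group = name, unit = unit,
                   max_abs_error = max(abs(e)), rmse = sqrt(mean(e^2)))
  }
  errors <- dplyr::bind_rows(
    grp("rotations", qerr[, rot] * 180 / pi, "deg"),
    grp("translations", qerr[, trn], "m"),
    grp("translations_excl_pelvis_vertical",
        qerr[, setdiff(trn, coord_index(model, "pelvis_ty"))], "m"),
    grp("grf", grf_err / bw1g, "BW"),
    grp("njm", njm_err / model$total_mass, "N.m/kg"))
  tres <- solution$tau_res
  njm_ref <- njm_exp[, colnames(tres), drop = FALSE]
  frac <- abs(tres) / pmax(abs(njm_ref), 1e-9)
  # the percentage criterion is read against meaningfully sized moments
  frac_max <- max(frac[abs(njm_ref) > 5])
  out <- list(errors = errors,
              reserve_max = max(abs(tres)),
              reserve_fraction_max = frac_max,
              accepted = max(abs(tres)) <= 5 && frac_max <= 0.10)
  class(out) <- "hop_tracking_diagnostics"
  out
}

#' @export
print.hop_tracking_diagnostics <- function(x, ...) {
  print(x$errors)
  cat(sprintf("reserves: max %.2f N m, max fraction %.1f%% -> %s\n",
              x$reserve_max, 100 * x$reserve_fraction_max,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Joint load summary over one hopping cycle
#'
#' Peaks and impulses of the mass-normalised net joint moments and
#' body-weight-normalised vertical joint reaction forces over one full
#' hopping cycle (touchdown to touchdown: contact plus flight).
#'
#' @param solution a `hop_ocp_solution`.
#' @param model the model used.
#' @param frame passed to [joint_reaction_forces()].
#' @return tibble with one row per joint: `peak_njm`, `njm_impulse`
#'   (N m/kg, N m/kg s), `peak_jrf`, `jrf_impulse` (BW, BW s).
#' @export
joint_load_summary <- function(solution, model, frame = "segment") {
  tr <- solution$nlp$tracking
  td <- tr$touchdown_times
  tmask <- solution$time[-1] >= td[1] & solution$time[-1] <= td[2]
  tcyc <- solution$time[-1][tmask]
  bw1g <- model$total_mass * model$gravity
  jrf <- joint_reaction_forces(solution, model, frame = frame)
  joints <- muscle_driven_coords(model)
  purrr::map_dfr(joints, function(jn) {
    pn <- peak_and_impulse(solution$njm_sim[tmask, jn] / model$total_mass, tcyc)
    pj <- peak_and_impulse(jrf[[jn]][tmask] / bw1g, tcyc)
    tibble::tibble(joint = jn,
                   peak_njm = pn$peak, njm_impulse = pn$impulse,
                   peak_jrf = pj$peak, jrf_impulse = pj$impulse)
  })
}

# scaled design vector of a solution (kept on the object via its nlp)
hopsim_solution_z <- function(solution) {
  if (!is.null(solution$z)) return(solution$z)
  stop("solution does not carry its design vector")
}
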