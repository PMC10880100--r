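#' Tracking OCP configuration
#'
#' @param n_mesh equally spaced mesh intervals.
#' @param degree collocation polynomial degree (three Radau points plus the
#'   interval start point).
#' @param feas_tol scaled constraint feasibility tolerance.
#' @param opt_tol scaled optimality (projected-gradient) tolerance.
#' @param max_outer maximum augmented-Lagrangian outer iterations.
#' @param max_inner Gauss-Newton iterations per subproblem.
#' @param rho0 initial penalty parameter.
#' @param scale_vars affinely scale all design variables to `[-1, 1]`.
#' @param fix_positions keep contact-sphere positions at their anatomical
#'   values instead of optimising them.
#' @param fix_contact keep stiffness/damping at the initial-guess values.
#' @param njm_mass_normalised track net joint moments on the mass-normalised
#'   (N m/kg) scale instead of raw newton-metres. The moment scale factor is
#'   derived as the moment performing 1 J of work over the rotational scale,
#'   which is a raw-moment quantity, so raw tracking is the default;
#'   reporting remains mass-normalised either way.
#' @return list of class `hop_ocp_config`.
#' @export
ocp_config <- function(n_mesh = 50, degree = 3,
                       feas_tol = 1e-5, opt_tol = 1e-4,
                       max_outer = 50, max_inner = 25, rho0 = 10,
                       scale_vars = TRUE,
                       fix_positions = FALSE, fix_contact = FALSE,
                       njm_mass_normalised = FALSE) {
  structure(list(n_mesh = n_mesh, degree = degree, feas_tol = feas_tol,
                 opt_tol = opt_tol, max_outer = max_outer,
                 max_inner = max_inner, rho0 = rho0,
                 scale_vars = scale_vars, fix_positions = fix_positions,
                 fix_contact = fix_contact,
                 njm_mass_normalised = njm_mass_normalised),
            class = "hop_ocp_config")
}

# variable layout ------------------------------------------------------------
# states per node: q (nq), qd (nq), a_m (nm), Ft (nm), a_tau (nta)
# collocation controls per node: qdd (nq), da (nm), dFt (nm), e_tau (nta)
# mesh controls per mesh point 1..K: u_GRF (2), tau_res (nres)
# parameters: log10 stiffness, damping, sphere positions (2 per sphere)
ocp_layout <- function(model, config) {
  nq <- length(model$coordinates)
  nm <- nrow(model$mtus)
  nta <- nrow(model$torque_actuators)
  nres <- length(muscle_driven_coords(model))
  nsph <- nrow(model$spheres)
  K <- config$n_mesh
  d <- config$degree
  nx <- 2 * nq + 2 * nm + nta
  nv <- nq + 2 * nm + nta
  nu <- 2 + nres
  n_nodes <- 1 + K * d
  npar <- 2 + 2 * nsph
  N <- n_nodes * nx + K * d * nv + K * nu + npar
  idx_x <- function(node, state) node * nx + state            # node 0-based
  off_v <- n_nodes * nx
  idx_v <- function(cnode, ctrl) off_v + (cnode - 1) * nv + ctrl  # cnode 1..K*d
  off_u <- off_v + K * d * nv
  idx_u <- function(k, ctrl) off_u + (k - 1) * nu + ctrl      # k 1..K
  off_p <- off_u + K * nu
  list(nq = nq, nm = nm, nta = nta, nres = nres, nsph = nsph,
       K = K, d = d, nx = nx, nv = nv, nu = nu, npar = npar,
       n_nodes = n_nodes, N = N,
       idx_x = idx_x, idx_v = idx_v, idx_u = idx_u, off_p = off_p,
       # state sub-blocks
       s_q = 1:nq, s_qd = nq + 1:nq, s_am = 2 * nq + 1:nm,
       s_ft = 2 * nq + nm + 1:nm, s_atau = 2 * nq + 2 * nm + seq_len(nta),
       v_qdd = 1:nq, v_da = nq + 1:nm, v_dft = nq + nm + 1:nm,
       v_etau = nq + 2 * nm + seq_len(nta),
       u_grf = 1:2, u_res = 2 + seq_len(nres))
}

# node index (0-based) of collocation point r in interval k; the last
# collocation point of interval k is mesh point k
node_of <- function(k, r, d) (k - 1) * d + r

#' Transcribe the tracking problem into a nonlinear program
#'
#' Legendre-Gauss-Radau direct collocation: state trajectories are
#' third-order polynomials per mesh interval (four points per interval);
#' implicit state dynamics are linear equalities at the collocation points
#' (state derivatives appear as controls); the nonlinear path constraints
#' (Hill equilibrium, inverse-dynamics consistency with zero pelvis
#' residuals, GRF-control/contact-model consistency) are imposed at the mesh
#' points; activation-rate inequalities are linear; foot-ground contact
#' stiffness, damping and sphere positions enter as static parameters. All
#' design variables are affinely scaled to `[-1, 1]`.
#'
#' @param model a [hop_model()] with fitted polynomials.
#' @param tracking a `hop_tracking` object from [preprocess_trial()].
#' @param config an [ocp_config()].
#' @param weights a [cost_weights()].
#' @param scales a [derive_scale_factors()].
#' @return An `hop_nlp` object: bounds, scaling, sparse linear equalities,
#'   nonlinear constraint evaluator, objective/gradient evaluator, and index
#'   metadata.
#' @export
transcribe <- function(model, tracking, config = ocp_config(),
                       weights = cost_weights(),
                       scales = derive_scale_factors()) {
  lay <- ocp_layout(model, config)
  K <- lay$K; d <- lay$d; nq <- lay$nq; nm <- lay$nm
  if (length(tracking$time) != K + 1) {
    stop(sprintf("tracking grid has %d points; expected %d mesh points",
                 length(tracking$time), K + 1))
  }
  h <- diff(tracking$time[1:2])
  col <- radau_collocation(d)
  mass <- tracking$mass

  # node times and data interpolants (for guesses and tracking targets)
  node_t <- c(tracking$time[1],
              as.vector(outer(col$tau * h, tracking$time[-(K + 1)], `+`)))
  node_t <- sort(node_t)
  dat_f <- lapply(seq_len(nq), function(j)
    splinefun(tracking$time, tracking$q[, j], method = "fmm"))

  # ---- bounds in natural units -------------------------------------------
  lb <- rep(-Inf, lay$N); ub <- rep(Inf, lay$N)
  rng <- function(x, pad) c(min(x) - pad, max(x) + pad)
  qb <- lapply(seq_len(nq), function(j) {
    pad <- if (model$coord_type[j] == "rotation") 0.4 else 0.3
    rng(tracking$q[, j], pad)
  })
  qdb <- lapply(seq_len(nq), function(j) {
    pad <- if (model$coord_type[j] == "rotation") 8 else 3
    rng(tracking$qd[, j], pad)
  })
  qddb <- lapply(seq_len(nq), function(j) {
    pad <- if (model$coord_type[j] == "rotation") 150 else 80
    rng(tracking$qdd[, j], pad)
  })
  for (node in 0:(lay$n_nodes - 1)) {
    for (j in seq_len(nq)) {
      lb[lay$idx_x(node, lay$s_q[j])] <- qb[[j]][1]
      ub[lay$idx_x(node, lay$s_q[j])] <- qb[[j]][2]
      lb[lay$idx_x(node, lay$s_qd[j])] <- qdb[[j]][1]
      ub[lay$idx_x(node, lay$s_qd[j])] <- qdb[[j]][2]
    }
    lb[lay$idx_x(node, lay$s_am)] <- 0;  ub[lay$idx_x(node, lay$s_am)] <- 1
    lb[lay$idx_x(node, lay$s_ft)] <- 0;  ub[lay$idx_x(node, lay$s_ft)] <- 3
    lb[lay$idx_x(node, lay$s_atau)] <- -1; ub[lay$idx_x(node, lay$s_atau)] <- 1
  }
  t_a <- 0.015; t_d <- 0.06
  for (cn in seq_len(K * d)) {
    for (j in seq_len(nq)) {
      lb[lay$idx_v(cn, lay$v_qdd[j])] <- qddb[[j]][1]
      ub[lay$idx_v(cn, lay$v_qdd[j])] <- qddb[[j]][2]
    }
    lb[lay$idx_v(cn, lay$v_da)] <- -1 / t_d; ub[lay$idx_v(cn, lay$v_da)] <- 1 / t_a
    lb[lay$idx_v(cn, lay$v_dft)] <- -40; ub[lay$idx_v(cn, lay$v_dft)] <- 40
    lb[lay$idx_v(cn, lay$v_etau)] <- -1; ub[lay$idx_v(cn, lay$v_etau)] <- 1
  }
  bw1g <- model$total_mass * model$gravity
  grfxb <- rng(tracking$grf[, 1], 0.3 * bw1g)
  grfyb <- c(-30, max(tracking$grf[, 2]) + 0.4 * bw1g)
  for (k in seq_len(K)) {
    lb[lay$idx_u(k, lay$u_grf[1])] <- grfxb[1]; ub[lay$idx_u(k, lay$u_grf[1])] <- grfxb[2]
    lb[lay$idx_u(k, lay$u_grf[2])] <- grfyb[1]; ub[lay$idx_u(k, lay$u_grf[2])] <- grfyb[2]
    lb[lay$idx_u(k, lay$u_res)] <- -100; ub[lay$idx_u(k, lay$u_res)] <- 100
  }
  sph0 <- as.matrix(model$spheres[, c("x", "y")])
  # physical Hunt-Crossley ranges: stiffness 1e5..1e7 N/m^2, damping <= 2 s/m;
  # sphere positions may move 5 cm along the sole but only 2 cm vertically
  # (larger vertical shifts disable a sphere outright)
  pad <- matrix(rep(c(0.05, 0.02), nrow(sph0)), ncol = 2, byrow = TRUE)
  p_lb <- c(5.0, 0.05, t(sph0 - pad))
  p_ub <- c(7.0, 2.0, t(sph0 + pad))
  if (config$fix_contact) {
    p_lb[1:2] <- p_ub[1:2] <- c(6, 2)   # initial-guess contact values
  }
  if (config$fix_positions) {
    p_lb[3:lay$npar] <- p_ub[3:lay$npar] <- t(sph0)
  }
  lb[lay$off_p + seq_len(lay$npar)] <- p_lb
  ub[lay$off_p + seq_len(lay$npar)] <- p_ub

  # affine scaling z in [-1, 1]
  if (config$scale_vars) {
    ctr <- (ub + lb) / 2
    scl <- pmax((ub - lb) / 2, 1e-9)
    zlb <- rep(-1, lay$N); zub <- rep(1, lay$N)
  } else {
    ctr <- rep(0, lay$N); scl <- rep(1, lay$N)
    zlb <- lb; zub <- ub
  }
  to_z <- function(x) (x - ctr) / scl
  to_x <- function(z) ctr + scl * z

  # ---- linear collocation equalities -------------------------------------
  nnz_cap <- K * d * lay$nx * (d + 3)
  ti <- tj <- integer(nnz_cap); tv <- numeric(nnz_cap)
  nnz <- 0L
  push <- function(i, j, v) {
    n <- length(v)
    ti[nnz + seq_len(n)] <<- i
    tj[nnz + seq_len(n)] <<- j
    tv[nnz + seq_len(n)] <<- v
    nnz <<- nnz + n
  }
  brow <- numeric(K * d * lay$nx)
  row <- 0L
  for (k in seq_len(K)) {
    nodes <- c(node_of(k, 0, d), vapply(seq_len(d), node_of, 0, k = k, d = d))
    for (r in seq_len(d)) {
      cn <- (k - 1) * d + r
      for (s in seq_len(lay$nx)) {
        row <- row + 1L
        # sum_j C[r, j] X[node_j, s] = h * f(node_r)
        for (j in seq_len(d + 1)) {
          push(row, lay$idx_x(nodes[j], s), col$C[r, j])
        }
        if (s %in% lay$s_q) {
          jq <- match(s, lay$s_q)
          push(row, lay$idx_x(nodes[r + 1], lay$s_qd[jq]), -h)
        } else if (s %in% lay$s_qd) {
          jq <- match(s, lay$s_qd)
          push(row, lay$idx_v(cn, lay$v_qdd[jq]), -h)
        } else if (s %in% lay$s_am) {
          jm <- match(s, lay$s_am)
          push(row, lay$idx_v(cn, lay$v_da[jm]), -h)
        } else if (s %in% lay$s_ft) {
          jm <- match(s, lay$s_ft)
          push(row, lay$idx_v(cn, lay$v_dft[jm]), -h)
        } else {
          jt <- match(s, lay$s_atau)
          delay <- model$torque_actuators$delay[jt]
          push(row, lay$idx_v(cn, lay$v_etau[jt]), -h / delay)
          push(row, lay$idx_x(nodes[r + 1], s), h / delay)
        }
      }
    }
  }
  ti <- ti[seq_len(nnz)]; tj <- tj[seq_len(nnz)]; tv <- tv[seq_len(nnz)]
  n_lin <- row
  # activation-rate inequalities at mesh points (rows scaled to order one)
  gi <- gj <- integer(0); gv <- numeric(0); gb <- numeric(0)
  pushg <- function(i, j, v) {
    gi <<- c(gi, i); gj <<- c(gj, j); gv <<- c(gv, v)
  }
  grow <- 0L
  for (k in seq_len(K)) {
    node <- node_of(k, d, d)
    cn <- k * d
    for (jm in seq_len(nm)) {
      grow <- grow + 1L     # t_a * da + a - 1 <= 0
      pushg(grow, lay$idx_v(cn, lay$v_da[jm]), t_a)
      pushg(grow, lay$idx_x(node, lay$s_am[jm]), 1)
      gb <- c(gb, 1)
      grow <- grow + 1L     # -t_d * da - a <= 0
      pushg(grow, lay$idx_v(cn, lay$v_da[jm]), -t_d)
      pushg(grow, lay$idx_x(node, lay$s_am[jm]), -1)
      gb <- c(gb, 0)
    }
  }
  # matrices in z-space: column j coefficient times scl[j]; rhs adjusted by ctr
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv * scl[tj],
                            dims = c(n_lin, lay$N))
  bA <- brow - as.numeric(Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                                               dims = c(n_lin, lay$N)) %*% ctr)
  G <- Matrix::sparseMatrix(i = gi, j = gj, x = gv * scl[gj],
                            dims = c(grow, lay$N))
  bG <- gb - as.numeric(Matrix::sparseMatrix(i = gi, j = gj, x = gv,
                                             dims = c(grow, lay$N)) %*% ctr)

  # ---- nonlinear path constraints ----------------------------------------
  blob <- model_blob(model)
  bw <- mean(tracking$bwss)
  mesh_nodes <- vapply(seq_len(K), node_of, 0, r = d, d = d)   # 0-based
  mesh_cn <- seq_len(K) * d
  # z-index matrix of the local variables per mesh point (for scatter ops)
  loc_idx <- matrix(0L, K, 3 * nq + 3 * nm + lay$nta + 2 + lay$nres + lay$npar)
  for (k in seq_len(K)) {
    node <- mesh_nodes[k]; cn <- mesh_cn[k]
    loc_idx[k, ] <- c(lay$idx_x(node, lay$s_q), lay$idx_x(node, lay$s_qd),
                      lay$idx_v(cn, lay$v_qdd), lay$idx_x(node, lay$s_am),
                      lay$idx_x(node, lay$s_ft), lay$idx_v(cn, lay$v_dft),
                      lay$idx_x(node, lay$s_atau),
                      lay$idx_u(k, lay$u_grf), lay$idx_u(k, lay$u_res),
                      lay$off_p + seq_len(lay$npar))
  }
  nloc <- ncol(loc_idx)
  # row scaling of the nonlinear constraints
  rs_force <- 500; rs_mom <- 100
  c_scale <- c(rep(1, nm),                 # hill residuals
               rs_force, rs_force, rs_mom, # pelvis residuals
               rep(rs_mom, nq - 3),        # joint moment consistency
               rs_force, rs_force)         # u_GRF vs contact
  n_nl_rows <- nm + nq + 2
  nmusdof <- lay$nres

  unpack <- function(z) {
    x <- to_x(z)
    X <- matrix(x[seq_len(lay$n_nodes * lay$nx)], lay$n_nodes, lay$nx,
                byrow = TRUE)
    V <- matrix(x[lay$n_nodes * lay$nx + seq_len(K * d * lay$nv)],
                K * d, lay$nv, byrow = TRUE)
    U <- matrix(x[lay$n_nodes * lay$nx + K * d * lay$nv + seq_len(K * lay$nu)],
                K, lay$nu, byrow = TRUE)
    par <- x[lay$off_p + seq_len(lay$npar)]
    list(X = X, V = V, U = U, par = par)
  }
  nat_par <- function(par) c(10^par[1], par[2:lay$npar])

  path_args <- function(z) {
    uz <- unpack(z)
    Xm <- uz$X[mesh_nodes + 1, , drop = FALSE]
    Vm <- uz$V[mesh_cn, , drop = FALSE]
    list(Q = Xm[, lay$s_q, drop = FALSE], QD = Xm[, lay$s_qd, drop = FALSE],
         QDD = Vm[, lay$v_qdd, drop = FALSE],
         AM = Xm[, lay$s_am, drop = FALSE], FT = Xm[, lay$s_ft, drop = FALSE],
         DFT = Vm[, lay$v_dft, drop = FALSE],
         ATAU = Xm[, lay$s_atau, drop = FALSE],
         UGRF = uz$U[, lay$u_grf, drop = FALSE],
         TRES = uz$U[, lay$u_res, drop = FALSE],
         par = nat_par(uz$par))
  }

  eval_path <- function(z) {
    a <- path_args(z)
    out <- cpp_path_eval(blob, bw, a$Q, a$QD, a$QDD, a$AM, a$FT, a$DFT,
                         a$ATAU, a$UGRF, a$TRES, a$par)
    list(C = sweep(out[, seq_len(n_nl_rows), drop = FALSE], 2, c_scale, `/`),
         TAU = out[, n_nl_rows + seq_len(nmusdof), drop = FALSE])
  }

  eval_path_jac <- function(z) {
    a <- path_args(z)
    steps <- c(rep(1e-6, 2 * nq), rep(1e-4, nq), rep(1e-6, 3 * nm),
               rep(1e-6, lay$nta), rep(1e-3, 2), rep(1e-3, lay$nres),
               a$par[1] * 1e-6, 1e-6, rep(1e-6, 2 * lay$nsph))
    J <- cpp_path_jacobian(blob, bw, a$Q, a$QD, a$QDD, a$AM, a$FT, a$DFT,
                           a$ATAU, a$UGRF, a$TRES, a$par, steps)
    nrow_all <- n_nl_rows + nmusdof
    # chain rule to z-space (affine scaling; log10 for the stiffness) and
    # constraint row scaling, applied by flat recycling (cheaper than sweep)
    colscl <- scl[loc_idx[1, ]]
    colscl[nloc - lay$npar + 1] <- colscl[nloc - lay$npar + 1] * a$par[1] * log(10)
    rowfac <- c(1 / c_scale, rep(1, nmusdof))
    J <- J * rep(colscl, each = K * nrow_all) * rep(rep(rowfac, each = K), nloc)
    dim(J) <- c(K, nrow_all, nloc)
    J
  }

  # ---- quadratic objective ------------------------------------------------
  # diagonal quadratic coefficients and linear terms in natural units,
  # converted to z-space at the end
  dnat <- numeric(lay$N); gnat <- numeric(lay$N); cnat <- 0
  add_quad <- function(i, w, target) {
    # contributes w * (x_i - target)^2
    dnat[i] <<- dnat[i] + w
    gnat[i] <<- gnat[i] - 2 * w * target
    cnat <<- cnat + sum(w * target^2)
  }
  rot_j <- which(model$coord_type == "rotation")
  tr_j <- which(model$coord_type == "translation")
  wtrap <- c(h / 2, rep(h, K - 1), h / 2)
  for (kk in 0:K) {
    node <- if (kk == 0) 0 else node_of(kk, d, d)
    for (j in rot_j) {
      add_quad(lay$idx_x(node, lay$s_q[j]),
               weights$w2 * wtrap[kk + 1] / scales$s_rot^2, tracking$q[kk + 1, j])
    }
    for (j in tr_j) {
      add_quad(lay$idx_x(node, lay$s_q[j]),
               weights$w1 * wtrap[kk + 1] / scales$s_tr^2, tracking$q[kk + 1, j])
    }
  }
  for (k in seq_len(K)) {
    add_quad(lay$idx_u(k, lay$u_grf[1]),
             weights$w2 * h / scales$s_grf[1]^2, tracking$grf[k + 1, 1])
    add_quad(lay$idx_u(k, lay$u_grf[2]),
             weights$w2 * h / scales$s_grf[2]^2, tracking$grf[k + 1, 2])
    for (r in seq_len(lay$nres)) {
      add_quad(lay$idx_u(k, lay$u_res[r]), weights$w2 * h / scales$s_res^2, 0)
    }
  }
  # torque-actuator moment tracking (linear in a_tau)
  njm_scale <- if (config$njm_mass_normalised) mass else 1
  act_cols <- match(model$torque_actuators$coordinate, colnames(tracking$njm))
  for (k in seq_len(K)) {
    node <- node_of(k, d, d)
    for (jt in seq_len(lay$nta)) {
      tm <- model$torque_actuators$tau_max[jt]
      target <- tracking$njm[[act_cols[jt]]][k + 1] / tm
      wq <- weights$w3 * h * (tm / njm_scale)^2 / scales$s_tau^2
      add_quad(lay$idx_x(node, lay$s_atau[jt]), wq, target)
    }
  }
  # effort and rate regularisation at collocation nodes (Radau quadrature)
  bq <- rep(col$B * h, K)
  for (cn in seq_len(K * d)) {
    node <- cn    # collocation node cn corresponds to state node cn (0-based)
    for (jm in seq_len(nm)) {
      add_quad(lay$idx_x(node, lay$s_am[jm]),
               weights$w2 * model$mtus$pv[jm] * bq[cn], 0)
      add_quad(lay$idx_v(cn, lay$v_da[jm]),
               weights$w3 * bq[cn] / ub[lay$idx_v(cn, lay$v_da[jm])]^2, 0)
      add_quad(lay$idx_v(cn, lay$v_dft[jm]),
               weights$w3 * bq[cn] / ub[lay$idx_v(cn, lay$v_dft[jm])]^2, 0)
    }
    for (j in seq_len(nq)) {
      sb <- max(abs(qddb[[j]]))
      add_quad(lay$idx_v(cn, lay$v_qdd[j]), weights$w2 * bq[cn] / sb^2, 0)
    }
  }
  # convert to z-space: x = ctr + scl z
  dz <- dnat * scl^2
  gz <- (2 * dnat * ctr + gnat) * scl
  cz <- cnat + sum(dnat * ctr^2 + gnat * ctr)

  # mass-normalised moment tracking targets for the nonlinear TAU outputs
  mus_cols <- match(muscle_driven_coords(model), colnames(tracking$njm))
  njm_target <- as.matrix(tracking$njm[2:(K + 1), mus_cols, drop = FALSE]) / njm_scale
  w_njm <- weights$w3 * h / (scales$s_tau * njm_scale)^2

  structure(list(
    model = model, tracking = tracking, config = config, weights = weights,
    scales = scales, layout = lay, col = col, h = h, node_t = node_t,
    lb = lb, ub = ub, zlb = zlb, zub = zub, ctr = ctr, scl = scl,
    to_z = to_z, to_x = to_x, unpack = unpack, nat_par = nat_par,
    A = A, bA = bA, G = G, bG = bG,
    eval_path = eval_path, eval_path_jac = eval_path_jac,
    loc_idx = loc_idx, c_scale = c_scale, n_nl_rows = n_nl_rows,
    mesh_nodes = mesh_nodes, mesh_cn = mesh_cn,
    dz = dz, gz = gz, cz = cz,
    njm_target = njm_target, w_njm = w_njm, njm_scale = njm_scale,
    bw = bw
  ), class = "hop_nlp")
}

#' @export
print.hop_nlp <- function(x, ...) {
  cat(sprintf("<hop_nlp> %d variables, %d linear equalities, %d x %d nonlinear path rows, %d inequality rows\n",
              x$layout$N, nrow(x$A), x$layout$K, x$n_nl_rows, nrow(x$G)))
  invisible(x)
}

#' Objective value and gradient of the transcribed problem
#'
#' The objective is quadratic in the design variables (tracking of
#' kinematics/GRF, effort, control regularisation) except for the
#' net-joint-moment tracking term, which goes through inverse dynamics.
#' @param nlp an `hop_nlp`.
#' @param z scaled design vector.
#' @param path optional precomputed [nlp$eval_path] result.
#' @return list with `f` and optionally the njm term parts.
#' @keywords internal
nlp_objective <- function(nlp, z, path = NULL) {
  if (is.null(path)) path <- nlp$eval_path(z)
  e <- path$TAU / nlp$njm_scale - nlp$njm_target
  f <- sum(nlp$dz * z^2) + sum(nlp$gz * z) + nlp$cz +
    nlp$w_njm * sum(e^2)
  list(f = f, e = e, path = path)
}

#' Decompose the objective of a solution into its cost terms
#' @keywords internal
nlp_cost_terms <- function(nlp, z) {
  uz <- nlp$unpack(z)
  lay <- nlp$layout
  K <- lay$K; d <- lay$d
  tr <- nlp$tracking
  tmesh <- tr$time
  Xm <- uz$X[nlp$mesh_nodes + 1, , drop = FALSE]
  qsim <- rbind(uz$X[1, lay$s_q], Xm[, lay$s_q])
  rot_j <- which(nlp$model$coord_type == "rotation")
  tr_j <- which(nlp$model$coord_type == "translation")
  # simulated njm: torque actuator + muscle-driven rows via path eval
  path <- nlp$eval_path(z)
  njm_sim <- path$TAU / nlp$njm_scale
  act_cols <- match(nlp$model$torque_actuators$coordinate, colnames(tr$njm))
  mus_cols <- match(muscle_driven_coords(nlp$model), colnames(tr$njm))
  J_track <- tracking_cost(
    tmesh,
    sim = list(q_rot = qsim[, rot_j], q_tr = qsim[, tr_j],
               grf = rbind(tr$grf[1, ], uz$U[, lay$u_grf]),
               njm = rbind(as.matrix(tr$njm)[1, mus_cols] / nlp$njm_scale, njm_sim)),
    exp = list(q_rot = tr$q[, rot_j], q_tr = tr$q[, tr_j], grf = tr$grf,
               njm = as.matrix(tr$njm)[, mus_cols] / nlp$njm_scale),
    scales = nlp$scales, weights = nlp$weights)
  # actuator moment tracking part (quadratic block)
  for (jt in seq_len(lay$nta)) {
    tm <- nlp$model$torque_actuators$tau_max[jt]
    e <- (Xm[, lay$s_atau[jt]] * tm - as.matrix(tr$njm)[-1, act_cols[jt]]) /
      (nlp$njm_scale * nlp$scales$s_tau)
    J_track <- J_track + nlp$weights$w3 * nlp$h * sum(e^2)
  }
  tcol <- nlp$node_t[-1]
  J_eff <- nlp$weights$w2 * sum(rep(nlp$col$B * nlp$h, K) *
                                  (uz$X[-1, lay$s_am, drop = FALSE]^2 %*%
                                     nlp$model$mtus$pv))
  bq <- rep(nlp$col$B * nlp$h, K)
  sb_qdd <- vapply(seq_len(lay$nq), function(j)
    max(abs(c(nlp$lb[nlp$layout$idx_v(1, lay$v_qdd[j])],
              nlp$ub[nlp$layout$idx_v(1, lay$v_qdd[j])]))), numeric(1))
  J_ctrl <- sum(bq * (sweep(uz$V[, lay$v_qdd, drop = FALSE], 2, sb_qdd, `/`)^2 %*%
                        rep(nlp$weights$w2, lay$nq))) +
    sum(bq * (uz$V[, lay$v_da, drop = FALSE] /
                nlp$ub[nlp$layout$idx_v(1, lay$v_da[1])])^2 * nlp$weights$w3) +
    sum(bq * (uz$V[, lay$v_dft, drop = FALSE] /
                nlp$ub[nlp$layout$idx_v(1, lay$v_dft[1])])^2 * nlp$weights$w3) +
    nlp$weights$w2 * nlp$h * sum((uz$U[, lay$u_res, drop = FALSE] /
                                    nlp$scales$s_res)^2)
  list(J_effort = J_eff, J_tracking = J_track, J_control = J_ctrl,
       total = J_eff + J_track + J_ctrl)
}

#' Initial guesses for the tracking problem
#'
#' The data-informed guess copies the experimental kinematics (positions,
#' velocities, accelerations) and GRFs into the corresponding variables and
#' sets every remaining state/control to its lower bound (zero where the
#' bounds cross zero). The cold guess sets every variable to zero, or its
#' lower bound where the bounds do not cross zero. Both guesses share the
#' contact parameter values: stiffness 1e6 N/m^2, damping 2 s/m, anatomical
#' sphere positions.
#'
#' @param nlp an `hop_nlp` from [transcribe()].
#' @return list with `data_informed` and `cold` scaled design vectors.
#' @export
make_initial_guesses <- function(nlp) {
  lay <- nlp$layout
  tr <- nlp$tracking
  lb <- nlp$lb; ub <- nlp$ub
  base <- ifelse(lb <= 0 & ub >= 0, 0, lb)
  x <- base
  qf <- lapply(seq_len(lay$nq), function(j)
    splinefun(tr$time, tr$q[, j], method = "fmm"))
  qdf <- lapply(seq_len(lay$nq), function(j)
    splinefun(tr$time, tr$qd[, j], method = "fmm"))
  qddf <- lapply(seq_len(lay$nq), function(j)
    splinefun(tr$time, tr$qdd[, j], method = "fmm"))
  grf_f <- list(splinefun(tr$time, tr$grf[, 1]), splinefun(tr$time, tr$grf[, 2]))
  for (node in 0:(lay$n_nodes - 1)) {
    tn <- nlp$node_t[node + 1]
    for (j in seq_len(lay$nq)) {
      x[lay$idx_x(node, lay$s_q[j])] <- qf[[j]](tn)
      x[lay$idx_x(node, lay$s_qd[j])] <- qdf[[j]](tn)
    }
  }
  for (cn in seq_len(lay$K * lay$d)) {
    tn <- nlp$node_t[cn + 1]
    for (j in seq_len(lay$nq)) {
      x[lay$idx_v(cn, lay$v_qdd[j])] <- qddf[[j]](tn)
    }
  }
  for (k in seq_len(lay$K)) {
    tk <- tr$time[k + 1]
    x[lay$idx_u(k, lay$u_grf[1])] <- grf_f[[1]](tk)
    x[lay$idx_u(k, lay$u_grf[2])] <- grf_f[[2]](tk)
  }
  par_guess <- c(6, 2, t(as.matrix(nlp$model$spheres[, c("x", "y")])))
  par_guess <- pmin(pmax(par_guess, lb[lay$off_p + seq_len(lay$npar)]),
                    ub[lay$off_p + seq_len(lay$npar)])
  x[lay$off_p + seq_len(lay$npar)] <- par_guess
  x <- pmin(pmax(x, lb), ub)
  cold <- base
  cold[lay$off_p + seq_len(lay$npar)] <- par_guess
  cold <- pmin(pmax(cold, lb), ub)
  list(data_informed = nlp$to_z(x), cold = nlp$to_z(cold))
}
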