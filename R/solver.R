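# Augmented-Lagrangian solution of the transcribed tracking NLP.
#
# The structure is exploited throughout: the objective is quadratic (diagonal
# Hessian) except for the moment-tracking term; the collocation dynamics are
# a constant sparse linear system; the nonlinear path constraints are
# separable per mesh point, so their Jacobian is evaluated blockwise in
# compiled code and applied without ever forming a global sparse matrix.
# Inner bounded subproblems are solved by projected Gauss-Newton with a
# sparse Cholesky factorisation of the structured Hessian approximation.

al_solve <- function(nlp, z0, verbose = FALSE) {
  cfg <- nlp$config
  A <- nlp$A; bA <- nlp$bA; G <- nlp$G; bG <- nlp$bG
  K <- nlp$layout$K
  nr <- nlp$n_nl_rows
  nres <- ncol(nlp$njm_target)
  N <- nlp$layout$N
  lamA <- numeric(nrow(A))
  lamC <- matrix(0, K, nr)
  lamG <- numeric(nrow(G))
  rho <- cfg$rho0
  z <- pmin(pmax(z0, nlp$zlb), nlp$zub)

  AtA <- Matrix::crossprod(A)
  GtG <- Matrix::crossprod(G)
  # index scaffolding for the blockwise Jacobian scatter (pattern constant)
  nloc <- ncol(nlp$loc_idx)
  blk_i <- blk_j <- integer(K * nloc * nloc)
  pos <- 1L
  for (k in seq_len(K)) {
    idx <- nlp$loc_idx[k, ]
    blk_i[pos:(pos + nloc * nloc - 1)] <- rep(idx, times = nloc)
    blk_j[pos:(pos + nloc * nloc - 1)] <- rep(idx, each = nloc)
    pos <- pos + nloc * nloc
  }

  al_value <- function(z, path) {
    e <- path$TAU / nlp$njm_scale - nlp$njm_target
    rA <- as.numeric(A %*% z - bA)
    rG <- as.numeric(G %*% z - bG)
    Cv <- path$C
    f0 <- sum(nlp$dz * z^2) + sum(nlp$gz * z) + nlp$cz + nlp$w_njm * sum(e^2)
    f0 + sum(lamA * rA) + rho / 2 * sum(rA^2) +
      sum(lamC * Cv) + rho / 2 * sum(Cv^2) +
      sum(pmax(0, lamG + rho * rG)^2 - lamG^2) / (2 * rho)
  }

  al_grad <- function(z, path, J) {
    e <- path$TAU / nlp$njm_scale - nlp$njm_target
    rA <- as.numeric(A %*% z - bA)
    rG <- as.numeric(G %*% z - bG)
    gplus <- pmax(0, lamG + rho * rG)
    g <- 2 * nlp$dz * z + nlp$gz
    g <- g + as.numeric(Matrix::crossprod(A, lamA + rho * rA))
    g <- g + as.numeric(Matrix::crossprod(G, gplus))
    WC <- lamC + rho * path$C
    Wt <- 2 * nlp$w_njm * e / nlp$njm_scale
    for (k in seq_len(K)) {
      w <- c(WC[k, ], Wt[k, ])
      g[nlp$loc_idx[k, ]] <- g[nlp$loc_idx[k, ]] +
        as.numeric(crossprod(J[k, , ], w))
    }
    list(g = g, gplus = gplus)
  }

  # Gauss-Newton Hessian of the AL subproblem (sparse, SPD after damping):
  # 2 diag + rho A'A + active-G rows + per-mesh-point J' W J blocks
  al_hess <- function(J, gplus) {
    wrow <- c(rep(rho, nr), rep(2 * nlp$w_njm / nlp$njm_scale^2, nres))
    vals <- numeric(K * nloc * nloc)
    pos <- 1L
    for (k in seq_len(K)) {
      Jk <- J[k, , ]
      Hk <- crossprod(Jk * sqrt(wrow))
      vals[pos:(pos + nloc * nloc - 1)] <- Hk
      pos <- pos + nloc * nloc
    }
    # the full G'G pattern is always included (zero-weighted when inactive)
    # so the sparsity pattern is constant and the symbolic Cholesky analysis
    # can be reused across iterations
    H <- Matrix::sparseMatrix(i = blk_i, j = blk_j, x = vals, dims = c(N, N)) +
      rho * AtA + 1e-12 * GtG + Matrix::Diagonal(N, 2 * nlp$dz + 1e-8)
    act <- which(gplus > 0)
    if (length(act)) {
      Ga <- G[act, , drop = FALSE]
      H <- H + rho * Matrix::crossprod(Ga)
    }
    H
  }

  feas <- function(z, path) {
    max(max(abs(A %*% z - bA)), max(abs(path$C)),
        max(0, max(as.numeric(G %*% z - bG))))
  }

  history <- list()
  status <- "max_outer"
  path <- nlp$eval_path(z)
  total_gn <- 0L
  lev <- 1e-6          # Levenberg damping, adapted on line-search behaviour
  step_mem <- 1
  chol_sym <- NULL     # symbolic Cholesky analysis, reused across iterations
  for (outer in seq_len(cfg$max_outer)) {
    # ---- projected Levenberg-damped Gauss-Newton inner loop ---------------
    # damping and step memory restart each subproblem: carrying a collapsed
    # step across outer rounds freezes the endgame
    lev <- 1e-6
    step_mem <- 1
    f_prev <- Inf
    stall <- 0L
    for (it in seq_len(cfg$max_inner)) {
      J <- nlp$eval_path_jac(z)
      gg <- al_grad(z, path, J)
      g <- gg$g
      pg <- z - pmin(pmax(z - g, nlp$zlb), nlp$zub)
      if (max(abs(pg)) < cfg$opt_tol) break
      at_lo <- z <= nlp$zlb + 1e-12
      at_hi <- z >= nlp$zub - 1e-12
      fixed <- (at_lo & g > 0) | (at_hi & g < 0)
      H0 <- al_hess(J, gg$gplus)
      dH <- pmax(Matrix::diag(H0), 1)
      g_eff <- g; g_eff[fixed] <- 0
      f0 <- al_value(z, path)
      accepted <- FALSE
      for (try_lev in 1:4) {
        # fixed variables are pinned by a large diagonal penalty, keeping the
        # sparsity pattern constant so the symbolic factorisation is reused
        H <- Matrix::forceSymmetric(
          H0 + Matrix::Diagonal(N, lev * dH + fixed * 1e12))
        chol_err <- NULL
        p <- tryCatch({
          if (is.null(chol_sym)) {
            chol_sym <- Matrix::Cholesky(H, LDL = FALSE, super = TRUE)
          } else {
            chol_sym <- tryCatch(Matrix::.updateCHMfactor(chol_sym, H, mult = 0),
                                 error = function(e)
                                   Matrix::Cholesky(H, LDL = FALSE, super = TRUE))
          }
          -as.numeric(Matrix::solve(chol_sym, g_eff))
        }, error = function(e) NULL)
        if (is.null(p)) {
          lev <- lev * 100; chol_sym <- NULL; next
        }
        p[fixed] <- 0
        d0 <- sum(g * p)
        step <- min(1, 4 * step_mem)
        for (ls in 1:30) {
          z1 <- pmin(pmax(z + step * p, nlp$zlb), nlp$zub)
          path1 <- nlp$eval_path(z1)
          f1 <- al_value(z1, path1)
          if (is.finite(f1) &&
              f1 <= f0 + 1e-4 * step * min(d0, 0) + 1e-12 * abs(f0)) {
            accepted <- TRUE; break
          }
          step <- step / 2
        }
        if (accepted) {
          step_mem <- step
          if (step >= 0.5) lev <- max(lev / 3, 1e-9)
          else if (step < 1e-3) lev <- min(lev * 10, 1e3)
          break
        }
        if (verbose) message(sprintf("   it %d try %d: LS failed f0=%.6g d0=%.3g lev=%.1e |p|=%.3g",
                                     it, try_lev, f0, d0, lev, max(abs(p))))
        lev <- min(lev * 30, 1e4)
      }
      total_gn <- total_gn + 1L
      if (!accepted) break
      moved <- max(abs(z1 - z))
      z <- z1; path <- path1
      if (moved < 1e-12) break
      # stop early once the subproblem value plateaus
      if (f_prev - f1 < 1e-7 * max(1, abs(f1))) {
        stall <- stall + 1L
        if (stall >= 2L) break
      } else stall <- 0L
      f_prev <- f1
    }
    fv <- feas(z, path)
    f_now <- al_value(z, path)
    history[[outer]] <- c(outer = outer, feas = fv, rho = rho, f = f_now,
                          gn = total_gn)
    if (verbose) {
      message(sprintf("  outer %2d: feas %.3e rho %.1e f %.6g (gn %d)",
                      outer, fv, rho, f_now, total_gn))
    }
    if (fv < cfg$feas_tol) { status <- "converged"; break }
    # stagnation: no meaningful feasibility progress over six outer rounds
    if (outer >= 6) {
      past <- vapply(history[(outer - 5):outer], `[[`, numeric(1), "feas")
      if (min(past) > 0.9 * max(past)) { status <- "stalled"; break }
    }
    rA <- as.numeric(A %*% z - bA)
    rG <- as.numeric(G %*% z - bG)
    lamA <- lamA + rho * rA
    lamC <- lamC + rho * path$C
    lamG <- pmax(0, lamG + rho * rG)
    # raise the penalty unless feasibility is dropping fast on its own
    if (outer > 1 && fv > 0.3 * history[[outer - 1]]["feas"]) {
      rho <- min(rho * 2.5, 1e7)
    }
  }
  list(z = z, status = status, feasibility = feas(z, nlp$eval_path(z)),
       history = do.call(rbind, history))
}

#' Solve the data-tracking optimal control problem
#'
#' Transcribes the problem (if needed), solves it from the two initial
#' guesses (data-informed and cold) with a structure-exploiting
#' augmented-Lagrangian method, and returns the solution with the lower cost
#' among those that reach the feasibility tolerance.
#'
#' @param model a [hop_model()].
#' @param tracking a `hop_tracking` object.
#' @param config an [ocp_config()].
#' @param weights,scales cost weights and scale factors.
#' @param guesses which initial guesses to attempt.
#' @param verbose print outer-iteration progress.
#' @return An object of class `hop_ocp_solution`.
#' @export
solve_tracking <- function(model, tracking, config = ocp_config(),
                           weights = cost_weights(),
                           scales = derive_scale_factors(),
                           guesses = c("data_informed", "cold"),
                           verbose = FALSE) {
  nlp <- transcribe(model, tracking, config, weights, scales)
  g <- make_initial_guesses(nlp)
  runs <- list()
  for (nm in guesses) {
    if (verbose) message("initial guess: ", nm)
    t0 <- Sys.time()
    res <- al_solve(nlp, g[[nm]], verbose = verbose)
    res$guess <- nm
    res$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res$cost <- nlp_cost_terms(nlp, res$z)
    runs[[nm]] <- res
  }
  ok <- vapply(runs, function(r) r$status == "converged", logical(1))
  if (!any(ok)) {
    stop("tracking solver failed to converge from any initial guess; ",
         "best feasibility: ",
         format(min(vapply(runs, `[[`, numeric(1), "feasibility"))))
  }
  costs <- vapply(runs, function(r) if (r$status == "converged")
    r$cost$total else Inf, numeric(1))
  best <- names(which.min(costs))   # ties resolve to the first listed guess
  build_solution(nlp, runs[[best]], runs)
}

build_solution <- function(nlp, run, runs) {
  lay <- nlp$layout
  uz <- nlp$unpack(run$z)
  path <- nlp$eval_path(run$z)
  mesh_t <- nlp$tracking$time
  Xm <- rbind(uz$X[1, ], uz$X[nlp$mesh_nodes + 1, , drop = FALSE])
  q <- Xm[, lay$s_q, drop = FALSE]; colnames(q) <- nlp$model$coordinates
  qd <- Xm[, lay$s_qd, drop = FALSE]; colnames(qd) <- nlp$model$coordinates
  am <- Xm[, lay$s_am, drop = FALSE]; colnames(am) <- nlp$model$mtus$name
  ft <- Xm[, lay$s_ft, drop = FALSE]; colnames(ft) <- nlp$model$mtus$name
  atau <- Xm[, lay$s_atau, drop = FALSE]
  colnames(atau) <- nlp$model$torque_actuators$name
  ugrf <- uz$U[, lay$u_grf, drop = FALSE]; colnames(ugrf) <- c("grf_x", "grf_y")
  tres <- uz$U[, lay$u_res, drop = FALSE]
  colnames(tres) <- muscle_driven_coords(nlp$model)
  par <- nlp$nat_par(uz$par)
  npos <- matrix(par[-(1:2)], ncol = 2, byrow = TRUE,
                 dimnames = list(nlp$model$spheres$name, c("x", "y")))
  njm_sim <- path$TAU
  colnames(njm_sim) <- muscle_driven_coords(nlp$model)
  structure(list(
    time = mesh_t,
    z = run$z,
    q = q, qd = qd, activations = am, tendon_force_norm = ft,
    actuator_activation = atau,
    u_grf = ugrf, tau_res = tres,
    njm_sim = njm_sim,              # at mesh points 1..K (N m)
    parameters = list(stiffness = par[1], damping = par[2], spheres = npos),
    cost = run$cost, guess = run$guess, status = run$status,
    feasibility = run$feasibility, seconds = run$seconds,
    history = run$history,
    attempts = lapply(runs, function(r)
      list(guess = r$guess, status = r$status, feasibility = r$feasibility,
           cost = r$cost$total, seconds = r$seconds)),
    nlp = nlp
  ), class = "hop_ocp_solution")
}

#' @export
print.hop_ocp_solution <- function(x, ...) {
  cat(sprintf("<hop_ocp_solution> %s from '%s' guess; J = %.4f (effort %.3f, tracking %.3f, control %.3f)\n",
              x$status, x$guess, x$cost$total, x$cost$J_effort,
              x$cost$J_tracking, x$cost$J_control))
  cat(sprintf("  feasibility %.2e, stiffness %.3g N/m^2, damping %.3g s/m, %.1f s\n",
              x$feasibility, x$parameters$stiffness, x$parameters$damping,
              x$seconds))
  invisible(x)
}

#' Tidy an OCP solution into a long tibble of trajectories
#' @param x a `hop_ocp_solution`.
#' @param ... unused.
#' @return tibble with `time`, `channel`, `group`, `value`.
#' @export
tidy.hop_ocp_solution <- function(x, ...) {
  grab <- function(mat, time, group) {
    tb <- tibble::as_tibble(as.data.frame(mat))
    tb$time <- time
    tb <- tidyr::pivot_longer(tb, -"time", names_to = "channel",
                              values_to = "value")
    tb$group <- group
    tb
  }
  dplyr::bind_rows(
    grab(x$q, x$time, "coordinate"),
    grab(x$activations, x$time, "activation"),
    grab(x$tendon_force_norm, x$time, "tendon_force"),
    grab(x$u_grf, x$time[-1], "grf"),
    grab(x$tau_res, x$time[-1], "reserve"),
    grab(x$njm_sim, x$time[-1], "njm")
  )
}

#' One-line summary of an OCP solution
#' @param x a `hop_ocp_solution`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.hop_ocp_solution <- function(x, ...) {
  tibble::tibble(status = x$status, guess = x$guess,
                 cost_total = x$cost$total, cost_effort = x$cost$J_effort,
                 cost_tracking = x$cost$J_tracking,
                 cost_control = x$cost$J_control,
                 feasibility = x$feasibility,
                 stiffness = x$parameters$stiffness,
                 damping = x$parameters$damping,
                 seconds = x$seconds)
}

#' Plot tracking performance of a solution
#' @param object a `hop_ocp_solution`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hop_ocp_solution <- function(object, ...) {
  tr <- object$nlp$tracking
  sim <- tidy(object)
  sim <- sim[sim$group %in% c("coordinate", "grf", "njm"), ]
  expd <- dplyr::bind_rows(
    tidyr::pivot_longer(tibble::as_tibble(cbind(time = tr$time,
                                                as.data.frame(tr$q))),
                        -"time", names_to = "channel", values_to = "value"),
    tidyr::pivot_longer(tibble::as_tibble(cbind(time = tr$time,
                                                as.data.frame(tr$grf))),
                        -"time", names_to = "channel", values_to = "value"),
    tidyr::pivot_longer(tibble::as_tibble(cbind(time = tr$time,
                                                as.data.frame(as.matrix(tr$njm)))),
                        -"time", names_to = "channel", values_to = "value"))
  expd$kind <- "experimental"
  sim$kind <- "simulated"
  both <- dplyr::bind_rows(sim[, c("time", "channel", "value", "kind")], expd)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tracking data rebuilt from a solution's own trajectories
#'
#' Converts a converged solution back into tracking data (kinematics with
#' their collocation-consistent derivatives, the optimised GRF controls, and
#' the solution's net joint moments), so the problem can be re-solved
#' against its own output in self-consistency experiments.
#'
#' @param solution a `hop_ocp_solution`.
#' @return A `hop_tracking` object on the same mesh.
#' @export
tracking_from_solution <- function(solution) {
  nlp <- solution$nlp
  lay <- nlp$layout
  uz <- nlp$unpack(solution$z)
  tr <- nlp$tracking
  n <- length(tr$time)
  q <- rbind(uz$X[1, lay$s_q], uz$X[nlp$mesh_nodes + 1, lay$s_q, drop = FALSE])
  qd <- rbind(uz$X[1, lay$s_qd], uz$X[nlp$mesh_nodes + 1, lay$s_qd, drop = FALSE])
  qdd <- rbind(uz$V[1, lay$v_qdd], uz$V[nlp$mesh_cn, lay$v_qdd, drop = FALSE])
  colnames(q) <- colnames(qd) <- colnames(qdd) <- nlp$model$coordinates
  grf <- rbind(tr$grf[1, ], uz$U[, lay$u_grf, drop = FALSE])
  colnames(grf) <- c("grf_x", "grf_y")
  # centre of pressure from the solution's contact forces
  par <- nlp$nat_par(uz$par)
  spos <- matrix(par[-(1:2)], ncol = 2, byrow = TRUE)
  sph <- sphere_contact_forces(nlp$model, q, qd, stiffness = par[1],
                               damping = par[2], spheres = spos)
  cop <- ifelse(is.na(sph$cop_x), tr$cop, sph$cop_x)
  njm_sim <- as.matrix(tr$njm)
  mus_cols <- match(colnames(solution$njm_sim), colnames(njm_sim))
  njm_sim[-1, mus_cols] <- solution$njm_sim
  act_cols <- match(nlp$model$torque_actuators$coordinate, colnames(njm_sim))
  njm_sim[-1, act_cols] <- sweep(solution$actuator_activation[-1, , drop = FALSE],
                                 2, nlp$model$torque_actuators$tau_max, `*`)
  structure(list(time = tr$time, q = q, qd = qd, qdd = qdd,
                 grf = grf, cop = cop, bwss = tr$bwss,
                 njm = tibble::as_tibble(njm_sim),
                 residuals = tr$residuals * 0,
                 touchdown_times = tr$touchdown_times,
                 mass = tr$mass, g_level = tr$g_level),
            class = "hop_tracking")
}
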