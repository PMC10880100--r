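#' Inverse dynamics of the planar model
#'
#' Recursive Newton-Euler inverse dynamics on the model tree: returns, for
#' each coordinate, the net generalised force required to produce the given
#' trajectory under the applied external forces. The three pelvis (root)
#' entries are the residual force/moment: they vanish exactly when the motion
#' is dynamically consistent with the applied external forces.
#'
#' @param model a [hop_model()].
#' @param q,qd,qdd coordinate trajectories (n x n_coordinates matrices; a
#'   single pose may be given as a vector).
#' @param grf ground reaction force (n x 2 matrix, world x/y, N) applied to
#'   the foot at the centre of pressure, or `NULL`.
#' @param cop centre of pressure x-position (length-n, m; applied at ground
#'   height y = 0).
#' @param bwss vertical body-weight-support force (N, scalar or length-n)
#'   applied at the pelvis centre of mass.
#' @param extra optional list of extra external forces, each a list with
#'   `segment` (name), `point` (n x 2 world coordinates), `force` (n x 2),
#'   and optionally `torque` (length n).
#'
#' @return A tibble with one column per coordinate (N for translations,
#'   N m for rotations).
#' @export
inverse_dynamics <- function(model, q, qd, qdd, grf = NULL, cop = NULL,
                             bwss = 0, extra = list()) {
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  q <- as_mat(q); qd <- as_mat(qd); qdd <- as_mat(qdd)
  nq <- length(model$coordinates)
  if (ncol(q) != nq || ncol(qd) != nq || ncol(qdd) != nq ||
      nrow(qd) != nrow(q) || nrow(qdd) != nrow(q)) {
    stop("q, qd, qdd must share dimensions n x ", nq,
         " matching the model coordinate list")
  }
  nt <- nrow(q)
  blob <- model_blob_bare(model)
  ext_seg <- integer(0); ext_pt <- list(); ext_force <- list(); ext_torque <- list()
  if (!is.null(grf)) {
    grf <- as_mat(grf)
    if (is.null(cop)) cop <- rep(0, nt)
    ext_seg <- c(ext_seg, segment_index(model, "foot"))
    ext_pt <- c(ext_pt, list(cbind(cop, 0)))
    ext_force <- c(ext_force, list(grf))
    ext_torque <- c(ext_torque, list(rep(0, nt)))
  }
  if (any(bwss != 0)) {
    fk <- cpp_forward_kinematics(blob, q, qd, qdd)
    th <- fk$theta[, 1]
    cx <- fk$ox[, 1] + cos(th) * model$segments$com_x[1] -
      sin(th) * model$segments$com_y[1]
    cy <- fk$oy[, 1] + sin(th) * model$segments$com_x[1] +
      cos(th) * model$segments$com_y[1]
    ext_seg <- c(ext_seg, 1L)
    ext_pt <- c(ext_pt, list(cbind(cx, cy)))
    ext_force <- c(ext_force, list(cbind(0, rep_len(bwss, nt))))
    ext_torque <- c(ext_torque, list(rep(0, nt)))
  }
  for (e in extra) {
    ext_seg <- c(ext_seg, segment_index(model, e$segment))
    ext_pt <- c(ext_pt, list(as_mat(e$point)))
    ext_force <- c(ext_force, list(as_mat(e$force)))
    ext_torque <- c(ext_torque, list(if (is.null(e$torque)) rep(0, nt) else e$torque))
  }
  tau <- cpp_inverse_dynamics(blob, q, qd, qdd, as.integer(ext_seg),
                              ext_pt, ext_force, ext_torque)
  colnames(tau) <- model$coordinates
  tibble::as_tibble(tau)
}

#' Forward kinematics of all segments
#'
#' @inheritParams inverse_dynamics
#' @return List of matrices (n x n_segments): `theta`, `omega`, `alpha`,
#'   joint origin position/velocity/acceleration (`ox`, `oy`, ...) and centre
#'   of mass position/velocity/acceleration (`cx`, `cy`, ...).
#' @export
forward_kinematics <- function(model, q, qd = NULL, qdd = NULL) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(qd)) qd <- matrix(0, nrow(q), ncol(q))
  if (is.null(qdd)) qdd <- matrix(0, nrow(q), ncol(q))
  fk <- cpp_forward_kinematics(model_blob_bare(model), q, as.matrix(qd), as.matrix(qdd))
  for (nm in names(fk)) colnames(fk[[nm]]) <- model$segments$name
  fk
}

#' Whole-body centre of mass trajectory
#' @inheritParams forward_kinematics
#' @return tibble with columns `x`, `y` (m).
#' @export
centre_of_mass <- function(model, q, qd = NULL, qdd = NULL) {
  fk <- forward_kinematics(model, q, qd, qdd)
  w <- model$segments$mass / model$total_mass
  tibble::tibble(x = as.numeric(fk$cx %*% w), y = as.numeric(fk$cy %*% w))
}

#' Mass matrix and bias forces via inverse dynamics
#'
#' Extracts the joint-space mass matrix and bias (gravity + velocity) vector
#' at a single pose by the unit-acceleration trick, enabling forward dynamics
#' `qdd = M^{-1} (tau_applied - bias)`.
#' @keywords internal
mass_matrix <- function(model, q, qd, grf = NULL, cop = NULL, bwss = 0,
                        extra = list()) {
  nq <- length(model$coordinates)
  bias <- as.numeric(as.matrix(inverse_dynamics(
    model, q, qd, rep(0, nq), grf = grf, cop = cop, bwss = bwss, extra = extra)))
  M <- matrix(0, nq, nq)
  for (j in seq_len(nq)) {
    e <- rep(0, nq); e[j] <- 1
    M[, j] <- as.numeric(as.matrix(inverse_dynamics(
      model, q, qd * 0, e, bwss = 0))) -
      as.numeric(as.matrix(inverse_dynamics(model, q, qd * 0, rep(0, nq), bwss = 0)))
  }
  list(M = M, bias = bias)
}

#' First-order torque-actuator response
#'
#' Idealised torque actuators produce `tau = a_tau * tau_max` where the
#' activation follows first-order dynamics
#' `da_tau/dt = (e_tau - a_tau) / delay` with a 35 ms electromechanical
#' delay.
#'
#' @param e_tau excitation trajectory (function of time or constant).
#' @param times evaluation times (s).
#' @param a0 initial activation.
#' @param delay time constant (s).
#' @return tibble with `time` and `a_tau`.
#' @export
torque_actuator_response <- function(e_tau, times, a0 = 0, delay = 0.035) {
  efun <- if (is.function(e_tau)) e_tau else function(t) rep_len(e_tau, length(t))
  sol <- deSolve::ode(y = c(a = a0), times = times,
                      func = function(t, y, p) list((efun(t) - y[1]) / delay),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  tibble::tibble(time = sol[, 1], a_tau = sol[, 2])
}
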