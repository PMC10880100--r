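#' Cost-function weights
#'
#' The three weight classes of the tracking objective: `w1` (translational
#' tracking, de-emphasised so the pelvis may move vertically to support GRF
#' tracking), `w2` (rotational/GRF tracking, muscle effort, acceleration and
#' reserve regularisation) and `w3` (net-joint-moment tracking and the
#' muscle-state rate regularisation, emphasised so muscle forces reproduce
#' accurate joint moments).
#'
#' @param w1,w2,w3 weights.
#' @return list of weights.
#' @export
cost_weights <- function(w1 = 0.01, w2 = 1, w3 = 10) {
  stopifnot(w1 > 0, w2 > 0, w3 > 0)
  list(w1 = w1, w2 = w2, w3 = w3)
}

#' Derive the tracking cost scale factors
#'
#' Kinematic scales are set directly (2 degrees for rotations, 0.02 m for
#' translations). The moment and force scales are the moment/force required
#' to perform one unit (1 J) of work over the corresponding kinematic scale:
#' `s_tau = 1 / s_rot` (in radians, reported to 3 significant figures) and
#' vertical force scale `1 / s_tr`. Horizontal force scales are reduced by
#' gravity (divided by 9.81, to 2 significant figures).
#'
#' @param s_rot_deg rotational scale (degrees).
#' @param s_tr translational scale (m).
#' @param gravity gravitational acceleration (m/s^2).
#' @param s_res reserve-actuator scale (N m).
#' @return list with `s_rot` (rad), `s_tr`, `s_tau`, `s_grf` (length 2:
#'   horizontal, vertical), `s_res`.
#' @export
derive_scale_factors <- function(s_rot_deg = 2, s_tr = 0.02, gravity = 9.81,
                                 s_res = 2) {
  stopifnot(s_rot_deg > 0, s_tr > 0)
  s_rot <- s_rot_deg * pi / 180
  s_tau <- signif(1 / s_rot, 3)
  s_vert <- 1 / s_tr
  s_horiz <- signif(s_vert / gravity, 2)
  list(s_rot = s_rot, s_tr = s_tr, s_tau = s_tau,
       s_grf = c(horizontal = s_horiz, vertical = s_vert), s_res = s_res)
}

#' Muscle-effort cost
#'
#' Volume-weighted squared activations integrated over the trial:
#' `w2 * sum_j PV_j * integral a_j^2 dt`, penalising the use of larger
#' muscles.
#'
#' @param time time grid (s).
#' @param activations matrix (n x n_muscles).
#' @param pv muscle volume percentages.
#' @param w2 weight.
#' @return scalar cost.
#' @export
effort_cost <- function(time, activations, pv, w2 = 1) {
  activations <- as.matrix(activations)
  stopifnot(length(pv) == ncol(activations))
  w2 * sum(vapply(seq_along(pv), function(j) {
    pv[j] * trapz_integral(time, activations[, j]^2)
  }, numeric(1)))
}

#' Data-tracking cost
#'
#' Scaled sum of squared tracking errors: rotations (weight `w2`, scale
#' `s_rot`), translations (`w1`, `s_tr`), ground reaction forces (`w2`,
#' `s_grf`) and mass-normalised net joint moments (`w3`, `s_tau`).
#'
#' @param time common time grid.
#' @param sim,exp lists with matrices `q_rot`, `q_tr`, `grf`, `njm`
#'   (moments already on the scale being compared, N m/kg).
#' @param scales [derive_scale_factors()] output.
#' @param weights [cost_weights()] output.
#' @return scalar cost.
#' @export
tracking_cost <- function(time, sim, exp, scales = derive_scale_factors(),
                          weights = cost_weights()) {
  acc <- 0
  pair <- function(a, b) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (!all(dim(a) == dim(b))) stop("simulated/experimental grid mismatch")
    a - b
  }
  if (!is.null(sim$q_rot)) {
    e <- pair(sim$q_rot, exp$q_rot) / scales$s_rot
    acc <- acc + weights$w2 * sum(apply(e^2, 2, trapz_integral, time = time))
  }
  if (!is.null(sim$q_tr)) {
    e <- pair(sim$q_tr, exp$q_tr) / scales$s_tr
    acc <- acc + weights$w1 * sum(apply(e^2, 2, trapz_integral, time = time))
  }
  if (!is.null(sim$grf)) {
    e <- sweep(pair(sim$grf, exp$grf), 2, scales$s_grf, `/`)
    acc <- acc + weights$w2 * sum(apply(e^2, 2, trapz_integral, time = time))
  }
  if (!is.null(sim$njm)) {
    e <- pair(sim$njm, exp$njm) / scales$s_tau
    acc <- acc + weights$w3 * sum(apply(e^2, 2, trapz_integral, time = time))
  }
  acc
}

#' Control-regularisation cost
#'
#' Controls scaled by their bounds (`s_bound`) or, for reserve actuators, by
#' `s_res`: accelerations and reserves weighted `w2`, muscle-state rates
#' weighted `w3`.
#'
#' @param time time grid.
#' @param qdd,dft,da,tau_res control matrices (may be `NULL`).
#' @param s_qdd,s_dft,s_da per-channel bound scales.
#' @param scales,weights scale factors and weights.
#' @return scalar cost.
#' @export
control_cost <- function(time, qdd = NULL, dft = NULL, da = NULL,
                         tau_res = NULL, s_qdd = 1, s_dft = 1, s_da = 1,
                         scales = derive_scale_factors(),
                         weights = cost_weights()) {
  acc <- 0
  term <- function(x, s, w) {
    x <- sweep(as.matrix(x), 2, rep_len(s, ncol(as.matrix(x))), `/`)
    w * sum(apply(x^2, 2, trapz_integral, time = time))
  }
  if (!is.null(qdd)) acc <- acc + term(qdd, s_qdd, weights$w2)
  if (!is.null(dft)) acc <- acc + term(dft, s_dft, weights$w3)
  if (!is.null(da)) acc <- acc + term(da, s_da, weights$w3)
  if (!is.null(tau_res)) acc <- acc + term(tau_res, scales$s_res, weights$w2)
  acc
}

trapz_integral <- function(time, y) {
  n <- length(time)
  sum((y[-1] + y[-n]) / 2 * diff(time))
}

#' Legendre-Gauss-Radau collocation matrices
#'
#' Third-order state parameterisation with the right-hand Radau points (the
#' interval end is a collocation point), i.e. four points per interval
#' including the interval start. Returns the differentiation matrix `C`
#' (d x (d+1): derivative of the Lagrange basis at each collocation point),
#' the end-state weights `D` and the quadrature weights `B`.
#'
#' @param degree polynomial degree (number of collocation points).
#' @return list with `tau` (collocation points), `C`, `D`, `B`.
#' @export
radau_collocation <- function(degree = 3) {
  tau <- switch(as.character(degree),
                "1" = 1,
                "2" = c(1 / 3, 1),
                "3" = c(0.155051025721682, 0.644948974278318, 1),
                stop("unsupported degree"))
  pts <- c(0, tau)
  d1 <- length(pts)
  Cm <- matrix(0, degree, d1)
  Dv <- numeric(d1)
  Bv <- numeric(degree)
  for (j in seq_len(d1)) {
    # Lagrange basis polynomial through pts with value 1 at pts[j]
    coef <- 1
    for (r in seq_len(d1)) {
      if (r == j) next
      # multiply by (x - pts[r]) / (pts[j] - pts[r])
      coef <- c(0, coef) - c(coef * pts[r], 0)
      coef <- coef / (pts[j] - pts[r])
    }
    # coef: highest order first after the construction above? build value fn
    poly_val <- function(x) {
      # coef stored with increasing powers: rebuild carefully
      sum(coef * x^(seq_along(coef) - 1))
    }
    # the construction yields coefficients in increasing power order
    dcoef <- coef[-1] * seq_len(length(coef) - 1)
    dpoly_val <- function(x) sum(dcoef * x^(seq_along(dcoef) - 1))
    for (r in seq_len(degree)) Cm[r, j] <- dpoly_val(tau[r])
    Dv[j] <- poly_val(1)
    if (j > 1) {
      icoef <- coef / seq_along(coef)
      Bv[j - 1] <- sum(icoef * 1^(seq_along(icoef)))
    }
  }
  list(tau = tau, C = Cm, D = Dv, B = Bv)
}
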