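#' Smoothed Hunt-Crossley contact force
#'
#' Normal contact force of one sphere against the ground plane, as a function
#' of penetration depth and penetration velocity:
#' `F = k * dp^(3/2) * (1 + 3/2 * c * ddot)` where `dp` is a smooth positive
#' part of the penetration, followed by a smooth non-negativity clamp, so the
#' force is infinitely differentiable everywhere and essentially zero out of
#' contact. The tangential component is a smooth Coulomb friction term
#' `-mu * F_n * tanh(v_slip / v0)`.
#'
#' @param penetration depth of the sphere's lowest point below the ground
#'   (m; negative when clear of the ground).
#' @param penetration_velocity rate of change of penetration (m/s).
#' @param slip_velocity horizontal velocity of the sphere centre (m/s).
#' @param stiffness Hunt-Crossley stiffness (N/m^2 in the 3/2-power law).
#' @param damping Hunt-Crossley damping (s/m).
#' @param model a [hop_model()] supplying the smoothing constants and the
#'   friction coefficient.
#' @return tibble with columns `normal` and `tangential` (N).
#' @export
contact_force <- function(penetration, penetration_velocity = 0,
                          slip_velocity = 0,
                          stiffness = NULL, damping = NULL,
                          model = hop_model(fit_polynomials = FALSE)) {
  cp <- model$contact
  if (is.null(stiffness)) stiffness <- cp$stiffness
  if (is.null(damping)) damping <- cp$damping
  stopifnot(stiffness > 0, damping >= 0)
  n <- max(length(penetration), length(penetration_velocity), length(slip_velocity))
  out <- cpp_contact_force(rep_len(as.double(penetration), n),
                           rep_len(as.double(penetration_velocity), n),
                           rep_len(as.double(slip_velocity), n),
                           stiffness, damping, cp$mu, cp$v0, cp$eps_d, cp$eps_f)
  tibble::as_tibble(out)
}

#' Per-sphere contact forces along a trajectory
#'
#' Evaluates the contact model for every sphere of the model along a
#' coordinate trajectory.
#'
#' @param model a [hop_model()].
#' @param q,qd coordinate trajectories (n x n_coordinates).
#' @param stiffness,damping contact parameters (shared across spheres).
#' @param spheres optional n_sph x 2 matrix of sphere positions in the foot
#'   frame (defaults to the model's).
#' @return list with `force_x`, `force_y` (n x n_sph matrices), sphere centre
#'   positions `cx`, `cy`, and totals `total_x`, `total_y`, plus the
#'   force-weighted centre of pressure `cop_x` (NA out of contact).
#' @export
sphere_contact_forces <- function(model, q, qd,
                                  stiffness = model$contact$stiffness,
                                  damping = model$contact$damping,
                                  spheres = NULL) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (is.null(dim(qd))) qd <- matrix(qd, nrow = 1)
  if (is.null(spheres)) spheres <- as.matrix(model$spheres[, c("x", "y")])
  kin <- cpp_sphere_kinematics(model_blob_bare(model), q, as.matrix(qd), spheres)
  cp <- model$contact
  nsph <- nrow(spheres)
  fx <- fy <- matrix(0, nrow(q), nsph)
  for (s in seq_len(nsph)) {
    f <- cpp_contact_force(kin$penetration[, s], kin$penetration_velocity[, s],
                           kin$slip_velocity[, s], stiffness, damping,
                           cp$mu, cp$v0, cp$eps_d, cp$eps_f)
    fx[, s] <- f$tangential
    fy[, s] <- f$normal
  }
  ty <- rowSums(fy)
  copx <- rowSums(fy * kin$cx) / ifelse(ty > 1e-6, ty, NA)
  list(force_x = fx, force_y = fy, cx = kin$cx, cy = kin$cy,
       penetration = kin$penetration,
       total_x = rowSums(fx), total_y = ty, cop_x = copx)
}
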