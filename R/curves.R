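#' Dimensionless Hill-type muscle curve set
#'
#' Constructs the set of dimensionless curves used by every muscle-tendon unit:
#' a three-Gaussian active force-length curve, a logarithmic force-velocity
#' curve, an exponential passive (parallel) force-length curve, and an
#' exponential tendon (series) force-length curve. The active and
#' force-velocity curves are normalised so that `f_act(1) = 1` and
#' `f_v(0) = 1` exactly. The tendon curve's offset is tied to its stiffness
#' parameter `kT` so that the normalised tendon force is zero at zero strain;
#' consequently the tendon cannot transmit compressive force.
#'
#' @param kT tendon stiffness parameter (dimensionless exponential rate).
#'   The shipped default is the value obtained by [calibrate_tendon_stiffness()]
#'   so that the tendon curve has slope 35 at 4% strain.
#' @param beta passive fibre damping coefficient (dimensionless, multiplies the
#'   normalised fibre velocity inside the Hill equilibrium). Small positive
#'   damping keeps the equilibrium well-posed at zero activation.
#' @param active 3 x 4 matrix of Gaussian coefficients (amplitude, centre,
#'   width offset, width slope) for the active force-length curve.
#' @param fv length-4 coefficient vector of the force-velocity curve.
#' @param kpe,e0 shape and strain-scale of the passive force-length curve.
#' @param c1,c3 tendon curve amplitude and offset coefficients.
#'
#' @return An object of class `hop_curves`: a list of coefficients plus the
#'   normalisation constants, suitable for [eval_muscle_curves()].
#' @export
muscle_curves <- function(kT = 35,
                          beta = 0.1,
                          active = rbind(c(0.815, 1.055, 0.162, 0.0633),
                                         c(0.433, 0.717, -0.0299, 0.2),
                                         c(0.100, 1.000, 0.354, 0.0)),
                          fv = c(-0.318, -8.149, -0.374, 0.886),
                          kpe = 4, e0 = 0.6, c1 = 0.2, c3 = 0.25) {
  stopifnot(is.matrix(active), nrow(active) == 3, ncol(active) == 4,
            length(fv) == 4, kT > 0, kpe > 0, e0 > 0, c1 > 0, c3 > 0)
  cr <- list(active = active, fv = fv, kpe = kpe, e0 = e0,
             c1 = c1, c3 = c3, kT = kT, beta = beta,
             act_norm = 1, fv_norm = 1)
  cr$act_norm <- .act_raw(cr, 1)
  cr$fv_norm <- .fv_raw(cr, 0)
  structure(cr, class = "hop_curves")
}

.act_raw <- function(cr, l) {
  a <- cr$active
  out <- 0
  for (i in 1:3) {
    z <- (l - a[i, 2]) / (a[i, 3] + a[i, 4] * l)
    out <- out + a[i, 1] * exp(-0.5 * z^2)
  }
  out
}

.fv_raw <- function(cr, v) {
  d <- cr$fv
  z <- d[2] * v + d[3]
  d[1] * log(z + sqrt(z^2 + 1)) + d[4]
}

#' Tendon curve offset implied by the stiffness parameter
#'
#' The tendon force-length curve is `c1 * exp(kT * (lt_norm - c2)) - c3` with
#' `c2` chosen so that the force is exactly zero at `lt_norm = 1`.
#' @keywords internal
.tendon_c2 <- function(cr) 1 - log(cr$c3 / cr$c1) / cr$kT

#' Evaluate the dimensionless muscle curves
#'
#' @param lm_norm normalised fibre length (fibre length / optimum fibre length).
#' @param vm_norm normalised fibre velocity (fibre velocity / maximum
#'   shortening velocity; negative = shortening).
#' @param tendon_strain tendon strain (tendon length / slack length - 1).
#' @param curves a [muscle_curves()] object.
#'
#' @return A tibble with columns `f_act_fl`, `f_v`, `f_pas`, `f_tendon`
#'   (dimensionless forces). All curves are smooth (infinitely differentiable)
#'   over the full real line.
#' @export
eval_muscle_curves <- function(lm_norm, vm_norm = 0, tendon_strain = 0,
                               curves = muscle_curves()) {
  n <- max(length(lm_norm), length(vm_norm), length(tendon_strain))
  lm_norm <- rep_len(lm_norm, n)
  vm_norm <- rep_len(vm_norm, n)
  tendon_strain <- rep_len(tendon_strain, n)
  if (!all(is.finite(lm_norm), is.finite(vm_norm), is.finite(tendon_strain))) {
    stop("non-finite input to eval_muscle_curves (lm_norm/vm_norm/tendon_strain)")
  }
  if (any(lm_norm <= 0)) stop("lm_norm must be positive")
  out <- cpp_muscle_curves(as.double(lm_norm), as.double(vm_norm),
                           as.double(tendon_strain), unclass(curves))
  tibble::as_tibble(out)
}

#' Calibrate the tendon stiffness parameter
#'
#' Adjusts the tendon curve's stiffness parameter `kT` so that the slope of
#' the normalised tendon force-length curve with respect to strain equals
#' `target_gradient` at `target_strain`. Because the curve offset is tied to
#' `kT` (zero force at zero strain), the slope at strain `s` is
#' `kT * c3 * exp(kT * s)`, which is strictly increasing in `kT`, so the
#' calibration root is unique.
#'
#' @param curves a [muscle_curves()] object (its `kT` is replaced).
#' @param target_gradient desired slope of normalised tendon force vs strain.
#' @param target_strain strain at which the slope is prescribed (must be > 0).
#' @param interval search bracket for `kT`.
#'
#' @return The calibrated `hop_curves` object.
#' @export
calibrate_tendon_stiffness <- function(curves = muscle_curves(),
                                       target_gradient = 35,
                                       target_strain = 0.04,
                                       interval = c(1, 500)) {
  if (target_strain <= 0) {
    stop("target_strain must be positive: the slack point has no prescribed slope")
  }
  stopifnot(target_gradient > 0)
  slope_gap <- function(kT) kT * curves$c3 * exp(kT * target_strain) - target_gradient
  lo <- slope_gap(interval[1]); hi <- slope_gap(interval[2])
  if (lo * hi > 0) {
    stop(sprintf("no tendon stiffness root in bracket [%g, %g]", interval[1], interval[2]))
  }
  root <- uniroot(slope_gap, interval, tol = 1e-12)$root
  curves$kT <- root
  curves
}

#' Hill equilibrium residual
#'
#' Residual of the force balance between the tendon and the
#' pennation-projected fibre force, in the implicit muscle-dynamics
#' formulation: the normalised tendon force and its time derivative are
#' treated as a state/control pair, from which tendon length and velocity are
#' recovered by inverting the tendon curve; the fibre state follows from the
#' muscle-tendon length and velocity under a fixed-height pennation model.
#' The residual is zero exactly when
#' `F_t = cos(pennation) * (a * f_act(lm) * f_v(vm) + f_pas(lm) + beta * vm)`.
#'
#' @param a_m muscle activation in `[0, 1]`.
#' @param lmt muscle-tendon unit length (m).
#' @param vmt muscle-tendon unit lengthening velocity (m/s).
#' @param ft_norm normalised tendon force (>= 0).
#' @param dft_norm time derivative of the normalised tendon force (1/s).
#' @param mtu a one-row MTU parameter list/tibble with `f_max_iso`, `l_opt`,
#'   `pennation_opt`, `l_slack`, `v_max` (in optimum fibre lengths per second).
#' @param curves a [muscle_curves()] object.
#'
#' @return Dimensionless residual (vectorised over the inputs).
#' @export
hill_equilibrium_residual <- function(a_m, lmt, vmt, ft_norm, dft_norm, mtu,
                                      curves = muscle_curves()) {
  c2 <- .tendon_c2(curves)
  lt_norm <- c2 + log((ft_norm + curves$c3) / curves$c1) / curves$kT
  lt <- lt_norm * mtu$l_slack
  lm_proj <- lmt - lt
  h <- mtu$l_opt * sin(mtu$pennation_opt)
  lm <- sqrt(lm_proj^2 + h^2)
  if (any(lm <= 0)) stop("fibre length must be positive")
  cos_p <- lm_proj / lm
  lm_norm <- lm / mtu$l_opt
  dft_dlt <- curves$kT * (ft_norm + curves$c3) / mtu$l_slack
  vt <- dft_norm / dft_dlt
  vm <- (vmt - vt) * cos_p
  vm_norm <- vm / (mtu$v_max * mtu$l_opt)
  cv <- eval_muscle_curves(lm_norm, vm_norm, 0, curves)
  fm <- a_m * cv$f_act_fl * cv$f_v + cv$f_pas + curves$beta * vm_norm
  ft_norm - cos_p * fm
}

#' Activation-rate envelope constraints
#'
#' The two inequality constraints of the excitation-activation model: with
#' first-order dynamics `da/dt = (e - a) / tau(e, a)` (time constant `t_a`
#' when exciting, `t_d` when de-exciting) and excitation bounded in `[0, 1]`,
#' the admissible activation rates lie between `-a / t_d` and `(1 - a) / t_a`.
#'
#' @param a_m activation in `[0, 1]`.
#' @param da_m activation rate (1/s).
#' @param t_a activation time constant (s).
#' @param t_d deactivation time constant (s).
#'
#' @return A tibble with columns `g_act` and `g_deact`; both are `<= 0` iff
#'   the rate is admissible.
#' @export
activation_rate_constraints <- function(a_m, da_m, t_a = 0.015, t_d = 0.06) {
  tibble::tibble(g_act = da_m - (1 - a_m) / t_a,
                 g_deact = -da_m - a_m / t_d)
}
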