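#' Muscle-adaptation model parameters
#'
#' Parameters of the cross-sectional-area growth model
#' `dCSA/dt = (1/tau) * (CSA_max - CSA)/(CSA_max - 1) * delta * max(F - F0, 0)`:
#' a first-order approach to a physiological ceiling `CSA_max`, driven by the
#' excess of the normalised quadriceps force over the loading threshold `F0`
#' (0.2, i.e. 20% of the one-repetition maximum). Growth-only: the drive is
#' clamped at zero below threshold (the model does not represent atrophy).
#' CSA is normalised to baseline (`CSA0 = 1`).
#'
#' @param tau time-like rate constant (s of loaded exercise).
#' @param delta dimensionless gain. Only `delta / tau` is identified by the
#'   model's behaviour, so calibration fixes `delta = 1` and solves for
#'   `tau`.
#' @param csa_max normalised physiological maximum (> 1).
#' @param f0 loading threshold (fraction of summed maximum isometric force).
#' @return list of class `hop_adaptation_params`.
#' @export
adaptation_params <- function(tau = NULL, delta = 1, csa_max = 1.2, f0 = 0.2) {
  if (is.null(tau)) {
    tau <- calibrate_adaptation()$tau
  }
  stopifnot(tau > 0, delta > 0, csa_max > 1, f0 > 0, f0 < 1)
  structure(list(tau = tau, delta = delta, csa_max = csa_max, csa0 = 1,
                 f0 = f0), class = "hop_adaptation_params")
}

#' Growth rate of muscle cross-sectional area
#'
#' @param csa current normalised cross-sectional area in `[1, csa_max]`.
#' @param f normalised quadriceps force (fraction of summed maximum
#'   isometric force).
#' @param params an [adaptation_params()].
#' @return growth rate (1/s), non-negative, zero at or below the threshold
#'   and at the ceiling.
#' @export
csa_rate <- function(csa, f, params) {
  if (any(csa > params$csa_max + 1e-12)) {
    stop("csa exceeds csa_max")
  }
  if (any(csa < params$csa0 - 1e-12)) stop("csa below baseline")
  drive <- pmax(f - params$f0, 0)
  (1 / params$tau) * (params$csa_max - csa) / (params$csa_max - 1) *
    params$delta * drive
}

#' Simulate CSA growth over repeated force cycles
#'
#' Integrates the adaptation model over `n_reps` back-to-back repetitions of
#' a force profile (adaptive ODE stepping; inter-repetition rest is not
#' modelled explicitly, consistent with parameters calibrated on whole
#' training programmes).
#'
#' @param profile tibble/list with `time` (s, one cycle) and `f_quad_norm`.
#' @param params an [adaptation_params()].
#' @param n_reps number of repetitions.
#' @param n_out number of output samples.
#' @return tibble with `time` and `csa`.
#' @export
simulate_growth <- function(profile, params, n_reps, n_out = 200) {
  f <- profile$f_quad_norm
  tt <- profile$time - profile$time[1]
  if (!all(is.finite(f)) || !all(is.finite(tt))) {
    stop("non-finite force profile")
  }
  period <- tail(tt, 1)
  ffun <- approxfun(tt, f, rule = 2)
  t_end <- n_reps * period
  times <- unique(c(seq(0, t_end, length.out = n_out), t_end))
  sol <- deSolve::lsoda(
    c(csa = params$csa0), times,
    function(t, y, p) {
      list(csa_rate(min(y[1], params$csa_max), ffun(t %% period), params))
    }, NULL, rtol = 1e-9, atol = 1e-11)
  tibble::tibble(time = sol[, 1], csa = pmin(sol[, 2], params$csa_max))
}

# cumulative supra-threshold drive of one cycle (exact, trapezoidal)
cycle_drive <- function(profile, params) {
  tt <- profile$time - profile$time[1]
  trapz_integral(tt, pmax(profile$f_quad_norm - params$f0, 0))
}

# The model is separable: with Phi(t) the cumulative supra-threshold drive,
#   CSA(t) = csa_max - (csa_max - 1) * exp(-delta * Phi(t) / (tau * (csa_max - 1))).
csa_after_drive <- function(phi, params) {
  params$csa_max - (params$csa_max - params$csa0) *
    exp(-params$delta * phi / (params$tau * (params$csa_max - 1)))
}

#' Repetitions required to reach a target CSA increase
#'
#' Smallest whole number of repetitions of the force profile after which the
#' CSA reaches `target`. Uses the exact per-repetition recursion of the
#' separable growth model (each repetition contributes a fixed cumulative
#' supra-threshold drive), which the numerical integrator reproduces.
#'
#' @param profile force profile over one cycle (see [simulate_growth()]).
#' @param params an [adaptation_params()].
#' @param target target normalised CSA (default the 3.37% minimal
#'   worthwhile increase).
#' @return list with `reps` (integer, or `Inf`), `feasible`, and the
#'   per-repetition drive. An unreachable target (profile never above
#'   threshold, or target above `csa_max`) yields `feasible = FALSE` with
#'   `reps = Inf`, not an error.
#' @export
reps_to_target <- function(profile, params, target = 1.0337) {
  if (target <= params$csa0) {
    return(list(reps = 0L, feasible = TRUE, drive_per_rep = cycle_drive(profile, params)))
  }
  phi_rep <- cycle_drive(profile, params)
  if (phi_rep <= 0 || target > params$csa_max) {
    return(list(reps = Inf, feasible = FALSE, drive_per_rep = phi_rep))
  }
  phi_need <- -params$tau * (params$csa_max - 1) / params$delta *
    log((params$csa_max - target) / (params$csa_max - params$csa0))
  list(reps = as.integer(ceiling(phi_need / phi_rep - 1e-9)), feasible = TRUE,
       drive_per_rep = phi_rep)
}

#' Convert a repetition count into a training schedule
#'
#' Week-normalised set arithmetic: with 12 repetitions per set and 3
#' sessions per week, the sets to complete per session are
#' `ceiling(reps / 12 / 3)`.
#'
#' @param reps_required repetitions.
#' @param reps_per_set repetitions per set.
#' @param sessions_per_week training sessions per week.
#' @return sets per session (integer).
#' @export
reps_to_schedule <- function(reps_required, reps_per_set = 12,
                             sessions_per_week = 3) {
  stopifnot(reps_required >= 0)
  as.integer(ceiling(reps_required / reps_per_set / sessions_per_week - 1e-9))
}

#' Calibrate the adaptation rate constant
#'
#' Solves for `tau` (with `delta` fixed at 1: only their ratio is
#' identified) so that a reference loading condition reaches the target
#' increase after a prescribed number of repetitions. The shipped default
#' reference emulates a heavy-resistance training programme: a constant
#' normalised force of 0.75 held for 3 s per repetition reaches the 3.37%
#' minimal worthwhile increase after 108 repetitions (9 sets of 12, the
#' middle of a 6-12 set fortnight at 3 sessions per week).
#'
#' @param reps_at_reference repetitions to the target at the reference load.
#' @param reference_force constant normalised force of the reference.
#' @param rep_duration seconds under load per repetition.
#' @param target_increase target fractional CSA increase (0.0337 = 3.37%).
#' @param csa_max,f0 remaining model constants.
#' @return An [adaptation_params()] with the calibrated `tau`.
#' @export
calibrate_adaptation <- function(reps_at_reference = 108,
                                 reference_force = 0.75,
                                 rep_duration = 3,
                                 target_increase = 0.0337,
                                 csa_max = 1.2, f0 = 0.2) {
  if (reference_force <= f0) {
    stop("reference force does not exceed the loading threshold: unreachable")
  }
  target <- 1 + target_increase
  if (target >= csa_max) stop("target above the physiological ceiling")
  phi_total <- reps_at_reference * rep_duration * (reference_force - f0)
  # invert the separable solution for tau (delta = 1)
  tau <- -phi_total / ((csa_max - 1) * log((csa_max - target) / (csa_max - 1)))
  structure(list(tau = tau, delta = 1, csa_max = csa_max, csa0 = 1, f0 = f0),
            class = "hop_adaptation_params")
}

#' Quadriceps force profile of a tracking solution
#'
#' Cumulative active plus parallel-passive fibre forces of the four knee
#' extensors (rectus femoris and the three vasti), projected along the
#' tendon and normalised to their summed maximum isometric force, over one
#' hopping cycle (touchdown to touchdown). In the implicit muscle
#' formulation this equals the normalised tendon force weighted by each
#' muscle's maximum isometric force.
#'
#' @param solution a `hop_ocp_solution`.
#' @param model the model used.
#' @return tibble with `time` and `f_quad_norm` (class `hop_force_profile`).
#' @export
quadriceps_profile <- function(solution, model) {
  quad <- c("rectus_femoris", "vastus_lateralis", "vastus_intermedius",
            "vastus_medialis")
  fmax <- model$mtus$f_max_iso[match(quad, model$mtus$name)]
  ften <- sweep(solution$tendon_force_norm[-1, quad, drop = FALSE], 2, fmax, `*`)
  td <- solution$nlp$tracking$touchdown_times
  tt <- solution$time[-1]
  mask <- tt >= td[1] & tt <= td[2]
  out <- tibble::tibble(time = tt[mask],
                        f_quad_norm = rowSums(ften[mask, , drop = FALSE]) / sum(fmax))
  class(out) <- c("hop_force_profile", class(out))
  out
}

#' Hypothetical training volume from a quadriceps force profile
#'
#' Runs the adaptation model on a force profile and reports the repetitions
#' and weekly sets required for the minimal worthwhile CSA increase.
#'
#' @param profile a force profile (see [quadriceps_profile()]).
#' @param params an [adaptation_params()].
#' @param target_increase fractional CSA increase sought.
#' @param reps_per_set,sessions_per_week schedule constants.
#' @return one-row tibble: `reps_required`, `sets_per_session`, `feasible`,
#'   `drive_per_rep`, `peak_force`.
#' @export
training_volume <- function(profile, params = adaptation_params(),
                            target_increase = 0.0337,
                            reps_per_set = 12, sessions_per_week = 3) {
  res <- reps_to_target(profile, params, target = 1 + target_increase)
  tibble::tibble(
    reps_required = res$reps,
    sets_per_session = if (is.finite(res$reps))
      reps_to_schedule(res$reps, reps_per_set, sessions_per_week) else NA_integer_,
    feasible = res$feasible,
    drive_per_rep = res$drive_per_rep,
    peak_force = max(profile$f_quad_norm))
}
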