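#' Detect foot touchdowns from the vertical ground reaction force
#'
#' A touchdown is a rising crossing of the vertical GRF through `threshold`.
#'
#' @param time,grf_y force-platform time series.
#' @param threshold vertical-force threshold (N).
#' @return Times of rising crossings (s), linearly interpolated.
#' @export
detect_touchdowns <- function(time, grf_y, threshold = 10) {
  below <- grf_y < threshold
  idx <- which(below[-length(below)] & !below[-1])
  if (!length(idx)) return(numeric(0))
  vapply(idx, function(i) {
    f0 <- grf_y[i]; f1 <- grf_y[i + 1]
    time[i] + (threshold - f0) / (f1 - f0) * (time[i + 1] - time[i])
  }, numeric(1))
}

#' Crop a trial around consecutive touchdowns
#'
#' Crops to `pre_window` seconds before the first detected touchdown and
#' `pre_window` seconds after the following touchdown (intersected with the
#' available data), recording the touchdown times.
#'
#' @param raw a [raw_trial()].
#' @param pre_window window either side of the touchdown pair (s).
#' @param threshold vertical-GRF touchdown threshold (N).
#' @return The cropped trial with attribute `touchdown_times`.
#' @export
crop_trial <- function(raw, pre_window = 0.15, threshold = 10) {
  td <- select_touchdown_pair(raw, pre_window, threshold)
  t0 <- max(td[1] - pre_window, min(raw$forces$time), min(raw$kinematics$time))
  t1 <- min(td[2] + pre_window, max(raw$forces$time), max(raw$kinematics$time))
  out <- raw
  out$kinematics <- raw$kinematics[raw$kinematics$time >= t0 & raw$kinematics$time <= t1, ]
  out$forces <- raw$forces[raw$forces$time >= t0 & raw$forces$time <= t1, ]
  attr(out, "touchdown_times") <- td
  out
}

# first pair of consecutive touchdowns with a full pre-window margin inside
# the recorded streams
select_touchdown_pair <- function(raw, pre_window = 0.15, threshold = 10) {
  td <- detect_touchdowns(raw$forces$time, raw$forces$grf_y, threshold)
  if (length(td) < 2) {
    stop(sprintf("fewer than 2 touchdowns found (vertical GRF threshold %g N)",
                 threshold))
  }
  tmin <- max(min(raw$forces$time), min(raw$kinematics$time))
  tmax <- min(max(raw$forces$time), max(raw$kinematics$time))
  for (i in seq_len(length(td) - 1)) {
    if (td[i] - pre_window >= tmin && td[i + 1] + pre_window <= tmax) {
      return(td[i:(i + 1)])
    }
  }
  td[1:2]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Second-order Butterworth applied forward and backward (zero phase lag;
#' effective magnitude response is the squared single-pass response).
#'
#' @param x signal.
#' @param rate sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz).
#' @param order filter order (single pass).
#' @return Filtered signal.
#' @export
lowpass_filter <- function(x, rate, cutoff = 6, order = 2) {
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  if (length(x) < 3 * (order + 1) * 3) stop("signal too short to filter stably")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # reflective padding keeps the ends well-behaved
  npad <- min(length(x) - 1, round(rate))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + length(x))]
}

#' Cubic-spline resampling with derivatives
#'
#' Fits an interpolating cubic spline and evaluates it, with its exact first
#' and second derivatives, on a new grid.
#'
#' @param time sample times (strictly increasing, at least 4).
#' @param x signal values.
#' @param t_out output grid.
#' @return tibble with `time`, `value`, `d1`, `d2`.
#' @export
spline_resample <- function(time, x, t_out) {
  if (length(time) < 4) stop("at least 4 samples required for spline resampling")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  sf <- splinefun(time, x, method = "fmm")
  tibble::tibble(time = t_out, value = sf(t_out),
                 d1 = sf(t_out, deriv = 1), d2 = sf(t_out, deriv = 2))
}

#' Net joint moments from processed streams
#'
#' Per-frame inverse dynamics: returns the net generalised forces at the
#' articulated joints, with the pelvis (root) rows reported separately as
#' experimental residuals.
#'
#' @param model a [hop_model()].
#' @param q,qd,qdd coordinate trajectories (n x n_coordinates).
#' @param grf n x 2 ground reaction force (N).
#' @param cop centre-of-pressure x position (m).
#' @param bwss body-weight-support force (N, scalar or length n).
#' @return list with `njm` (tibble, one column per articulated coordinate)
#'   and `residuals` (tibble: pelvis rows).
#' @export
compute_net_joint_moments <- function(model, q, qd, qdd, grf, cop, bwss) {
  tau <- inverse_dynamics(model, q, qd, qdd, grf = grf, cop = cop, bwss = bwss)
  list(njm = tau[, -(1:3)], residuals = tau[, 1:3])
}

#' Preprocess a raw trial into tracking data
#'
#' The full pipeline from a raw trial to OCP-ready tracking data: crop around
#' two consecutive touchdowns, low-pass filter every stream (6 Hz second-order
#' zero-phase Butterworth), resample kinematics with cubic splines onto the
#' collocation mesh (velocities and accelerations are the spline
#' derivatives), and run inverse dynamics to obtain the experimental net
#' joint moments.
#'
#' @param raw a [raw_trial()].
#' @param model a [hop_model()].
#' @param n_mesh number of mesh intervals (the grid has `n_mesh + 1` points).
#' @param cutoff filter cutoff (Hz).
#' @param threshold touchdown threshold (N).
#' @param pre_window crop window (s).
#' @return An object of class `hop_tracking`: time grid, `q`, `qd`, `qdd`
#'   matrices, `grf` (n x 2), `cop`, `bwss`, `njm` (articulated joints),
#'   `residuals` (pelvis rows), touchdown times, mass and gravity level.
#' @export
preprocess_trial <- function(raw, model, n_mesh = 50, cutoff = 6,
                             threshold = 10, pre_window = 0.15) {
  # filter the full-length streams first so that start-up artifacts of the
  # zero-phase filter fall outside the analysis window, then crop
  filt <- raw
  for (cn in setdiff(names(filt$kinematics), "time")) {
    filt$kinematics[[cn]] <- lowpass_filter(filt$kinematics[[cn]], raw$rate_kin, cutoff)
  }
  for (cn in c("grf_x", "grf_y", "bwss")) {
    filt$forces[[cn]] <- lowpass_filter(filt$forces[[cn]], raw$rate_force, cutoff)
  }
  td <- select_touchdown_pair(filt, pre_window, threshold)
  # splines are built on the full filtered record and evaluated only inside
  # the crop window, so no end-condition artifact enters the mesh
  kin <- filt$kinematics
  frc <- filt$forces
  # centre of pressure: fill flight-phase gaps before smoothing lightly
  cop <- frc$cop_x
  if (anyNA(cop)) {
    ok <- which(!is.na(cop))
    if (!length(ok)) stop("centre of pressure entirely missing")
    cop <- approxfun(frc$time[ok], cop[ok], rule = 2)(frc$time)
  }
  frc$cop_x <- cop
  t0 <- max(td[1] - pre_window, min(kin$time), min(frc$time))
  t1 <- min(td[2] + pre_window, max(kin$time), max(frc$time))
  tgrid <- seq(t0, t1, length.out = n_mesh + 1)
  nq <- length(model$coordinates)
  q <- qd <- qdd <- matrix(0, n_mesh + 1, nq,
                           dimnames = list(NULL, model$coordinates))
  for (j in seq_len(nq)) {
    cn <- model$coordinates[j]
    if (!cn %in% names(kin)) stop("missing kinematic channel: ", cn)
    rs <- spline_resample(kin$time, kin[[cn]], tgrid)
    q[, j] <- rs$value; qd[, j] <- rs$d1; qdd[, j] <- rs$d2
  }
  grf <- cbind(spline_resample(frc$time, frc$grf_x, tgrid)$value,
               spline_resample(frc$time, frc$grf_y, tgrid)$value)
  colnames(grf) <- c("grf_x", "grf_y")
  cop_g <- spline_resample(frc$time, frc$cop_x, tgrid)$value
  bwss_g <- spline_resample(frc$time, frc$bwss, tgrid)$value
  id <- compute_net_joint_moments(model, q, qd, qdd, grf, cop_g, bwss_g)
  structure(list(time = tgrid, q = q, qd = qd, qdd = qdd,
                 grf = grf, cop = cop_g, bwss = bwss_g,
                 njm = id$njm, residuals = id$residuals,
                 touchdown_times = td, mass = raw$mass, g_level = raw$g_level),
            class = "hop_tracking")
}

#' @export
print.hop_tracking <- function(x, ...) {
  cat(sprintf("<hop_tracking> g = %.2f: %d mesh points over %.3f s, touchdowns at %.3f / %.3f s\n",
              x$g_level, length(x$time) - 1, diff(range(x$time)),
              x$touchdown_times[1], x$touchdown_times[2]))
  invisible(x)
}

#' Tidy a tracking-data object into a long tibble
#'
#' @param x a `hop_tracking` object.
#' @param ... unused.
#' @return Long tibble with `time`, `channel`, `value`.
#' @export
tidy.hop_tracking <- function(x, ...) {
  wide <- tibble::as_tibble(cbind(time = x$time, x$q, setNames(as.data.frame(x$grf),
                                                               c("grf_x", "grf_y")),
                                  bwss = x$bwss, as.data.frame(x$njm)))
  tidyr::pivot_longer(wide, -"time", names_to = "channel", values_to = "value")
}
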