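#' Planar musculoskeletal hopping model
#'
#' Builds the reduced planar model used throughout the package: a five-segment
#' tree (pelvis root with two translations and a tilt, torso via a lumbar
#' joint, thigh, shank, foot) with 10 Hill-type muscle-tendon units spanning
#' hip, knee and ankle, one idealised lumbar torque actuator, and two
#' foot-ground contact spheres (heel, toe). Segment masses are distributed so
#' they sum to `mass`; the contralateral (flexed, non-hopping) leg is lumped
#' into the pelvis segment. Geometry is stored as via-point paths fixed in
#' segment frames, which gives an exact muscle-length function used to fit
#' the polynomial geometry.
#'
#' Coordinate conventions (sagittal plane, x forward, y up, angles
#' counter-clockwise positive): hip flexion positive, knee flexion negative,
#' ankle dorsiflexion positive.
#'
#' @param mass total body mass (kg).
#' @param height stature (m); retained as metadata (the default geometry is
#'   for an adult of about this stature).
#' @param curves a [muscle_curves()] object; by default tendon stiffness is
#'   calibrated to slope 35 at 4% strain.
#' @param fit_polynomials fit the degree-`degree` muscle-geometry polynomials
#'   at construction (required by the tracking OCP).
#' @param degree,n_poses,seed,margin polynomial-fit configuration passed to
#'   [fit_mtu_polynomials()].
#'
#' @return An object of class `hop_model`.
#' @export
hop_model <- function(mass = 79.9, height = 1.82,
                      curves = calibrate_tendon_stiffness(),
                      fit_polynomials = TRUE,
                      degree = 6, n_poses = 2000, seed = 1, margin = 0.2) {
  stopifnot(mass > 0, height > 0)
  mfrac <- mass / 79.9
  segments <- tibble::tibble(
    name      = c("pelvis", "torso", "thigh", "shank", "foot"),
    parent    = c(NA, "pelvis", "pelvis", "thigh", "shank"),
    parent_joint = c(NA, "lumbar", "hip", "knee", "ankle"),
    joint_x   = c(NA, 0.00, 0.00, 0.00, 0.00),
    joint_y   = c(NA, 0.08, -0.07, -0.45, -0.44),
    mass      = mfrac * c(30.5, 31.0, 12.0, 5.0, 1.4),
    com_x     = c(0.00, 0.00, 0.00, 0.00, 0.06),
    com_y     = c(0.00, 0.24, -0.19, -0.19, -0.03),
    inertia_zz = mfrac * c(0.90, 2.50, 0.20, 0.07, 0.010),
    length    = c(0.15, 0.55, 0.45, 0.44, 0.25)
  )
  coordinates <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
                   "lumbar", "hip", "knee", "ankle")
  coord_type <- c("translation", "translation", "rotation",
                  "rotation", "rotation", "rotation", "rotation")
  # expected range of motion per rotational coordinate (rad)
  rom <- list(lumbar = c(-0.35, 0.35), hip = c(-0.5, 1.2),
              knee = c(-1.8, 0.3), ankle = c(-1.0, 0.8))

  paths <- list(
    iliopsoas = path_tbl("pelvis", 0.05, 0.00, "thigh", 0.02, -0.12),
    glutei    = path_tbl("pelvis", -0.08, 0.02, "thigh", -0.03, -0.10),
    # the distal thigh via point acts as a patellar pulley: it keeps the
    # extensor path anterior to the knee centre so the moment arm does not
    # collapse at deep flexion
    rectus_femoris = rbind(path_tbl("pelvis", 0.04, -0.02, "thigh", 0.065, -0.47),
                           path_tbl("shank", 0.04, -0.05)),
    vastus_lateralis = rbind(path_tbl("thigh", 0.045, -0.15, "thigh", 0.065, -0.47),
                             path_tbl("shank", 0.04, -0.05)),
    vastus_intermedius = rbind(path_tbl("thigh", 0.040, -0.15, "thigh", 0.062, -0.465),
                               path_tbl("shank", 0.038, -0.05)),
    vastus_medialis = rbind(path_tbl("thigh", 0.042, -0.16, "thigh", 0.064, -0.475),
                            path_tbl("shank", 0.042, -0.055)),
    hamstrings = path_tbl("pelvis", -0.07, -0.01, "shank", -0.035, -0.06),
    gastrocnemius = path_tbl("thigh", -0.025, -0.40, "foot", -0.06, -0.03),
    soleus = path_tbl("shank", -0.025, -0.15, "foot", -0.06, -0.03),
    tibialis_anterior = path_tbl("shank", 0.03, -0.20, "foot", 0.04, -0.02)
  )
  mtus <- tibble::tibble(
    name = names(paths),
    f_max_iso = mfrac * c(2800, 3200, 2600, 4400, 3200, 3200, 3000, 3500, 7000, 1200),
    l_opt = c(0.12, 0.16, 0.11, 0.10, 0.10, 0.10, 0.11, 0.09, 0.08, 0.09),
    pennation_opt = c(0.14, 0.10, 0.24, 0.32, 0.08, 0.51, 0.20, 0.30, 0.49, 0.17),
    v_max = 10,
    pv = c(8.7, 17.5, 5.2, 14.8, 10.1, 9.5, 14.9, 9.0, 7.3, 3.0)
  )
  # reference crouched pose: fibre at optimum length, tendon unloaded
  ref_pose <- c(pelvis_tx = 0, pelvis_ty = 0, pelvis_tilt = 0,
                lumbar = 0, hip = 0.4, knee = -0.8, ankle = 0.2)
  spheres <- tibble::tibble(
    name = c("heel", "toe"),
    x = c(-0.05, 0.15),
    y = c(-0.05, -0.05)
  )
  model <- structure(list(
    segments = segments,
    coordinates = coordinates,
    coord_type = coord_type,
    rom = rom,
    mtus = mtus,
    paths = paths,
    curves = curves,
    spheres = spheres,
    contact = list(radius = 0.02, mu = 0.8, v0 = 0.05,
                   eps_d = 1e-4, eps_f = 1e-4,
                   stiffness = 2e6, damping = 1.0),
    torque_actuators = tibble::tibble(
      name = "lumbar_actuator", coordinate = "lumbar",
      tau_max = 250 * mfrac, delay = 0.035),
    gravity = 9.81,
    total_mass = sum(segments$mass),
    mass = mass, height = height,
    ref_pose = ref_pose
  ), class = "hop_model")
  # tendon slack lengths from the reference pose (fibre at optimum, zero strain)
  model$mtus$l_slack <- model$mtus$l_opt  # placeholder during first FK call
  L0 <- mtu_length_reference(model, matrix(ref_pose, nrow = 1))
  model$mtus$l_slack <- as.numeric(L0) - model$mtus$l_opt * cos(model$mtus$pennation_opt)
  stopifnot(all(model$mtus$l_slack > 0))
  if (fit_polynomials) {
    model <- fit_mtu_polynomials(model, degree = degree, n = n_poses,
                                 seed = seed, margin = margin)
  }
  model
}

path_tbl <- function(...) {
  a <- list(...)
  stopifnot(length(a) %% 3 == 0)
  n <- length(a) / 3
  tibble::tibble(
    segment = vapply(seq_len(n), function(i) a[[3 * i - 2]], character(1)),
    x = vapply(seq_len(n), function(i) a[[3 * i - 1]], numeric(1)),
    y = vapply(seq_len(n), function(i) a[[3 * i]], numeric(1))
  )
}

#' @export
print.hop_model <- function(x, ...) {
  cat("<hop_model>: planar", nrow(x$segments), "segment model,",
      length(x$coordinates), "coordinates,", nrow(x$mtus), "MTUs,",
      nrow(x$spheres), "contact spheres\n")
  cat("  total mass:", format(x$total_mass), "kg; polynomials:",
      if (is.null(x$polynomials)) "not fitted" else "fitted", "\n")
  invisible(x)
}

# index helpers -------------------------------------------------------------

coord_index <- function(model, name) match(name, model$coordinates)
segment_index <- function(model, name) match(name, model$segments$name)

muscle_driven_coords <- function(model) {
  acted <- model$torque_actuators$coordinate
  setdiff(model$coordinates[-(1:3)], acted)
}

#' Body-weight-support force for a gravity condition
#'
#' The support force is vertical, applied at the pelvis centre of mass, and
#' equals the offloaded fraction of body weight:
#' `(1 - g_level) * total_mass * 9.81`. At `g_level = 1` (terrestrial
#' gravity) the harness is removed and the force is zero.
#'
#' @param g_level gravity level as a fraction of terrestrial gravity,
#'   in `(0, 1]`.
#' @param model a [hop_model()].
#' @return Support force in newtons.
#' @export
bwss_force <- function(g_level, model) {
  if (!is.numeric(g_level) || any(g_level <= 0) || any(g_level > 1)) {
    stop("g_level must lie in (0, 1]")
  }
  (1 - g_level) * model$total_mass * model$gravity
}

# flat numeric representation consumed by the compiled core ------------------
model_blob <- function(model, stiffness = model$contact$stiffness,
                       damping = model$contact$damping) {
  seg <- model$segments
  parent_idx <- ifelse(is.na(seg$parent), 0L, match(seg$parent, seg$name))
  # coordinate index of each segment's joint (root = 0)
  cidx <- ifelse(is.na(seg$parent_joint), 0L,
                 match(seg$parent_joint, model$coordinates))
  jloc <- rbind(ifelse(is.na(seg$joint_x), 0, seg$joint_x),
                ifelse(is.na(seg$joint_y), 0, seg$joint_y))
  poly <- model$polynomials
  if (is.null(poly)) {
    poly <- lapply(seq_len(nrow(model$mtus)), function(i)
      list(coords = 1L, expo = matrix(0L, 1, 1), coef = 0))
  } else {
    poly <- lapply(poly, function(p)
      list(coords = as.integer(p$coords), expo = p$expo, coef = p$coef))
  }
  mus_coords <- match(muscle_driven_coords(model), model$coordinates)
  list(
    nseg = nrow(seg), nq = length(model$coordinates),
    parent = as.integer(parent_idx), jloc = jloc,
    mass = seg$mass, com = rbind(seg$com_x, seg$com_y), izz = seg$inertia_zz,
    coord = as.integer(cidx), grav = model$gravity,
    mus_fmax = model$mtus$f_max_iso, mus_lopt = model$mtus$l_opt,
    mus_lslack = model$mtus$l_slack,
    mus_vmax = model$mtus$v_max * model$mtus$l_opt,
    mus_h = model$mtus$l_opt * sin(model$mtus$pennation_opt),
    mus_pv = model$mtus$pv,
    poly = poly,
    curves = unclass(model$curves),
    mu = model$contact$mu, v0 = model$contact$v0,
    eps_d = model$contact$eps_d, eps_f = model$contact$eps_f,
    nsph = nrow(model$spheres), sph_seg = segment_index(model, "foot"),
    radius = model$contact$radius,
    act_coord = coord_index(model, model$torque_actuators$coordinate[1]),
    act_taumax = model$torque_actuators$tau_max[1],
    mus_coord_idx = as.integer(mus_coords),
    stiffness = stiffness, damping = damping
  )
}
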