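#' Write / read a model configuration file
#'
#' Serialises the full planar-model description — segments, muscle-tendon
#' parameter tables, via-point paths, curve coefficients, contact spheres
#' and torque actuators — as a versioned, structured key-value (YAML) file.
#' Angles are stored in degrees at the file boundary (declared in the file)
#' and radians internally. Reading reconstructs the model, recomputes the
#' tendon slack lengths from the stored reference pose, and refits the
#' geometry polynomials (the fit is deterministic given the stored seed and
#' degree, so the round trip reproduces the model).
#'
#' @param model a [hop_model()].
#' @param path output file.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns the model.
#' @export
write_model_config <- function(model, path) {
  deg <- function(x) x * 180 / pi
  cfg <- list(
    hopsim_model = 1L,
    angles = "degrees",
    mass = model$mass, height = model$height, gravity = model$gravity,
    segments = as.data.frame(model$segments),
    coordinates = model$coordinates,
    coord_type = model$coord_type,
    rom_deg = lapply(model$rom, deg),
    mtus = local({
      tb <- as.data.frame(model$mtus)
      tb$pennation_opt <- deg(tb$pennation_opt)
      tb
    }),
    paths = lapply(model$paths, as.data.frame),
    curves = local({
      cc <- unclass(model$curves)[c("fv", "kpe", "e0", "c1", "c3", "kT", "beta")]
      # store the gaussian coefficient matrix row-wise and unambiguously
      cc$active_rows <- lapply(seq_len(nrow(model$curves$active)),
                               function(i) as.numeric(model$curves$active[i, ]))
      cc
    }),
    spheres = as.data.frame(model$spheres),
    contact = model$contact,
    torque_actuators = as.data.frame(model$torque_actuators),
    ref_pose_deg = local({
      rp <- model$ref_pose
      rot <- model$coord_type[match(names(rp), model$coordinates)] == "rotation"
      rp[rot] <- deg(rp[rot])
      as.list(rp)
    }),
    polynomial_fit = list(
      degree = model$polynomials[[1]]$degree %||% 6L,
      n = 2000L, seed = 1L, margin = 0.2)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_model_config
#' @param fit_polynomials refit the geometry polynomials on read.
#' @export
read_model_config <- function(path, fit_polynomials = TRUE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$hopsim_model)) stop("not a hopsim model configuration: ", path)
  if (!identical(cfg$angles, "degrees")) {
    stop("unknown angle unit '", cfg$angles, "' in ", path)
  }
  rad <- function(x) x * pi / 180
  as_tb <- function(x) tibble::as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
  active <- do.call(rbind, lapply(cfg$curves$active_rows, unlist))
  curves <- do.call(muscle_curves, c(list(kT = cfg$curves$kT,
                                          beta = cfg$curves$beta,
                                          active = active,
                                          fv = unlist(cfg$curves$fv)),
                                     cfg$curves[c("kpe", "e0", "c1", "c3")]))
  mtus <- as_tb(cfg$mtus)
  mtus$pennation_opt <- rad(mtus$pennation_opt)
  rp <- unlist(cfg$ref_pose_deg)
  rot <- unlist(cfg$coord_type)[match(names(rp), unlist(cfg$coordinates))] == "rotation"
  rp[rot] <- rad(rp[rot])
  model <- structure(list(
    segments = as_tb(cfg$segments),
    coordinates = unlist(cfg$coordinates),
    coord_type = unlist(cfg$coord_type),
    rom = lapply(cfg$rom_deg, rad),
    mtus = mtus,
    paths = lapply(cfg$paths, as_tb),
    curves = curves,
    spheres = as_tb(cfg$spheres),
    contact = cfg$contact,
    torque_actuators = as_tb(cfg$torque_actuators),
    gravity = cfg$gravity,
    total_mass = sum(as_tb(cfg$segments)$mass),
    mass = cfg$mass, height = cfg$height,
    ref_pose = rp
  ), class = "hop_model")
  # slack lengths are derived quantities: recompute from the reference pose
  model$mtus$l_slack <- model$mtus$l_opt
  L0 <- mtu_length_reference(model, matrix(rp, nrow = 1))
  model$mtus$l_slack <- as.numeric(L0) - model$mtus$l_opt * cos(model$mtus$pennation_opt)
  if (fit_polynomials) {
    pf <- cfg$polynomial_fit
    model <- fit_mtu_polynomials(model, degree = pf$degree, n = pf$n,
                                 seed = pf$seed, margin = pf$margin)
  }
  model
}
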