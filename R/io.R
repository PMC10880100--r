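#' Raw hopping trial container
#'
#' Bundles one trial's raw time series: joint kinematics at the motion-capture
#' rate and forces (ground reaction force, centre of pressure, body-weight
#' support force) at the force-platform rate, together with participant mass
#' and the gravity condition. Angles are radians internally; the file
#' boundary uses degrees (declared in the file header).
#'
#' @param kinematics tibble: `time` plus one column per model coordinate
#'   (rad / m).
#' @param forces tibble: `time`, `grf_x`, `grf_y`, `cop_x`, `bwss` (N, m).
#' @param mass participant mass (kg).
#' @param g_level gravity condition in (0, 1].
#' @param rate_kin,rate_force nominal sampling rates (Hz).
#' @return An object of class `hop_raw_trial`.
#' @export
raw_trial <- function(kinematics, forces, mass, g_level,
                      rate_kin = 200, rate_force = 2000) {
  stopifnot(is.data.frame(kinematics), is.data.frame(forces))
  for (tb in list(kinematics, forces)) {
    if (!"time" %in% names(tb)) stop("missing column: time")
    if (any(diff(tb$time) <= 0)) stop("time must be strictly increasing")
  }
  need <- c("grf_x", "grf_y", "cop_x", "bwss")
  miss <- setdiff(need, names(forces))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  structure(list(kinematics = tibble::as_tibble(kinematics),
                 forces = tibble::as_tibble(forces),
                 mass = mass, g_level = g_level,
                 rate_kin = rate_kin, rate_force = rate_force),
            class = "hop_raw_trial")
}

#' @export
print.hop_raw_trial <- function(x, ...) {
  cat(sprintf("<hop_raw_trial> g = %.2f, mass = %.1f kg, %d kinematic x %d force samples (%.2f s)\n",
              x$g_level, x$mass, nrow(x$kinematics), nrow(x$forces),
              diff(range(x$forces$time))))
  invisible(x)
}

rot_coord_names <- function() c("pelvis_tilt", "lumbar", "hip", "knee", "ankle")

write_stream <- function(tb, path, type, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("hopsim_timeseries", "version=1", paste0("type=", type),
               sprintf("mass_kg=%.17g", meta$mass),
               sprintf("g_level=%.17g", meta$g_level),
               sprintf("rate_hz=%.17g", meta$rate),
               "angles=degrees", "endheader"), con)
  writeLines(paste(names(tb), collapse = "\t"), con)
  body <- apply(vapply(tb, function(col) sprintf("%.17g", col),
                       character(nrow(tb))), 1, paste, collapse = "\t")
  writeLines(body, con)
}

read_stream <- function(path) {
  lines <- readLines(path, n = 50)
  if (lines[1] != "hopsim_timeseries") stop("not a hopsim time-series file: ", path)
  endh <- which(lines == "endheader")[1]
  if (is.na(endh)) stop("missing endheader in ", path)
  hdr <- strsplit(lines[2:(endh - 1)], "=", fixed = TRUE)
  meta <- setNames(lapply(hdr, `[`, 2), vapply(hdr, `[`, "", 1))
  if (!identical(meta$angles, "degrees")) {
    stop("unknown angle unit '", meta$angles, "' in ", path)
  }
  tb <- utils::read.delim(path, skip = endh, check.names = FALSE)
  list(meta = meta, data = tibble::as_tibble(tb))
}

#' Write / read a raw trial
#'
#' A trial is stored as two self-describing tab-delimited time-series files
#' (`<stem>_kinematics.tsv`, `<stem>_forces.tsv`): a small header block
#' (participant mass, gravity level, sampling rate, angle unit) terminated by
#' `endheader`, then a column-name row (first column time) and the samples.
#' Rotational coordinates are written in degrees and converted back to
#' radians on read; the round trip reproduces doubles to full numeric
#' precision (converted angle channels to a relative 1e-15).
#'
#' @param trial a [raw_trial()].
#' @param stem path stem (without the `_kinematics.tsv` suffix).
#' @return `write_trial` returns `stem` invisibly; `read_trial` returns the
#'   trial.
#' @export
write_trial <- function(trial, stem) {
  stopifnot(inherits(trial, "hop_raw_trial"))
  kin <- trial$kinematics
  for (cn in intersect(rot_coord_names(), names(kin))) {
    kin[[cn]] <- kin[[cn]] * 180 / pi
  }
  write_stream(kin, paste0(stem, "_kinematics.tsv"), "kinematics",
               list(mass = trial$mass, g_level = trial$g_level, rate = trial$rate_kin))
  write_stream(trial$forces, paste0(stem, "_forces.tsv"), "forces",
               list(mass = trial$mass, g_level = trial$g_level, rate = trial$rate_force))
  invisible(stem)
}

#' @rdname write_trial
#' @export
read_trial <- function(stem) {
  kf <- paste0(stem, "_kinematics.tsv")
  ff <- paste0(stem, "_forces.tsv")
  for (f in c(kf, ff)) if (!file.exists(f)) stop("missing trial file: ", f)
  k <- read_stream(kf)
  f <- read_stream(ff)
  kin <- k$data
  for (cn in intersect(rot_coord_names(), names(kin))) {
    kin[[cn]] <- kin[[cn]] * pi / 180
  }
  raw_trial(kin, f$data,
            mass = as.numeric(k$meta$mass_kg),
            g_level = as.numeric(k$meta$g_level),
            rate_kin = as.numeric(k$meta$rate_hz),
            rate_force = as.numeric(f$meta$rate_hz))
}
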