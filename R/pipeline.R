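#' Write solution time series and summaries
#'
#' Emits the solution's state/control trajectories, per-term costs and
#' optimised parameters as tab-delimited files under `dir`.
#'
#' @param solution a `hop_ocp_solution`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_solution <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- tidyr::pivot_wider(tidy(solution),
                             names_from = c("group", "channel"),
                             values_from = "value")
  utils::write.table(wide, file.path(dir, "trajectories.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gl <- glance(solution)
  utils::write.table(gl, file.path(dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  par <- solution$parameters
  writeLines(jsonlite::toJSON(list(
    stiffness = par$stiffness, damping = par$damping,
    spheres = as.data.frame(par$spheres), guess = solution$guess,
    cost = solution$cost, feasibility = solution$feasibility
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE),
  file.path(dir, "solution.json"))
  invisible(dir)
}

file_sha <- function(path) {
  # content fingerprint without external digest dependencies
  con <- file(path, "rb")
  on.exit(close(con))
  dat <- readBin(con, "raw", file.size(path))
  rlang::hash(dat)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates the five stages (synthesise trials, preprocess, track,
#' analyse, adapt) for one or more gravity conditions, writing per-stage
#' outputs and a run manifest (configuration hash, seeds, per-stage file
#' hashes, solver summaries) so that a run is reproducible and its outputs
#' traceable. A stage failure short-circuits the remaining stages; the
#' manifest records the partial completion.
#'
#' @param out_dir output directory.
#' @param model a [hop_model()].
#' @param config a [synth_config()] (its `seed` governs all randomness).
#' @param g_levels conditions to run (default all in `config`).
#' @param trials trial indices per condition.
#' @param ocp an [ocp_config()].
#' @param adaptation an [adaptation_params()].
#' @param verbose print progress.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(out_dir, model = hop_model(),
                         config = synth_config(), g_levels = config$g_levels,
                         trials = 1, ocp = ocp_config(),
                         adaptation = adaptation_params(),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hopsim")),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    stages = list(), files = list(), status = "running")
  say <- function(...) if (verbose) message(sprintf(...))
  finish <- function(status) {
    manifest$status <<- status
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, force = TRUE),
               file.path(out_dir, "manifest.json"))
    invisible(manifest)
  }
  results <- list()
  for (g in g_levels) {
    for (tr_i in trials) {
      tag <- sprintf("g%03d_t%d", round(100 * g), tr_i)
      stage <- function(name, expr) {
        say("[%s] %s", tag, name)
        out <- tryCatch(expr, error = function(e) e)
        manifest$stages[[tag]][[name]] <<-
          if (inherits(out, "error")) paste("failed:", conditionMessage(out))
          else "ok"
        out
      }
      raw <- stage("synth", {
        tr <- generate_condition_trial(model, config, g, tr_i)
        stem <- file.path(out_dir, paste0("trial_", tag))
        write_trial(tr, stem)
        for (f in paste0(stem, c("_kinematics.tsv", "_forces.tsv"))) {
          manifest$files[[basename(f)]] <- file_sha(f)
        }
        tr
      })
      if (inherits(raw, "error")) next
      tracking <- stage("preprocess", preprocess_trial(raw, model,
                                                       n_mesh = ocp$n_mesh))
      if (inherits(tracking, "error")) next
      sol <- stage("track", solve_tracking(model, tracking, ocp))
      if (inherits(sol, "error")) next
      soldir <- file.path(out_dir, paste0("solution_", tag))
      write_solution(sol, soldir)
      manifest$stages[[tag]][["solver"]] <- list(
        status = sol$status, guess = sol$guess, cost = sol$cost$total,
        feasibility = sol$feasibility, seconds = sol$seconds)
      ana <- stage("analyze", {
        diag <- tracking_errors(sol)
        loads <- joint_load_summary(sol, model)
        utils::write.table(loads, file.path(out_dir, paste0("loads_", tag, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        list(diagnostics = diag, loads = loads)
      })
      if (inherits(ana, "error")) next
      vol <- stage("adapt", {
        prof <- quadriceps_profile(sol, model)
        tv <- training_volume(prof, adaptation)
        utils::write.table(tv, file.path(out_dir, paste0("adapt_", tag, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        tv
      })
      results[[tag]] <- list(g_level = g, trial = tr_i, solution = sol,
                             analysis = ana, volume = vol)
    }
  }
  manifest$results <- lapply(results, function(r) list(
    g_level = r$g_level, trial = r$trial,
    accepted = r$analysis$diagnostics$accepted,
    reps_required = r$volume$reps_required,
    sets_per_session = r$volume$sets_per_session))
  out <- finish("complete")
  attr(out, "results") <- results
  out
}
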