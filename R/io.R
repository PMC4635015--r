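#' Write a trajectory table
#'
#' CSV with `#`-prefixed header metadata (units, dt, field kind, seed)
#' followed by columns `t,x,y`. This minimal schema is the package's
#' interchange format for 2-D tracks.
#'
#' @param traj A trajectory (data frame with `t`, `x`, `y`).
#' @param path Output file path.
#' @param units Coordinate units to write: `"sim"` (default) or `"mm"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, units = c("sim", "mm")) {
  units <- match.arg(units)
  cv <- if (units == "mm") units_to_mm else identity
  f <- attr(traj, "field")
  seed <- attr(traj, "seed")
  hdr <- c(sprintf("# units: %s", units),
           sprintf("# dt: %.10g", traj_dt(traj)),
           if (!is.null(f)) sprintf("# field: %s", f$kind),
           if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(t = traj$t, x = cv(traj$x), y = cv(traj$y)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory table
#'
#' Reads the CSV schema of [write_trajectory()]: optional `#` metadata
#' lines, a header row naming at least `t`, `x`, `y`, and numeric rows on
#' a uniform time grid. Coordinates declared in mm are converted to
#' simulation units.
#'
#' @param path Input file path.
#' @param field Optional [field_geometry][make_field] to attach.
#' @return A `wigwag_traj` in simulation units.
#' @export
load_trajectory <- function(path, field = NULL) {
  if (!file.exists(path)) stop_wigwag("no such file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*", "", kv))
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  for (col in c("t", "x", "y"))
    if (!col %in% names(df))
      stop_wigwag("trajectory file is missing column '", col, "'")
  for (col in c("t", "x", "y"))
    if (!is.numeric(df[[col]]))
      stop_wigwag("column '", col, "' contains non-numeric values")
  if (nrow(df) >= 3L) {
    dts <- diff(df$t)
    if (max(dts) - min(dts) > 1e-6 * max(abs(dts)))
      stop_wigwag("time column is not a uniform grid")
  }
  units <- meta[["units"]] %||% "sim"
  if (!units %in% c("sim", "mm")) stop_wigwag("unknown units: ", units)
  if (units == "mm") {
    df$x <- mm_to_units(df$x)
    df$y <- mm_to_units(df$y)
  }
  dt <- as.numeric(meta[["dt"]] %||% stats::median(diff(df$t)))
  new_wigwag_traj(df[c("t", "x", "y")], field = field, dt = dt)
}

#' Write an occupancy grid as a CSV matrix
#'
#' @param grid An [occupancy_grid][occupancy_kde].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occupancy_grid <- function(grid, path) {
  m <- grid$density
  dimnames(m) <- list(sprintf("%.6g", grid$x), sprintf("%.6g", grid$y))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_mm: %.6g", grid$cell_mm),
               sprintf("# bandwidth_mm: %.8g", grid$bandwidth_mm),
               sprintf("# bandwidth_method: %s", grid$bandwidth_method)), con)
  utils::write.csv(m, con, quote = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML file with blocks: `arena` (either `preset` naming a
#' [field_preset()] or `kind` plus mm dimensions, optional
#' `wall_margin_mm`), `params` (either `preset` naming a
#' [preset_params()] group or explicit [wigwag_params()] fields),
#' `duration_s`, `n_reps`, `seed`, and optional `analyses` toggles
#' (`preference`, `episodes`, `kde`, `fit`).
#'
#' @param path YAML file path.
#' @return Validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  if (is.null(cfg$arena)) stop_wigwag("config needs an 'arena' block")
  field <- if (!is.null(cfg$arena$preset)) {
    field_preset(cfg$arena$preset)
  } else {
    do.call(make_field, c(list(kind = cfg$arena$kind),
                          cfg$arena[setdiff(names(cfg$arena),
                                            c("kind", "wall_margin_mm"))]))
  }
  if (is.null(cfg$params)) stop_wigwag("config needs a 'params' block")
  params <- if (!is.null(cfg$params$preset)) {
    preset_params(cfg$params$preset)$params
  } else {
    do.call(wigwag_params, cfg$params)
  }
  if (is.null(cfg$duration_s) || cfg$duration_s <= 0)
    stop_wigwag("config needs a positive 'duration_s'")
  if (is.null(cfg$seed)) stop_wigwag("config needs an explicit 'seed'")
  structure(list(
    field = field,
    wall_margin_mm = cfg$arena$wall_margin_mm %||% 5,
    params = params,
    duration_s = cfg$duration_s,
    n_reps = cfg$n_reps %||% 1L,
    seed = as.integer(cfg$seed),
    analyses = cfg$analyses %||% list(preference = TRUE),
    raw = cfg), class = "run_config")
}

#' Run the simulate-and-analyse pipeline
#'
#' Simulates `n_reps` replicate trajectories under a [run
#' configuration][load_run_config] and writes the artifact bundle to
#' `out_dir`: trajectory CSVs, a preference-index table, and (per the
#' `analyses` toggles) wall-episode tables, occupancy grids and
#' distribution fits, plus a `run_info.json` recording the seed, package
#' version and a hash of the configuration. Reruns with the same
#' configuration and seed are reproducible.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory (created if needed).
#' @return List with the computed tables, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop_wigwag("output path not writable: ", out_dir)
  partition <- if (config$field$kind != "open")
    partition_regions(config$field, config$wall_margin_mm) else NULL
  seeds <- derive_seeds(config$seed, config$n_reps)
  trajs <- vector("list", config$n_reps)
  pref <- NULL
  for (r in seq_len(config$n_reps)) {
    tr <- simulate_planarian(config$params, config$field, config$duration_s,
                             seed = seeds[r])
    trajs[[r]] <- tr
    write_trajectory(tr, file.path(out_dir, sprintf("trajectory_%03d.csv", r)))
    if (!is.null(partition)) {
      pi_ <- preference_indices(tr, partition)
      row <- data.frame(rep = r, seed = seeds[r], T = pi_$T)
      idx <- pi_[grep("_index$", names(pi_))]
      pref <- rbind(pref, cbind(row, as.data.frame(idx)))
    }
  }
  out <- list(trajectories = trajs, preference = pref)
  if (!is.null(pref))
    utils::write.csv(pref, file.path(out_dir, "preference.csv"), row.names = FALSE)
  an <- config$analyses
  if (isTRUE(an$episodes) && !is.null(partition)) {
    eps <- do.call(rbind, lapply(seq_along(trajs), function(r) {
      e <- wall_episodes(trajs[[r]], partition)$episodes
      if (nrow(e)) cbind(rep = r, e) else NULL
    }))
    out$episodes <- eps
    if (!is.null(eps))
      utils::write.csv(eps, file.path(out_dir, "episodes.csv"), row.names = FALSE)
  }
  if (isTRUE(an$kde)) {
    out$kde <- occupancy_kde(trajs, config$field)
    write_occupancy_grid(out$kde, file.path(out_dir, "occupancy.csv"))
  }
  if (isTRUE(an$fit)) {
    ww <- extract_wigwag(trajs[[1]])
    fits <- list()
    if (length(ww$angles) >= 2) fits$angle <- fit_normal_mle(ww$angles)
    if (length(ww$intervals) >= 2) fits$interval <- fit_lognormal_mle(ww$intervals)
    out$fits <- fits
    if (length(fits)) {
      ft <- do.call(rbind, lapply(names(fits), function(nm) {
        f <- fits[[nm]]
        data.frame(what = nm, family = f$family, location = f$location,
                   scale = f$scale, n = f$n, log_likelihood = f$log_likelihood)
      }))
      utils::write.csv(ft, file.path(out_dir, "fits.csv"), row.names = FALSE)
    }
  }
  info <- list(package_version = as.character(utils::packageVersion("wigwag")),
               seed = config$seed,
               replicate_seeds = seeds,
               config_hash = config_hash(config$raw),
               config = config$raw)
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
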