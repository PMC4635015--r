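#' Behavioral parameter set of the wigwag agent
#'
#' The agent moves straight at constant `speed`; at stochastic intervals
#' it applies an instantaneous heading change ("wigwag") xi drawn from
#' Normal(`angle_mean`, `angle_sd`). The interval k between wigwags, in
#' seconds, is lognormal with log-space location `interval_logmean` and
#' scale `interval_logsd`. Both draws are rounded to two decimals before
#' use, and the interval is realised as an integer tick countdown
#' `i = max(1, round(10 k))` on the 0.1-s step grid.
#'
#' @param angle_mean,angle_sd Wigwag angle distribution, radians.
#' @param interval_logmean,interval_logsd Interval distribution, log-seconds.
#' @param speed Locomotion speed, simulation units per second (default 10).
#' @param dt Timestep, seconds (default 0.1). Under the defaults the agent
#'   advances exactly one simulation unit per tick.
#' @return Object of class `wigwag_params`.
#' @seealso [preset_params()] for the measured group presets.
#' @export
wigwag_params <- function(angle_mean = 0, angle_sd,
                          interval_logmean, interval_logsd,
                          speed = 10, dt = 0.1) {
  stopifnot(is.numeric(angle_mean), is.numeric(angle_sd),
            is.numeric(interval_logmean), is.numeric(interval_logsd))
  if (angle_sd < 0) stop_wigwag("angle_sd must be >= 0")
  if (interval_logsd < 0) stop_wigwag("interval_logsd must be >= 0")
  if (speed <= 0) stop_wigwag("speed must be > 0")
  if (dt <= 0) stop_wigwag("dt must be > 0")
  structure(list(angle_mean = angle_mean, angle_sd = angle_sd,
                 interval_logmean = interval_logmean,
                 interval_logsd = interval_logsd,
                 speed = speed, dt = dt),
            class = "wigwag_params")
}

#' @export
print.wigwag_params <- function(x, ...) {
  cat(sprintf(
    "<wigwag_params> angle %.3g +/- %.3g rad; interval lognormal(%.3g, %.3g) s; speed %.3g units/s; dt %.3g s\n",
    x$angle_mean, x$angle_sd, x$interval_logmean, x$interval_logsd,
    x$speed, x$dt))
  invisible(x)
}

# Draw a fresh integer countdown from the interval distribution.
draw_countdown <- function(params) {
  k <- round(stats::rlnorm(1, params$interval_logmean, params$interval_logsd), 2)
  list(k = k, i = max(1L, as.integer(round(10 * k))))
}

#' Advance the agent by one timestep
#'
#' One tick of the locomotion model: if the wigwag countdown `i` is
#' nonzero it is decremented and the heading kept; if it is zero a wigwag
#' angle xi ~ Normal(angle_mean, angle_sd) (rounded to 0.01 rad) is added
#' to the heading and the countdown reset to `max(1, round(10 k))` with
#' k ~ LogNormal (rounded to 0.01 s). The agent then advances `speed * dt`
#' along its heading, with [collide_and_slide()] applied to the move.
#'
#' @param state List with `x`, `y` (simulation units), `theta` (bearing,
#'   radians) and `i` (non-negative integer countdown).
#' @param params A [wigwag_params()] object.
#' @param field A [field_geometry][make_field].
#' @return The new state, with extra elements `contact` (logical),
#'   `turned` (logical) and, on turn ticks, `xi` and `k`.
#' @export
step <- function(state, params, field) {
  if (!all(c("x", "y", "theta", "i") %in% names(state)) || state$i < 0)
    stop_wigwag("invalid agent state")
  if (!point_inside(field, state$x, state$y))
    stop_wigwag("agent state lies outside the field")
  theta <- state$theta
  i <- as.integer(state$i)
  turned <- FALSE; xi <- NA_real_; k <- NA_real_
  if (i != 0L) {
    i <- i - 1L
  } else {
    xi <- round(stats::rnorm(1, params$angle_mean, params$angle_sd), 2)
    theta <- theta + xi
    cd <- draw_countdown(params)
    k <- cd$k; i <- cd$i
    turned <- TRUE
  }
  len <- params$speed * params$dt
  res <- collide_and_slide(field,
                           c(state$x, state$y),
                           c(state$x + sin(theta) * len,
                             state$y + cos(theta) * len),
                           theta)
  list(x = res$pos[1], y = res$pos[2], theta = res$heading, i = i,
       contact = res$contact, turned = turned, xi = xi, k = k)
}

default_start <- function(field) {
  if (field$kind == "donut")
    c((field$inner_radius + field$outer_radius) / 2, 0)
  else c(0, 0)
}

#' Simulate a spontaneous-locomotion trajectory
#'
#' Runs the wigwag agent for `duration_s` seconds and returns the
#' sampled trajectory. Defaults follow the assay conventions: start at
#' the arena centre (for the donut, mid-annulus on the +x axis, e.g.
#' (175, 0) for the standard donut), initial heading uniform on
#' `[0, 2 pi)`, initial countdown drawn from the interval distribution.
#'
#' @param params A [wigwag_params()] object.
#' @param field A [field_geometry][make_field].
#' @param duration_s Assay duration, seconds.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   trajectories. `NULL` uses the current RNG stream.
#' @param start Optional start position `c(x, y)` in simulation units.
#' @param start_theta Optional initial heading (bearing, radians).
#' @return A `wigwag_traj`: a data frame with columns `t`, `x`, `y`
#'   (`floor(duration_s/dt) + 1` rows) and attributes `field`, `params`,
#'   `dt`, `seed`, `contact` (per-sample wall-contact flags) and
#'   `event_log` (data frame of applied wigwags: `tick`, `angle`,
#'   `interval`, `countdown`).
#' @examples
#' tr <- simulate_planarian(preset_params("intact")$params,
#'                          field_preset("circle90"), 60, seed = 1)
#' head(tr)
#' @export
simulate_planarian <- function(params, field, duration_s, seed = NULL,
                               start = NULL, start_theta = NULL) {
  stopifnot(inherits(params, "wigwag_params"),
            inherits(field, "field_geometry"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_wigwag("duration_s must be positive")
  start <- start %||% default_start(field)
  if (field$kind != "open" && !point_inside(field, start[1], start[2]))
    stop_wigwag("start position lies outside the field")
  n <- as.integer(floor(duration_s / params$dt))
  with_seed(seed, {
    theta <- (start_theta %||% stats::runif(1, 0, 2 * pi)) %% (2 * pi)
    xs <- numeric(n + 1L); ys <- numeric(n + 1L)
    contact <- logical(n + 1L)
    xs[1] <- start[1]; ys[1] <- start[2]
    ev_tick <- integer(0); ev_angle <- numeric(0)
    ev_k <- numeric(0); ev_i <- integer(0)
    i <- draw_countdown(params)$i
    len <- params$speed * params$dt
    x <- xs[1]; y <- ys[1]
    am <- params$angle_mean; asd <- params$angle_sd
    for (t in seq_len(n)) {
      if (i != 0L) {
        i <- i - 1L
      } else {
        xi <- round(stats::rnorm(1, am, asd), 2)
        theta <- theta + xi
        cd <- draw_countdown(params)
        i <- cd$i
        ev_tick <- c(ev_tick, t - 1L); ev_angle <- c(ev_angle, xi)
        ev_k <- c(ev_k, cd$k); ev_i <- c(ev_i, cd$i)
      }
      res <- collide_and_slide(field, c(x, y),
                               c(x + sin(theta) * len, y + cos(theta) * len),
                               theta)
      x <- res$pos[1]; y <- res$pos[2]; theta <- res$heading
      xs[t + 1L] <- x; ys[t + 1L] <- y; contact[t + 1L] <- res$contact
    }
    new_wigwag_traj(
      data.frame(t = (0:n) * params$dt, x = xs, y = ys),
      field = field, dt = params$dt, params = params, seed = seed,
      contact = contact,
      event_log = data.frame(tick = ev_tick, angle = ev_angle,
                             interval = ev_k, countdown = ev_i))
  })
}

new_wigwag_traj <- function(df, field, dt, params = NULL, seed = NULL,
                            contact = NULL, event_log = NULL) {
  structure(df, field = field, dt = dt, params = params,
            seed = seed, contact = contact, event_log = event_log,
            class = c("wigwag_traj", "data.frame"))
}

traj_dt <- function(traj) attr(traj, "dt") %||% stats::median(diff(traj$t))

#' @export
print.wigwag_traj <- function(x, ...) {
  f <- attr(x, "field")
  cat(sprintf("<wigwag_traj> %d samples, %.4g s at dt = %.3g s, field: %s\n",
              nrow(x), max(x$t), traj_dt(x),
              if (is.null(f)) "unknown" else f$kind))
  invisible(x)
}

#' Sweep wigwag parameters and summarise wall preference
#'
#' Runs a grid of parameter variants (columns of `param_grid` override the
#' corresponding fields of `base_params`; typical columns are `angle_sd`
#' and `interval_logmean`), with `n_reps` seeded replicate simulations per
#' grid point, and reports the wall-preference index of every replicate
#' plus per-point mean and SD.
#'
#' @param param_grid Data frame; each row is one parameter combination.
#' @param field Bounded rectangle or circle [field_geometry][make_field].
#' @param n_reps Replicates per grid point.
#' @param duration_s Assay duration per replicate, seconds.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param base_params Defaults for parameters not in the grid
#'   (intact-group preset if omitted).
#' @param wall_margin_mm Wall band width for the preference index.
#' @return List of class `wigwag_sweep` with `summary` (one row per grid
#'   point: grid columns, `mean_wall_index`, `sd_wall_index`, `n_reps`)
#'   and `replicates` (per-replicate indices and seeds).
#' @export
sweep_wall_preference <- function(param_grid, field, n_reps, duration_s,
                                  seed = NULL, base_params = NULL,
                                  wall_margin_mm = 5) {
  if (!is.data.frame(param_grid) || nrow(param_grid) == 0L)
    stop_wigwag("param_grid must be a non-empty data frame")
  if (!field$kind %in% c("rectangle", "circle"))
    stop_wigwag("sweep_wall_preference requires a rectangle or circle field")
  if (n_reps < 1L) stop_wigwag("n_reps must be >= 1")
  base_params <- base_params %||% preset_params("intact")$params
  ok <- names(param_grid) %in% names(base_params)
  if (!all(ok))
    stop_wigwag("unknown parameter column(s): ",
                paste(names(param_grid)[!ok], collapse = ", "))
  partition <- partition_regions(field, wall_margin_mm)
  n_pts <- nrow(param_grid)
  seeds <- derive_seeds(seed, n_pts * n_reps)
  reps <- vector("list", n_pts)
  for (g in seq_len(n_pts)) {
    pars <- base_params
    for (cn in names(param_grid)) pars[[cn]] <- param_grid[g, cn]
    class(pars) <- "wigwag_params"
    wi <- numeric(n_reps)
    sd_g <- seeds[(g - 1L) * n_reps + seq_len(n_reps)]
    for (r in seq_len(n_reps)) {
      tr <- simulate_planarian(pars, field, duration_s, seed = sd_g[r])
      wi[r] <- preference_indices(tr, partition)$wall_index
    }
    grow <- param_grid[g, , drop = FALSE]
    rownames(grow) <- NULL
    reps[[g]] <- cbind(grow,
                       data.frame(rep = seq_len(n_reps), seed = sd_g,
                                  wall_index = wi, row.names = NULL))
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  agg <- do.call(rbind, lapply(reps, function(d) {
    cbind(d[1, names(param_grid), drop = FALSE],
          data.frame(mean_wall_index = mean(d$wall_index),
                     sd_wall_index = stats::sd(d$wall_index),
                     n_reps = nrow(d)))
  }))
  rownames(agg) <- NULL
  structure(list(summary = agg, replicates = replicates, seed = seed),
            class = "wigwag_sweep")
}

#' @export
print.wigwag_sweep <- function(x, ...) {
  cat("<wigwag_sweep>\n")
  print(x$summary, digits = 4)
  invisible(x)
}
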