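#' Wall- and central-preference indices
#'
#' Region dwell times are computed by sample counting at the trajectory's
#' sampling resolution: each sample contributes `dt` seconds to the
#' region it is classified into, so `T_w + T_c + T_middle = T` exactly.
#' The wall-preference index is `T_w / T` and the central-preference
#' index `T_c / T`. For a donut partition the analogous convex- and
#' concave-curve indices are returned instead.
#'
#' @param traj A trajectory (data frame with `t`, `x`, `y`).
#' @param partition A [region_partition][partition_regions] whose field
#'   contains the trajectory.
#' @return Object of class `preference_result`: `T`, `region_times`
#'   (named, seconds), and `wall_index`/`central_index` (rectangle,
#'   circle) or `convex_index`/`concave_index` (donut).
#' @export
preference_indices <- function(traj, partition) {
  stopifnot(inherits(partition, "region_partition"))
  if (is.null(traj) || nrow(traj) == 0L)
    stop_wigwag("empty trajectory")
  dt <- traj_dt(traj)
  labels <- classify_points(partition, traj$x, traj$y)
  total <- nrow(traj) * dt
  lv <- if (partition$field$kind == "donut") c("convex", "concave", "outside")
        else c("wall", "central", "middle", "outside")
  times <- dt * table(factor(labels, levels = lv))
  times <- stats::setNames(as.numeric(times), lv)
  res <- list(T = total, region_times = times)
  if (partition$field$kind == "donut") {
    res$convex_index <- times[["convex"]] / total
    res$concave_index <- times[["concave"]] / total
  } else {
    res$T_w <- times[["wall"]]
    res$T_c <- times[["central"]]
    res$wall_index <- times[["wall"]] / total
    res$central_index <- times[["central"]] / total
  }
  structure(res, class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("<preference_result> T = %.4g s\n", x$T))
  idx <- x[grep("_index$", names(x))]
  print(round(unlist(idx), 4))
  invisible(x)
}

#' Path linearity (T/N ratio)
#'
#' Total path length travelled divided by the net start-to-end
#' displacement; 1 for perfectly straight motion, larger for more
#' tortuous paths.
#'
#' @param traj Trajectory with at least two points and positive net
#'   displacement.
#' @return The ratio (>= 1).
#' @export
tn_ratio <- function(traj) {
  if (nrow(traj) < 2L) stop_wigwag("need at least 2 points")
  dx <- diff(traj$x); dy <- diff(traj$y)
  path <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt((traj$x[nrow(traj)] - traj$x[1])^2 +
              (traj$y[nrow(traj)] - traj$y[1])^2)
  if (net < 1e-12)
    stop_wigwag("T/N ratio undefined: zero net displacement")
  path / net
}

# Per-sample membership of the wall band (donut: band next to one or both
# walls), used for episode and arrival-time analyses.
in_wall_band <- function(traj, partition, wall = c("any", "inner", "outer")) {
  wall <- match.arg(wall)
  f <- partition$field
  if (f$kind != "donut")
    return(classify_points(partition, traj$x, traj$y) == "wall")
  r <- sqrt(traj$x^2 + traj$y^2)
  m <- partition$wall_margin
  inner <- r <= f$inner_radius + m
  outer <- r >= f$outer_radius - m
  switch(wall, any = inner | outer, inner = inner, outer = outer)
}

#' Wall contact/detachment episodes
#'
#' Segments a trajectory into episodes of continuous residence in the
#' wall band. An episode opens at the first sample inside the band after
#' being outside it (or at the first sample, for trajectories that start
#' in the band) and closes at the first subsequent sample outside the
#' band; an episode still running at the end of the trajectory is
#' reported open with dwell equal to the remaining time.
#'
#' @inheritParams preference_indices
#' @param wall For donut fields, which wall band to use: `"any"`,
#'   `"inner"` (convex) or `"outer"` (concave).
#' @return List of class `wall_episodes`: `episodes` (data frame
#'   `t_contact`, `t_detach`, `dwell`, `open`), `mean_dwell` (open
#'   episodes included) and `n_open`.
#' @export
wall_episodes <- function(traj, partition, wall = "any") {
  stopifnot(inherits(partition, "region_partition"))
  inb <- in_wall_band(traj, partition, wall)
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  eps <- data.frame(t_contact = numeric(0), t_detach = numeric(0),
                    dwell = numeric(0), open = logical(0))
  if (any(keep)) {
    s <- starts[keep]; e <- ends[keep]
    open <- e == nrow(traj)
    t_contact <- traj$t[s]
    t_detach <- ifelse(open, NA_real_, traj$t[pmin(e + 1L, nrow(traj))])
    dwell <- ifelse(open, traj$t[nrow(traj)] - t_contact, t_detach - t_contact)
    eps <- data.frame(t_contact = t_contact, t_detach = t_detach,
                      dwell = dwell, open = open)
  }
  structure(list(episodes = eps,
                 mean_dwell = if (nrow(eps)) mean(eps$dwell) else NA_real_,
                 n_open = sum(eps$open)),
            class = "wall_episodes")
}

#' @export
print.wall_episodes <- function(x, ...) {
  cat(sprintf("<wall_episodes> %d episode(s), %d open; mean dwell %.4g s\n",
              nrow(x$episodes), x$n_open, x$mean_dwell))
  invisible(x)
}

# Per-sample wall contact: recorded flags if the trajectory carries them
# (simulated data), otherwise boundary proximity within `tol` units.
contact_flags <- function(traj, field, tol = 1e-6) {
  fl <- attr(traj, "contact")
  if (!is.null(fl) && length(fl) == nrow(traj)) return(fl)
  wall_distance(field, traj$x, traj$y) <= tol
}

#' Incidence and reflection angles at wall contacts
#'
#' At each wall-contact event (first contacting sample of a contact run),
#' measures the angle between the movement direction and the local wall
#' tangent one sample before (incidence) and one sample after
#' (reflection) the contact. The tangent reference direction is the one
#' of the two opposite tangents closest to the outgoing movement, so a
#' wall-sliding agent has reflection near 0 degrees regardless of
#' incidence.
#'
#' For simulated trajectories carrying an event log, contact events where
#' a wigwag turn fired on the outgoing step are excluded: there the
#' post-contact direction measures the spontaneous turn, not the wall
#' response.
#'
#' @param traj Trajectory inside `field`.
#' @param field Bounded [field_geometry][make_field].
#' @param tol Boundary-proximity tolerance (simulation units) used when
#'   the trajectory carries no recorded contact flags.
#' @return Data frame with `time`, `incidence_deg`, `reflection_deg`
#'   (one row per contact event; empty if the wall is never reached).
#' @export
incidence_reflection <- function(traj, field, tol = 1e-6) {
  stopifnot(inherits(field, "field_geometry"))
  if (field$kind == "open") stop_wigwag("open fields have no wall")
  n <- nrow(traj)
  fl <- contact_flags(traj, field, tol)
  hits <- which(fl & !c(FALSE, fl[-n]))            # first sample of each run
  hits <- hits[hits >= 2L & hits <= n - 1L]        # need pre & post headings
  el <- attr(traj, "event_log")
  if (!is.null(el) && length(hits))                # nonzero turn on the outgoing step
    hits <- hits[!(hits - 1L) %in% el$tick[abs(el$angle) > 1e-12]]
  out <- data.frame(time = numeric(0), incidence_deg = numeric(0),
                    reflection_deg = numeric(0))
  for (j in hits) {
    h_in <- bearing_of(traj$x[j] - traj$x[j - 1L], traj$y[j] - traj$y[j - 1L])
    dxo <- traj$x[j + 1L] - traj$x[j]; dyo <- traj$y[j + 1L] - traj$y[j]
    if (dxo^2 + dyo^2 < 1e-18) next                # stalled: no outgoing step
    h_out <- bearing_of(dxo, dyo)
    cand <- wall_tangent_candidates(field, traj$x[j], traj$y[j])
    tangent <- cand[which.min(abs(ang_diff(cand, h_out)))]
    out <- rbind(out, data.frame(
      time = traj$t[j],
      incidence_deg = abs(ang_diff(h_in, tangent)) * 180 / pi,
      reflection_deg = abs(ang_diff(h_out, tangent)) * 180 / pi))
  }
  out
}

# Tangent bearings of the wall at (x, y); at a rectangle corner both
# adjacent edges contribute candidates.
wall_tangent_candidates <- function(field, x, y, tol = 1e-6) {
  if (field$kind == "rectangle") {
    dvert <- field$width / 2 - abs(x)    # distance to vertical edges
    dhor <- field$height / 2 - abs(y)
    cand <- c(if (dvert <= tol) c(0, pi),
              if (dhor <= tol) c(pi / 2, 3 * pi / 2))
    if (is.null(cand))
      cand <- if (dvert <= dhor) c(0, pi) else c(pi / 2, 3 * pi / 2)
    cand
  } else {
    phi <- bearing_of(x, y)              # circle or donut: perpendicular to radius
    c(phi + pi / 2, phi - pi / 2)
  }
}

#' Basic kinematics of a trajectory
#'
#' @inheritParams preference_indices
#' @param partition Optional partition; when supplied, the time of first
#'   entry into the wall band is reported.
#' @return List with `speeds` (per-tick speed, units/s), `total_distance`
#'   (simulation units) and `time_to_first_wall` (seconds; `NA` if the
#'   band is never entered or no partition given).
#' @export
kinematics <- function(traj, partition = NULL) {
  if (nrow(traj) < 2L) stop_wigwag("need at least 2 points")
  dt <- traj_dt(traj)
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  ttw <- NA_real_
  if (!is.null(partition)) {
    inb <- in_wall_band(traj, partition)
    if (any(inb)) ttw <- traj$t[which(inb)[1]]
  }
  list(speeds = steps / dt, total_distance = sum(steps),
       time_to_first_wall = ttw)
}

#' Recover wigwag events from a tracked trajectory
#'
#' Inverse of the simulator's event process: headings are taken from
#' consecutive position differences and a wigwag event is declared
#' wherever the heading change exceeds `min_turn_rad` in absolute value.
#' Intended for trajectories truncated before the first wall contact (or
#' recorded in an open field), where heading changes come only from
#' wigwags. Turns whose angle rounds to zero are invisible by
#' construction.
#'
#' @param traj Trajectory with at least 3 points on a uniform time grid.
#' @param min_turn_rad Event detection threshold, radians (default 0.005,
#'   half the 0.01-rad rounding grid of the simulator).
#' @return List with `angles` (radians, signed), `times` (event times,
#'   seconds) and `intervals` (times between successive events, seconds).
#' @export
extract_wigwag <- function(traj, min_turn_rad = 0.005) {
  if (nrow(traj) < 3L) stop_wigwag("need at least 3 points")
  h <- bearing_of(diff(traj$x), diff(traj$y))
  dh <- ang_diff(h[-1], h[-length(h)])
  ev <- which(abs(dh) > min_turn_rad)
  times <- traj$t[ev + 1L]   # the turn took effect on the step starting here
  list(angles = dh[ev], times = times,
       intervals = if (length(times) > 1L) diff(times) else numeric(0))
}
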