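#' Construct an arena geometry
#'
#' Defines the assay field in which the agent moves. Four shapes are
#' supported: a rectangle, a circle, a donut (annulus between an inner
#' convex wall and an outer concave wall) and an unbounded open field.
#' Dimensions may be given in millimetres (default) or directly in
#' simulation units; internally everything is stored in simulation units
#' at the fixed scale of 14/3 units per mm (140 units = 30 mm).
#'
#' @param kind One of `"rectangle"`, `"circle"`, `"donut"`, `"open"`.
#' @param width,height Rectangle sides.
#' @param radius Circle radius.
#' @param inner_radius,outer_radius Donut wall radii (inner < outer).
#' @param units `"mm"` (default) or `"sim"` for raw simulation units.
#'
#' @return An object of class `field_geometry`: a list with `kind`, the
#'   relevant dimensions in simulation units, and `mm_per_unit`.
#'
#' @examples
#' make_field("rectangle", width = 30, height = 60)   # 140 x 280 units
#' make_field("circle", radius = 45)                  # radius 210 units
#' make_field("donut", inner_radius = 30, outer_radius = 45)
#' @export
make_field <- function(kind = c("rectangle", "circle", "donut", "open"),
                       width = NULL, height = NULL, radius = NULL,
                       inner_radius = NULL, outer_radius = NULL,
                       units = c("mm", "sim")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  cv <- if (units == "mm") mm_to_units else identity
  chk <- function(x, name) {
    if (is.null(x)) stop_wigwag("field kind '", kind, "' requires dimension '", name, "'")
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop_wigwag("dimension '", name, "' must be a single positive number")
    cv(x)
  }
  f <- list(kind = kind, mm_per_unit = MM_PER_UNIT)
  if (kind == "rectangle") {
    f$width <- chk(width, "width")
    f$height <- chk(height, "height")
  } else if (kind == "circle") {
    f$radius <- chk(radius, "radius")
  } else if (kind == "donut") {
    f$inner_radius <- chk(inner_radius, "inner_radius")
    f$outer_radius <- chk(outer_radius, "outer_radius")
    if (f$inner_radius >= f$outer_radius)
      stop_wigwag("donut requires inner_radius < outer_radius")
  }
  structure(f, class = "field_geometry")
}

#' Named arena presets used in the behavioral assays
#'
#' @param name `"rect30x60"` (30 x 60 mm rectangle), `"circle90"` /
#'   `"circle60"` / `"circle200"` (90-, 60- and 200-mm circular dishes),
#'   `"donut"` (60-mm dish centred in a 90-mm dish) or `"open"`.
#' @return A [field_geometry][make_field] object.
#' @export
field_preset <- function(name = c("rect30x60", "circle90", "circle60",
                                  "circle200", "donut", "open")) {
  name <- match.arg(name)
  switch(name,
    rect30x60 = make_field("rectangle", width = 30, height = 60),
    circle90  = make_field("circle", radius = 45),
    circle60  = make_field("circle", radius = 30),
    circle200 = make_field("circle", radius = 100),
    donut     = make_field("donut", inner_radius = 30, outer_radius = 45),
    open      = make_field("open")
  )
}

#' @export
print.field_geometry <- function(x, ...) {
  dims <- switch(x$kind,
    rectangle = sprintf("%.4g x %.4g units (%.4g x %.4g mm)",
                        x$width, x$height,
                        units_to_mm(x$width), units_to_mm(x$height)),
    circle = sprintf("radius %.4g units (%.4g mm)",
                     x$radius, units_to_mm(x$radius)),
    donut = sprintf("radii %.4g / %.4g units (%.4g / %.4g mm)",
                    x$inner_radius, x$outer_radius,
                    units_to_mm(x$inner_radius), units_to_mm(x$outer_radius)),
    open = "unbounded")
  cat("<field_geometry>", x$kind, dims, "\n")
  invisible(x)
}

field_bbox <- function(field) {
  switch(field$kind,
    rectangle = c(-field$width / 2, field$width / 2,
                  -field$height / 2, field$height / 2),
    circle = c(-field$radius, field$radius, -field$radius, field$radius),
    donut = c(-field$outer_radius, field$outer_radius,
              -field$outer_radius, field$outer_radius),
    stop_wigwag("open fields have no bounding box"))
}

# Signed distance from the wall: >= 0 inside, < 0 outside (vectorised).
wall_distance <- function(field, x, y) {
  switch(field$kind,
    rectangle = pmin(field$width / 2 - abs(x), field$height / 2 - abs(y)),
    circle = field$radius - sqrt(x^2 + y^2),
    donut = {
      r <- sqrt(x^2 + y^2)
      pmin(field$outer_radius - r, r - field$inner_radius)
    },
    open = rep(Inf, length(x)))
}

point_inside <- function(field, x, y, tol = 1e-9) {
  wall_distance(field, x, y) >= -tol
}

#' Partition an arena into the assay regions
#'
#' For bounded non-donut arenas two regions are defined: the *wall region*,
#' the band within `wall_margin_mm` of the wall, and the *central region*,
#' a concentric figure similar to the arena whose area equals that of the
#' wall band, leaving an intermediate *middle* zone. For the donut arena
#' the annulus is instead split by a circle into two equal-area halves:
#' the *convex-curve region* adjacent to the inner wall and the
#' *concave-curve region* adjacent to the outer wall (the same
#' `wall_margin_mm` band is retained for per-wall contact analyses).
#'
#' @param field A [field_geometry][make_field] object (not `"open"`).
#' @param wall_margin_mm Width of the wall band, mm (default 5).
#' @return An object of class `region_partition` carrying the analytic
#'   region boundaries (simulation units) and areas.
#'
#' @examples
#' p <- partition_regions(field_preset("circle90"))
#' region_areas(p, units = "mm")  # wall band and central circle: 425*pi each
#' @export
partition_regions <- function(field, wall_margin_mm = 5) {
  stopifnot(inherits(field, "field_geometry"))
  if (field$kind == "open")
    stop_wigwag("cannot partition an open (unbounded) field")
  if (!is.numeric(wall_margin_mm) || wall_margin_mm <= 0)
    stop_wigwag("wall_margin_mm must be positive")
  m <- mm_to_units(wall_margin_mm)
  p <- list(field = field, wall_margin = m, wall_margin_mm = wall_margin_mm)

  if (field$kind == "rectangle") {
    w <- field$width; h <- field$height
    if (m >= min(w, h) / 2)
      stop_wigwag("wall margin too large for this rectangle")
    band_area <- w * h - (w - 2 * m) * (h - 2 * m)
    s <- sqrt(band_area / (w * h))   # similar-figure scale for equal area
    p$central_width <- s * w
    p$central_height <- s * h
    if (p$central_width > w - 2 * m + 1e-9 || p$central_height > h - 2 * m + 1e-9)
      stop_wigwag("wall margin too large: central region would overlap the wall band")
    p$areas <- c(wall = band_area,
                 central = p$central_width * p$central_height,
                 middle = w * h - band_area - p$central_width * p$central_height)
  } else if (field$kind == "circle") {
    R <- field$radius
    if (m >= R) stop_wigwag("wall margin too large for this circle")
    p$band_inner_radius <- R - m
    p$central_radius <- sqrt(R^2 - (R - m)^2)
    if (p$central_radius > p$band_inner_radius + 1e-9)
      stop_wigwag("wall margin too large: central region would overlap the wall band")
    p$areas <- c(wall = pi * (R^2 - (R - m)^2),
                 central = pi * p$central_radius^2,
                 middle = pi * ((R - m)^2 - p$central_radius^2))
  } else { # donut
    ri <- field$inner_radius; ro <- field$outer_radius
    if (2 * m >= ro - ri)
      stop_wigwag("wall margin too large for this donut")
    p$split_radius <- sqrt((ri^2 + ro^2) / 2)   # equal-area annulus split
    p$areas <- c(convex = pi * (p$split_radius^2 - ri^2),
                 concave = pi * (ro^2 - p$split_radius^2))
  }
  structure(p, class = "region_partition")
}

#' Analytic region areas of a partition
#'
#' @param partition A [region_partition][partition_regions].
#' @param units `"sim"` (squared simulation units) or `"mm"` (mm^2).
#' @return Named numeric vector of region areas.
#' @export
region_areas <- function(partition, units = c("sim", "mm")) {
  stopifnot(inherits(partition, "region_partition"))
  units <- match.arg(units)
  a <- partition$areas
  if (units == "mm") a <- a * MM_PER_UNIT^2
  a
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>", x$field$kind,
      sprintf("(wall margin %.3g mm)\n", x$wall_margin_mm))
  print(round(region_areas(x, "mm"), 3))
  invisible(x)
}

#' Classify points into assay regions
#'
#' Assigns each point exactly one label. For rectangles and circles the
#' labels are `wall`, `central`, `middle` (or `outside`); for donuts they
#' are `convex`, `concave` (or `outside`). The wall band is closed on its
#' inner boundary: a point exactly at the margin distance from the wall
#' counts as `wall`, so a wall-sliding agent is always inside the wall
#' region. The donut split circle is assigned to `concave`.
#'
#' @param partition A [region_partition][partition_regions].
#' @param x,y Point coordinates in simulation units (vectors, or `x` may
#'   be a two-column matrix).
#' @return Character vector of region labels.
#' @export
classify_points <- function(partition, x, y = NULL) {
  stopifnot(inherits(partition, "region_partition"))
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  f <- partition$field
  tol <- 1e-9
  out <- character(length(x))
  if (f$kind == "donut") {
    r <- sqrt(x^2 + y^2)
    out[] <- "convex"
    out[r >= partition$split_radius] <- "concave"
    out[r > f$outer_radius + tol | r < f$inner_radius - tol] <- "outside"
    return(out)
  }
  d <- wall_distance(f, x, y)
  out[] <- "middle"
  inc <- if (f$kind == "rectangle") {
    abs(x) <= partition$central_width / 2 & abs(y) <= partition$central_height / 2
  } else {
    x^2 + y^2 <= partition$central_radius^2
  }
  out[inc] <- "central"
  out[d <= partition$wall_margin] <- "wall"   # closed inner boundary
  out[d < -tol] <- "outside"
  out
}

#' @rdname classify_points
#' @param point Length-2 numeric `c(x, y)`.
#' @export
classify_point <- function(partition, point) {
  classify_points(partition, point[1], point[2])
}

#' Wall collision with tangent sliding
#'
#' Implements the boundary rule of the locomotion model: when a proposed
#' step would cross the arena wall, the position is adjusted to the
#' nearest point on the wall and the heading is realigned to the wall
#' tangent direction — of the two opposite tangents, the one with the
#' smaller absolute angular difference from the incoming heading (an
#' exact tie is broken by the current random stream). Interior moves pass
#' through unchanged. At a rectangle corner the realignment edge is the
#' one whose (inward) direction is angularly closest to the incoming
#' heading.
#'
#' @param field A [field_geometry][make_field].
#' @param pos Current position `c(x, y)`, inside or on the boundary.
#' @param proposed_pos Proposed next position `c(x, y)`.
#' @param heading Incoming heading, radians (bearing: 0 = +y, clockwise).
#' @return `list(pos, heading, contact)`; `contact` is `TRUE` when the
#'   move was clamped to the wall.
#' @export
collide_and_slide <- function(field, pos, proposed_pos, heading) {
  if (field$kind == "open")
    return(list(pos = proposed_pos, heading = heading %% (2 * pi), contact = FALSE))
  if (wall_distance(field, pos[1], pos[2]) < -1e-9)
    stop_wigwag("current position lies outside the field")
  px <- proposed_pos[1]; py <- proposed_pos[2]

  if (field$kind == "rectangle") {
    hw <- field$width / 2; hh <- field$height / 2
    if (abs(px) <= hw && abs(py) <= hh)
      return(list(pos = c(px, py), heading = heading %% (2 * pi), contact = FALSE))
    cx <- min(max(px, -hw), hw)
    cy <- min(max(py, -hh), hh)
    on_x <- abs(cx) >= hw          # clamped against a vertical edge
    on_y <- abs(cy) >= hh          # clamped against a horizontal edge
    cand <- if (on_x && on_y) {
      # corner: inward directions along the two adjacent edges
      c(if (cy > 0) pi else 0,               # along the vertical edge
        if (cx > 0) 3 * pi / 2 else pi / 2)  # along the horizontal edge
    } else if (on_x) {
      c(0, pi)                # vertical edge runs along +/- y
    } else {
      c(pi / 2, 3 * pi / 2)   # horizontal edge runs along +/- x
    }
    new_h <- pick_tangent(cand, heading)
    return(list(pos = c(cx, cy), heading = new_h, contact = TRUE))
  }

  r2 <- px^2 + py^2
  if (field$kind == "circle") {
    R <- field$radius
    if (r2 <= R^2)
      return(list(pos = c(px, py), heading = heading %% (2 * pi), contact = FALSE))
    wallr <- R
  } else { # donut
    ri <- field$inner_radius; ro <- field$outer_radius
    if (r2 >= ri^2 && r2 <= ro^2)
      return(list(pos = c(px, py), heading = heading %% (2 * pi), contact = FALSE))
    wallr <- if (r2 > ro^2) ro else ri
  }
  r <- sqrt(r2)
  if (r < 1e-12) stop_wigwag("degenerate collision through the arena centre")
  cx <- px * wallr / r; cy <- py * wallr / r
  phi <- bearing_of(cx, cy)               # radial bearing of the contact point
  new_h <- pick_tangent(c(phi + pi / 2, phi - pi / 2), heading)
  list(pos = c(cx, cy), heading = new_h, contact = TRUE)
}

# Choose the candidate tangent bearing closest in angle to `heading`;
# exact ties are resolved by the current random stream.
pick_tangent <- function(candidates, heading) {
  d <- abs(ang_diff(candidates, heading))
  if (length(candidates) > 1L && abs(d[1] - d[2]) < 1e-12) {
    candidates[sample.int(2L, 1L)] %% (2 * pi)
  } else {
    candidates[which.min(d)] %% (2 * pi)
  }
}
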