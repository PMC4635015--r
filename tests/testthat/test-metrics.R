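test_that("preference indices count samples at dt resolution", {
  pr <- partition_regions(field_preset("rect30x60"))
  # 10-sample toy: 4 samples in the wall band (|x| >= 140/2 - margin)
  xs <- c(rep(0, 6), rep(69, 4))
  tr <- toy_traj(xs, rep(0, 10))
  res <- preference_indices(tr, pr)
  expect_equal(res$wall_index, 0.4)
  expect_equal(res$central_index, 0.6)   # x = 0 rows sit in the central figure
  expect_equal(res$T, 1.0)
  # conservation: region times sum to T exactly
  expect_equal(sum(res$region_times), res$T)
})

test_that("a trajectory entirely inside the wall band has wall index 1", {
  pr <- partition_regions(field_preset("circle90"))
  tr <- toy_traj(rep(0, 5), rep(209, 5))
  res <- preference_indices(tr, pr)
  expect_equal(res$wall_index, 1.0)
  expect_equal(res$central_index, 0.0)
  expect_lte(res$wall_index + res$central_index, 1)
  expect_error(preference_indices(tr[0, ], pr), "empty")
})

test_that("donut preference reports convex and concave indices", {
  pd <- partition_regions(field_preset("donut"))
  tr <- toy_traj(c(150, 150, 205, 205), c(0, 0, 0, 0))
  res <- preference_indices(tr, pd)
  expect_equal(res$convex_index, 0.5)
  expect_equal(res$concave_index, 0.5)
})

test_that("T/N ratio measures path tortuosity", {
  expect_equal(tn_ratio(toy_traj(c(0, 1, 2), c(0, 0, 0))), 1.0)
  # right angle, two equal legs
  expect_equal(tn_ratio(toy_traj(c(0, 1, 1), c(0, 0, 1))), sqrt(2))
  expect_error(tn_ratio(toy_traj(c(0, 1, 0), c(0, 0, 0))), "net displacement")
  expect_error(tn_ratio(toy_traj(0, 0)), "2 points")
  # any simulated trajectory with net displacement: ratio >= 1
  tr <- simulate_planarian(intact_params(), field_preset("open"), 30, seed = 4)
  expect_gte(tn_ratio(tr), 1)
})

test_that("intact-preset approach paths to the wall are nearly straight", {
  # linearity is measured on the approach step: centre until wall arrival
  f <- field_preset("circle90")
  part <- partition_regions(f)
  ratios <- sapply(1:20, function(s) {
    tr <- simulate_planarian(intact_params(), f, 120, seed = 40 + s)
    arrive <- which(wigwag:::in_wall_band(tr, part))[1]
    if (is.na(arrive) || arrive < 3) return(NA)
    tn_ratio(tr[seq_len(arrive - 1L), ])
  })
  # the behavioral regime: most approach paths have T/N close to 1
  expect_lt(median(ratios, na.rm = TRUE), 1.2)
})

test_that("wall episodes segment band residence correctly", {
  pr <- partition_regions(field_preset("circle90"))
  # enters band (r >= 186.67) at t = 5.0, exits at t = 12.0
  n <- 150
  r <- rep(100, n)
  r[51:120] <- 200
  tr <- toy_traj(r, rep(0, n))
  we <- wall_episodes(tr, pr)
  expect_equal(nrow(we$episodes), 1)
  expect_equal(we$episodes$t_contact, 5.0)
  expect_equal(we$episodes$t_detach, 12.0)
  expect_equal(we$episodes$dwell, 7.0)
  expect_false(we$episodes$open)
  # closed-episode dwells sum to the band dwell time T_w
  expect_equal(sum(we$episodes$dwell),
               preference_indices(tr, pr)$T_w)

  # reaches the band at t = 5 and never leaves: open episode, dwell T - 5
  r2 <- c(rep(100, 50), rep(200, 50))
  tr2 <- toy_traj(r2, rep(0, 100))
  we2 <- wall_episodes(tr2, pr)
  expect_equal(nrow(we2$episodes), 1)
  expect_true(we2$episodes$open)
  expect_equal(we2$episodes$dwell, tr2$t[100] - 5.0)
  expect_equal(we2$n_open, 1)

  # never enters the band
  we3 <- wall_episodes(toy_traj(rep(0, 10), rep(0, 10)), pr)
  expect_equal(nrow(we3$episodes), 0)
})

test_that("incidence/reflection is empty without contact and tangential with it", {
  f <- field_preset("circle90")
  none <- incidence_reflection(toy_traj(c(0, 1, 2), c(0, 0, 0)), f)
  expect_equal(nrow(none), 0)
  # radial (normal-incidence) approach from the centre
  tr <- simulate_planarian(straight_params(), f, 30, seed = 8)
  ir <- incidence_reflection(tr, f)
  expect_equal(nrow(ir), 1)
  expect_equal(ir$incidence_deg, 90, tolerance = 1e-6)
  # tangent realignment: outgoing motion along the wall (chord bound ~0.14 deg)
  expect_lt(ir$reflection_deg, 0.5)
  expect_error(incidence_reflection(tr, field_preset("open")), "wall")
})

test_that("kinematics reports speed, distance and wall arrival", {
  f <- field_preset("circle90")
  part <- partition_regions(f)
  tr <- simulate_planarian(intact_params(), f, 30, seed = 2)
  k <- kinematics(tr, part)
  interior <- !attr(tr, "contact")[-1]
  expect_true(all(abs(k$speeds[interior] - 10) < 1e-9))
  expect_equal(k$total_distance, sum(k$speeds) * 0.1)
  st <- kinematics(toy_traj(c(0, 0), c(0, 0)))
  expect_equal(st$total_distance, 0)
  expect_true(is.na(st$time_to_first_wall))
})

test_that("extract_wigwag inverts the simulator event process", {
  tr <- simulate_planarian(intact_params(), field_preset("open"), 120, seed = 21)
  ww <- extract_wigwag(tr)
  el <- attr(tr, "event_log")
  vis <- el[abs(el$angle) > 0.005, ]      # zero-rounded turns are invisible
  expect_equal(ww$angles, vis$angle, tolerance = 1e-9)
  expect_equal(ww$times, vis$tick * 0.1, tolerance = 1e-9)
  # intervals are positive multiples of dt
  expect_true(all(ww$intervals > 0))
  expect_equal(ww$intervals, round(ww$intervals / 0.1) * 0.1, tolerance = 1e-9)
  # perfectly straight trajectory: no events
  straight <- extract_wigwag(toy_traj(0:10, rep(0, 11)))
  expect_equal(length(straight$angles), 0)
  expect_error(extract_wigwag(toy_traj(c(0, 1), c(0, 0))), "3 points")
})

test_that("occupancy grids are normalised, peaked at the data and deterministic", {
  f <- field_preset("circle90")
  tr <- simulate_planarian(intact_params(), f, 60, seed = 5)
  g <- suppressWarnings(occupancy_kde(tr, f))
  expect_equal(sum(g$density), 1, tolerance = 1e-9)
  expect_true(all(g$density >= 0))
  expect_equal(g$cell_mm, 1)
  g2 <- suppressWarnings(occupancy_kde(tr, f))
  expect_identical(g$density, g2$density)

  # all mass at one location: argmax lands in that cell
  pt <- toy_traj(rep(10 * UNITS_PER_MM + 0.1, 3), rep(0, 3))
  gp <- suppressWarnings(occupancy_kde(pt, f, bandwidth_mm = 2))
  am <- arrayInd(which.max(gp$density), dim(gp$density))
  expect_equal(gp$x[am[1]], 10.5)
  expect_equal(abs(gp$y[am[2]]), 0.5)
  expect_error(occupancy_kde(list(), f), "no trajectories")
})

test_that("occupancy is invariant to trajectory order and set duplication", {
  f <- field_preset("circle90")
  a <- simulate_planarian(intact_params(), f, 30, seed = 1)
  b <- simulate_planarian(intact_params(), f, 30, seed = 2)
  g_ab <- suppressWarnings(occupancy_kde(list(a, b), f))
  g_ba <- suppressWarnings(occupancy_kde(list(b, a), f))
  expect_equal(g_ab$density, g_ba$density, tolerance = 1e-12)
  expect_equal(g_ab$bandwidth_mm, g_ba$bandwidth_mm)
  # duplicating the whole set leaves the (fixed-bandwidth) density unchanged
  g1 <- occupancy_kde(list(a, b), f, bandwidth_mm = 3)
  g2 <- occupancy_kde(list(a, b, a, b), f, bandwidth_mm = 3)
  expect_equal(g1$density, g2$density, tolerance = 1e-12)
})

test_that("LSCV selects an interior bandwidth on scattered data", {
  set.seed(1)
  n <- 400
  pts <- toy_traj(rnorm(n, 0, 40), rnorm(n, 0, 40))
  g <- occupancy_kde(pts, field_preset("circle90"))
  expect_equal(g$bandwidth_method, "lscv")
  expect_true(g$bandwidth_mm > 0)
  # heavily duplicated data has no interior LSCV minimum: fallback + warning
  dup <- toy_traj(rep(c(0, 40), each = 10), rep(0, 20))
  expect_warning(gd <- occupancy_kde(dup, field_preset("circle90")), "LSCV")
  expect_equal(gd$bandwidth_method, "reference")
  expect_equal(sum(gd$density), 1, tolerance = 1e-9)
})
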