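test_that("arena dimensions convert mm to simulation units at 14/3 per mm", {
  fr <- make_field("rectangle", width = 30, height = 60)
  expect_equal(c(fr$width, fr$height), c(140, 280))
  fc <- make_field("circle", radius = 45)
  expect_equal(fc$radius, 210)
  fd <- make_field("donut", inner_radius = 30, outer_radius = 45)
  expect_equal(c(fd$inner_radius, fd$outer_radius), c(140, 210))
  expect_equal(field_preset("circle200")$radius, 100 * 14 / 3)
})

test_that("invalid dimensions are rejected", {
  expect_error(make_field("rectangle", width = 30), "height")
  expect_error(make_field("circle", radius = -1), "positive")
  expect_error(make_field("donut", inner_radius = 45, outer_radius = 30),
               "inner_radius < outer_radius")
})

test_that("partitions have the stated equal-area geometry", {
  # rectangle 30x60 mm, 5-mm band: band area 800 mm^2, central 20x40 mm
  pr <- partition_regions(field_preset("rect30x60"))
  a <- region_areas(pr, units = "mm")
  expect_equal(a[["wall"]], 800)
  expect_equal(pr$central_width * MM_PER_UNIT, 20)
  expect_equal(pr$central_height * MM_PER_UNIT, 40)
  expect_equal(a[["wall"]], a[["central"]], tolerance = 1e-6)

  # circle radius 45 mm: central radius sqrt(425) mm
  pc <- partition_regions(field_preset("circle90"))
  expect_equal(pc$central_radius * MM_PER_UNIT, sqrt(425))
  ac <- region_areas(pc, units = "mm")
  expect_equal(ac[["wall"]], ac[["central"]], tolerance = 1e-6)
  expect_equal(ac[["wall"]], 425 * pi)

  # donut 30/45 mm: split radius sqrt((30^2+45^2)/2), halves 562.5*pi each
  pd <- partition_regions(field_preset("donut"))
  expect_equal(pd$split_radius * MM_PER_UNIT, sqrt((30^2 + 45^2) / 2))
  ad <- region_areas(pd, units = "mm")
  expect_equal(ad[["convex"]], 562.5 * pi)
  expect_equal(ad[["convex"]], ad[["concave"]], tolerance = 1e-6)
})

test_that("oversized wall margins are rejected", {
  expect_error(partition_regions(field_preset("rect30x60"), wall_margin_mm = 15),
               "margin")
  expect_error(partition_regions(field_preset("circle60"), wall_margin_mm = 30),
               "margin")
  expect_error(partition_regions(field_preset("open")), "open")
})

test_that("point classification follows the closed-wall-band convention", {
  pc <- partition_regions(field_preset("circle90"))
  expect_equal(classify_point(pc, c(0, 0)), "central")
  # a point on the wall itself
  expect_equal(classify_point(pc, c(0, 210)), "wall")
  # exactly at the inner band boundary (radius 40 mm): closed, counts wall
  expect_equal(classify_point(pc, c(40 * UNITS_PER_MM, 0)), "wall")
  expect_equal(classify_point(pc, c(0, 300)), "outside")
  # between central circle and band
  expect_equal(classify_point(pc, c(0, 30 * UNITS_PER_MM)), "middle")

  pr <- partition_regions(field_preset("rect30x60"))
  expect_equal(classify_point(pr, c(0, 0)), "central")
  expect_equal(classify_point(pr, c(70, 0)), "wall")

  pd <- partition_regions(field_preset("donut"))
  expect_equal(classify_point(pd, c(150, 0)), "convex")
  expect_equal(classify_point(pd, c(0, 205)), "concave")
  expect_equal(classify_point(pd, c(pd$split_radius, 0)), "concave")
  expect_equal(classify_point(pd, c(0, 50)), "outside")
})

test_that("interior moves pass through collide_and_slide unchanged", {
  f <- field_preset("circle90")
  r <- collide_and_slide(f, c(0, 0), c(1, 1), pi / 4)
  expect_identical(r$pos, c(1, 1))
  expect_false(r$contact)
  expect_equal(r$heading, pi / 4)
})

test_that("oblique approach to a flat wall slides tangentially, sign preserved", {
  f <- make_field("rectangle", width = 140, height = 280, units = "sim")
  up <- collide_and_slide(f, c(69.5, 0), c(69.5 + sin(pi / 4), cos(pi / 4)), pi / 4)
  expect_true(up$contact)
  expect_equal(up$pos[1], 70)
  expect_equal(up$heading, 0)            # +y, same along-wall sign as incoming
  down <- collide_and_slide(f, c(69.5, 0),
                            c(69.5 + sin(3 * pi / 4), cos(3 * pi / 4)), 3 * pi / 4)
  expect_equal(down$heading, pi)         # -y
})

test_that("radial circle contact clamps to the boundary and ties are random", {
  f <- make_field("circle", radius = 210, units = "sim")
  r <- collide_and_slide(f, c(0, 209.5), c(0, 210.5), 0)
  expect_equal(r$pos, c(0, 210))
  expect_true(abs(sqrt(sum(r$pos^2)) - 210) < 1e-9)
  set.seed(7)
  hs <- replicate(100, collide_and_slide(f, c(0, 209.5), c(0, 210.5), 0)$heading)
  expect_setequal(round(hs, 9), round(c(pi / 2, 3 * pi / 2), 9))
})

test_that("clamped points satisfy the boundary equation and stay near the incoming heading", {
  set.seed(11)
  fields <- list(field_preset("circle90"), field_preset("donut"),
                 field_preset("rect30x60"))
  for (f in fields) {
    for (i in 1:50) {
      # random boundary-adjacent position and outward heading
      h <- runif(1, 0, 2 * pi)
      pos <- switch(f$kind,
        circle = (f$radius - 0.4) * c(sin(h), cos(h)),
        donut = (f$outer_radius - 0.4) * c(sin(h), cos(h)),
        rectangle = c(f$width / 2 - 0.4, runif(1, -f$height / 2 + 1, f$height / 2 - 1)))
      out_h <- switch(f$kind, rectangle = pi / 2, h)   # roughly outward
      hh <- out_h + runif(1, -1, 1)
      prop <- pos + c(sin(hh), cos(hh))
      r <- collide_and_slide(f, pos, prop, hh)
      if (r$contact) {
        expect_lt(abs(wigwag:::wall_distance(f, r$pos[1], r$pos[2])), 1e-9)
        expect_lte(abs(wigwag:::ang_diff(r$heading, hh)), pi / 2 + 1e-9)
      }
    }
  }
})

test_that("positions outside the field are rejected", {
  f <- field_preset("circle90")
  expect_error(collide_and_slide(f, c(0, 300), c(0, 301), 0), "outside")
})
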