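test_that("containment honours the selection margin on both patterns", {
  disc <- disc_pattern()
  ell <- ellipse_pattern()
  expect_true(pattern_contains(disc, 0, 0, margin = 2))
  # the 2-um margin shrinks the disc to 95.5 um
  expect_false(pattern_contains(disc, 96.0, 0, margin = 2))
  expect_true(pattern_contains(disc, 95.5, 0, margin = 2))  # boundary inclusive
  # the 2-um margin shrinks the ellipse semi-axes to 193.5 x 47
  expect_true(pattern_contains(ell, 193.5, 0, margin = 2))
  expect_false(pattern_contains(ell, 193.6, 0, margin = 2))
  expect_true(pattern_contains(ell, 0, 47, margin = 2))
  expect_error(pattern_contains(disc, 0, 0, margin = 100), "margin")
  expect_error(micropattern("disc", interior_margin = 98), "margin")
  expect_error(micropattern("ellipse", semi_major = 40, semi_minor = 49))
})

test_that("containment is monotone in the margin", {
  disc <- disc_pattern()
  ell <- ellipse_pattern()
  set.seed(1)
  for (k in 1:200) {
    p <- runif(2, -200, 200)
    m1 <- runif(1, 0, 20); m2 <- runif(1, m1, 40)
    if (pattern_contains(disc, p[1], p[2], margin = m2)) {
      expect_true(pattern_contains(disc, p[1], p[2], margin = m1))
    }
    if (pattern_contains(ell, p[1], p[2], margin = m2)) {
      expect_true(pattern_contains(ell, p[1], p[2], margin = m1))
    }
  }
})

test_that("interior selection keeps exactly the margin-interior cells", {
  disc <- disc_pattern()
  cells <- data.frame(colony_id = 1, cell_id = 1:3,
                      cell_type = c("Tplus", "Tminus", "Tplus"),
                      x_um = c(0, 95.0, 97.0), y_um = c(0, 0, 0))
  kept <- select_interior(cells, disc)
  expect_equal(kept$cell_id, c(1L, 2L))
  # idempotent, order preserved, empty input tolerated
  expect_identical(select_interior(kept, disc), kept)
  expect_equal(nrow(select_interior(cells[0, ], disc)), 0L)
  all_centre <- data.frame(x_um = rep(0, 5), y_um = rep(0, 5))
  expect_equal(nrow(select_interior(all_centre, disc)), 5L)
})

test_that("exit_check flags moves whose endpoint leaves the pattern", {
  disc <- disc_pattern()
  ell <- ellipse_pattern()
  expect_true(exit_check(disc, 97, 0, heading = 0, step_length = 5))
  expect_false(exit_check(disc, 0, 0, heading = 123, step_length = 10))
  expect_false(exit_check(ell, 194, 0, heading = 180, step_length = 5))
  expect_true(exit_check(ell, 194, 0, heading = 0, step_length = 5))
})

test_that("nearest exterior heading is radial on the disc", {
  disc <- disc_pattern()
  expect_equal(nearest_exterior_heading(disc, 50, 0), 0)
  expect_equal(nearest_exterior_heading(disc, 0, -30), 270)
  set.seed(2)
  for (k in 1:100) {
    th <- runif(1, 0, 2 * pi); r <- runif(1, 1, 95)
    p <- c(r * cos(th), r * sin(th))
    expect_equal(nearest_exterior_heading(disc, p[1], p[2]),
                 (atan2(p[2], p[1]) * 180 / pi) %% 360, tolerance = 1e-9)
  }
  expect_error(nearest_exterior_heading(disc, 100, 0), "inside")
})

test_that("ellipse nearest-boundary search agrees with dense sampling", {
  ell <- ellipse_pattern()
  th <- seq(0, 2 * pi, length.out = 10001)[-1]
  bx <- ell$semi_major * cos(th)
  by <- ell$semi_minor * sin(th)
  pts <- list(c(0, 10), c(50, 20), c(-80, -10), c(150, 5), c(-170, 0),
              c(30, -40), c(100, 25))
  for (p in pts) {
    d2 <- (bx - p[1])^2 + (by - p[2])^2
    k <- which.min(d2)
    ref <- (atan2(by[k] - p[2], bx[k] - p[1]) * 180 / pi) %% 360
    got <- nearest_exterior_heading(ell, p[1], p[2])
    diff <- abs(got - ref) %% 360
    expect_lt(min(diff, 360 - diff), 0.5)
  }
  # co-vertex is the nearest boundary point from a point on the +y axis
  expect_equal(nearest_exterior_heading(ell, 0, 10), 90, tolerance = 1e-3)
})
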