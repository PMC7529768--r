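test_that("model specification matches the rule-combination table", {
  expect_error(model_spec(17), "1..16")
  expect_error(model_spec(0), "1..16")
  m1 <- model_spec(1)
  expect_false(any(c(m1$rule_velocity, m1$rule_persistence,
                     m1$rule_directional, m1$rule_border)))
  m7 <- model_spec(7)
  expect_true(m7$rule_velocity && m7$rule_directional)
  expect_false(m7$rule_persistence || m7$rule_border)
  m14 <- model_spec(14)
  expect_true(m14$rule_velocity && m14$rule_directional && m14$rule_border)
  expect_false(m14$rule_persistence)
  m16 <- model_spec(16)
  expect_true(all(c(m16$rule_velocity, m16$rule_persistence,
                    m16$rule_directional, m16$rule_border)))
  # all 16 flag combinations are distinct
  combos <- vapply(1:16, function(k) {
    m <- model_spec(k)
    paste0(as.integer(c(m$rule_velocity, m$rule_persistence,
                        m$rule_directional, m$rule_border)), collapse = "")
  }, character(1))
  expect_equal(length(unique(combos)), 16L)
})

test_that("neighbour forces follow the inverse-square law", {
  # symmetric neighbours cancel exactly
  f <- compute_force(0, 0, c(5, -5), c(0, 0), R = 50, sign = "push")
  expect_equal(f$fx, 0)
  expect_equal(f$fy, 0)
  # magnitude ratio at distances D and 2D is exactly 4
  f1 <- compute_force(0, 0, 1, 0, R = 50, sign = "push")
  f2 <- compute_force(0, 0, 2, 0, R = 50, sign = "push")
  expect_equal(sqrt(f1$fx^2 + f1$fy^2) / sqrt(f2$fx^2 + f2$fy^2), 4)
  # push points away from the neighbour, pull towards it
  expect_lt(compute_force(0, 0, 3, 0, R = 50, sign = "push")$fx, 0)
  expect_gt(compute_force(0, 0, 3, 0, R = 50, sign = "pull")$fx, 0)
  # no neighbour within range
  expect_equal(compute_force(0, 0, 60, 0, R = 50, sign = "push"),
               list(fx = 0, fy = 0, mag_sum = 0))
  expect_error(compute_force(0, 0, 0, 0, R = 50, sign = "push"),
               "coincident")
})

test_that("net force matches a per-pair brute-force oracle", {
  set.seed(42)
  for (k in 1:1000) {
    n <- sample(1:8, 1)
    nx <- runif(n, -60, 60); ny <- runif(n, -60, 60)
    R <- runif(1, 10, 80)
    sign <- sample(c("push", "pull"), 1)
    f <- compute_force(0, 0, nx, ny, R, sign)
    ref <- brute_force_sum(0, 0, nx, ny, R, sign)
    scale <- max(1e-12, sqrt(sum(ref^2)))
    expect_lt(abs(f$fx - ref[1]) / scale, 1e-9)
    expect_lt(abs(f$fy - ref[2]) / scale, 1e-9)
  }
})

test_that("velocity ratio has its closed-form values and stays in [0,1]", {
  expect_equal(velocity_ratio(1, 0), 1)
  expect_equal(velocity_ratio(c(1, -1), c(0, 0)), 0)
  expect_equal(velocity_ratio(c(1, 0), c(0, 1)), sqrt(2) / 2)
  expect_equal(velocity_ratio(numeric(0), numeric(0)), 1)  # no neighbours
  set.seed(7)
  for (k in 1:2000) {
    n <- sample(1:6, 1)
    r <- velocity_ratio(rnorm(n), rnorm(n))
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("direction sampling is Gaussian about the force angle", {
  set.seed(3)
  expect_equal(sample_direction(1, 0, 0), 0)
  expect_equal(sample_direction(0, 1, 0), 90)
  draws <- replicate(1e5, sample_direction(1, 0, 5))
  # wrap to (-180, 180] around the force angle 0
  centred <- ifelse(draws > 180, draws - 360, draws)
  expect_lt(abs(mean(centred)), 0.1)
  expect_lt(abs(sd(centred) - 5), 0.2)
  # zero force carries no information: uniform heading
  u <- replicate(2e4, sample_direction(0, 0, 5))
  expect_gt(suppressWarnings(ks.test(u / 360, "punif")$p.value), 1e-4)
})

test_that("border turn rotates away from the escape direction", {
  expect_equal(border_turn(0, 30, 20), 340)
  expect_equal(border_turn(0, 330, 20), 20)
  expect_equal(border_turn(10, 10, 20), 30)  # tie: counter-clockwise
  expect_equal(border_turn(350, 20, 20), 330)
  expect_error(border_turn(0, 0, 200), "alpha")
})

test_that("colony seeding respects counts, types and separation", {
  pat <- disc_pattern()
  par <- sim_params()
  set.seed(5)
  col <- init_colony(pat, 6, 0.5, par)
  expect_equal(nrow(col$cells), 6L)
  expect_equal(sum(col$cells$cell_type == "Tplus"), 3L)
  expect_true(all(pattern_contains(pat, col$cells$x_um, col$cells$y_um,
                                   margin = pat$interior_margin)))
  d <- dist(col$cells[, c("x_um", "y_um")])
  expect_gte(min(d), par$min_separation)
  # single cell: no pairwise constraint
  set.seed(5)
  expect_equal(nrow(init_colony(pat, 1, 1, par)$cells), 1L)
  # determinism
  set.seed(9); a <- init_colony(pat, 6, 0.5, par)
  set.seed(9); b <- init_colony(pat, 6, 0.5, par)
  expect_identical(a, b)
})

test_that("a pushed cell moves directly away from its only neighbour", {
  pat <- disc_pattern()
  par <- sim_params(Tplus = cell_type_params(100, 105, direction_sd = 0,
                                             force_sign = "push"),
                    Tminus = cell_type_params(40, 15, direction_sd = 0,
                                              force_sign = "pull"))
  col <- structure(list(
    pattern = pat,
    cells = data.frame(id = 1:2, cell_type = c("Tplus", "Tminus"),
                       x_um = c(0, 20), y_um = c(0, 0),
                       heading = c(0, 0), repoll = c(7L, 1L)),
    timestamp = 0L), class = "colony")
  set.seed(1)
  out <- step_colony(col, model_spec(7), par)
  # T+ focal cell had its neighbour due east: it ends strictly west
  expect_lt(out$cells$x_um[1], -10)
  expect_equal(out$cells$y_um[1], 0, tolerance = 1e-9)
})

test_that("trajectories are reproducible and confined", {
  pat <- ellipse_pattern()
  par <- sim_params()
  a <- run_model(model_spec(16), par, pat, n_colonies = 2, seed = 31)
  b <- run_model(model_spec(16), par, pat, n_colonies = 2, seed = 31)
  expect_identical(a, b)
  expect_true(all(pattern_contains(pat, a$x_um, a$y_um)))
})

test_that("neighbour fraction matches a brute-force count", {
  close_pair <- data.frame(x_um = c(0, 1), y_um = c(0, 0))
  expect_equal(neighbor_fraction(close_pair, 2), 1)
  far_pair <- data.frame(x_um = c(0, 5), y_um = c(0, 0))
  expect_equal(neighbor_fraction(far_pair, 2), 0)
  set.seed(8)
  cells <- data.frame(x_um = runif(40, -90, 90), y_um = runif(40, -90, 90))
  for (radius in c(5, 20, 60)) {
    ref <- mean(vapply(seq_len(40), function(i) {
      any(sqrt((cells$x_um[-i] - cells$x_um[i])^2 +
                 (cells$y_um[-i] - cells$y_um[i])^2) <= radius)
    }, logical(1)))
    expect_equal(neighbor_fraction(cells, radius), ref)
  }
})
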