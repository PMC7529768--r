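# gaussian bump evaluated on a pattern grid, for constructed density maps
bump_map <- function(pattern, centres, sds, weights = NULL, n_grid = 128) {
  ext <- scapd:::pattern_extent(pattern)
  gx <- seq(ext$x[1], ext$x[2], length.out = n_grid)
  gy <- seq(ext$y[1], ext$y[2], length.out = n_grid)
  if (is.null(weights)) weights <- rep(1, nrow(centres))
  vals <- matrix(0, n_grid, n_grid)
  for (k in seq_len(nrow(centres))) {
    vals <- vals + weights[k] *
      outer(dnorm(gx, centres[k, 1], sds[k]), dnorm(gy, centres[k, 2], sds[k]))
  }
  density_map(vals, gx, gy)
}

test_that("iso-contours reflect the density topology", {
  pat <- disc_pattern()
  uni <- bump_map(pat, matrix(c(0, 0), 1), sds = 30)
  cc <- extract_border_points(uni, density_threshold(uni))
  expect_gte(length(cc), 1L)
  # a radial unimodal density has an approximately circular outermost contour
  r <- sqrt(cc[[1]]$x^2 + cc[[1]]$y^2)
  expect_lt(diff(range(r)) / mean(r), 0.05)
  # bimodal tip fixture on the ellipse yields two contours
  ell <- ellipse_pattern()
  tips <- bump_map(ell, rbind(c(-160, 0), c(160, 0)), sds = c(15, 15))
  cc2 <- extract_border_points(tips, density_threshold(tips))
  expect_equal(length(cc2), 2L)
  expect_error(extract_border_points(uni, max(uni$values) * 1.1), "between")
})

test_that("symmetrisation recentres and mirrors fitted borders", {
  # disc circle: radius kept, centre moved to the origin
  b <- symmetrize_border(list(list(cx = 3, cy = -2, r = 40)), "circle",
                         "inside")
  expect_equal(b$components[[1]], list(cx = 0, cy = 0, r = 40))
  # tip pair: shared per-axis maxima, centres +/- mean |x|, y = 0
  fits <- list(list(cx = 150.2, cy = 1.5, a = 32, b = 18, angle = 0),
               list(cx = -148.8, cy = -0.9, a = 30, b = 20, angle = 0))
  tp <- symmetrize_border(fits, "ellipse", "inside")
  expect_equal(tp$components[[1]], list(cx = 149.5, cy = 0, ax = 32, ay = 20))
  expect_equal(tp$components[[2]], list(cx = -149.5, cy = 0, ax = 32, ay = 20))
  # single central ellipse: centre reset, axes preserved
  ce <- symmetrize_border(list(list(cx = 1.2, cy = -0.4, a = 50, b = 20,
                                    angle = 0)), "ellipse", "inside")
  expect_equal(ce$components[[1]], list(cx = 0, cy = 0, ax = 50, ay = 20))
  # a near-vertical fitted ellipse maps its major axis to y
  cv <- symmetrize_border(list(list(cx = 0, cy = 0, a = 50, b = 20,
                                    angle = 88)), "ellipse", "inside")
  expect_equal(cv$components[[1]], list(cx = 0, cy = 0, ax = 20, ay = 50))
  expect_error(symmetrize_border(fits, "circle", "inside"), "one circle")
})

test_that("total density integrates grid mass inside the border", {
  pat <- disc_pattern()
  set.seed(10)
  vals <- matrix(rexp(128 * 128), 128, 128)
  ext <- scapd:::pattern_extent(pat)
  d <- density_map(vals, seq(ext$x[1], ext$x[2], length.out = 128),
                   seq(ext$y[1], ext$y[2], length.out = 128))
  # a border covering the whole grid holds all the mass
  big <- symmetrize_border(list(list(cx = 0, cy = 0, r = 1000)), "circle",
                           "inside")
  expect_equal(total_density(d, big, pat), 1, tolerance = 1e-12)
  # brute-force oracle on an arbitrary circle
  born <- symmetrize_border(list(list(cx = 0, cy = 0, r = 55)), "circle",
                            "inside")
  ref <- 0
  for (i in seq_along(d$x)) for (j in seq_along(d$y)) {
    if (d$x[i]^2 + d$y[j]^2 <= 55^2) ref <- ref + d$values[i, j]
  }
  expect_equal(total_density(d, born, pat), ref, tolerance = 1e-12)
  # inside + outside-within-pattern + outside-pattern mass is everything
  out_b <- symmetrize_border(list(list(cx = 0, cy = 0, r = 55)), "circle",
                             "outside")
  gx <- rep(d$x, times = 128); gy <- rep(d$y, each = 128)
  mass_out_pat <- sum(d$values[matrix(!pattern_contains(pat, gx, gy), 128)])
  expect_equal(total_density(d, born, pat) + total_density(d, out_b, pat) +
                 mass_out_pat, 1, tolerance = 1e-9)
})

test_that("uniform mass splits in proportion to the border area", {
  pat <- disc_pattern()
  ext <- scapd:::pattern_extent(pat)
  n <- 256
  d <- density_map(matrix(1, n, n), seq(ext$x[1], ext$x[2], length.out = n),
                   seq(ext$y[1], ext$y[2], length.out = n))
  # circle of half the grid area; the point lattice spans (n-1)/n of the
  # nominal side, so the expected count fraction carries that factor
  r_half <- sqrt((2 * 107.25)^2 / (2 * pi))
  bh <- symmetrize_border(list(list(cx = 0, cy = 0, r = r_half)), "circle",
                          "inside")
  expect_equal(total_density(d, bh, pat), 0.5 * (255 / 256)^2,
               tolerance = 2e-3)
})

test_that("ground truth borders are symmetric and self-distance is zero", {
  for (kind in c("disc", "ellipse")) {
    ref <- small_reference(kind)
    pat <- micropattern(kind)
    gt <- suppressWarnings(build_ground_truth(ref, pat))
    expect_s3_class(gt, "ground_truth")
    expect_true(all(gt$Te > 0 & gt$Te < 1))
    # symmetrised borders: disc circles at the origin; ellipse components
    # mirrored in x with y-centres 0
    for (b in gt$borders) {
      xs <- vapply(b$components, `[[`, numeric(1), "cx")
      ys <- vapply(b$components, `[[`, numeric(1), "cy")
      expect_equal(sum(xs), 0)
      expect_equal(ys, rep(0, length(ys)))
    }
    res <- scapd(gt, ref)
    expect_identical(res$scapd, 0)
    # deterministic rebuild
    gt2 <- suppressWarnings(build_ground_truth(ref, pat))
    expect_equal(gt$Te, gt2$Te)
  }
})

test_that("SCAPD grows monotonically as mass leaves the reference HDA", {
  # constructed maps: move a fraction phi of T+ mass from the HDA centre to
  # the far outside; the T+ term must increase monotonically in phi
  pat <- disc_pattern()
  border <- symmetrize_border(list(list(cx = 0, cy = 0, r = 40)), "circle",
                              "inside")
  Te <- total_density(bump_map(pat, matrix(c(0, 0), 1), 12), border, pat)
  terms <- vapply(seq(0, 0.8, by = 0.2), function(phi) {
    moved <- bump_map(pat, rbind(c(0, 0), c(80, 0)), c(12, 12),
                      weights = c(1 - phi, phi))
    abs(Te - total_density(moved, border, pat))
  }, numeric(1))
  expect_true(all(diff(terms) > 0))
  # bounds
  expect_lte(max(terms), 2)
})

test_that("SCAPD compares model output against the reference borders", {
  pat <- disc_pattern()
  ref <- small_reference("disc")
  gt <- suppressWarnings(build_ground_truth(ref, pat))
  # a uniform null set scores worse than the reference itself
  nul <- generate_null_reference(pat, pattern_spec(n_colonies = 60),
                                 seed = 12)
  res <- scapd(gt, nul)
  expect_gt(res$scapd, 0)
  expect_lte(res$scapd, 2)
  expect_equal(res$scapd,
               sum(abs(res$Te - res$Tm)))
  expect_error(scapd(gt, nul[nul$cell_type == "Tplus", ]), "Tminus")
})
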