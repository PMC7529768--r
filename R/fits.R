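# Least-squares circle and ellipse fits used to approximate high-density-area
# borders extracted from density maps.

#' Algebraic least-squares circle fit
#'
#' Kasa's formulation: minimises the algebraic residual
#' sum (x^2 + y^2 + D x + E y + F)^2, a linear least-squares problem whose
#' solution gives centre (-D/2, -E/2) and radius sqrt((D^2 + E^2)/4 - F).
#' For three non-collinear points this is the exact circumcircle.
#'
#' @param points Data frame or matrix with columns `x`, `y` (first two
#'   columns used).
#' @return List with `cx`, `cy`, `r`.
#' @export
fit_circle <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 points to fit a circle")
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- tryCatch(unname(qr.solve(A, b)), error = function(e)
    stop("circle fit is degenerate (collinear points?)"))
  D <- coef[1]; E <- coef[2]; F <- coef[3]
  r2 <- (D^2 + E^2) / 4 - F
  if (!is.finite(r2) || r2 <= 0) stop("circle fit is degenerate")
  list(cx = -D / 2, cy = -E / 2, r = sqrt(r2))
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic A x^2 + B x y + C y^2 + D x + E y + F = 0 under the
#' ellipse-specific constraint 4AC - B^2 = 1 (Fitzgibbon's direct method, in
#' the numerically stable partitioned form of Halir & Flusser), and converts
#' the conic to geometric parameters.
#'
#' @param points Data frame or matrix with columns `x`, `y`.
#' @return List with centre `cx`, `cy`, semi-axes `a >= b`, orientation
#'   `angle` of the major axis in degrees in `[0, 180)`, and the conic
#'   coefficient vector `conic` (A, B, C, D, E, F).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 6) stop("need at least 6 points to fit an ellipse")
  x <- pts[, 1]; y <- pts[, 2]
  # centre/scale for conditioning; the conic is mapped back afterwards
  mx <- mean(x); my <- mean(y)
  sx <- max(stats::sd(x), 1e-12); sy <- max(stats::sd(y), 1e-12)
  xs <- (x - mx) / sx; ys <- (y - my) / sy
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("ellipse fit is degenerate"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) stop("no ellipse solution (degenerate conic)")
  a1 <- evec[, idx[1]]
  coef_s <- c(a1, as.vector(Tm %*% a1))  # conic in scaled coordinates
  # map conic back to original coordinates
  A <- coef_s[1] / sx^2
  B <- coef_s[2] / (sx * sy)
  C <- coef_s[3] / sy^2
  D <- coef_s[4] / sx - 2 * coef_s[1] * mx / sx^2 - coef_s[2] * my / (sx * sy)
  E <- coef_s[5] / sy - 2 * coef_s[3] * my / sy^2 - coef_s[2] * mx / (sx * sy)
  F <- coef_s[6] + coef_s[1] * mx^2 / sx^2 + coef_s[3] * my^2 / sy^2 +
    coef_s[2] * mx * my / (sx * sy) - coef_s[4] * mx / sx -
    coef_s[5] * my / sy
  conic_to_geometric(c(A, B, C, D, E, F))
}

# convert conic coefficients (A,B,C,D,E,F) to centre/axes/angle
conic_to_geometric <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- B^2 - 4 * A * C
  if (!is.finite(den) || den >= 0) stop("conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a2 <- num * (A + C + s) / den^2
  b2 <- num * (A + C - s) / den^2
  semi <- sqrt(sort(c(a2, b2), decreasing = TRUE))
  if (any(!is.finite(semi)) || any(semi <= 0)) stop("conic is not an ellipse")
  # principal-axis angle of the quadratic form [A, B/2; B/2, C]; the axis
  # with the smaller form value is the major one (sign-robust)
  theta <- 0.5 * atan2(B, A - C)
  ct <- cos(theta); st <- sin(theta)
  lam_here <- A * ct^2 + B * ct * st + C * st^2
  lam_perp <- A * st^2 - B * ct * st + C * ct^2
  if ((lam_here - lam_perp) * (A + C) > 0) theta <- theta + pi / 2
  angle <- (theta * 180 / pi) %% 180
  list(cx = cx, cy = cy, a = semi[1], b = semi[2], angle = angle,
       conic = c(A = A, B = B, C = C, D = D, E = E, F = F))
}

# algebraic residual sum of squares of a conic on points, with the conic
# normalised to 4AC - B^2 = 1 (used by oracle comparisons)
conic_residual <- function(conic, points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  k <- conic / sqrt(4 * conic[1] * conic[3] - conic[2]^2)
  x <- pts[, 1]; y <- pts[, 2]
  sum((k[1] * x^2 + k[2] * x * y + k[3] * y^2 +
         k[4] * x + k[5] * y + k[6])^2)
}
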