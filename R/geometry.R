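#' Micropattern geometry
#'
#' Constructs the adhesive micropattern that geometrically confines a stem-cell
#' colony: a disc (default radius 97.5 um) or an ellipse (default semi-axes
#' 195.5 x 49 um), centred at the origin. Cells observed less than
#' `interior_margin` um inside the border are excluded from analysis
#' (see [select_interior()]); for the defaults this reproduces the 95.5 um
#' selection disc and the 193.5 x 47 um selection ellipse.
#'
#' @param kind `"disc"` or `"ellipse"`.
#' @param disc_radius Disc radius in um.
#' @param semi_major,semi_minor Ellipse semi-axes in um (`semi_major >=
#'   `semi_minor`).
#' @param interior_margin Interior selection margin in um; must be smaller than
#'   every half-dimension.
#'
#' @return An object of class `micropattern`.
#' @examples
#' disc <- micropattern("disc")
#' ell  <- micropattern("ellipse")
#' @export
micropattern <- function(kind = c("disc", "ellipse"),
                         disc_radius = 97.5,
                         semi_major = 195.5,
                         semi_minor = 49,
                         interior_margin = 2) {
  kind <- match.arg(kind)
  stopifnot(disc_radius > 0, semi_major > 0, semi_minor > 0,
            interior_margin >= 0)
  if (semi_major < semi_minor) {
    stop("semi_major must be >= semi_minor")
  }
  half_min <- if (kind == "disc") disc_radius else semi_minor
  if (interior_margin >= half_min) {
    stop("interior_margin must be smaller than the smallest half-dimension")
  }
  structure(
    list(kind = kind,
         disc_radius = disc_radius,
         semi_major = semi_major,
         semi_minor = semi_minor,
         interior_margin = interior_margin),
    class = "micropattern"
  )
}

#' @export
print.micropattern <- function(x, ...) {
  if (x$kind == "disc") {
    cat(sprintf("micropattern: disc, radius %.1f um (interior margin %.1f um)\n",
                x$disc_radius, x$interior_margin))
  } else {
    cat(sprintf("micropattern: ellipse, %.1f x %.1f um semi-axes (interior margin %.1f um)\n",
                x$semi_major, x$semi_minor, x$interior_margin))
  }
  invisible(x)
}

# smallest half-dimension of the pattern
pattern_half_min <- function(pattern) {
  if (pattern$kind == "disc") pattern$disc_radius else pattern$semi_minor
}

#' Point-in-pattern test with a shrink margin
#'
#' Tests whether points lie inside the micropattern shrunk inward by `margin`
#' um. For the disc the shrunk region is the concentric disc of radius
#' `radius - margin`; for the ellipse each semi-axis is shrunk by `margin`
#' (the 2 um margin on the default ellipse gives semi-axes 193.5 and 47).
#' The boundary is inclusive.
#'
#' @param pattern A [micropattern()].
#' @param x,y Point coordinates in um (vectorised).
#' @param margin Non-negative shrink margin in um, smaller than every
#'   half-dimension.
#' @return Logical vector.
#' @export
pattern_contains <- function(pattern, x, y, margin = 0) {
  stopifnot(inherits(pattern, "micropattern"), margin >= 0)
  if (margin >= pattern_half_min(pattern)) {
    stop("margin must be smaller than the smallest half-dimension")
  }
  if (pattern$kind == "disc") {
    r <- pattern$disc_radius - margin
    x^2 + y^2 <= r^2
  } else {
    a <- pattern$semi_major - margin
    b <- pattern$semi_minor - margin
    (x / a)^2 + (y / b)^2 <= 1
  }
}

#' Interior selection of cells
#'
#' Keeps only cells lying more than the pattern's interior margin inside the
#' micropattern border, mirroring the exclusion of cells at (or beyond) the
#' edge of the adhesive area in the imaging data.
#'
#' @param cells Data frame with at least `x_um` and `y_um` columns.
#' @param pattern A [micropattern()].
#' @return The subset of rows of `cells` whose positions pass the margin test,
#'   original order preserved.
#' @export
select_interior <- function(cells, pattern) {
  stopifnot(is.data.frame(cells), all(c("x_um", "y_um") %in% names(cells)))
  if (nrow(cells) == 0L) return(cells)
  keep <- pattern_contains(pattern, cells$x_um, cells$y_um,
                           margin = pattern$interior_margin)
  cells[keep, , drop = FALSE]
}

# unit vector for a heading in degrees (counter-clockwise from +x)
heading_unit <- function(heading_deg) {
  th <- heading_deg * pi / 180
  c(cos(th), sin(th))
}

wrap_heading <- function(deg) deg %% 360

#' Would a straight-line move exit the micropattern?
#'
#' @param pattern A [micropattern()].
#' @param x,y Current position in um.
#' @param heading Heading in degrees counter-clockwise from +x.
#' @param step_length Move length in um (>= 0).
#' @return `TRUE` iff the endpoint of the move lies outside the pattern
#'   (margin 0).
#' @export
exit_check <- function(pattern, x, y, heading, step_length) {
  stopifnot(step_length >= 0)
  u <- heading_unit(heading)
  !pattern_contains(pattern, x + step_length * u[1], y + step_length * u[2])
}

#' Heading towards the nearest point outside the pattern
#'
#' For a point strictly inside the micropattern, returns the heading (degrees)
#' from the point to the nearest boundary point — the direction of quickest
#' escape, used by the border-turn motility rule to decide the turn sense.
#' On the disc this is the outward radial direction; on the ellipse the
#' nearest boundary point is found numerically.
#'
#' @param pattern A [micropattern()].
#' @param x,y Position in um, strictly inside the pattern.
#' @return Heading in degrees in `[0, 360)`.
#' @export
nearest_exterior_heading <- function(pattern, x, y) {
  if (!pattern_contains(pattern, x, y)) {
    stop("point must lie inside the micropattern")
  }
  if (pattern$kind == "disc") {
    if (x == 0 && y == 0) {
      # undefined by symmetry: any escape direction is equally near
      return(stats::runif(1, 0, 360))
    }
    return(wrap_heading(atan2(y, x) * 180 / pi))
  }
  a <- pattern$semi_major
  b <- pattern$semi_minor
  if (x == 0 && y == 0) {
    # nearest boundary point of an ellipse from the centre is a co-vertex
    return(if (stats::runif(1) < 0.5) 90 else 270)
  }
  # minimise squared distance to the boundary point (a cos t, b sin t)
  d2 <- function(t) (a * cos(t) - x)^2 + (b * sin(t) - y)^2
  t0 <- atan2(y / b, x / a)
  opt <- stats::optimize(d2, interval = c(t0 - pi / 2, t0 + pi / 2),
                         tol = 1e-12)
  tb <- opt$minimum
  wrap_heading(atan2(b * sin(tb) - y, a * cos(tb) - x) * 180 / pi)
}

# Largest t in [0, step] such that (x,y) + t*u stays inside the pattern,
# given the endpoint at t = step is outside. Both disc and ellipse boundaries
# are quadrics, so the crossing solves a quadratic in t.
boundary_clip <- function(pattern, x, y, ux, uy, step) {
  if (pattern$kind == "disc") {
    a2 <- 1; b2 <- 1; r2 <- pattern$disc_radius^2
  } else {
    a2 <- pattern$semi_major^2
    b2 <- pattern$semi_minor^2
    r2 <- 1
    # scale coordinates so the boundary is the unit circle
    x <- x / sqrt(a2); y <- y / sqrt(b2)
    ux <- ux / sqrt(a2); uy <- uy / sqrt(b2)
    a2 <- 1; b2 <- 1
  }
  # solve |(x,y) + t (ux,uy)|^2 = r2
  A <- ux^2 + uy^2
  B <- 2 * (x * ux + y * uy)
  C <- x^2 + y^2 - r2
  disc <- B^2 - 4 * A * C
  if (A == 0 || disc < 0) return(0)
  t1 <- (-B + sqrt(disc)) / (2 * A)
  # back off slightly so rounding never lands the endpoint outside
  max(0, min(step, t1 - 1e-9))
}
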