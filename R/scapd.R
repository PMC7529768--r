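# SCAPD: per-cell-type density maps -> mid-range threshold -> iso-contours ->
# least-squares circle/ellipse fits -> symmetrisation -> total density inside
# the fitted high-density-area (HDA) borders -> sum of absolute per-type
# differences.

#' Iso-contours of a density map
#'
#' Extracts the level-`T` contours of the density surface (marching squares
#' with linear interpolation, via [grDevices::contourLines()]), in um
#' coordinates. Contours with fewer than 6 points are discarded as noise.
#'
#' @param dmap A [density_map()].
#' @param T Contour level, strictly between the map's minimum and maximum.
#' @return List of data frames with columns `x`, `y`, ordered by decreasing
#'   enclosed area.
#' @export
extract_border_points <- function(dmap, T) {
  stopifnot(inherits(dmap, "density_map"))
  if (T <= min(dmap$values) || T >= max(dmap$values)) {
    stop("threshold must lie strictly between the density extremes")
  }
  cl <- grDevices::contourLines(dmap$x, dmap$y, dmap$values, levels = T)
  cl <- Filter(function(cc) length(cc$x) >= 6, cl)
  if (length(cl) == 0) stop("no contour at the requested level")
  out <- lapply(cl, function(cc) data.frame(x = cc$x, y = cc$y))
  areas <- vapply(out, polygon_area, numeric(1))
  out[order(areas, decreasing = TRUE)]
}

# absolute shoelace area of a (possibly open) contour, closed implicitly
polygon_area <- function(df) {
  x <- df$x; y <- df$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Symmetrise fitted HDA borders
#'
#' Colonies are seeded at random, so pooled patterns carry no preferred
#' orientation: the disc assessment must be rotation-symmetric and the
#' ellipse assessment mirror-symmetric in both axes. Fitted borders are
#' therefore recentred: a disc circle keeps its radius but moves to the
#' origin; a single central ellipse moves to the origin (axis-aligned, axes
#' preserved); a tip-ellipse pair becomes an axis-aligned mirrored pair at
#' (+/- mean |x|, 0) sharing the per-axis maximum semi-axes of the two fits.
#'
#' @param fits For `shape = "circle"`: a list with one [fit_circle()] result.
#'   For `shape = "ellipse"`: a list of one (central) or two (tip pair)
#'   [fit_ellipse()] results.
#' @param shape `"circle"` or `"ellipse"`.
#' @param hda_side `"inside"` if the HDA is the interior of the fitted
#'   shape(s), `"outside"` if it is the part of the micropattern outside them
#'   (an annulus for edge-concentrated cells on the disc).
#' @return An object of class `fitted_border` with a `components` list of
#'   shapes (`cx`, `cy`, and `r` or `ax`, `ay`).
#' @export
symmetrize_border <- function(fits, shape = c("circle", "ellipse"),
                              hda_side = c("inside", "outside")) {
  shape <- match.arg(shape)
  hda_side <- match.arg(hda_side)
  if (shape == "circle") {
    if (length(fits) != 1) stop("disc patterns take exactly one circle fit")
    comp <- list(list(cx = 0, cy = 0, r = fits[[1]]$r))
  } else if (length(fits) == 1) {
    f <- fits[[1]]
    ax_ay <- aligned_axes(f)
    comp <- list(list(cx = 0, cy = 0, ax = ax_ay[1], ay = ax_ay[2]))
  } else if (length(fits) == 2) {
    ax1 <- aligned_axes(fits[[1]]); ax2 <- aligned_axes(fits[[2]])
    ax <- max(ax1[1], ax2[1])
    ay <- max(ax1[2], ax2[2])
    xc <- mean(c(abs(fits[[1]]$cx), abs(fits[[2]]$cx)))
    comp <- list(list(cx = xc, cy = 0, ax = ax, ay = ay),
                 list(cx = -xc, cy = 0, ax = ax, ay = ay))
  } else {
    stop("ellipse patterns take one (central) or two (tip) ellipse fits")
  }
  structure(list(shape = shape, components = comp, hda_side = hda_side,
                 symmetrized = TRUE),
            class = "fitted_border")
}

# assign the fitted semi-axes to the x/y axes when orientation is dropped:
# the semi-axis whose direction is closer to x becomes the x semi-axis
aligned_axes <- function(fit) {
  th <- fit$angle * pi / 180
  if (abs(cos(th)) >= abs(sin(th))) c(fit$a, fit$b) else c(fit$b, fit$a)
}

#' @export
print.fitted_border <- function(x, ...) {
  cat(sprintf("fitted border: %s, HDA %s, %d component(s)\n",
              x$shape, x$hda_side, length(x$components)))
  for (cp in x$components) {
    if (x$shape == "circle") {
      cat(sprintf("  circle centre (%.2f, %.2f), r = %.2f um\n",
                  cp$cx, cp$cy, cp$r))
    } else {
      cat(sprintf("  ellipse centre (%.2f, %.2f), semi-axes %.2f x %.2f um\n",
                  cp$cx, cp$cy, cp$ax, cp$ay))
    }
  }
  invisible(x)
}

# membership of grid points in the union of border components
border_member <- function(border, x, y) {
  inside <- rep(FALSE, length(x))
  for (cp in border$components) {
    if (border$shape == "circle") {
      inside <- inside | ((x - cp$cx)^2 + (y - cp$cy)^2 <= cp$r^2)
    } else {
      inside <- inside |
        (((x - cp$cx) / cp$ax)^2 + ((y - cp$cy) / cp$ay)^2 <= 1)
    }
  }
  inside
}

#' Total density inside an HDA border
#'
#' Sums the density-map values over the grid points that fall in the HDA
#' region: inside the (union of) fitted shape(s) for `hda_side = "inside"`,
#' or inside the micropattern but outside the shapes for `"outside"`.
#' Membership is decided at grid-point centres.
#'
#' @param dmap A [density_map()].
#' @param border A [symmetrize_border()] result.
#' @param pattern The [micropattern()] (used for the `"outside"` side).
#' @return Proportion of total mass in `[0, 1]`.
#' @export
total_density <- function(dmap, border, pattern) {
  stopifnot(inherits(dmap, "density_map"), inherits(border, "fitted_border"))
  gx <- rep(dmap$x, times = length(dmap$y))
  gy <- rep(dmap$y, each = length(dmap$x))
  inside_shape <- border_member(border, gx, gy)
  sel <- if (border$hda_side == "inside") {
    inside_shape
  } else {
    pattern_contains(pattern, gx, gy) & !inside_shape
  }
  sum(dmap$values[matrix(sel, nrow(dmap$values))])
}

# Build one cell type's HDA border from its density map: the marked border
# points (all level-T contour points pooled) are fitted with the shape
# matching the pattern. Topology by pattern/type: disc T- -> central circle
# (HDA inside); disc T+ -> circle through the annular ridge, HDA outside
# (the rim annulus); ellipse T- -> central ellipse (inside); ellipse T+ ->
# mirrored tip pair (inside), contours assigned to a tip by the sign of
# their centroid x. The chosen side is auto-checked: its mean density must
# exceed the threshold, else the side flips with a warning.
build_type_border <- function(dmap, pattern, cell_type) {
  T <- density_threshold(dmap)
  contours <- extract_border_points(dmap, T)
  pooled <- do.call(rbind, contours)
  if (pattern$kind == "disc") {
    if (cell_type == "Tminus") {
      fit <- fit_circle(pooled)
      border <- symmetrize_border(list(fit), "circle", "inside")
    } else {
      # the T+ HDA is the rim annulus; its border circle is the annulus'
      # inner boundary: the contour points lying inside the density ridge
      r_grid <- arrayInd(which.max(dmap$values), dim(dmap$values))
      r_peak <- sqrt(dmap$x[r_grid[1]]^2 + dmap$y[r_grid[2]]^2)
      inner <- pooled[sqrt(pooled$x^2 + pooled$y^2) < r_peak, , drop = FALSE]
      if (nrow(inner) < 6) inner <- pooled
      fit <- fit_circle(inner)
      border <- symmetrize_border(list(fit), "circle", "outside")
    }
  } else {
    if (cell_type == "Tminus") {
      fit <- fit_ellipse_or_circle(pooled)
      border <- symmetrize_border(list(fit), "ellipse", "inside")
    } else {
      cx <- vapply(contours, function(cc) mean(cc$x), numeric(1))
      right <- do.call(rbind, contours[cx >= 0])
      left <- do.call(rbind, contours[cx < 0])
      fits <- if (is.null(right) || nrow(right) < 6) {
        rep(list(fit_ellipse_or_circle(left)), 2)
      } else if (is.null(left) || nrow(left) < 6) {
        rep(list(fit_ellipse_or_circle(right)), 2)
      } else {
        list(fit_ellipse_or_circle(right), fit_ellipse_or_circle(left))
      }
      border <- symmetrize_border(fits, "ellipse", "inside")
    }
  }
  check_hda_side(border, dmap, pattern, T)
}

# fall back to a circle (as a degenerate ellipse) when the direct conic fit
# rejects a nearly circular contour
fit_ellipse_or_circle <- function(contour) {
  tryCatch(fit_ellipse(contour), error = function(e) {
    f <- fit_circle(contour)
    list(cx = f$cx, cy = f$cy, a = f$r, b = f$r, angle = 0)
  })
}

# flip hda_side if the chosen side is less dense on average than the other
# side of the fitted border (guards against a mis-identified topology)
check_hda_side <- function(border, dmap, pattern, T) {
  gx <- rep(dmap$x, times = length(dmap$y))
  gy <- rep(dmap$y, each = length(dmap$x))
  inside_shape <- border_member(border, gx, gy)
  in_pat <- pattern_contains(pattern, gx, gy)
  vals <- dmap$values
  m_in <- mean(vals[matrix(inside_shape & in_pat, nrow(vals))])
  m_out <- mean(vals[matrix(!inside_shape & in_pat, nrow(vals))])
  denser <- if (isTRUE(m_in >= m_out)) "inside" else "outside"
  if (!is.na(denser) && denser != border$hda_side) {
    warning(sprintf("the %s side of the fitted border is the denser one; flipping HDA side from %s",
                    denser, border$hda_side))
    border$hda_side <- denser
  }
  border
}

#' Ground truth: HDA borders and reference total densities
#'
#' Runs the full border pipeline (density map, threshold, contours, fit,
#' symmetrisation) independently for the pooled T+ and T- cell positions of a
#' reference colony set, then integrates each type's density over its own
#' border to obtain the reference total densities.
#'
#' @param cells Data frame with `cell_type` (`"Tplus"`/`"Tminus"`), `x_um`,
#'   `y_um` — pooled reference colonies.
#' @param pattern A [micropattern()].
#' @param min_points Minimum pooled points per type.
#' @return An object of class `ground_truth`: `borders` and `Te` (named
#'   `Tplus`, `Tminus`), plus the per-type density maps' bandwidths.
#' @export
build_ground_truth <- function(cells, pattern, min_points = 10) {
  stopifnot(all(c("cell_type", "x_um", "y_um") %in% names(cells)))
  borders <- list()
  Te <- c(Tplus = NA_real_, Tminus = NA_real_)
  bw <- list()
  for (ct in c("Tplus", "Tminus")) {
    sub <- cells[cells$cell_type == ct, , drop = FALSE]
    if (nrow(sub) < min_points) {
      stop(sprintf("need at least %d pooled %s cells", min_points, ct))
    }
    dmap <- estimate_density(sub, pattern)
    border <- build_type_border(dmap, pattern, ct)
    borders[[ct]] <- border
    Te[ct] <- total_density(dmap, border, pattern)
    bw[[ct]] <- dmap$bandwidth
  }
  structure(list(pattern = pattern, borders = borders, Te = Te,
                 bandwidths = bw),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth on %s pattern\n", x$pattern$kind))
  cat(sprintf("  T+ reference total density: %.4f\n", x$Te["Tplus"]))
  cat(sprintf("  T- reference total density: %.4f\n", x$Te["Tminus"]))
  invisible(x)
}

#' Stem cell aggregate pattern distance (SCAPD)
#'
#' Pools the model colonies per cell type, estimates each type's density map
#' with the same estimator settings and grid as the ground truth, integrates
#' it over the ground-truth HDA borders, and returns the sum of the absolute
#' differences of the per-type total densities:
#' `|Te_T+ - Tm_T+| + |Te_T- - Tm_T-|`. A model identical to the reference
#' scores exactly 0; the maximum is 2.
#'
#' @param gt A [build_ground_truth()] result.
#' @param model_cells Data frame with `cell_type`, `x_um`, `y_um` — pooled
#'   model output (the aggregate of all runs).
#' @return An object of class `scapd_result`: `Tm`, `Te`, `scapd`.
#' @export
scapd <- function(gt, model_cells) {
  stopifnot(inherits(gt, "ground_truth"),
            all(c("cell_type", "x_um", "y_um") %in% names(model_cells)))
  Tm <- c(Tplus = NA_real_, Tminus = NA_real_)
  for (ct in c("Tplus", "Tminus")) {
    sub <- model_cells[model_cells$cell_type == ct, , drop = FALSE]
    if (nrow(sub) < 2) stop(sprintf("no %s cells in the model output", ct))
    # same estimator settings as the reference: the ground truth's per-type
    # bandwidths are reused for the model maps
    dmap <- estimate_density(sub, gt$pattern,
                             bandwidth = gt$bandwidths[[ct]])
    Tm[ct] <- total_density(dmap, gt$borders[[ct]], gt$pattern)
  }
  structure(list(Te = gt$Te, Tm = Tm,
                 scapd = sum(abs(gt$Te - Tm))),
            class = "scapd_result")
}

#' @export
print.scapd_result <- function(x, ...) {
  cat(sprintf("SCAPD = %.4f  (T+ %.4f vs %.4f; T- %.4f vs %.4f)\n",
              x$scapd, x$Te["Tplus"], x$Tm["Tplus"],
              x$Te["Tminus"], x$Tm["Tminus"]))
  invisible(x)
}
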