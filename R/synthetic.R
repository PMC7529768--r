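# Generator of synthetic reference colonies standing in for the imaging
# data: T- cells concentrate at the pattern centre, T+ cells at the disc rim
# or the ellipse tips. These are qualitative stand-ins for undeposited
# empirical data, not reconstructions of it.

#' Spatial law of the synthetic reference colonies
#'
#' Defaults emulate the qualitative pattern reported for 48-h colonies:
#' T- cells follow an isotropic Gaussian at the pattern centre (SD a fraction
#' of the smallest half-dimension); T+ cells follow a rim-weighted radial
#' beta law on the disc, and a mixture of two isotropic Gaussians at the
#' ellipse tips. Colony counts default to the study's 186 disc / 152 ellipse
#' images.
#'
#' @param n_colonies Number of colonies; `NULL` picks 186 (disc) or 152
#'   (ellipse) when the pattern is known.
#' @param cells_per_colony Cells per colony.
#' @param fraction_Tplus Proportion of T+ cells per colony.
#' @param tminus_sd_frac T- Gaussian SD as a fraction of the smallest
#'   half-dimension.
#' @param tplus_beta Shape parameters of the radial beta law for disc T+
#'   cells (relative radius `r / r_max ~ Beta(shape1, shape2)`).
#' @param tip_offset Distance of each tip Gaussian centre from the ellipse
#'   vertex, um (centres at `+/-(semi_major - tip_offset), 0`).
#' @param tip_sd SD of each tip Gaussian, um.
#' @param min_separation Minimum pairwise distance, um.
#' @param margin Containment margin, um (cells are kept this far inside the
#'   border, matching the interior-selection filter).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(n_colonies = NULL,
                         cells_per_colony = 6,
                         fraction_Tplus = 0.5,
                         tminus_sd_frac = 0.35,
                         tplus_beta = c(5, 1.5),
                         tip_offset = 30,
                         tip_sd = 20,
                         min_separation = 2,
                         margin = 2) {
  stopifnot(cells_per_colony >= 1, fraction_Tplus >= 0, fraction_Tplus <= 1,
            tminus_sd_frac > 0, all(tplus_beta > 0), tip_offset > 0,
            tip_sd > 0, min_separation > 0, margin >= 0)
  structure(list(n_colonies = n_colonies,
                 cells_per_colony = cells_per_colony,
                 fraction_Tplus = fraction_Tplus,
                 tminus_sd_frac = tminus_sd_frac,
                 tplus_beta = tplus_beta,
                 tip_offset = tip_offset,
                 tip_sd = tip_sd,
                 min_separation = min_separation,
                 margin = margin),
            class = "pattern_spec")
}

spec_n_colonies <- function(spec, pattern) {
  if (!is.null(spec$n_colonies)) return(spec$n_colonies)
  if (pattern$kind == "disc") 186L else 152L
}

# draw one point from a type's spatial law (not yet separation-checked)
draw_point <- function(pattern, spec, cell_type, uniform = FALSE) {
  repeat {
    if (uniform) {
      hw <- if (pattern$kind == "disc") {
        c(pattern$disc_radius, pattern$disc_radius)
      } else {
        c(pattern$semi_major, pattern$semi_minor)
      }
      p <- stats::runif(2, -hw, hw)
    } else if (cell_type == "Tminus") {
      s <- spec$tminus_sd_frac * pattern_half_min(pattern)
      p <- stats::rnorm(2, 0, s)
    } else if (pattern$kind == "disc") {
      rmax <- pattern$disc_radius - spec$margin
      r <- rmax * stats::rbeta(1, spec$tplus_beta[1], spec$tplus_beta[2])
      th <- stats::runif(1, 0, 2 * pi)
      p <- c(r * cos(th), r * sin(th))
    } else {
      side <- if (stats::runif(1) < 0.5) 1 else -1
      cx <- side * (pattern$semi_major - spec$tip_offset)
      p <- stats::rnorm(2, c(cx, 0), spec$tip_sd)
    }
    if (pattern_contains(pattern, p[1], p[2], margin = spec$margin)) return(p)
  }
}

generate_colonies <- function(pattern, spec, uniform, max_tries = 10000L) {
  n_col <- spec_n_colonies(spec, pattern)
  n <- spec$cells_per_colony
  n_plus <- round(n * spec$fraction_Tplus)
  types <- c(rep("Tplus", n_plus), rep("Tminus", n - n_plus))
  out <- vector("list", n_col)
  for (k in seq_len(n_col)) {
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        if (tries >= max_tries) stop("could not place cells at the required separation")
        tries <- tries + 1L
        p <- draw_point(pattern, spec, types[i], uniform = uniform)
        if (i == 1L) break
        d2 <- (pos[seq_len(i - 1), 1] - p[1])^2 +
              (pos[seq_len(i - 1), 2] - p[2])^2
        if (all(d2 >= spec$min_separation^2)) break
      }
      pos[i, ] <- p
    }
    out[[k]] <- data.frame(colony_id = k, cell_id = seq_len(n),
                           cell_type = types, x_um = pos[, 1],
                           y_um = pos[, 2], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate synthetic reference colonies
#'
#' Draws colonies i.i.d. from the spatial laws of the [pattern_spec()], with
#' rejection sampling for containment (inside the margin-shrunk pattern) and
#' minimum pairwise separation.
#'
#' @param pattern A [micropattern()].
#' @param spec A [pattern_spec()].
#' @param seed Optional integer seed.
#' @return Data frame with `colony_id`, `cell_id`, `cell_type`, `x_um`,
#'   `y_um`.
#' @export
generate_reference <- function(pattern, spec = pattern_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  generate_colonies(pattern, spec, uniform = FALSE)
}

#' Generate uniform control colonies
#'
#' As [generate_reference()], but both cell types are uniform over the
#' margin-shrunk pattern interior — a null reference for metric testing.
#'
#' @inheritParams generate_reference
#' @return Data frame with `colony_id`, `cell_id`, `cell_type`, `x_um`,
#'   `y_um`.
#' @export
generate_null_reference <- function(pattern, spec = pattern_spec(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  generate_colonies(pattern, spec, uniform = TRUE)
}
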