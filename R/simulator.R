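#' Per-cell-type motility parameters
#'
#' Parameters governing one cell type's motility. Defaults follow measured
#' values for brachyury-positive (T+, primed) and brachyury-negative (T-,
#' naive) mouse embryonic stem cells: mean speeds 100 and 40 um/h and
#' directional persistence times 105 and 15 min respectively. T+ cells are
#' pushed away from neighbours, T- cells pulled towards them.
#'
#' @param mean_velocity Mean migration speed, um/h.
#' @param persistence_time Directional persistence time, min; must be a
#'   positive multiple of the 15-min timestep.
#' @param sensing_radius Neighbour-sensing radius R, um: neighbours within R
#'   exert inverse-square forces.
#' @param direction_sd Standard deviation sigma, degrees, of the Gaussian
#'   noise added to the force-derived heading.
#' @param force_sign `"push"` (move away from neighbours) or `"pull"` (move
#'   towards them).
#' @return An object of class `cell_type_params`.
#' @export
cell_type_params <- function(mean_velocity, persistence_time,
                             sensing_radius = 100, direction_sd = 3,
                             force_sign = c("push", "pull")) {
  force_sign <- match.arg(force_sign)
  stopifnot(mean_velocity >= 0, persistence_time > 0,
            sensing_radius > 0, direction_sd >= 0)
  structure(list(mean_velocity = mean_velocity,
                 persistence_time = persistence_time,
                 sensing_radius = sensing_radius,
                 direction_sd = direction_sd,
                 force_sign = force_sign),
            class = "cell_type_params")
}

#' Simulation parameters
#'
#' Global settings of a simulation run: 192 timesteps of 15 min (48 h of
#' culture), a 2 um minimum centre-to-centre cell separation (nuclei projected
#' to 2D), the border-turn angle alpha, and the per-type motility parameters.
#'
#' @param Tplus,Tminus [cell_type_params()] for the two cell types.
#' @param timestep_min Timestep, min.
#' @param n_steps Number of timesteps.
#' @param min_separation Minimum pairwise cell distance, um.
#' @param border_turn_angle Turn angle alpha, degrees, in (0, 180), applied by
#'   the border rule.
#' @param use_velocity_ratio If `TRUE`, speed is additionally scaled by the
#'   velocity ratio |sum F| / sum |F| of the sensed neighbour forces.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(Tplus = cell_type_params(100, 105, force_sign = "push"),
                       Tminus = cell_type_params(40, 15, force_sign = "pull"),
                       timestep_min = 15,
                       n_steps = 192,
                       min_separation = 2,
                       border_turn_angle = 20,
                       use_velocity_ratio = FALSE) {
  stopifnot(inherits(Tplus, "cell_type_params"),
            inherits(Tminus, "cell_type_params"),
            timestep_min > 0, n_steps >= 1, min_separation > 0,
            border_turn_angle > 0, border_turn_angle < 180)
  for (p in list(Tplus, Tminus)) {
    k <- p$persistence_time / timestep_min
    if (abs(k - round(k)) > 1e-9 || k < 1) {
      stop("persistence_time must be a positive multiple of the timestep")
    }
  }
  structure(list(Tplus = Tplus, Tminus = Tminus,
                 timestep_min = timestep_min, n_steps = n_steps,
                 min_separation = min_separation,
                 border_turn_angle = border_turn_angle,
                 use_velocity_ratio = use_velocity_ratio),
            class = "sim_params")
}

# rule flags for models 1..16: every combination of
# i (velocity), ii (persistence), iii (directional), iv (border)
MODEL_RULES <- list(
  `1`  = character(0),
  `2`  = "i",
  `3`  = "ii",
  `4`  = "iii",
  `5`  = "iv",
  `6`  = c("i", "ii"),
  `7`  = c("i", "iii"),
  `8`  = c("i", "iv"),
  `9`  = c("ii", "iii"),
  `10` = c("ii", "iv"),
  `11` = c("iii", "iv"),
  `12` = c("i", "ii", "iii"),
  `13` = c("i", "ii", "iv"),
  `14` = c("i", "iii", "iv"),
  `15` = c("ii", "iii", "iv"),
  `16` = c("i", "ii", "iii", "iv")
)

#' Motility-rule model specification
#'
#' The sixteen candidate models enumerate all combinations of four motility
#' rules: (i) type-specific mean velocity, (ii) type-specific directional
#' persistence time, (iii) direction set by neighbour push/pull forces, and
#' (iv) the border effect (fixed-angle turn when a move would leave the
#' micropattern). Model 1 has no rule (the random model); model 7 is i+iii;
#' model 14 is i+iii+iv; model 16 has all four.
#'
#' @param model_number Integer 1..16.
#' @return An object of class `model_spec` with logical fields
#'   `rule_velocity`, `rule_persistence`, `rule_directional`, `rule_border`.
#' @examples
#' model_spec(7)
#' @export
model_spec <- function(model_number) {
  if (length(model_number) != 1 || !model_number %in% 1:16) {
    stop("model_number must be an integer in 1..16")
  }
  rules <- MODEL_RULES[[as.character(as.integer(model_number))]]
  structure(list(model_number = as.integer(model_number),
                 rule_velocity = "i" %in% rules,
                 rule_persistence = "ii" %in% rules,
                 rule_directional = "iii" %in% rules,
                 rule_border = "iv" %in% rules),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  rules <- c("i", "ii", "iii", "iv")[c(x$rule_velocity, x$rule_persistence,
                                       x$rule_directional, x$rule_border)]
  cat(sprintf("model %d: rules {%s}\n", x$model_number,
              paste(rules, collapse = "+")))
  invisible(x)
}

type_params <- function(params, cell_type) {
  if (cell_type == "Tplus") params$Tplus else params$Tminus
}

persistence_steps <- function(params, cell_type) {
  as.integer(round(type_params(params, cell_type)$persistence_time /
                     params$timestep_min))
}

#' Seed a colony of cells on a micropattern
#'
#' Places `n_cells` cells uniformly at random in the margin-shrunk interior of
#' the pattern, rejection-sampling until all pairwise distances are at least
#' `params$min_separation`. Cell types are assigned so the T+ count is
#' `round(n_cells * fraction_Tplus)`; initial headings are uniform.
#'
#' @param pattern A [micropattern()].
#' @param n_cells Number of cells (>= 1); colonies are seeded with about 6
#'   cells in the experiments this emulates.
#' @param fraction_Tplus Proportion of T+ cells in `[0, 1]`.
#' @param params A [sim_params()].
#' @param max_tries Rejection-sampling attempt bound per cell.
#' @return A `colony` object: list with `pattern`, `cells` (data frame with
#'   columns `id`, `cell_type`, `x_um`, `y_um`, `heading`, `repoll`) and
#'   `timestamp = 0`.
#' @export
init_colony <- function(pattern, n_cells = 6, fraction_Tplus = 0.5,
                        params = sim_params(), max_tries = 10000L) {
  stopifnot(n_cells >= 1, fraction_Tplus >= 0, fraction_Tplus <= 1)
  pos <- sample_positions(pattern, n_cells,
                          margin = pattern$interior_margin,
                          min_sep = params$min_separation,
                          max_tries = max_tries)
  n_plus <- round(n_cells * fraction_Tplus)
  types <- c(rep("Tplus", n_plus), rep("Tminus", n_cells - n_plus))
  cells <- data.frame(
    id = seq_len(n_cells),
    cell_type = types,
    x_um = pos[, 1],
    y_um = pos[, 2],
    heading = stats::runif(n_cells, 0, 360),
    repoll = vapply(types, function(tt) persistence_steps(params, tt),
                    integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(pattern = pattern, cells = cells, timestamp = 0L),
            class = "colony")
}

# uniform positions inside the margin-shrunk pattern with min-separation
# rejection sampling
sample_positions <- function(pattern, n, margin, min_sep, max_tries = 10000L) {
  if (pattern$kind == "disc") {
    hw <- c(pattern$disc_radius, pattern$disc_radius)
  } else {
    hw <- c(pattern$semi_major, pattern$semi_minor)
  }
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    if (tries >= max_tries) {
      stop("could not place cells at the required separation")
    }
    tries <- tries + 1L
    p <- stats::runif(2, -hw, hw)
    if (!pattern_contains(pattern, p[1], p[2], margin = margin)) next
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1] - p[1])^2 +
            (pos[seq_len(placed), 2] - p[2])^2
      if (any(d2 < min_sep^2)) next
    }
    placed <- placed + 1L
    pos[placed, ] <- p
    tries <- 0L
  }
  pos
}

#' Net neighbour force on a cell
#'
#' Each neighbour within the sensing radius R exerts a force of magnitude
#' 1/D^2 (D the centre-to-centre Euclidean distance) directed along the
#' focal-neighbour axis: away from the neighbour for `"push"` (T+ cells),
#' towards it for `"pull"` (T- cells). Returns the vector sum together with
#' the scalar sum of magnitudes used by the velocity ratio.
#'
#' @param x,y Focal cell position, um.
#' @param nx,ny Neighbour positions (vectors), excluding the focal cell.
#' @param R Sensing radius, um.
#' @param sign `"push"` or `"pull"`.
#' @return List with `fx`, `fy` (net force components) and `mag_sum`
#'   (sum of individual force magnitudes within R).
#' @export
compute_force <- function(x, y, nx, ny, R, sign = c("push", "pull")) {
  sign <- match.arg(sign)
  stopifnot(R > 0, length(nx) == length(ny))
  force_sum(x, y, nx, ny, R, if (sign == "push") -1 else 1)
}

# unchecked kernel of compute_force (hot loop); s = -1 push, +1 pull
force_sum <- function(x, y, nx, ny, R, s) {
  if (length(nx) == 0L) {
    return(list(fx = 0, fy = 0, mag_sum = 0))
  }
  dx <- nx - x
  dy <- ny - y
  d2 <- dx * dx + dy * dy
  if (any(d2 == 0)) stop("coincident cells: force undefined at D = 0")
  within <- d2 <= R * R
  if (!any(within)) {
    return(list(fx = 0, fy = 0, mag_sum = 0))
  }
  dx <- dx[within]; dy <- dy[within]; d2 <- d2[within]
  # unit vector along the axis scaled by 1/D^2; push points away from the
  # neighbour, pull towards it
  w <- s / (sqrt(d2) * d2)
  list(fx = sum(w * dx), fy = sum(w * dy), mag_sum = sum(1 / d2))
}

#' Sample a heading from a force vector
#'
#' The migration heading is the angle of the net force perturbed by Gaussian
#' noise with standard deviation `sigma` degrees. A zero net force carries no
#' directional information and yields a uniform random heading.
#'
#' @param fx,fy Net force components.
#' @param sigma Noise standard deviation, degrees (>= 0).
#' @return Heading in degrees in `[0, 360)`.
#' @export
sample_direction <- function(fx, fy, sigma) {
  stopifnot(sigma >= 0)
  if (fx == 0 && fy == 0) {
    return(stats::runif(1, 0, 360))
  }
  base <- atan2(fy, fx) * 180 / pi
  wrap_heading(base + stats::rnorm(1, 0, sigma))
}

#' Velocity ratio from neighbour forces
#'
#' The ratio |sum F| / sum |F| of the vector sum of the sensed forces to the
#' sum of their magnitudes. It is 1 when all forces align (or when there is
#' no neighbour within range, leaving the speed unmodulated) and 0 under
#' perfect cancellation; the actual speed is `mean_velocity * ratio`.
#'
#' @param fx,fy Components of the individual forces (vectors, one entry per
#'   sensed neighbour); may be empty.
#' @return A value in `[0, 1]`.
#' @export
velocity_ratio <- function(fx, fy) {
  stopifnot(length(fx) == length(fy))
  if (length(fx) == 0L) return(1)
  mag_sum <- sum(sqrt(fx^2 + fy^2))
  if (mag_sum == 0) return(1)
  min(1, sqrt(sum(fx)^2 + sum(fy)^2) / mag_sum)
}

# ratio from a compute_force() result
force_ratio <- function(f) {
  if (f$mag_sum == 0) 1 else min(1, sqrt(f$fx^2 + f$fy^2) / f$mag_sum)
}

#' Border turn
#'
#' When a move would leave the micropattern, the border rule rotates the
#' heading by a fixed angle `alpha`, in the rotational sense that moves it
#' away from the escape heading (the direction to the nearest exterior
#' point): clockwise if the escape heading lies counter-clockwise of the
#' current heading, counter-clockwise otherwise (ties break
#' counter-clockwise).
#'
#' @param current Current heading, degrees.
#' @param escape Heading to the nearest exterior point, degrees.
#' @param alpha Turn angle, degrees, in (0, 180).
#' @return New heading in `[0, 360)`.
#' @export
border_turn <- function(current, escape, alpha) {
  stopifnot(alpha > 0, alpha < 180)
  diff <- wrap_heading(escape - current)
  if (diff > 180) diff <- diff - 360  # signed difference in (-180, 180]
  if (diff > 0) wrap_heading(current - alpha) else wrap_heading(current + alpha)
}

# move one cell along its heading in 1-um sub-steps up to `budget` um.
# A sub-step that would leave the pattern triggers the border turn under
# rule iv; without rule iv the cell re-orients uniformly at random (bounded
# retries), the agent-based idiom for hard confinement that leaves an
# unbiased walk uniform over the pattern. Min-separation violations
# truncate the move at the last admissible sub-step.
# Returns c(x, y, heading).
move_cell <- function(pattern, x, y, heading, budget, others_x, others_y,
                      min_sep, rule_border, alpha) {
  max_turns <- ceiling(360 / alpha) + 1L
  min_sep2 <- min_sep^2
  # inlined containment constants (hot loop)
  is_disc <- pattern$kind == "disc"
  if (is_disc) {
    r2 <- pattern$disc_radius^2
    inv_a2 <- inv_b2 <- 1
  } else {
    r2 <- 1
    inv_a2 <- 1 / pattern$semi_major^2
    inv_b2 <- 1 / pattern$semi_minor^2
  }
  inside <- function(px, py) px * px * inv_a2 + py * py * inv_b2 <= r2
  rad <- heading * (pi / 180)
  while (budget > 1e-9) {
    stp <- min(1, budget)
    px <- x + stp * cos(rad)
    py <- y + stp * sin(rad)
    if (!inside(px, py)) {
      ok <- FALSE
      if (rule_border) {
        turned <- 0L
        repeat {
          heading <- border_turn(heading,
                                 nearest_exterior_heading(pattern, x, y),
                                 alpha)
          rad <- heading * (pi / 180)
          turned <- turned + 1L
          px <- x + stp * cos(rad)
          py <- y + stp * sin(rad)
          if (inside(px, py)) { ok <- TRUE; break }
          if (turned >= max_turns) break
        }
      } else {
        for (tries in 1:20) {
          heading <- stats::runif(1, 0, 360)
          rad <- heading * (pi / 180)
          px <- x + stp * cos(rad)
          py <- y + stp * sin(rad)
          if (inside(px, py)) { ok <- TRUE; break }
        }
      }
      if (!ok) return(c(x, y, heading))
    }
    if (length(others_x) &&
        any((others_x - px)^2 + (others_y - py)^2 < min_sep2)) {
      return(c(x, y, heading))  # truncate before the violating sub-step
    }
    x <- px; y <- py
    budget <- budget - stp
  }
  c(x, y, heading)
}

#' Advance a colony by one timestep
#'
#' Updates every cell once, in randomised order, under the model's active
#' rules. Speed is the type's mean velocity under rule i (both types use the
#' T- default otherwise), optionally scaled by the velocity ratio. Direction
#' comes from the neighbour forces under rule iii (re-polled every step, or
#' at persistence expiry when rule ii is also active); without rule iii it is
#' a persistent random walk whose re-poll interval is the type's persistence
#' time under rule ii and one step otherwise. Movement proceeds in 1-um
#' sub-steps with border handling (turn under rule iv, clip otherwise) and
#' min-separation truncation.
#'
#' @param colony A colony from [init_colony()].
#' @param model A [model_spec()].
#' @param params A [sim_params()].
#' @return The advanced colony.
#' @export
step_colony <- function(colony, model, params) {
  cells <- colony$cells
  pattern <- colony$pattern
  n <- nrow(cells)
  order_idx <- if (n > 1) sample.int(n) else 1L
  dt_h <- params$timestep_min / 60
  # plain vectors in the hot loop; written back once at the end
  x <- cells$x_um; y <- cells$y_um
  heading <- cells$heading; repoll <- cells$repoll
  is_plus <- cells$cell_type == "Tplus"
  pstep <- ifelse(is_plus, persistence_steps(params, "Tplus"),
                  persistence_steps(params, "Tminus"))
  for (i in order_idx) {
    tp <- if (is_plus[i]) params$Tplus else params$Tminus
    v <- if (model$rule_velocity) tp$mean_velocity else
      params$Tminus$mean_velocity
    hi <- heading[i]
    ri <- repoll[i] - 1L
    expired <- !model$rule_persistence || ri <= 0L
    ratio <- 1
    if (model$rule_directional) {
      f <- force_sum(x[i], y[i], x[-i], y[-i], tp$sensing_radius,
                     if (tp$force_sign == "push") -1 else 1)
      if (params$use_velocity_ratio) ratio <- force_ratio(f)
      if (expired) {
        hi <- sample_direction(f$fx, f$fy, tp$direction_sd)
        ri <- if (model$rule_persistence) pstep[i] else 1L
      }
    } else {
      if (expired) {
        hi <- stats::runif(1, 0, 360)
        ri <- if (model$rule_persistence) pstep[i] else 1L
      }
    }
    budget <- v * ratio * dt_h
    res <- move_cell(pattern, x[i], y[i], hi, budget, x[-i], y[-i],
                     params$min_separation, model$rule_border,
                     params$border_turn_angle)
    x[i] <- res[1]
    y[i] <- res[2]
    heading[i] <- res[3]
    repoll[i] <- ri
  }
  cells$x_um <- x
  cells$y_um <- y
  cells$heading <- heading
  cells$repoll <- repoll
  colony$cells <- cells
  colony$timestamp <- colony$timestamp + 1L
  colony
}

#' Run a model over independent colonies
#'
#' Seeds `n_colonies` independent colonies and advances each through the full
#' simulation (192 steps of 15 min by default, i.e. 48 h), returning the
#' final snapshots pooled in one data frame. Fully reproducible for a given
#' seed.
#'
#' @param model A [model_spec()].
#' @param params A [sim_params()].
#' @param pattern A [micropattern()].
#' @param n_colonies Number of independent colonies.
#' @param n_cells Cells per colony.
#' @param fraction_Tplus Proportion of T+ cells.
#' @param seed Optional integer seed.
#' @return Data frame with columns `colony_id`, `cell_id`, `cell_type`,
#'   `x_um`, `y_um`.
#' @export
run_model <- function(model, params, pattern, n_colonies = 100,
                      n_cells = 6, fraction_Tplus = 0.5, seed = NULL) {
  stopifnot(n_colonies >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_colonies)
  for (k in seq_len(n_colonies)) {
    col <- init_colony(pattern, n_cells, fraction_Tplus, params)
    for (s in seq_len(params$n_steps)) {
      col <- step_colony(col, model, params)
    }
    out[[k]] <- data.frame(colony_id = k,
                           cell_id = col$cells$id,
                           cell_type = col$cells$cell_type,
                           x_um = col$cells$x_um,
                           y_um = col$cells$y_um,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fraction of cells with a neighbour within a radius
#'
#' The neighbour-distance statistic used to characterise colony crowding:
#' the proportion of cells having at least one other cell of the same colony
#' pool within `radius` um.
#'
#' @param cells Data frame with `x_um`, `y_um`.
#' @param radius Neighbourhood radius, um (> 0).
#' @return Proportion in `[0, 1]`.
#' @export
neighbor_fraction <- function(cells, radius) {
  stopifnot(radius > 0)
  n <- nrow(cells)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(cells[, c("x_um", "y_um")]))
  diag(d) <- Inf
  mean(apply(d, 1, min) <= radius)
}
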