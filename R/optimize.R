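# Exhaustive grid-search calibration of the sensing radius R and direction
# noise sigma (shared across cell types or per type), and the sensitivity
# sweep over the border-turn angle alpha.

with_motility <- function(params, R_plus, sd_plus, R_minus, sd_minus) {
  params$Tplus$sensing_radius <- R_plus
  params$Tplus$direction_sd <- sd_plus
  params$Tminus$sensing_radius <- R_minus
  params$Tminus$direction_sd <- sd_minus
  params
}

scapd_for_params <- function(model, params, gt, n_runs, n_cells,
                             fraction_Tplus, seed) {
  pooled <- run_model(model, params, gt$pattern, n_colonies = n_runs,
                      n_cells = n_cells, fraction_Tplus = fraction_Tplus,
                      seed = seed)
  scapd(gt, pooled)$scapd
}

#' Grid search over sensing radius and direction noise
#'
#' Evaluates every combination of the candidate sensing radii and direction
#' noise levels (shared by both cell types, or independently per type when
#' `per_type = TRUE`, squaring the grid) by simulating `n_runs` colonies,
#' pooling them, and scoring the pool with SCAPD against the ground truth.
#' All combinations are simulated with common random numbers (the same seed)
#' so their comparison is low-variance. Ties on SCAPD break towards smaller
#' R, then smaller sigma.
#'
#' @param model A [model_spec()].
#' @param params Base [sim_params()].
#' @param gt A [build_ground_truth()] result.
#' @param R_grid Candidate sensing radii, um (default the 25/50/75/100
#'   screen).
#' @param sd_grid Candidate direction noise SDs, degrees (default 1/3/5).
#' @param per_type If `TRUE`, R and sigma vary independently for T+ and T-.
#' @param n_runs Colonies per combination.
#' @param n_cells,fraction_Tplus Colony seeding settings.
#' @param seed Integer seed shared by all combinations.
#' @return A `grid_search_result`: `table` (one row per combination with its
#'   SCAPD), `best` (the argmin row), `n_runs`, `seed`.
#' @export
grid_search <- function(model, params, gt,
                        R_grid = c(25, 50, 75, 100),
                        sd_grid = c(1, 3, 5),
                        per_type = FALSE,
                        n_runs = 100, n_cells = 6, fraction_Tplus = 0.5,
                        seed = 1) {
  if (length(R_grid) == 0 || length(sd_grid) == 0) {
    stop("parameter grids must be non-empty")
  }
  stopifnot(n_runs >= 1)
  if (per_type) {
    grid <- expand.grid(R_plus = R_grid, R_minus = R_grid,
                        sd_plus = sd_grid, sd_minus = sd_grid,
                        KEEP.OUT.ATTRS = FALSE)
  } else {
    shared <- expand.grid(R = R_grid, sd = sd_grid, KEEP.OUT.ATTRS = FALSE)
    grid <- data.frame(R_plus = shared$R, R_minus = shared$R,
                       sd_plus = shared$sd, sd_minus = shared$sd)
  }
  grid$scapd <- NA_real_
  for (k in seq_len(nrow(grid))) {
    pk <- with_motility(params, grid$R_plus[k], grid$sd_plus[k],
                        grid$R_minus[k], grid$sd_minus[k])
    grid$scapd[k] <- scapd_for_params(model, pk, gt, n_runs, n_cells,
                                      fraction_Tplus, seed)
  }
  ord <- order(grid$scapd, grid$R_plus, grid$R_minus,
               grid$sd_plus, grid$sd_minus)
  structure(list(table = grid, best = grid[ord[1], , drop = FALSE],
                 per_type = per_type, n_runs = n_runs, seed = seed),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid search: %d combinations, %d runs each (seed %d)\n",
              nrow(x$table), x$n_runs, x$seed))
  cat("best combination:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Sensitivity sweep over the border-turn angle
#'
#' Runs the model at each candidate turn angle alpha with common random
#' numbers and scores each pooled output with SCAPD, quantifying how robust
#' the output is to this parameter.
#'
#' @param model A [model_spec()] (the border rule should be active for alpha
#'   to matter).
#' @param params Base [sim_params()].
#' @param gt A [build_ground_truth()] result.
#' @param alpha_list Turn angles in degrees, each in (0, 180).
#' @param n_runs Colonies per angle.
#' @param n_cells,fraction_Tplus Colony seeding settings.
#' @param seed Integer seed shared across angles.
#' @return Data frame with columns `alpha`, `scapd`.
#' @export
angle_sweep <- function(model, params, gt,
                        alpha_list = c(10, 20, 30, 40),
                        n_runs = 100, n_cells = 6, fraction_Tplus = 0.5,
                        seed = 1) {
  stopifnot(all(alpha_list > 0), all(alpha_list < 180))
  out <- data.frame(alpha = alpha_list, scapd = NA_real_)
  for (k in seq_along(alpha_list)) {
    pk <- params
    pk$border_turn_angle <- alpha_list[k]
    out$scapd[k] <- scapd_for_params(model, pk, gt, n_runs, n_cells,
                                     fraction_Tplus, seed)
  }
  out
}
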