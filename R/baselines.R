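# Baseline pattern-distance metrics used for benchmarking SCAPD: earth
# mover's distance, Kullback-Leibler divergence, and the ensemble CRPS.

check_same_grid <- function(d1, d2) {
  stopifnot(inherits(d1, "density_map"), inherits(d2, "density_map"))
  if (!identical(dim(d1$values), dim(d2$values)) ||
      max(abs(d1$x - d2$x)) > 1e-9 || max(abs(d1$y - d2$y)) > 1e-9) {
    stop("density maps must share the same grid")
  }
}

#' Mass-conserving down-sampling of a density map
#'
#' Aggregates the grid into `out_n` x `out_n` blocks by summation (mass is
#' conserved exactly); the coordinate of each block is the mean of its
#' members' coordinates. The grid size must be a multiple of `out_n`.
#'
#' @param dmap A [density_map()].
#' @param out_n Target grid size per axis.
#' @return A [density_map()] on the coarser grid.
#' @export
downsample_density <- function(dmap, out_n) {
  nx <- nrow(dmap$values); ny <- ncol(dmap$values)
  if (nx %% out_n != 0 || ny %% out_n != 0) {
    stop("grid size must be a multiple of the target size")
  }
  fx <- nx / out_n; fy <- ny / out_n
  gi <- rep(seq_len(out_n), each = fx)
  gj <- rep(seq_len(out_n), each = fy)
  vals <- rowsum(t(rowsum(dmap$values, gi)), gj)
  # rowsum twice: first over rows (x), then over columns (via transpose)
  vals <- t(vals)
  x <- as.vector(tapply(dmap$x, gi, mean))
  y <- as.vector(tapply(dmap$y, gj, mean))
  density_map(vals, x, y)
}

#' Earth mover's distance between density maps
#'
#' Exact optimal-transport cost between the two discrete distributions, with
#' Euclidean ground distance (um) between grid-point centres, solved by a
#' network-simplex transportation solver. Maps larger than
#' `resolution` x `resolution` are first down-sampled by mass-conserving
#' block sums for tractability.
#'
#' @param d1,d2 [density_map()]s on the same grid.
#' @param resolution Maximum per-axis grid size passed to the solver.
#' @return Non-negative transport cost in um.
#' @export
emd <- function(d1, d2, resolution = 64) {
  check_same_grid(d1, d2)
  if (nrow(d1$values) > resolution || ncol(d1$values) > resolution) {
    d1 <- downsample_density(d1, resolution)
    d2 <- downsample_density(d2, resolution)
  }
  nx <- length(d1$x); ny <- length(d1$y)
  gx <- rep(d1$x, times = ny)
  gy <- rep(d1$y, each = nx)
  p <- as.vector(d1$values)
  q <- as.vector(d2$values)
  # drop empty bins on both sides to shrink the problem
  keep_p <- p > 0
  keep_q <- q > 0
  cost <- sqrt(outer(gx[keep_p], gx[keep_q], "-")^2 +
                 outer(gy[keep_p], gy[keep_q], "-")^2)
  res <- .emd_network_simplex(p[keep_p], q[keep_q], cost)
  res$cost
}

#' Kullback-Leibler divergence between density maps
#'
#' `sum p log(p / q)` in nats, after additive smoothing with `eps` on both
#' maps (kernel maps can contain exact zeros) and renormalisation.
#'
#' @param p,q [density_map()]s on the same grid.
#' @param eps Additive smoothing constant.
#' @return Non-negative divergence.
#' @export
kl_divergence <- function(p, q, eps = 1e-12) {
  check_same_grid(p, q)
  pv <- as.vector(p$values) + eps
  qv <- as.vector(q$values) + eps
  pv <- pv / sum(pv)
  qv <- qv / sum(qv)
  sum(pv * log(pv / qv))
}

#' Ensemble CRPS between per-run density maps and a reference
#'
#' For each grid point, the continuous ranked probability score of the
#' ensemble of per-run density values against the reference density value,
#' using the standard ensemble estimator
#' `mean |x_i - y| - mean |x_i - x_j| / 2`; the result is the mean over grid
#' points.
#'
#' @param ensemble List of [density_map()]s (>= 2), one per run.
#' @param reference A [density_map()] on the same grid.
#' @return Non-negative mean CRPS.
#' @export
crps_ensemble <- function(ensemble, reference) {
  if (length(ensemble) < 2) stop("need an ensemble of at least 2 maps")
  for (e in ensemble) check_same_grid(e, reference)
  M <- length(ensemble)
  X <- vapply(ensemble, function(e) as.vector(e$values),
              numeric(length(reference$values)))      # G x M
  y <- as.vector(reference$values)
  term1 <- rowMeans(abs(X - y))
  # E|Xi - Xj| via the sorted representation: for sorted x(1)..x(M),
  # sum_{i<j} (x(j)-x(i)) = sum_i (2i - M - 1) x(i)
  Xs <- t(apply(X, 1, sort))
  w <- 2 * seq_len(M) - M - 1
  gini <- (Xs %*% w) * (2 / M^2)
  mean(term1 - 0.5 * gini)
}
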