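#' @useDynLib scapd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- diffusion (Botev) bandwidth selection, 1D ----------------------------

# DCT-II of an even-length vector (Botev's dct1d)
dct1d <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  w <- c(1, 2 * exp(-1i * (1:(n - 1)) * pi / (2 * n)))
  reordered <- c(x[seq(1, n - 1, by = 2)], x[seq(n, 2, by = -2)])
  Re(w * stats::fft(reordered))
}

# Fixed-point map for the improved Sheather-Jones / diffusion plug-in.
# t is squared bandwidth on the unit interval; I are squared frequencies,
# a2 the squared (halved) DCT coefficients, N the effective sample size.
isj_fixed_point <- function(t, N, I, a2) {
  l <- 7
  f <- 2 * pi^(2 * l) * sum(I^l * a2 * exp(-I * pi^2 * t))
  if (f <= 0) return(Inf)
  for (s in (l - 1):2) {
    K0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
    const <- (1 + (1 / 2)^(s + 1 / 2)) / 3
    time <- (2 * const * K0 / (N * f))^(2 / (3 + 2 * s))
    f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * time))
    if (f <= 0) return(Inf)
  }
  (2 * N * sqrt(pi) * f)^(-2 / 5)
}

#' Diffusion (Botev) bandwidth for one axis
#'
#' The improved Sheather-Jones plug-in bandwidth computed by the discrete
#' cosine transform fixed-point iteration. Falls back to Silverman's rule of
#' thumb (with a warning) when the fixed point cannot be bracketed, e.g. for
#' very small or pathological samples.
#'
#' @param x Numeric data (one coordinate axis).
#' @param n_grid Power-of-two histogram size used internally.
#' @return Bandwidth (standard deviation of the Gaussian kernel) in data
#'   units.
#' @export
botev_bandwidth <- function(x, n_grid = 2^14) {
  x <- x[is.finite(x)]
  N <- length(unique(x))
  if (N < 2) stop("need at least 2 distinct points for bandwidth selection")
  rng <- range(x)
  R <- rng[2] - rng[1]
  lo <- rng[1] - R / 2
  hi <- rng[2] + R / 2
  R2 <- hi - lo
  breaks <- seq(lo, hi, length.out = n_grid + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = n_grid)
  initial <- counts / sum(counts)
  a <- dct1d(initial)
  I <- (1:(n_grid - 1))^2
  a2 <- (a[-1] / 2)^2
  g <- function(t) isj_fixed_point(t, N, I, a2) - t
  # bracket the root of the fixed-point equation on a log grid
  ts <- 10^seq(-10, 0, length.out = 60)
  gs <- vapply(ts, g, numeric(1))
  ok <- is.finite(gs)
  bracket <- NULL
  idx <- which(ok)
  if (length(idx) >= 2) {
    sgn <- sign(gs[idx])
    flip <- which(diff(sgn) != 0)
    if (length(flip) > 0) {
      i1 <- idx[flip[1]]; i2 <- idx[flip[1] + 1]
      bracket <- c(ts[i1], ts[i2])
    }
  }
  if (is.null(bracket)) {
    warning("diffusion bandwidth fixed point not bracketed; using Silverman's rule")
    return(silverman_bandwidth(x))
  }
  t_star <- stats::uniroot(g, interval = bracket, tol = 1e-14)$root
  sqrt(t_star) * R2
}

silverman_bandwidth <- function(x) {
  n <- length(x)
  s <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (s == 0) s <- stats::sd(x)
  0.9 * s * n^(-1 / 5)
}

# ---- density maps ----------------------------------------------------------

# fixed evaluation extent per micropattern: bounding box inflated by 10%
# on each side, shared by ground-truth and model maps
pattern_extent <- function(pattern) {
  if (pattern$kind == "disc") {
    hx <- hy <- 1.1 * pattern$disc_radius
  } else {
    hx <- 1.1 * pattern$semi_major
    hy <- 1.1 * pattern$semi_minor
  }
  list(x = c(-hx, hx), y = c(-hy, hy))
}

#' Construct a density map
#'
#' A normalised density surface on a rectangular grid: `values[i, j]` is the
#' mass at grid point `(x[i], y[j])`, and the values sum to one.
#'
#' @param values Numeric matrix of non-negative grid values.
#' @param x,y Grid coordinates (um) for the rows and columns of `values`.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, x, y) {
  stopifnot(is.matrix(values), nrow(values) == length(x),
            ncol(values) == length(y), all(values >= 0))
  total <- sum(values)
  if (total <= 0) stop("density map has no mass")
  structure(list(values = values / total, x = x, y = y),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density map: %d x %d grid, x in [%.1f, %.1f] um, y in [%.1f, %.1f] um\n",
              nrow(x$values), ncol(x$values),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Kernel density map of cell positions
#'
#' Gaussian-kernel density estimate of pooled cell positions on the
#' micropattern's fixed 256 x 256 evaluation grid (the pattern's bounding box
#' inflated by 10% per side, shared by all maps for a given pattern so their
#' grid sums are comparable). The bandwidth is selected per axis by the
#' diffusion (Botev) plug-in; grid values are renormalised to sum to one.
#'
#' @param cells Data frame with `x_um`, `y_um` columns (or a 2-column
#'   matrix).
#' @param pattern A [micropattern()] fixing the grid extent.
#' @param n_grid Grid size per axis.
#' @param bandwidth Optional length-2 numeric `(hx, hy)` overriding the
#'   selected bandwidths.
#' @return A [density_map()].
#' @export
estimate_density <- function(cells, pattern, n_grid = 256, bandwidth = NULL) {
  if (is.matrix(cells)) {
    cells <- data.frame(x_um = cells[, 1], y_um = cells[, 2])
  }
  px <- cells$x_um
  py <- cells$y_um
  stopifnot(length(px) == length(py))
  if (length(px) < 2 || (length(unique(px)) < 2 && length(unique(py)) < 2)) {
    stop("need at least 2 distinct points for a density estimate")
  }
  ext <- pattern_extent(pattern)
  gx <- seq(ext$x[1], ext$x[2], length.out = n_grid)
  gy <- seq(ext$y[1], ext$y[2], length.out = n_grid)
  if (is.null(bandwidth)) {
    hx <- tryCatch(botev_bandwidth(px), error = function(e) silverman_bandwidth(px))
    hy <- tryCatch(botev_bandwidth(py), error = function(e) silverman_bandwidth(py))
  } else {
    hx <- bandwidth[1]; hy <- bandwidth[2]
  }
  # product Gaussian kernel, evaluated as an outer product over points
  Kx <- outer(gx, px, function(g, p) stats::dnorm(g, p, hx))
  Ky <- outer(gy, py, function(g, p) stats::dnorm(g, p, hy))
  vals <- Kx %*% t(Ky)
  out <- density_map(vals, gx, gy)
  out$bandwidth <- c(hx, hy)
  out
}

#' Mid-range density threshold
#'
#' The threshold separating high-density areas from the rest of the map: the
#' mean of the maximum and minimum grid values.
#'
#' @param dmap A [density_map()].
#' @return `(max(g) + min(g)) / 2`.
#' @export
density_threshold <- function(dmap) {
  stopifnot(inherits(dmap, "density_map"))
  (max(dmap$values) + min(dmap$values)) / 2
}
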