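# shared fixtures built in code

disc_pattern <- function() micropattern("disc")
ellipse_pattern <- function() micropattern("ellipse")

# small synthetic reference: enough pooled cells for stable ground truths
# without the full 186/152-colony defaults
small_reference <- function(kind, n_colonies = 60, seed = 11) {
  generate_reference(micropattern(kind),
                     pattern_spec(n_colonies = n_colonies), seed = seed)
}

# a density map built directly from a matrix on a unit-spaced grid
toy_map <- function(values, spacing = 1) {
  n <- nrow(values); m <- ncol(values)
  density_map(values, x = (seq_len(n) - 1) * spacing,
              y = (seq_len(m) - 1) * spacing)
}

# independent per-pair force summation used as the oracle for compute_force
brute_force_sum <- function(x, y, nx, ny, R, sign) {
  fx <- 0; fy <- 0
  s <- if (sign == "push") -1 else 1
  for (k in seq_along(nx)) {
    d <- sqrt((nx[k] - x)^2 + (ny[k] - y)^2)
    if (d <= R) {
      ux <- (nx[k] - x) / d
      uy <- (ny[k] - y) / d
      fx <- fx + s * ux / d^2
      fy <- fy + s * uy / d^2
    }
  }
  c(fx, fy)
}

# points on a circle / axis-aligned ellipse
circle_points <- function(cx, cy, r, n = 12) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_points <- function(cx, cy, a, b, angle = 0, n = 20) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  phi <- angle * pi / 180
  x0 <- a * cos(th); y0 <- b * sin(th)
  data.frame(x = cx + x0 * cos(phi) - y0 * sin(phi),
             y = cy + x0 * sin(phi) + y0 * cos(phi))
}
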