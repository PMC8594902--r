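# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the package's own code paths.

# closed-form eigenvalues of the 2x2 symmetric covariance of a point set
oracle_cov_eigen <- function(v) {
  v <- as.matrix(v)
  d <- sweep(v, 2L, colMeans(v))
  sxx <- mean(d[, 1L]^2); syy <- mean(d[, 2L]^2); sxy <- mean(d[, 1L] * d[, 2L])
  tr <- sxx + syy; det <- sxx * syy - sxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  c(tr / 2 + disc, tr / 2 - disc)
}

# shoelace area, written independently
oracle_area <- function(v) {
  n <- nrow(v); j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

# connected components of points at a distance cutoff (union-find)
oracle_components <- function(pts, cutoff) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(stats::dist(pts))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && d[i, j] <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  length(unique(roots))
}

# random star-shaped (hence simple) polygon: jittered even angles keep every
# angular gap below pi, which guarantees simplicity
random_simple_polygon <- function(n = 12L, rmin = 1, rmax = 4) {
  th <- (seq_len(n) - 1L) / n * 2 * pi + stats::runif(n, 0, 0.8 * 2 * pi / n)
  r <- stats::runif(n, rmin, rmax)
  cbind(r * cos(th), r * sin(th))
}

# analytic covariance eigenvalue ratio of an ellipse contour is (a/b)^2
ellipse_contour <- function(a, b, n = 96L, phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)] + phase
  mp_contour(cbind(a * cos(th), b * sin(th)), validate = FALSE)
}

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)

make_disc_ing <- function(px = 20L, nmpp = 0.2, name = "disc") {
  mp_ingredient_from_image(
    mesopaint:::fixture_sprite_image("disc", px = px),
    nmpp, "soluble", name = name)
}

make_bar_fiber_ing <- function(spacing = 10, n_springs = 3L, name = "fib",
                               aspect = 6, px = 24L, nmpp = 0.5) {
  mp_ingredient_from_image(
    mesopaint:::fixture_sprite_image("bar", px = px, aspect = aspect),
    nmpp, "fiber", fiber = mp_fiber_spec(spacing, n_springs = n_springs),
    name = name)
}

demo_scene <- function(seed = 1L, width = 300, height = 300) {
  rec <- mp_fixture_recipe()
  sc <- mp_scene(width, height, seed = seed)
  for (ing in rec$ingredients) mp_add_ingredient(sc, ing)
  sc
}
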