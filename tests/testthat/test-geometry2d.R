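test_that("contour extraction traces masks at the right scale", {
  # filled 11 x 11 disc at 1 nm/px: roughly circular, max radius about 5 nm
  m <- outer(-5:5, -5:5, function(i, j) sqrt(i^2 + j^2) <= 5)
  ct <- mp_extract_contour(m, 1)
  r <- sqrt(rowSums(ct$vertices^2))
  expect_true(ct$closed)
  expect_lt(abs(max(r) - 5), 0.8)
  expect_lt(stats::sd(r), 0.5)

  # 2 x 20 opaque bar: rectangular, aspect about 10:1
  bar <- mp_extract_contour(matrix(TRUE, 2L, 20L), 1)
  ext <- apply(bar$vertices, 2L, function(z) diff(range(z)))
  expect_equal(unname(ext[1L] / ext[2L]), 10, tolerance = 0.05)

  # random blobs: polygon area matches opaque pixel count x scale^2 (10%)
  for (seed in 1:5) {
    ctf <- mp_fixture_contour("blob", a = 10, b = 3, seed = seed)
    grid <- expand.grid(x = seq(-16, 16, by = 1), y = seq(-16, 16, by = 1))
    inside <- vapply(seq_len(nrow(grid)), function(k)
      mesopaint:::point_in_polygon(c(grid$x[k], grid$y[k]), ctf$vertices), TRUE)
    mask <- matrix(inside, nrow = 33L, byrow = TRUE)
    ct2 <- mp_extract_contour(mask, 2)     # 2 nm/px
    expect_equal(abs(mp_polygon_area(ct2)), sum(mask) * 4, tolerance = 0.1)
  }

  expect_error(mp_extract_contour(matrix(FALSE, 3L, 3L), 1), "no opaque")
  expect_error(mp_extract_contour(matrix(TRUE, 3L, 3L), 0), "invalid argument")
})

test_that("eigen frames match the closed-form covariance oracle", {
  # isotropy: unit circle
  circ <- ellipse_contour(1, 1, 64L)
  fr <- mp_eigen_frame(circ)
  expect_lt(fr$values[1L] - fr$values[2L], 1e-6)

  # axis-aligned 4:1 ellipse
  el <- ellipse_contour(4, 1)
  fr <- mp_eigen_frame(el)
  expect_equal(fr$axes[, 1L], c(1, 0), tolerance = 1e-9)
  expect_equal(fr$values[1L] / fr$values[2L], 16, tolerance = 0.01)

  # rotated square and random polygons: frozen against the hand oracle
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)) %*% t(rot2(pi / 6))
  fr <- mp_eigen_frame(mp_contour(sq))
  expect_equal(sort(fr$values), sort(oracle_cov_eigen(sq)), tolerance = 1e-12)

  set.seed(11)
  for (k in 1:50) {
    v <- random_simple_polygon(n = sample(5:20, 1L))
    fr <- mp_eigen_frame(mp_contour(v, validate = FALSE))
    expect_equal(fr$values, oracle_cov_eigen(v), tolerance = 1e-9)
    expect_equal(sum(fr$axes[, 1L] * fr$axes[, 2L]), 0, tolerance = 1e-12)
    expect_gte(fr$axes[1L, 1L], -1e-12)   # sign convention
  }
})

test_that("eigen_frame is rotation-equivariant", {
  set.seed(7)
  v <- random_simple_polygon(14L)
  fr0 <- mp_eigen_frame(mp_contour(v, validate = FALSE))
  for (th in c(0.3, 1.1, 2.8)) {
    fr <- mp_eigen_frame(mp_contour(v %*% t(rot2(th)), validate = FALSE))
    expect_equal(fr$values, fr0$values, tolerance = 1e-9)
    want <- rot2(th) %*% fr0$axes[, 1L]
    got <- fr$axes[, 1L]
    expect_lt(min(sum((got - want)^2), sum((got + want)^2)), 1e-18)
  }
})

test_that("collider selection flips at the threshold and is scale-equivariant", {
  circ <- ellipse_contour(1, 1)
  expect_identical(mp_select_collider(mp_eigen_frame(circ), circ)$variant,
                   "circle")
  el <- ellipse_contour(4, 1)
  expect_identical(mp_select_collider(mp_eigen_frame(el), el)$variant, "rect")

  # sweep eigenvalue ratios through the threshold; oracle = direct comparison
  for (ratio in c(1.0, 1.05, 1.1, 1.149, 1.151, 1.3, 2.0)) {
    ct <- ellipse_contour(sqrt(ratio), 1)
    fr <- mp_eigen_frame(ct)
    col <- mp_select_collider(fr, ct)
    want <- if (fr$values[1L] / fr$values[2L] < 1.15) "circle" else "rect"
    expect_identical(col$variant, want)
  }

  # scale equivariance: decision unchanged, dimensions scale linearly
  ct <- ellipse_contour(2, 1)
  for (s in c(0.1, 1, 25)) {
    cs <- mp_contour(ct$vertices * s, validate = FALSE)
    c1 <- mp_select_collider(mp_eigen_frame(ct), ct)
    c2 <- mp_select_collider(mp_eigen_frame(cs), cs)
    expect_identical(c1$variant, c2$variant)
    expect_equal(c2$width, c1$width * s, tolerance = 1e-9)
    expect_equal(c2$height, c1$height * s, tolerance = 1e-9)
  }

  # circle radius is the max projected extent on the major axis
  # (96-gon discretization: a vertex need not sit exactly on the axis)
  cc <- mp_select_collider(mp_eigen_frame(circ), circ)
  expect_equal(cc$radius, 1, tolerance = 1e-3)
})

test_that("Graham hull is convex, minimal, and contains its input", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(2, 2))
  h <- mp_graham_hull(sq)
  expect_equal(nrow(h$vertices), 4L)       # interior point excluded

  set.seed(23)
  for (k in 1:20) {
    pts <- matrix(stats::rnorm(2L * sample(10:100, 1L)), ncol = 2L)
    h <- mp_graham_hull(pts)
    expect_true(all(mp_in_convex(pts, h, tol = 1e-7)))
    # minimal vertex count agrees with the base-R hull oracle
    expect_equal(nrow(h$vertices), length(grDevices::chull(pts)))
    # idempotence
    h2 <- mp_graham_hull(h$vertices)
    expect_equal(nrow(h2$vertices), nrow(h$vertices))
    # counter-clockwise
    expect_gt(mp_polygon_area(h$vertices), 0)
  }
  expect_error(mp_graham_hull(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(mp_graham_hull(cbind(1:5, 1:5)), "degenerate")
})

test_that("mean shift matches the connected-components oracle", {
  expect_length(mp_mean_shift(matrix(c(1, 2), 1L)), 1L)

  set.seed(5)
  two_far <- rbind(matrix(stats::rnorm(24, 0, 0.5), ncol = 2L),
                   matrix(stats::rnorm(24, 30, 0.5), ncol = 2L))
  expect_length(mp_mean_shift(two_far, 8), 2L)
  two_near <- rbind(matrix(stats::rnorm(24, 0, 0.4), ncol = 2L),
                    cbind(stats::rnorm(12, 4, 0.4), stats::rnorm(12, 0, 0.4)))
  expect_length(mp_mean_shift(two_near, 8), 1L)

  # every point in exactly one cluster; limits of the bandwidth
  pts <- matrix(stats::runif(60, 0, 50), ncol = 2L)
  cl <- mp_mean_shift(pts, 8)
  expect_setequal(unlist(cl), seq_len(nrow(pts)))
  expect_length(mp_mean_shift(pts, 1e6), 1L)
  expect_length(mp_mean_shift(pts, 1e-4), nrow(pts))
})

test_that("ear clipping triangulates simple polygons and conserves area", {
  quad <- rbind(c(0, 0), c(3, 0), c(3, 2), c(0, 2))
  expect_length(mp_triangulate(quad), 2L)

  L <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  tris <- mp_triangulate(L)
  expect_length(tris, 4L)
  expect_equal(sum(vapply(tris, mesopaint:::triangle_area, 0)), 3,
               tolerance = 1e-12)

  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_length(mp_triangulate(tri), 1L)

  set.seed(31)
  for (k in 1:100) {
    v <- random_simple_polygon(n = sample(4:25, 1L))
    tris <- mp_triangulate(v)
    expect_length(tris, nrow(v) - 2L)
    expect_equal(sum(vapply(tris, mesopaint:::triangle_area, 0)),
                 oracle_area(v), tolerance = 1e-6)
  }
})

test_that("orientation follows the shoelace sign", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(mp_orientation(mp_contour(sq)), "counter-clockwise")
  expect_identical(mp_orientation(mp_contour(sq[4:1, ])), "clockwise")
  set.seed(2)
  for (k in 1:25) {
    v <- random_simple_polygon()
    want <- if (sum(v[, 1L] * v[c(2:nrow(v), 1L), 2L] -
                    v[c(2:nrow(v), 1L), 1L] * v[, 2L]) > 0)
      "counter-clockwise" else "clockwise"
    expect_identical(mp_orientation(mp_contour(v, validate = FALSE)), want)
  }
  expect_error(mp_orientation(mp_contour(cbind(c(0, 1, 2), c(0, 0, 0)),
                                         validate = FALSE)),
               "degenerate")
})

test_that("contour validation rejects bad input", {
  expect_error(mp_contour(rbind(c(0, 0), c(1, 1))), "at least 3")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(mp_contour(bowtie), "self-intersecting")
  expect_warning(mp_eigen_frame(mp_contour(cbind(0:4, 0), closed = FALSE)),
                 "degenerate")
})
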