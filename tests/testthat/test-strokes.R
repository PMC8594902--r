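test_that("arc-length resampling gives predictable subunit counts", {
  straight <- cbind(seq(0, 100, length.out = 173L), 0)
  s <- mp_resample_path(straight, 10)
  expect_identical(nrow(s), 11L)
  expect_equal(diff(s[, 1L]), rep(10, 10L), tolerance = 1e-9)

  # rigid-motion invariance: transforming the path transforms the chain
  th <- 0.7; shift <- c(12, -30)
  moved <- straight %*% t(rot2(th)) + rep(shift, each = nrow(straight))
  s2 <- mp_resample_path(moved, 10)
  expect_equal(s2, s %*% t(rot2(th)) + rep(shift, each = nrow(s)),
               tolerance = 1e-9)
})

test_that("fibers are articulated chains with the stated constraint topology", {
  sc <- demo_scene()
  f <- mp_draw_fiber(sc, "dsdna", cbind(seq(50, 150, length.out = 200), 150),
                     layer = 0L)
  expect_length(f$body_ids, 11L)
  expect_identical(f$n_hinges, 10L)
  expect_false(f$closed)

  w <- sc$world
  # hinge anchors coincide at rest: consecutive end circles overlap
  h <- w$hinges
  expect_identical(nrow(h), 10L)
  expect_equal(h[1L, 3:4], c(5, 0))
  expect_equal(h[1L, 5:6], c(-5, 0))

  # DNA preset: 10 persistence springs per originating subunit, rest
  # lengths proportional to spacing x span
  sc2 <- demo_scene()
  f2 <- mp_draw_fiber(sc2, "dsdna", cbind(seq(10, 290, length.out = 400), 40),
                      layer = 0L)
  n <- length(f2$body_ids)
  expect_identical(n, 29L)
  sp <- sc2$world$springs
  for (i in f2$body_ids[seq_len(n - 11L)]) {
    mine <- sp[sp[, 1L] == i, , drop = FALSE]
    expect_identical(nrow(mine), 10L)
    ks <- (mine[, 3L]) / 10          # rest = spacing x k
    expect_setequal(ks, 2:11)
  }
})

test_that("closed fiber strokes become rings", {
  sc <- demo_scene()
  r <- 20 * 10 / (2 * pi)            # circumference = 20 subunits x 10 nm
  ring <- mp_draw_fiber(sc, "dsdna",
                        mp_fixture_stroke("circle", radius = r,
                                          center = c(150, 150)),
                        layer = 0L)
  expect_true(ring$closed)
  expect_length(ring$body_ids, 20L)
  expect_identical(ring$n_hinges, 20L)   # hinge count = subunit count
})

test_that("fiber layer policies follow the painting rules", {
  sc <- demo_scene()
  fixed <- mp_draw_fiber(sc, "dsdna",
                         cbind(seq(10, 290, length.out = 300), 60), layer = 2L)
  expect_true(all(fixed$layers == 2L))

  sc2 <- demo_scene(seed = 21L)
  long <- mp_draw_fiber(sc2, "dsdna",
                        cbind(seq(5, 295, length.out = 500) * 2, 500) / 2,
                        layer = "auto")
  expect_identical(long$layers[1L], 0L)  # starts in the foreground
  jumps <- which(diff(long$layers) != 0L)
  expect_true(length(jumps) >= 1L)       # long fibers jump periodically
  expect_true(all(diff(jumps) %% 15L == 0L))

  # identical seed, identical jump pattern
  sc3 <- demo_scene(seed = 21L)
  long2 <- mp_draw_fiber(sc3, "dsdna",
                         cbind(seq(5, 295, length.out = 500) * 2, 500) / 2,
                         layer = "auto")
  expect_identical(long$layers, long2$layers)
})

test_that("fiber strokes crossing a membrane are rejected atomically", {
  sc <- demo_scene()
  mp_draw_membrane(sc, "bilayer",
                   mp_fixture_stroke("circle", radius = 50,
                                     center = c(150, 150), clockwise = TRUE))
  n_before <- sum(sc$world$alive[seq_len(sc$world$n)])
  expect_error(
    mp_draw_fiber(sc, "dsdna", cbind(seq(50, 250, length.out = 300), 150),
                  layer = 0L),
    "crosses a membrane")
  expect_identical(sum(sc$world$alive[seq_len(sc$world$n)]), n_before)
})

test_that("membrane closure follows the segment-length rule", {
  sc <- demo_scene()
  r <- 40 * 10 / (2 * pi)
  closed <- mp_draw_membrane(sc, "bilayer",
                             mp_fixture_stroke("circle", radius = r,
                                               center = c(150, 150),
                                               clockwise = TRUE))
  expect_true(closed$closed)
  expect_length(closed$body_ids, 40L)
  expect_false(closed$reversed)
  expect_equal(closed$area, pi * r^2, tolerance = 0.05)
  expect_identical(mp_orientation(mp_vesicle_polygon(sc, closed$chain_id)$polygon),
                   "clockwise")
  # membrane preset: 3 springs per subunit
  spr <- sc$world$springs
  expect_identical(nrow(spr), 40L * 3L)

  # counter-clockwise stroke is stored clockwise, flagged
  sc2 <- demo_scene()
  ccw <- mp_draw_membrane(sc2, "bilayer",
                          mp_fixture_stroke("circle", radius = r,
                                            center = c(150, 150),
                                            clockwise = FALSE))
  expect_true(ccw$reversed)
  expect_identical(mp_orientation(mp_vesicle_polygon(sc2, ccw$chain_id)$polygon),
                   "clockwise")

  # open arc: two end pins, no fill
  sc3 <- demo_scene()
  open <- mp_draw_membrane(sc3, "bilayer",
                           mp_fixture_stroke("arc", radius = 60,
                                             center = c(150, 100)))
  expect_false(open$closed)
  expect_length(open$end_pins, 2L)
  expect_true(all(sc3$world$pinned[open$end_pins]))
  expect_length(sc3$fills, 0L)

  # self-intersecting closed stroke rejected
  sc4 <- demo_scene()
  t <- seq(0, 2 * pi, length.out = 200L)
  fig8 <- cbind(150 + 60 * sin(2 * t), 150 + 40 * sin(t))
  expect_error(mp_draw_membrane(sc4, "bilayer", fig8), "self-intersecting")
})

test_that("membrane proteins ride the rail with correct sidedness", {
  sc <- demo_scene()
  r <- 40 * 10 / (2 * pi)
  memb <- mp_draw_membrane(sc, "bilayer",
                           mp_fixture_stroke("circle", radius = r,
                                             center = c(150, 150),
                                             clockwise = TRUE))
  id <- suppressWarnings(mp_paint(sc, "gatekeeper", c(150, 150), layer = 1L,
                                  settle = FALSE))
  # soluble ingredients cannot ride a rail
  sid <- mp_paint(sc, "blobulin", c(20, 20), settle = FALSE)
  expect_error(mp_attach_to_membrane(sc, sid, memb$chain_id, 0), "kind error")

  # find the arc position of 12 o'clock: the chain starts at angle 0 on the
  # stroke circle, so walk until the topmost point
  w <- sc$world
  mb <- memb$body_ids
  top <- mb[which.max(w$y[mb])]
  arc <- (which(mb == top) - 1L) * 10
  mp_attach_to_membrane(sc, id, memb$chain_id, arc)
  # protein sits outside the vesicle center by about the surface offset
  d_center <- sqrt((w$x[id] - 150)^2 + (w$y[id] - 150)^2)
  expect_equal(d_center, r + 0, tolerance = 1.5)
  # oriented outward: sprite +Y (exterior side) points away from the center
  outward <- c(w$x[id] - 150, w$y[id] - 150) / d_center
  ydir <- c(-sin(w$angle[id]), cos(w$angle[id]))
  expect_gt(sum(outward * ydir), 0.95)

  # rail projection survives simulation: protein stays on the membrane
  mp_diffuse(w, 100L)
  d2 <- sqrt((w$x[id] - 150)^2 + (w$y[id] - 150)^2)
  expect_equal(d2, d_center, tolerance = 2)

  # placement beyond an open membrane end is a detached error
  sc2 <- demo_scene()
  arc_open <- mp_draw_membrane(sc2, "bilayer",
                               mp_fixture_stroke("arc", radius = 60,
                                                 center = c(150, 100)))
  pid <- suppressWarnings(mp_paint(sc2, "gatekeeper", c(150, 150), layer = 1L,
                                   settle = FALSE))
  expect_error(mp_attach_to_membrane(sc2, pid, arc_open$chain_id, 1e4),
               "detached")
})

test_that("closed vesicles conserve area during settling", {
  sc <- demo_scene(seed = 13L)
  r <- 40 * 10 / (2 * pi)
  memb <- mp_draw_membrane(sc, "bilayer",
                           mp_fixture_stroke("circle", radius = r,
                                             center = c(150, 150),
                                             clockwise = TRUE))
  a0 <- mp_vesicle_polygon(sc, memb$chain_id)$area
  mp_settle(sc$world, 250L)
  a1 <- mp_vesicle_polygon(sc, memb$chain_id)$area
  expect_equal(a1, a0, tolerance = 0.05)
})

test_that("stiffness presets order chain flexibility (pilot)", {
  # 3-seed pilot of the acceptance property: full 20-seed run lives in
  # test-acceptance.R
  e2e <- function(nspr, seed) {
    ing <- make_bar_fiber_ing(spacing = 10, n_springs = nspr, name = "f")
    sc <- mp_scene(2000, 2000, seed = seed)
    mp_add_ingredient(sc, ing)
    ch <- mp_draw_fiber(sc, "f",
                        cbind(seq(500, 500 + 59 * 10, length.out = 240), 1000),
                        layer = 0L)
    mp_diffuse(sc$world, 400L)
    w <- sc$world; b <- ch$body_ids
    sqrt((w$x[b[1L]] - w$x[b[60L]])^2 + (w$y[b[1L]] - w$y[b[60L]])^2)
  }
  dna <- mean(vapply(1:3, function(s) e2e(10L, s), 0))
  rna <- mean(vapply(1:3, function(s) e2e(0L, s), 0))
  expect_gt(dna, rna)
})
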