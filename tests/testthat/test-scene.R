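test_that("painting places, settles locally, and tracks copy numbers", {
  sc <- demo_scene()
  expect_error(mp_paint(sc, "nonesuch", c(10, 10)), "unknown ingredient")
  expect_error(mp_paint(sc, "blobulin", c(-5, 10)), "outside the canvas")
  expect_identical(mp_copy_number(sc, "blobulin"), 0L)

  id1 <- mp_paint(sc, "blobulin", c(100, 100))
  w <- sc$world
  expect_equal(c(w$x[id1], w$y[id1]), c(100, 100))   # empty canvas: exact

  # painting onto an occupied spot: new body takes the push-out, old body
  # nearly unmoved (pairwise push-out oracle: separation >= 2 radii)
  id2 <- mp_paint(sc, "blobulin", c(100, 100))
  r <- mesopaint:::collider_radius(sc$palette$blobulin$main_collider)
  expect_lt(sqrt(sum((c(w$x[id1], w$y[id1]) - c(100, 100))^2)), 0.1)
  expect_lt(mp_pair_overlap(w, id1, id2), 0.05)
  expect_identical(mp_copy_number(sc, "blobulin"), 2L)

  # membrane-bound paint with no membrane: free body plus warning
  expect_warning(mp_paint(sc, "gatekeeper", c(50, 50)), "without a membrane")
})

test_that("erase removes instances, constraints, and splits chains", {
  sc <- demo_scene()
  for (i in 1:5) mp_paint(sc, "blobulin", c(30 * i, 30), settle = FALSE)
  expect_identical(mp_erase(sc, 1L), 1L)
  expect_identical(mp_copy_number(sc, "blobulin"), 4L)
  expect_identical(mp_erase(sc, "blobulin"), 4L)
  expect_identical(mp_copy_number(sc, "blobulin"), 0L)
  expect_error(mp_erase(sc, "nonesuch"), "unknown ingredient")

  # erasing a middle subunit splits the fiber into two valid chains;
  # oracle: connected components of the hinge graph
  f <- mp_draw_fiber(sc, "dsdna", cbind(seq(30, 270, length.out = 300), 200),
                     layer = 0L)
  w <- sc$world
  mid <- f$body_ids[13L]
  mp_erase(sc, mid)
  h <- w$hinges
  expect_false(any(h[, 1L] == mid | h[, 2L] == mid))
  # hinge-graph components
  ids <- f$body_ids[f$body_ids != mid]
  comp <- stats::setNames(seq_along(ids), ids)
  for (k in seq_len(nrow(h))) {
    a <- as.character(h[k, 1L]); b <- as.character(h[k, 2L])
    comp[comp == comp[b]] <- comp[a]
  }
  expect_identical(length(unique(comp)), 2L)
  # springs never bridge the two pieces
  sp <- w$springs
  expect_true(all(w$chain[sp[, 1L]] == w$chain[sp[, 2L]]))
  # both pieces are registered chains with sequential subindices
  pieces <- unique(w$chain[ids])
  expect_length(pieces, 2L)
  for (ci in pieces) {
    ch <- w$chains[[ci]]
    expect_identical(w$subidx[ch$bodies], seq_along(ch$bodies))
  }
})

test_that("pins freeze bodies; pin-to holds distances isotropically", {
  sc <- demo_scene(seed = 6L)
  a <- mp_paint(sc, "blobulin", c(100, 100), settle = FALSE)
  b <- mp_paint(sc, "blobulin", c(120, 100), settle = FALSE)
  w <- sc$world
  mp_pin(sc, a)
  mp_diffuse(w, 1000L)
  expect_identical(c(w$x[a], w$y[a]), c(100, 100))   # bitwise stationary
  mp_unpin(sc, a)
  mp_diffuse(w, 50L)
  expect_false(identical(c(w$x[a], w$y[a]), c(100, 100)))

  # pin-to: drag apart, settle restores the anchor distance within 1%
  sc2 <- demo_scene()
  a <- mp_paint(sc2, "blobulin", c(100, 100), settle = FALSE)
  b <- mp_paint(sc2, "blobulin", c(115, 100), settle = FALSE)
  w2 <- sc2$world
  expect_error(mp_pin_to(sc2, a, c(0, 0), a, c(1, 0)), "itself")
  d0 <- 15
  mp_pin_to(sc2, a, c(0, 0), b, c(0, 0))
  w2$x[b] <- 160                      # drag apart
  mp_settle(w2, 300L)
  expect_equal(w2$x[b] - w2$x[a], d0, tolerance = 0.15)

  # a chain of pin-tos is satisfied simultaneously (residual oracle)
  sc3 <- demo_scene()
  ids <- vapply(1:3, function(i)
    mp_paint(sc3, "blobulin", c(40 * i, 60), settle = FALSE), 0L)
  mp_pin_to(sc3, ids[1L], c(0, 0), ids[2L], c(0, 0))
  mp_pin_to(sc3, ids[2L], c(0, 0), ids[3L], c(0, 0))
  mp_pin_to(sc3, ids[1L], c(0, 0), ids[3L], c(0, 0))
  w3 <- sc3$world
  w3$x[ids] <- w3$x[ids] + c(-20, 5, 20)   # perturb
  mp_settle(w3, 400L)
  p <- w3$pintos
  for (k in seq_len(nrow(p))) {
    d <- sqrt((w3$x[p[k, 1L]] - w3$x[p[k, 4L]])^2 +
              (w3$y[p[k, 1L]] - w3$y[p[k, 4L]])^2)
    expect_equal(d, p[k, 7L], tolerance = 0.02 * p[k, 7L])
  }
})

test_that("groups stamp rigid copies that stay individually dynamic", {
  sc <- demo_scene(seed = 8L)
  a <- mp_paint(sc, "blobulin", c(60, 60), settle = FALSE)
  b <- mp_paint(sc, "blobulin", c(70, 60), settle = FALSE)
  mp_pin_to(sc, a, c(0, 0), b, c(0, 0))
  expect_error(mp_group(sc, integer(0)), "empty")
  g <- mp_group(sc, c(a, b))

  ids <- mp_stamp(sc, g, c(200, 200), settle = FALSE)
  w <- sc$world
  expect_length(ids, 2L)
  expect_equal(sqrt((w$x[ids[1L]] - w$x[ids[2L]])^2 +
                    (w$y[ids[1L]] - w$y[ids[2L]])^2), 10, tolerance = 1e-9)
  # internal pin-to copied
  expect_identical(nrow(w$pintos), 2L)

  ids90 <- mp_stamp(sc, g, c(100, 230), angle = pi / 2, settle = FALSE)
  dv <- c(w$x[ids90[2L]] - w$x[ids90[1L]], w$y[ids90[2L]] - w$y[ids90[1L]])
  expect_equal(dv, c(0, 10), tolerance = 1e-9)     # rotated exactly

  # stamped members keep their physics: they diffuse individually
  before <- c(w$x[ids], w$y[ids])
  mp_diffuse(w, 50L)
  expect_false(identical(before, c(w$x[ids], w$y[ids])))
})

test_that("locking clusters members and excludes outsiders by hulls", {
  sc <- demo_scene(seed = 10L)
  tight <- vapply(1:3, function(i)
    mp_paint(sc, "blobulin", c(96 + 4 * i, 100), settle = FALSE), 0L)
  lr <- mp_lock(sc, tight)
  expect_length(sc$lock_regions[[lr]]$hull_bodies, 1L)  # 3 bodies within 8 nm
  expect_message(mp_lock(sc, tight), "already locked")
  mp_unlock(sc, lr)

  # two clumps 40 nm apart: two hulls (oracle: connected components at 8 nm)
  far <- vapply(1:3, function(i)
    mp_paint(sc, "blobulin", c(196 + 4 * i, 100), settle = FALSE), 0L)
  expect_identical(oracle_components(cbind(sc$world$x[c(tight, far)],
                                           sc$world$y[c(tight, far)]), 8), 2L)
  lr2 <- mp_lock(sc, c(tight, far))
  expect_length(sc$lock_regions[[lr2]]$hull_bodies, 2L)

  # members are frozen and internally collision-free
  w <- sc$world
  expect_true(all(w$locked[c(tight, far)]))
  expect_false(mp_collidable(w, tight[1L], tight[2L]))

  # a soluble body painted into the hull settles outside it
  hull <- w$fixtures[[sc$lock_regions[[lr2]]$hull_bodies[1L]]][[1L]]$verts
  center <- colMeans(hull)
  id <- mp_paint(sc, "blobulin", pmin(pmax(center, 5), 295))
  r <- mesopaint:::collider_radius(sc$palette$blobulin$main_collider)
  expect_false(all(mp_in_convex(matrix(c(w$x[id], w$y[id]), 1L), hull,
                                tol = -0.5)))

  # unlock -> settle leaves a clean, overlap-free neighbourhood
  mp_unlock(sc, lr2)
  expect_true(all(!w$locked[c(tight, far)]))
  mp_settle(w, 300L)
  ids <- mesopaint:::world_alive_ids(w)
  for (i in seq_along(ids)) for (j in seq_len(i - 1L))
    expect_lt(mp_pair_overlap(w, ids[i], ids[j]), 0.05)
})

test_that("measurements are live and translation-invariant", {
  sc <- demo_scene()
  a <- mp_paint(sc, "blobulin", c(10, 10), settle = FALSE)
  b <- mp_paint(sc, "blobulin", c(13, 14), settle = FALSE)
  expect_equal(mp_measure(sc, a, b), 5)
  expect_equal(mp_measure(sc, a, a), 0)
  expect_error(mp_measure(sc, a, 999L), "unknown instance")

  mp_settle(sc$world, 10L)
  m <- mp_measurements(sc)
  w <- sc$world
  expect_equal(m$distance[1L],
               sqrt((w$x[a] - w$x[b])^2 + (w$y[a] - w$y[b])^2))
  # global translation leaves measurements unchanged
  d0 <- mp_measurements(sc)$distance
  ids <- mesopaint:::world_alive_ids(w)
  w$x[ids] <- w$x[ids] + 31.4; w$y[ids] <- w$y[ids] - 2.7
  expect_equal(mp_measurements(sc)$distance, d0, tolerance = 1e-12)
})

test_that("nudge translates selections rigidly and re-anchors pins", {
  sc <- demo_scene(seed = 14L)
  ids <- vapply(1:3, function(i)
    mp_paint(sc, "blobulin", c(60 + 6 * i, 60), settle = FALSE), 0L)
  lr <- mp_lock(sc, ids)
  w <- sc$world
  x0 <- w$x[ids]
  hull0 <- w$fixtures[[sc$lock_regions[[lr]]$hull_bodies[1L]]][[1L]]$verts
  hb <- sc$lock_regions[[lr]]$hull_bodies[1L]
  mp_nudge(sc, c(5, 0), lock_region = lr)
  expect_equal(w$x[ids], x0 + 5, tolerance = 1e-9)
  expect_equal(w$x[hb], 5)                       # hull moved with the region

  # nudging into another body pushes it out
  target <- mp_paint(sc, "blobulin", c(150, 150), settle = FALSE)
  free <- mp_paint(sc, "blobulin", c(141, 150), settle = FALSE)
  mp_nudge(sc, c(6, 0), instances = free)
  expect_lt(mp_pair_overlap(w, free, target), 0.05)
  expect_equal(w$x[free], 147, tolerance = 1e-6) # nudged body holds its pose

  # pinned bodies move with an explicit nudge (pin re-anchored)
  p <- mp_paint(sc, "blobulin", c(30, 200), settle = FALSE)
  mp_pin(sc, p)
  mp_nudge(sc, c(0, 7), instances = p)
  expect_equal(w$y[p], 207)
  mp_diffuse(w, 100L)
  expect_equal(w$y[p], 207)                      # still pinned, at the new spot
})

test_that("copy numbers track every mutating operation", {
  sc <- demo_scene(seed = 2L)
  for (i in 1:7) mp_paint(sc, "blobulin", c(30 * i, 140), settle = FALSE)
  mp_erase(sc, 1L); mp_erase(sc, 2L)
  expect_identical(mp_copy_number(sc, "blobulin"), 5L)

  f <- mp_draw_fiber(sc, "dsdna", cbind(seq(30, 270, length.out = 300), 250),
                     layer = 0L)
  expect_identical(mp_copy_number(sc, "dsdna"), length(f$body_ids))
  g <- mp_group(sc, c(3L, 4L))
  mp_stamp(sc, g, c(150, 60), settle = FALSE)
  expect_identical(mp_copy_number(sc, "blobulin"), 7L)
})

test_that("backgrounds validate and register in z order", {
  sc <- demo_scene()
  img <- array(stats::runif(12 * 12 * 3), c(12L, 12L, 3L))
  expect_error(mp_set_background(sc, img, 0), "bad scale")
  b1 <- mp_set_background(sc, img, 0.36)
  b2 <- mp_set_background(sc, img, 1, opacity = 0.5, z = -1)
  expect_identical(c(b1, b2), c(1L, 2L))
  expect_equal(sc$backgrounds[[b1]]$nm_per_pixel, 0.36)
})
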