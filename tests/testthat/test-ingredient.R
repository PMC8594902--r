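test_that("longest axis matches the SVD oracle and the sign convention", {
  rod <- mp_structure(cbind(3 * (0:9), 0, 0))
  ax <- mp_longest_axis(rod)
  expect_equal(abs(as.numeric(ax)), c(1, 0, 0), tolerance = 1e-9)
  expect_gte(ax[1L], 0)

  helix <- mp_fixture_structure("helix", n = 40L)
  ax <- mp_longest_axis(helix)
  # oracle: dominant right singular vector of the centered coordinates
  sv <- svd(scale(helix$positions, scale = FALSE))$v[, 1L]
  ang <- acos(min(1, abs(sum(ax * sv)))) * 180 / pi
  expect_lt(ang, 5)
  expect_lt(acos(min(1, abs(ax[3L]))) * 180 / pi, 5)  # helix axis is Z

  shell <- mp_fixture_structure("globule", n = 200L, radius = 10, seed = 2L)
  ax <- mp_longest_axis(shell)
  expect_equal(sqrt(sum(ax^2)), 1, tolerance = 1e-9)

  expect_error(mp_longest_axis(mp_structure(matrix(0, 1L, 3L))), "no axis")
})

test_that("sprite rendering aligns the longest axis with image Y", {
  # single atom: one outlined disc, contour is approximately a circle
  one <- mp_structure(matrix(0, 1L, 3L), elements = "C")
  sp <- mp_render_sprite(one, 0.05)
  r <- sqrt(rowSums(sp$contour$vertices^2))
  expect_lt(stats::sd(r) / mean(r), 0.1)
  expect_equal(mean(r), 0.17 * 1.3, tolerance = 0.15)  # vdW 1.7 A x coarsening

  # two atoms 3 nm apart along the longest axis: opaque-pixel height known
  # (the contour itself keeps only the largest blob; measure the alpha plane)
  two <- mp_structure(rbind(c(0, 0, 0), c(0, 0, 30)), elements = c("C", "C"))
  sp <- mp_render_sprite(two, 0.05)
  rows <- which(apply(sp$image[, , 4L], 1L, max) > 0)
  expect_equal(diff(range(rows)) * 0.05, 3 + 2 * 0.17 * 1.3, tolerance = 0.15)

  # elongated structures render with the major axis vertical
  for (kind in c("helix", "rod")) {
    st <- mp_fixture_structure(kind, n = 30L)
    sp <- mp_render_sprite(st, 0.05)
    fr <- mp_eigen_frame(sp$contour)
    if (fr$values[1L] / fr$values[2L] > 2) {
      ang <- atan2(fr$axes[2L, 1L], fr$axes[1L, 1L]) * 180 / pi
      expect_lt(min(abs(ang - 90), abs(ang + 90)), 5)
    }
    # projected longest extent tracks the 3D extent (viewpoint captures size)
    d3 <- max(stats::dist(st$positions)) / 10
    d2 <- max(stats::dist(sp$contour$vertices))
    expect_equal(d2, d3, tolerance = 0.12)
  }

  expect_error(mp_render_sprite(one, 50), "resolution")
})

test_that("contour partition obeys the membrane inequalities", {
  ct <- mp_fixture_contour("dumbbell", a = 6, b = 2)
  bind <- mp_binding(thickness = 4, surface_offset = 0, padding = 0.5)
  part <- mp_partition_contour(ct, bind)
  # symmetric dumbbell, zero offset: equal exterior and interior sets
  expect_equal(length(part$exterior), length(part$interior))
  expect_equal(sort(c(part$exterior, part$intramembrane, part$interior)),
               seq_len(nrow(ct$vertices)))

  # brute-force per-vertex oracle at a nonzero offset
  bind2 <- mp_binding(thickness = 4, surface_offset = 1.5, padding = 0.5)
  part2 <- mp_partition_contour(ct, bind2)
  y <- ct$vertices[, 2L]
  expect_identical(part2$exterior, which(y > -1.5 + 2 + 0.5))
  expect_identical(part2$interior, which(y < -1.5 - 2 - 0.5))

  # membrane far above the contour: everything is interior
  bind3 <- mp_binding(thickness = 4, surface_offset = -100)
  part3 <- mp_partition_contour(ct, bind3)
  expect_length(part3$exterior, 0L)
  expect_length(part3$interior, nrow(ct$vertices))

  # all intramembrane: warning, not an error
  bind4 <- mp_binding(thickness = 1000, surface_offset = 0)
  expect_warning(mp_partition_contour(ct, bind4), "no anchor")
})

test_that("membrane-bound ingredients carry the full dual collider set", {
  img <- mesopaint:::fixture_sprite_image("dumbbell", px = 48L)
  ing <- mp_ingredient_from_image(img, 0.25, "membrane_bound",
                                  binding = mp_binding(4, 0, 0.5), name = "gk")
  mc <- ing$membrane_colliders
  n_col <- 1L + sum(!vapply(mc[c("exterior_box", "interior_box")], is.null, TRUE)) +
    length(mc$wheels)
  expect_identical(n_col, 7L)                      # 1 main + 2 boxes + 4 wheels
  expect_identical(ing$main_collider$collision_class, "protein")
  expect_true(all(vapply(mc$wheels, `[[`, "", "collision_class") == "membrane"))

  # wheels straddle the membrane line symmetrically at zero offset
  wy <- vapply(mc$wheels, function(wl) wl$center[2L], 0)
  expect_equal(sort(unique(round(wy, 9))), c(-2.5, 2.5))
  wr <- vapply(mc$wheels, `[[`, 0, "radius")
  expect_true(all(wr == 2))                        # thickness / 2

  # contour entirely on the exterior side: interior box skipped
  ing2 <- mp_ingredient_from_image(img, 0.25, "membrane_bound",
                                   binding = mp_binding(4, -100, 0.5),
                                   name = "gk2")
  expect_null(ing2$membrane_colliders$exterior_box)
  expect_false(is.null(ing2$membrane_colliders$interior_box))
})

test_that("fiber subunits get a rect main collider and spaced end circles", {
  # 22 x 2 opaque px at 0.5 nm/px: an 11 x 1 nm bar, spacing 10
  ing <- make_bar_fiber_ing(spacing = 10, n_springs = 10L)
  expect_identical(ing$main_collider$variant, "rect")
  expect_equal(ing$main_collider$width, 11, tolerance = 0.3)
  expect_equal(ing$main_collider$height, 1, tolerance = 0.3)
  ec <- ing$end_circles
  expect_equal(vapply(ec, function(e) e$center[1L], 0), c(-5, 5))
  expect_equal(ec[[1L]]$radius, ing$main_collider$height / 2)
  expect_identical(ing$fiber$n_springs, 10L)      # DNA preset records 10

  # square sprite still yields a rect (fiber is always rect)
  sq <- mp_ingredient_from_image(mesopaint:::fixture_sprite_image("disc"),
                                 0.25, "fiber",
                                 fiber = mp_fiber_preset("rna", spacing = 4),
                                 name = "sq")
  expect_identical(sq$main_collider$variant, "rect")
  expect_identical(sq$fiber$n_springs, 0L)

  expect_warning(make_bar_fiber_ing(spacing = 100), "gappy")
})

test_that("fiber presets carry the published spring counts", {
  expect_identical(mp_fiber_preset("dna")$n_springs, 10L)
  expect_identical(mp_fiber_preset("rna")$n_springs, 0L)
  expect_identical(mp_fiber_preset("membrane")$n_springs, 3L)
  expect_identical(mp_fiber_preset("user")$n_springs, 3L)
})

test_that("soluble colliders approximate the contour", {
  disc <- make_disc_ing()
  expect_identical(disc$main_collider$variant, "circle")
  bar <- mp_ingredient_from_image(
    mesopaint:::fixture_sprite_image("bar", px = 30L, aspect = 5),
    0.2, "soluble", name = "bar")
  expect_identical(bar$main_collider$variant, "rect")

  # collider area within [50%, 200%] of contour area on random blobs
  for (seed in 1:30) {
    img <- mesopaint:::fixture_sprite_image("blob", px = 30L, seed = seed)
    ing <- mp_ingredient_from_image(img, 0.3, "soluble", name = "b")
    ratio <- mesopaint:::collider_area(ing$main_collider) /
      abs(mp_polygon_area(ing$sprite$contour))
    expect_gte(ratio, 0.5)
    expect_lte(ratio, 2.0)
  }
})

test_that("image ingestion validates transparency and is deterministic", {
  opaque <- array(1, c(10L, 10L, 3L))
  expect_error(mp_ingredient_from_image(opaque, 1, "soluble"), "format error")
  all_opaque <- array(1, c(10L, 10L, 4L))
  expect_error(mp_ingredient_from_image(all_opaque, 1, "soluble"), "format error")

  img <- mesopaint:::fixture_sprite_image("blob", px = 30L, seed = 4L)
  a <- mp_ingredient_from_image(img, 0.3, "soluble", name = "x")
  b <- mp_ingredient_from_image(img, 0.3, "soluble", name = "x")
  expect_identical(a$main_collider, b$main_collider)   # bit-for-bit
})

test_that("ingredient colliders stay near the sprite contour", {
  img <- mesopaint:::fixture_sprite_image("dumbbell", px = 48L)
  ing <- mp_ingredient_from_image(img, 0.25, "membrane_bound",
                                  binding = mp_binding(4, 0, 0.5), name = "gk")
  bb <- apply(ing$sprite$contour$vertices, 2L, range)
  pad <- ing$binding$padding + ing$binding$thickness   # padding + 2 wheel radii
  centers <- rbind(ing$main_collider$center,
                   t(vapply(ing$membrane_colliders$wheels,
                            function(wl) wl$center, c(0, 0))))
  expect_true(all(centers[, 1L] >= bb[1L, 1L] - pad - 2 &
                  centers[, 1L] <= bb[2L, 1L] + pad + 2))
  expect_true(all(centers[, 2L] >= bb[1L, 2L] - pad &
                  centers[, 2L] <= bb[2L, 2L] + pad))
})
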