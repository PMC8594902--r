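# Synthetic fixture generators: contours with known eigen-structure,
# pseudo-atom structures with known longest axes, stroke paths with known
# arc length, a miniature recipe, and a small demo scene. Everything is
# deterministic under a seed and generated in code (no stored data).

#' Synthetic contour fixtures
#'
#' `"ellipse"` is an axis-aligned ellipse with semi-axes `a >= b` (covariance
#' eigenvalue ratio (a/b)^2); `"dumbbell"` has two lobes along Y separated by
#' a neck at y = 0 (the membrane-protein test shape); `"blob"` is a random
#' smooth radial polygon (low-order Fourier jitter, always simple).
#'
#' @param kind `"ellipse"`, `"dumbbell"`, or `"blob"`.
#' @param a,b semi-axes in nm (ellipse: major/minor; dumbbell: lobe radius /
#'   half-separation; blob: mean radius / jitter amplitude).
#' @param n vertex count.
#' @param seed RNG seed (blob only).
#' @return an [mp_contour], centered.
#' @export
mp_fixture_contour <- function(kind = c("ellipse", "dumbbell", "blob"),
                               a = 4, b = 1, n = 64L, seed = 1L) {
  kind <- match.arg(kind)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  v <- switch(kind,
    ellipse = cbind(a * cos(th), b * sin(th)),
    dumbbell = {
      r <- a * (0.55 + 0.45 * sin(th)^2)
      cbind(r * cos(th), r * sin(th) * (1 + b / a))
    },
    blob = {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      amp <- stats::runif(4L, 0, b / a)
      ph <- stats::runif(4L, 0, 2 * pi)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      r <- a * (1 + rowSums(sapply(1:4, function(k)
        amp[k] * cos(k * th + ph[k]) / k)))
      cbind(r * cos(th), r * sin(th))
    })
  v <- sweep(v, 2L, colMeans(v))
  mp_contour(v, closed = TRUE, validate = FALSE)
}

#' Synthetic pseudo-atom structures
#'
#' `"helix"`: ideal alpha-helix CA trace along Z (2.3 A radius, 1.5 A rise,
#' 100 degrees per residue); `"rod"`: atoms along X at 3 A spacing;
#' `"globule"`: uniform random points in a sphere.
#'
#' @param kind `"helix"`, `"rod"`, or `"globule"`.
#' @param n atom count.
#' @param radius sphere radius in Angstrom (globule).
#' @param seed RNG seed (globule).
#' @return an [mp_structure].
#' @export
mp_fixture_structure <- function(kind = c("helix", "rod", "globule"),
                                 n = 30L, radius = 15, seed = 1L) {
  kind <- match.arg(kind)
  pos <- switch(kind,
    helix = {
      i <- seq_len(n) - 1L
      cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
            1.5 * i)
    },
    rod = cbind(3 * (seq_len(n) - 1L), 0, 0),
    globule = {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      m <- matrix(stats::rnorm(3L * n * 3L), ncol = 3L)
      m <- m[rowSums(m^2) > 1e-9, , drop = FALSE]
      u <- stats::runif(nrow(m))^(1 / 3)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      (m / sqrt(rowSums(m^2)) * u * radius)[seq_len(n), , drop = FALSE]
    })
  mp_structure(pos, elements = rep("C", nrow(pos)))
}

#' Synthetic stroke paths
#'
#' `"circle"`: a full circle of given radius (closed when painted);
#' `"arc"`: a half circle; `"s_curve"`: one sine period. Arc lengths are
#' analytic, so subunit counts after resampling are predictable.
#'
#' @param kind `"circle"`, `"arc"`, or `"s_curve"`.
#' @param radius circle/arc radius, nm.
#' @param length s-curve extent, nm.
#' @param center path center, nm.
#' @param n point count along the path.
#' @param clockwise draw direction (circle/arc).
#' @return n x 2 matrix of path points.
#' @export
mp_fixture_stroke <- function(kind = c("circle", "arc", "s_curve"),
                              radius = 50, length = 100, center = c(0, 0),
                              n = 400L, clockwise = FALSE) {
  kind <- match.arg(kind)
  pts <- switch(kind,
    circle = {
      th <- seq(0, 2 * pi, length.out = n)
      if (clockwise) th <- rev(th)
      cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
    },
    arc = {
      th <- seq(0, pi, length.out = n)
      if (clockwise) th <- rev(th)
      cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
    },
    s_curve = {
      x <- seq(0, length, length.out = n)
      cbind(center[1L] + x - length / 2,
            center[2L] + 0.15 * length * sin(2 * pi * x / length))
    })
  pts
}

# a filled-disc / bar / blob RGBA sprite image, for image-route ingredients
fixture_sprite_image <- function(kind = c("disc", "bar", "blob", "dumbbell"),
                                 px = 40L, aspect = 5, seed = 1L,
                                 color = c(0.62, 0.66, 0.74)) {
  kind <- match.arg(kind)
  if (kind == "bar") {
    h <- max(4L, round(px / aspect)); wd <- px
    img <- array(0, c(h, wd, 4L))
    img[2:(h - 1L), 2:(wd - 1L), 4L] <- 1
  } else {
    img <- array(0, c(px, px, 4L))
    cx <- (px + 1) / 2
    d <- sqrt(outer((seq_len(px) - cx)^2, (seq_len(px) - cx)^2, "+"))
    r0 <- px / 2 - 1.5
    mask <- switch(kind,
      disc = d <= r0,
      blob = {
        ct <- mp_fixture_contour("blob", a = r0, b = r0 * 0.3, seed = seed)
        m <- matrix(FALSE, px, px)
        for (i in seq_len(px)) for (j in seq_len(px))
          m[i, j] <- point_in_polygon(c(j - cx, cx - i), ct$vertices)
        m
      },
      dumbbell = {
        ct <- mp_fixture_contour("dumbbell", a = r0 * 0.6, b = r0 * 0.25)
        m <- matrix(FALSE, px, px)
        for (i in seq_len(px)) for (j in seq_len(px))
          m[i, j] <- point_in_polygon(c(j - cx, cx - i), ct$vertices)
        m
      })
    img[, , 4L][mask] <- 1
  }
  for (ch in 1:3) img[, , ch][img[, , 4L] > 0] <- color[ch]
  img
}

#' Miniature demo recipe
#'
#' Three compartments echoing a typical default palette: a soluble blob
#' protein ("blobulin", cytoplasm), a membrane-bound dumbbell ("gatekeeper",
#' membrane, 4 nm membrane), and a stiff DNA-like fiber subunit ("dsdna",
#' nucleoid, DNA preset: 10 persistence springs), plus a membrane segment
#' ingredient ("bilayer") used by the membrane-drawing tool.
#'
#' @param dir directory to write `recipe.json` and sprites into; when NULL
#'   the recipe object is returned without touching disk.
#' @param seed seed for the blob outline.
#' @return an `mp_recipe` (with `$path` attribute when written).
#' @export
mp_fixture_recipe <- function(dir = NULL, seed = 1L) {
  blob <- mp_ingredient_from_image(
    fixture_sprite_image("blob", px = 36L, seed = seed, color = c(0.95, 0.65, 0.2)),
    nm_per_pixel = 0.25, kind = "soluble", name = "blobulin",
    color = c(0.95, 0.65, 0.2), compartment = "cytoplasm")
  gate <- mp_ingredient_from_image(
    fixture_sprite_image("dumbbell", px = 48L, color = c(0.3, 0.75, 0.45)),
    nm_per_pixel = 0.25, kind = "membrane_bound",
    binding = mp_binding(thickness = 4, surface_offset = 0, padding = 0.5),
    name = "gatekeeper", color = c(0.3, 0.75, 0.45), compartment = "membrane")
  dna <- mp_ingredient_from_image(
    fixture_sprite_image("bar", px = 24L, aspect = 6, color = c(0.7, 0.4, 0.85)),
    nm_per_pixel = 0.5, kind = "fiber",
    fiber = mp_fiber_preset("dna", spacing = 10),
    name = "dsdna", color = c(0.7, 0.4, 0.85), compartment = "nucleoid")
  bilayer <- mp_ingredient_from_image(
    fixture_sprite_image("bar", px = 24L, aspect = 3, color = c(0.55, 0.8, 0.5)),
    nm_per_pixel = 0.5, kind = "fiber",
    fiber = mp_fiber_preset("membrane", spacing = 10),
    name = "bilayer", color = c(0.55, 0.8, 0.5), compartment = "membrane")
  rec <- mp_recipe(list(blob, gate, dna, bilayer), name = "demo",
                   dir = dir %||% ".")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mp_save_recipe(rec, file.path(dir, "recipe.json"))
    rec$dir <- dir
    attr(rec, "path") <- file.path(dir, "recipe.json")
  }
  rec
}

#' Small demo scene
#'
#' A vesicle with membrane-bound proteins on its rail and soluble bodies
#' inside and outside (the structure of a locked-virus-style figure, at toy
#' scale): 1 closed membrane, `n_attached` rail proteins, `n_soluble`
#' blobs, on a 200 x 200 nm canvas.
#'
#' @param seed world seed.
#' @param n_attached membrane proteins to attach.
#' @param n_soluble soluble bodies to paint.
#' @return list: `scene`, `recipe`, `membrane` (the chain info).
#' @export
mp_fixture_scene <- function(seed = 1L, n_attached = 6L, n_soluble = 12L) {
  rec <- mp_fixture_recipe()
  sc <- mp_scene(width = 200, height = 200, seed = seed)
  for (ing in rec$ingredients) mp_add_ingredient(sc, ing)
  memb <- mp_draw_membrane(sc, "bilayer",
                           mp_fixture_stroke("circle", radius = 50,
                                             center = c(100, 100),
                                             clockwise = TRUE))
  total <- 2 * pi * 50
  for (k in seq_len(n_attached)) {
    id <- suppressWarnings(
      mp_paint(sc, "gatekeeper", c(100, 100), layer = 1L, settle = FALSE))
    mp_attach_to_membrane(sc, id, memb$chain_id, arc_position = (k - 1) * total / n_attached)
  }
  pts_in <- cbind(100 + 25 * cos(seq_len(n_soluble)),
                  100 + 25 * sin(seq_len(n_soluble) * 2))
  for (k in seq_len(n_soluble)) {
    p <- if (k <= n_soluble / 2) pts_in[k, ]
         else c(100 + 75 * cos(k), 100 + 75 * sin(k * 1.7))
    p <- pmin(pmax(p, 5), 195)
    mp_paint(sc, "blobulin", p, layer = 1L, settle = FALSE)
  }
  mp_settle(sc$world, max_steps = 25L)
  list(scene = sc, recipe = rec, membrane = memb)
}

#' Write synthetic fixture files
#'
#' Dispatcher used by the command line: generates contour/structure/stroke/
#' recipe/scene fixtures deterministically and writes them under `out_dir`.
#'
#' @param kind `"contour"`, `"structure"`, `"stroke"`, `"recipe"`, `"scene"`.
#' @param out_dir output directory.
#' @param params named list of parameters forwarded to the generator.
#' @param seed RNG seed.
#' @return character vector of files written.
#' @export
mp_fixtures_generate <- function(kind, out_dir, params = list(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(kind,
    contour = {
      ct <- do.call(mp_fixture_contour, c(params, list(seed = seed)))
      f <- file.path(out_dir, "contour.json")
      jsonlite::write_json(list(vertices = ct$vertices, closed = ct$closed),
                           f, digits = NA)
      f
    },
    structure = {
      st <- do.call(mp_fixture_structure, c(params, list(seed = seed)))
      f <- file.path(out_dir, "structure.pdb")
      write_pdb(st, f)
      f
    },
    stroke = {
      pts <- do.call(mp_fixture_stroke, params)
      f <- file.path(out_dir, "stroke.json")
      jsonlite::write_json(list(points = pts), f, digits = NA)
      f
    },
    recipe = {
      rec <- mp_fixture_recipe(out_dir, seed = seed)
      c(attr(rec, "path"),
        list.files(file.path(out_dir, "sprites"), full.names = TRUE))
    },
    scene = {
      fx <- mp_fixture_scene(seed = seed)
      f <- file.path(out_dir, "scene.txt")
      mp_save_scene(fx$scene, f)
      f
    },
    stop(sprintf("unknown fixture kind '%s'", kind)))
}

# minimal PDB writer for fixture structures
write_pdb <- function(st, path) {
  n <- nrow(st$positions)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), substr(st$chains, 1L, 1L), seq_len(n),
    st$positions[, 1L], st$positions[, 2L], st$positions[, 3L],
    st$elements)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
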