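# Ingredient factory: from atomic structures or transparent sprite images to
# paintable ingredients with automatically inferred colliders.

# van der Waals radii, Angstrom (Bondi-style defaults; CA-only chains fall
# back to a per-residue pseudo-atom radius)
VDW_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
               FE = 1.8, MG = 1.73, ZN = 1.39, CA = 2.31, "NA" = 2.27,
               K = 2.75, CL = 1.75)
DEFAULT_VDW <- 1.7
CA_ONLY_RADIUS <- 3.0      # pseudo-residue radius when only CA atoms present
COARSEN_FACTOR <- 1.3      # disc inflation for the cartoony sprite look

#' Atomic structure container
#'
#' @param positions n x 3 matrix of coordinates in Angstrom.
#' @param elements character vector of element symbols.
#' @param radii per-atom radii in Angstrom; inferred from `elements` when
#'   omitted.
#' @param chains per-atom chain identifiers.
#' @param assembly_id label of the assembly the coordinates represent.
#' @return `mp_structure` object.
#' @export
mp_structure <- function(positions, elements = NULL, radii = NULL,
                         chains = NULL, assembly_id = "asym") {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  stopifnot(ncol(positions) == 3L, nrow(positions) >= 1L)
  n <- nrow(positions)
  if (is.null(elements)) elements <- rep("C", n)
  elements <- toupper(elements)
  if (is.null(radii)) {
    radii <- unname(VDW_RADII[elements])
    radii[is.na(radii)] <- DEFAULT_VDW
  }
  stopifnot(all(radii > 0))
  if (is.null(chains)) chains <- rep("A", n)
  structure(list(positions = positions, elements = elements, radii = radii,
                 chains = chains, assembly_id = assembly_id),
            class = "mp_structure")
}

#' @export
print.mp_structure <- function(x, ...) {
  cat(sprintf("<mp_structure: %d atoms, %d chain(s), assembly '%s'>\n",
              nrow(x$positions), length(unique(x$chains)), x$assembly_id))
  invisible(x)
}

#' Longest axis of a structure
#'
#' Principal axis of the atomic position covariance (largest eigenvalue),
#' with a deterministic sign convention: non-negative Z component, ties
#' broken toward non-negative Y, then X. Near-isotropic structures
#' (eigenvalue ratio < 1.05) are flagged via the `near_degenerate` attribute.
#'
#' @param structure an [mp_structure] with at least 2 atoms.
#' @return 3D unit vector.
#' @export
mp_longest_axis <- function(structure) {
  p <- structure$positions
  if (nrow(p) < 2L) stop("no axis: structure has a single atom")
  cv <- stats::cov(p)
  e <- eigen(cv, symmetric = TRUE)
  ax <- e$vectors[, 1L]
  s <- if (abs(ax[3L]) > 1e-9) sign(ax[3L])
       else if (abs(ax[2L]) > 1e-9) sign(ax[2L])
       else sign(ax[1L])
  if (s == 0) s <- 1
  ax <- ax * s
  attr(ax, "near_degenerate") <- e$values[1L] < 1.05 * max(e$values[2L], 1e-12)
  ax
}

# rotation matrix taking unit vector `a` onto unit vector `b` (Rodrigues)
rotation_between <- function(a, b) {
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {           # antiparallel: flip about any normal axis
    ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ref - sum(ref * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Sprite container
#'
#' @param image RGBA array (rows x cols x 4), values in `[0, 1]`.
#' @param nm_per_pixel physical scale.
#' @param contour optional pre-extracted [mp_contour]; derived from the alpha
#'   channel otherwise.
#' @return `mp_sprite`: image, scale, contour (centered, nm, Y-up), and
#'   `anchor` (contour centroid in pixel coordinates, for rendering).
#' @export
mp_sprite <- function(image, nm_per_pixel, contour = NULL) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 4L)
  if (!any(image[, , 4L] >= 0.5)) stop("sprite has no opaque pixel")
  if (is.null(contour))
    contour <- mp_extract_contour(image[, , 4L], nm_per_pixel)
  structure(list(image = image, nm_per_pixel = nm_per_pixel,
                 contour = contour,
                 anchor = attr(contour, "centroid_px") %||%
                   c(dim(image)[2L], dim(image)[1L]) / 2),
            class = "mp_sprite")
}

#' @export
print.mp_sprite <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<mp_sprite: %d x %d px at %.3g nm/px, %d contour vertices>\n",
              d[2L], d[1L], x$nm_per_pixel, nrow(x$contour$vertices)))
  invisible(x)
}

#' Render a coarse sprite from an atomic structure
#'
#' Orients the structure so its longest axis lies along image Y (Y-up),
#' projects along Z, and draws atoms back-to-front as flat-shaded discs with
#' a darker outline (painter's algorithm); the background is fully
#' transparent. A stand-in for a full non-photorealistic molecular renderer:
#' it captures overall size and shape, which is what the colliders need.
#'
#' @param structure an [mp_structure] (coordinates in Angstrom; converted to
#'   nm here).
#' @param nm_per_pixel output scale (> 0).
#' @param orient `"auto"` (align longest axis to Y) or a 3 x 3 rotation
#'   matrix applied to the coordinates before projection.
#' @param color RGB triple in `[0, 1]` for the fill.
#' @return an [mp_sprite].
#' @export
mp_render_sprite <- function(structure, nm_per_pixel, orient = "auto",
                             color = c(0.62, 0.66, 0.74)) {
  if (nm_per_pixel <= 0) stop("invalid argument: nm_per_pixel must be > 0")
  pos <- structure$positions / 10   # Angstrom -> nm
  rad <- structure$radii / 10
  if (length(unique(structure$elements)) == 1L &&
      all(structure$elements == "C") && nrow(pos) > 1L &&
      !is.null(attr(structure, "ca_only")) && isTRUE(attr(structure, "ca_only")))
    rad <- rep(CA_ONLY_RADIUS / 10, nrow(pos))
  R <- if (identical(orient, "auto")) {
    if (nrow(pos) >= 2L) rotation_between(mp_longest_axis(structure), c(0, 1, 0))
    else diag(3)
  } else orient
  p <- pos %*% t(R)
  rpx <- rad * COARSEN_FACTOR / nm_per_pixel
  margin <- max(rpx) + 2
  xr <- range(p[, 1L] / nm_per_pixel)
  yr <- range(p[, 2L] / nm_per_pixel)
  wpx <- ceiling(diff(xr) + 2 * margin)
  hpx <- ceiling(diff(yr) + 2 * margin)
  if (wpx < 3L || hpx < 3L || max(rpx) < 0.5)
    stop("resolution error: sprite smaller than 3 px at this scale")
  img <- array(0, dim = c(hpx, wpx, 4L))
  cx <- p[, 1L] / nm_per_pixel - xr[1L] + margin
  cy <- p[, 2L] / nm_per_pixel - yr[1L] + margin
  outline <- color * 0.55
  ord <- order(p[, 3L])            # back to front (viewer looks down -Z)
  colgrid <- matrix(seq_len(wpx), hpx, wpx, byrow = TRUE)
  rowgrid <- matrix(seq_len(hpx), hpx, wpx)
  for (i in ord) {
    r <- rpx[i]
    ci <- cx[i] + 0.5
    ri <- hpx - cy[i] + 0.5        # Y-up -> image rows
    rows <- max(1L, floor(ri - r)):min(hpx, ceiling(ri + r))
    cols <- max(1L, floor(ci - r)):min(wpx, ceiling(ci + r))
    if (!length(rows) || !length(cols)) next
    dd <- sqrt(outer((rows - ri)^2, (cols - ci)^2, "+"))
    ow <- max(1, 0.18 * r)
    fill <- dd <= r - ow
    ring <- dd <= r & !fill
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      sub[fill] <- color[ch]
      sub[ring] <- outline[ch]
      img[rows, cols, ch] <- sub
    }
    suba <- img[rows, cols, 4L]
    suba[fill | ring] <- 1
    img[rows, cols, 4L] <- suba
  }
  mp_sprite(img, nm_per_pixel)
}

#' Membrane-binding parameters
#'
#' @param thickness membrane thickness in nm (> 0).
#' @param surface_offset Y displacement of the protein center above the
#'   membrane center, nm (the membrane centerline sits at
#'   `y = -surface_offset` in the sprite frame).
#' @param padding extra clearance around the intramembrane band, nm (>= 0).
#' @param rotation in-plane rotation of the sprite relative to the membrane
#'   normal, rad.
#' @export
mp_binding <- function(thickness = 4, surface_offset = 0, padding = 0.5,
                       rotation = 0) {
  stopifnot(thickness > 0, padding >= 0)
  structure(list(thickness = thickness, surface_offset = surface_offset,
                 padding = padding, rotation = rotation),
            class = "mp_binding")
}

#' Fiber subunit parameters
#'
#' @param spacing distance between consecutive subunit centers, nm (> 0).
#' @param subunit_rotation relative twist applied per subunit, rad.
#' @param n_springs number of persistence springs per subunit (DNA preset
#'   uses 10, RNA 0, membranes 3; user fibers default to 3).
#' @param angle_limit optional hinge angle limit, rad (NULL = unlimited).
#' @export
mp_fiber_spec <- function(spacing, subunit_rotation = 0, n_springs = 3L,
                          angle_limit = NULL) {
  stopifnot(spacing > 0, n_springs >= 0)
  structure(list(spacing = spacing, subunit_rotation = subunit_rotation,
                 n_springs = as.integer(n_springs), angle_limit = angle_limit),
            class = "mp_fiber_spec")
}

#' Built-in fiber presets
#'
#' Persistence-spring counts tuned to biological stiffness: DNA is very
#' stiff (10 springs), RNA is floppy (0), membranes are intermediate (3).
#'
#' @param type `"dna"`, `"rna"`, `"membrane"`, or `"user"`.
#' @param spacing subunit spacing in nm.
#' @return an [mp_fiber_spec].
#' @export
mp_fiber_preset <- function(type = c("dna", "rna", "membrane", "user"),
                            spacing = 3) {
  type <- match.arg(type)
  n <- switch(type, dna = 10L, rna = 0L, membrane = 3L, user = 3L)
  mp_fiber_spec(spacing = spacing, n_springs = n)
}

#' Partition a contour around the membrane
#'
#' With the membrane centerline at `y = -surface_offset` in the Y-up sprite
#' frame, contour vertices are split into the exterior side
#' (`y > -offset + thickness/2 + padding`), the interior side
#' (`y < -offset - thickness/2 - padding`), and the intramembrane band (the
#' rest). The three index sets always partition the vertex set.
#'
#' @param contour an [mp_contour].
#' @param binding an [mp_binding].
#' @return list of integer index vectors `exterior`, `intramembrane`,
#'   `interior`.
#' @export
mp_partition_contour <- function(contour, binding) {
  y <- contour$vertices[, 2L]
  hi <- -binding$surface_offset + binding$thickness / 2 + binding$padding
  lo <- -binding$surface_offset - binding$thickness / 2 - binding$padding
  ext <- which(y > hi)
  itr <- which(y < lo)
  mid <- setdiff(seq_along(y), c(ext, itr))
  if (!length(ext) && !length(itr))
    warning("no anchor: every contour point is intramembrane (wheels only)")
  list(exterior = ext, intramembrane = mid, interior = itr)
}

# rectangle collider forced from a (possibly small) point subset
forced_rect <- function(points, class = "membrane") {
  p <- as.matrix(points)
  if (nrow(p) < 2L) return(NULL)
  cen <- colMeans(p)
  d <- sweep(p, 2L, cen)
  cv <- crossprod(d) / nrow(d)
  e <- eigen(cv, symmetric = TRUE)
  major <- e$vectors[, 1L]
  s <- if (abs(major[1L]) > 1e-12) sign(major[1L]) else sign(major[2L])
  if (s == 0) s <- 1
  major <- major * s
  minor <- c(-major[2L], major[1L])
  proj <- d %*% cbind(major, minor)
  w <- max(diff(range(proj[, 1L])), 0.2)
  h <- max(diff(range(proj[, 2L])), 0.2)
  mp_rect(cen, w, h, atan2(major[2L], major[1L]), class = class)
}

new_ingredient <- function(name, kind, sprite, main_collider,
                           membrane_colliders = NULL, end_circles = NULL,
                           binding = NULL, fiber = NULL,
                           color = c(0.62, 0.66, 0.74), compartment = "cytoplasm") {
  stopifnot(kind %in% c("soluble", "membrane_bound", "fiber"))
  if ((kind == "membrane_bound") != !is.null(binding) && kind == "membrane_bound")
    stop("membrane_bound ingredient needs a binding")
  if (kind == "fiber" && is.null(fiber))
    stop("fiber ingredient needs a fiber spec")
  structure(list(name = name, kind = kind, sprite = sprite,
                 main_collider = main_collider,
                 membrane_colliders = membrane_colliders,
                 end_circles = end_circles, binding = binding, fiber = fiber,
                 color = color, compartment = compartment),
            class = "mp_ingredient")
}

#' @export
print.mp_ingredient <- function(x, ...) {
  ncol_ <- 1L + length(x$membrane_colliders$wheels) +
    sum(!vapply(x$membrane_colliders[c("exterior_box", "interior_box")],
                is.null, TRUE)) + length(x$end_circles)
  cat(sprintf("<mp_ingredient '%s': %s, %d collider(s)>\n", x$name, x$kind, ncol_))
  invisible(x)
}

#' Build a soluble ingredient
#'
#' One main collider chosen by [mp_select_collider] (protein class).
#'
#' @param sprite an [mp_sprite].
#' @param name,color,compartment bookkeeping fields.
#' @export
mp_make_soluble <- function(sprite, name = "soluble",
                            color = c(0.62, 0.66, 0.74),
                            compartment = "cytoplasm") {
  fr <- mp_eigen_frame(sprite$contour)
  main <- mp_select_collider(fr, sprite$contour, class = "protein")
  new_ingredient(name, "soluble", sprite, main, color = color,
                 compartment = compartment)
}

#' Build a membrane-bound ingredient
#'
#' Dual collider groups: the main collider (protein class, collides with
#' proteins/fibers) from the full contour, plus a membrane-class group made
#' of an exterior box, an interior box (rectangles fit to the contour points
#' on each side of the membrane; skipped when a side is empty), and four
#' wheel circles of radius thickness/2 straddling the membrane line just
#' outside the main collider, which ride the membrane like wheels on a rail.
#'
#' @param sprite an [mp_sprite].
#' @param binding an [mp_binding].
#' @param name,color,compartment bookkeeping fields.
#' @export
mp_make_membrane_bound <- function(sprite, binding, name = "membrane-protein",
                                   color = c(0.62, 0.66, 0.74),
                                   compartment = "membrane") {
  ct <- sprite$contour
  fr <- mp_eigen_frame(ct)
  main <- mp_select_collider(fr, ct, class = "protein")
  part <- mp_partition_contour(ct, binding)
  stopifnot(length(part$exterior) + length(part$intramembrane) +
              length(part$interior) == nrow(ct$vertices))
  ext_box <- if (length(part$exterior))
    forced_rect(ct$vertices[part$exterior, , drop = FALSE]) else NULL
  int_box <- if (length(part$interior))
    forced_rect(ct$vertices[part$interior, , drop = FALSE]) else NULL
  main_w <- if (main$variant == "circle") 2 * main$radius else main$width
  wr <- binding$thickness / 2
  y0 <- -binding$surface_offset
  dy <- binding$thickness / 2 + binding$padding
  wheels <- list(
    mp_circle(c(-(main_w / 2 + wr), y0 + dy), wr, class = "membrane"),
    mp_circle(c(+(main_w / 2 + wr), y0 + dy), wr, class = "membrane"),
    mp_circle(c(-(main_w / 2 + wr), y0 - dy), wr, class = "membrane"),
    mp_circle(c(+(main_w / 2 + wr), y0 - dy), wr, class = "membrane"))
  new_ingredient(name, "membrane_bound", sprite, main,
                 membrane_colliders = list(exterior_box = ext_box,
                                           interior_box = int_box,
                                           wheels = wheels),
                 binding = binding, color = color, compartment = compartment)
}

#' Build a fiber subunit ingredient
#'
#' The subunit sprite is assumed aligned along the horizontal axis. The main
#' collider is always a rectangle (width = major extent, height = minor
#' extent); two end circles of radius = minor half-extent sit at
#' (+/- spacing/2, 0). The end circles anchor the hinge joints between
#' consecutive subunits, fill the gap at acute bend angles, and are tagged so
#' they ignore the neighbouring subunit's colliders.
#'
#' @param sprite an [mp_sprite].
#' @param spec an [mp_fiber_spec].
#' @param name,color,compartment bookkeeping fields.
#' @export
mp_make_fiber_subunit <- function(sprite, spec, name = "fiber",
                                  color = c(0.62, 0.66, 0.74),
                                  compartment = "cytoplasm") {
  ct <- sprite$contour
  fr <- mp_eigen_frame(ct)
  proj <- sweep(ct$vertices, 2L, fr$center) %*% fr$axes
  w <- diff(range(proj[, 1L]))
  h <- diff(range(proj[, 2L]))
  if (h > w) { tmp <- w; w <- h; h <- tmp }
  main <- mp_rect(fr$center, w, h, 0, class = "fiber")
  if (spec$spacing > 2 * w) warning("gappy fiber: spacing exceeds twice the subunit width")
  r <- h / 2
  ends <- list(mp_circle(c(-spec$spacing / 2, 0), r, class = "fiber"),
               mp_circle(c(+spec$spacing / 2, 0), r, class = "fiber"))
  new_ingredient(name, "fiber", sprite, main, end_circles = ends,
                 fiber = spec, color = color, compartment = compartment)
}

#' Build an ingredient from an RGBA image
#'
#' Accepts any image with a transparency channel (a PNG path or an RGBA
#' array), extracts the contour from the alpha channel, and routes to the
#' kind-specific factory.
#'
#' @param image RGBA array or path to a PNG file.
#' @param nm_per_pixel physical scale.
#' @param kind `"soluble"`, `"membrane_bound"`, or `"fiber"`.
#' @param binding [mp_binding] (membrane_bound only).
#' @param fiber [mp_fiber_spec] (fiber only).
#' @param name,color,compartment bookkeeping fields.
#' @export
mp_ingredient_from_image <- function(image, nm_per_pixel,
                                     kind = c("soluble", "membrane_bound", "fiber"),
                                     binding = NULL, fiber = NULL,
                                     name = "ingredient",
                                     color = c(0.62, 0.66, 0.74),
                                     compartment = "cytoplasm") {
  kind <- match.arg(kind)
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3L || dim(image)[3L] != 4L)
    stop("format error: image has no transparency channel (RGBA required)")
  if (all(image[, , 4L] >= 0.5))
    stop("format error: image is fully opaque (transparent background required)")
  sp <- mp_sprite(image, nm_per_pixel)
  switch(kind,
    soluble = mp_make_soluble(sp, name = name, color = color,
                              compartment = compartment),
    membrane_bound = {
      if (is.null(binding)) stop("membrane_bound ingredient needs a binding")
      mp_make_membrane_bound(sp, binding, name = name, color = color,
                             compartment = compartment)
    },
    fiber = {
      if (is.null(fiber)) stop("fiber ingredient needs a fiber spec")
      mp_make_fiber_subunit(sp, fiber, name = name, color = color,
                            compartment = compartment)
    })
}
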