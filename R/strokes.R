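# Stroke paths -> articulated fiber chains and membranes, with the closure,
# pinning, spring-topology and layer rules of the painting engine.

LAYER_JUMP_PERIOD <- 15L  # subunits between stochastic layer jumps (auto policy)

#' Resample a polyline by arc length
#'
#' Samples at multiples of `spacing` from the start of the path; the final
#' partial segment is dropped (subunits are never stretched).
#'
#' @param points n x 2 matrix of path points (nm), n >= 2.
#' @param spacing sample spacing (> 0).
#' @return matrix of sample points.
#' @export
mp_resample_path <- function(points, spacing) {
  p <- as.matrix(points)
  stopifnot(nrow(p) >= 2L, spacing > 0)
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg <= 0)) stop("path has zero-length segments")
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  svals <- seq(0, total, by = spacing)
  out <- matrix(0, length(svals), 2L)
  for (i in seq_along(svals)) {
    s <- svals[i]
    k <- findInterval(s, cum, rightmost.closed = TRUE)
    k <- min(k, length(seg))
    t <- (s - cum[k]) / seg[k]
    out[i, ] <- p[k, ] + t * (p[k + 1L, ] - p[k, ])
  }
  out
}

# local tangent angles of an (optionally closed) sample sequence
sample_tangents <- function(pts, closed) {
  n <- nrow(pts)
  idx_prev <- if (closed) c(n, 1:(n - 1L)) else c(1L, 1:(n - 1L))
  idx_next <- if (closed) c(2:n, 1L) else c(2:n, n)
  d <- pts[idx_next, , drop = FALSE] - pts[idx_prev, , drop = FALSE]
  atan2(d[, 2L], d[, 1L])
}

# membrane segments are membrane-class colliders (the membrane ingredient is
# authored as a fiber subunit, but once drawn it lives in the membrane group)
retag_membrane <- function(fixtures) {
  lapply(fixtures, function(f) {
    if (f$class == CLASS_ID[["fiber"]]) f$class <- CLASS_ID[["membrane"]]
    f
  })
}

# does segment (a, b) cross any segment of an existing membrane chain?
path_crosses_membranes <- function(scene, pts) {
  w <- scene$world
  for (ch in w$chains) {
    if (is.null(ch) || !identical(ch$type, "membrane")) next
    mb <- ch$bodies[w$alive[ch$bodies]]
    if (length(mb) < 2L) next
    mpts <- cbind(w$x[mb], w$y[mb])
    nseg <- if (isTRUE(ch$closed)) nrow(mpts) else nrow(mpts) - 1L
    for (i in seq_len(nrow(pts) - 1L)) {
      for (j in seq_len(nseg)) {
        j2 <- if (j == nrow(mpts)) 1L else j + 1L
        if (segments_cross(pts[i, ], pts[i + 1L, ], mpts[j, ], mpts[j2, ]))
          return(list(crossing = (pts[i, ] + pts[i + 1L, ]) / 2))
      }
    }
  }
  NULL
}

# shared chain-construction core for fibers and membranes
build_chain <- function(scene, ing, samples, closed, layers, type,
                        n_springs, extra_fixtures = NULL) {
  w <- scene$world
  spec <- ing$fiber
  n <- nrow(samples)
  tang <- sample_tangents(samples, closed)
  cid <- length(w$chains) + 1L
  ids <- integer(n)
  for (i in seq_len(n)) {
    ang <- tang[i] + (i - 1L) * spec$subunit_rotation
    ids[i] <- world_add_body(w, ing, position = samples[i, ], angle = ang,
                             layer = layers[i])
    w$chain[ids[i]] <- cid
    w$subidx[ids[i]] <- i
    if (!is.null(extra_fixtures))
      w$fixtures[[ids[i]]] <- c(w$fixtures[[ids[i]]], extra_fixtures)
    if (identical(type, "membrane"))
      w$fixtures[[ids[i]]] <- retag_membrane(w$fixtures[[ids[i]]])
  }
  s2 <- spec$spacing / 2
  nh <- if (closed) n else n - 1L
  for (i in seq_len(nh)) {
    j <- if (i == n) 1L else i + 1L
    world_add_hinge(w, ids[i], ids[j], c(s2, 0), c(-s2, 0), chain = cid)
  }
  if (n_springs > 0L) {
    for (i in seq_len(n)) {
      for (k in 2:(n_springs + 1L)) {
        j <- i + k
        if (closed) {
          if (k >= n) next
          j <- ((j - 1L) %% n) + 1L   # wrap-around spans close the ring
        } else if (j > n) next
        world_add_spring(w, ids[i], ids[j], rest = spec$spacing * k,
                         chain = cid)
      }
    }
    if (closed && n > 2L) {
      # deduplicate wrap springs added from both endpoints
      sp <- w$springs
      mine <- sp[, 5L] == cid
      key <- paste(pmin(sp[mine, 1L], sp[mine, 2L]),
                   pmax(sp[mine, 1L], sp[mine, 2L]), sp[mine, 3L])
      drop <- which(mine)[duplicated(key)]
      if (length(drop)) w$springs <- sp[-drop, , drop = FALSE]
    }
  }
  w$chains[[cid]] <- list(bodies = ids, closed = closed, type = type,
                          spacing = spec$spacing, ingredient = ing$name)
  cid
}

#' Draw a fiber along a stroke path
#'
#' The path is resampled by arc length at the subunit spacing; one subunit is
#' placed per sample, oriented to the local tangent plus the cumulative
#' subunit twist. Consecutive subunits are hinged at their coincident end
#' circles; persistence springs connect each subunit i to i+k for
#' k = 2..n_springs+1 with rest length spacing x k. If the stroke ends within
#' one spacing of its start the chain closes into a ring (circular DNA), with
#' wrap-around hinges and springs. Under the `"auto"` layer policy long
#' fibers start in the front layer and jump to a random other layer every few
#' subunits (seeded); pass a layer number to force a single layer. Strokes
#' that cross an existing membrane are rejected.
#'
#' @param scene an [mp_scene].
#' @param fiber_ingredient palette name or [mp_ingredient] of kind `"fiber"`.
#' @param path n x 2 matrix of stroke points (nm).
#' @param layer `"auto"` or a fixed layer 0/1/2.
#' @return list describing the chain: `chain_id`, `body_ids`, `closed`,
#'   `layers`, `n_hinges`, `n_springs`.
#' @export
mp_draw_fiber <- function(scene, fiber_ingredient, path, layer = "auto") {
  ing <- if (is.character(fiber_ingredient))
    get_ingredient(scene, fiber_ingredient) else fiber_ingredient
  if (!identical(ing$kind, "fiber"))
    stop("ingredient is not a fiber")
  if (is.null(scene$palette[[ing$name]])) mp_add_ingredient(scene, ing)
  path <- as.matrix(path)
  cross <- path_crosses_membranes(scene, path)
  if (!is.null(cross))
    stop(sprintf("stroke rejected: fiber crosses a membrane near (%.1f, %.1f)",
                 cross$crossing[1L], cross$crossing[2L]))
  spec <- ing$fiber
  samples <- mp_resample_path(path, spec$spacing)
  closed <- sqrt(sum((path[1L, ] - path[nrow(path), ])^2)) < spec$spacing
  if (closed && nrow(samples) > 1L &&
      sqrt(sum((samples[1L, ] - samples[nrow(samples), ])^2)) < spec$spacing / 2)
    samples <- samples[-nrow(samples), , drop = FALSE]
  n <- nrow(samples)
  if (n < 2L) stop("stroke too short for even two subunits")
  if (closed && n < 3L) stop("closed stroke too short")
  layers <- if (identical(layer, "auto")) {
    lay <- integer(n)
    cur <- 0L
    with_world_rng(scene$world, {
      for (i in seq_len(n)) {
        if (i > 1L && (i - 1L) %% LAYER_JUMP_PERIOD == 0L)
          cur <- sample(setdiff(0:2, cur), 1L)
        lay[i] <- cur
      }
    })
    lay
  } else rep(as.integer(layer), n)
  nsp0 <- nrow(scene$world$springs)
  cid <- build_chain(scene, ing, samples, closed, layers, "fiber",
                     n_springs = spec$n_springs)
  ch <- scene$world$chains[[cid]]
  list(chain_id = cid, body_ids = ch$bodies, closed = closed, layers = layers,
       n_hinges = if (closed) n else n - 1L,
       n_springs = nrow(scene$world$springs) - nsp0)
}

#' Draw a membrane along a stroke path
#'
#' Membranes are articulated chains of rectangular segments with end-circle
#' hinges, three persistence springs, and small spacer colliders above and
#' below each segment that keep membranes a minimum distance apart. If the
#' stroke's start and end lie within one segment length the membrane closes
#' into a vesicle: the ends fuse, the orientation is forced clockwise (so
#' membrane-protein sidedness is well defined), and the interior polygon is
#' triangulated into a compartment fill. Otherwise both end segments are
#' pinned in place. Self-intersecting closed strokes are rejected.
#'
#' @param scene an [mp_scene].
#' @param membrane_ingredient palette name or fiber-kind [mp_ingredient]
#'   whose subunit rectangle is one membrane segment.
#' @param path n x 2 matrix of stroke points (nm).
#' @param layer depth layer for the whole membrane (default 1).
#' @return list: `chain_id`, `body_ids`, `closed`, `reversed` (TRUE when a
#'   counter-clockwise stroke was stored clockwise), `area` (interior polygon
#'   area, closed only), `end_pins` (open only), `fill_id`.
#' @export
mp_draw_membrane <- function(scene, membrane_ingredient, path, layer = 1L) {
  ing <- if (is.character(membrane_ingredient))
    get_ingredient(scene, membrane_ingredient) else membrane_ingredient
  if (!identical(ing$kind, "fiber"))
    stop("membrane ingredient must be a fiber-type subunit")
  if (is.null(scene$palette[[ing$name]])) mp_add_ingredient(scene, ing)
  path <- as.matrix(path)
  spec <- ing$fiber
  closed <- sqrt(sum((path[1L, ] - path[nrow(path), ])^2)) < spec$spacing
  samples <- mp_resample_path(path, spec$spacing)
  if (closed && nrow(samples) > 1L &&
      sqrt(sum((samples[1L, ] - samples[nrow(samples), ])^2)) < spec$spacing / 2)
    samples <- samples[-nrow(samples), , drop = FALSE]
  n <- nrow(samples)
  if (closed && n < 3L) stop("closed membrane too short")
  if (!closed && n < 2L) stop("stroke too short for even two segments")
  reversed <- FALSE
  if (closed) {
    if (!is_simple_polygon(samples))
      stop("stroke rejected: closed membrane is self-intersecting")
    if (mp_orientation(samples) == "counter-clockwise") {
      samples <- samples[nrow(samples):1, , drop = FALSE]
      reversed <- TRUE
    }
  }
  thickness <- ing$main_collider$height
  spacer_r <- thickness / 2
  spacers <- list(
    make_fixture(0L, 0, +(thickness / 2 + spacer_r), p1 = spacer_r,
                 class = "membrane", role = "spacer"),
    make_fixture(0L, 0, -(thickness / 2 + spacer_r), p1 = spacer_r,
                 class = "membrane", role = "spacer"))
  cid <- build_chain(scene, ing, samples, closed,
                     layers = rep(as.integer(layer), n), type = "membrane",
                     n_springs = 3L, extra_fixtures = spacers)
  ch <- scene$world$chains[[cid]]
  out <- list(chain_id = cid, body_ids = ch$bodies, closed = closed,
              reversed = reversed, area = NA_real_, end_pins = integer(0),
              fill_id = NA_integer_)
  if (closed) {
    tri <- mp_triangulate(samples)
    out$area <- abs(mp_polygon_area(samples))
    fid <- length(scene$fills) + 1L
    scene$fills[[fid]] <- list(chain = cid, polygon = samples,
                               triangles = tri,
                               name = sprintf("vesicle-%d", fid),
                               color = ing$color)
    scene$compartments[[sprintf("vesicle-%d", fid)]] <- character(0)
    out$fill_id <- fid
  } else {
    ends <- c(ch$bodies[1L], ch$bodies[n])
    mp_pin(scene, ends)
    out$end_pins <- ends
  }
  out
}

# arc-length position and frame on a membrane chain polyline
chain_point_at <- function(w, ch, s) {
  mb <- ch$bodies[w$alive[ch$bodies]]
  pts <- cbind(w$x[mb], w$y[mb])
  n <- nrow(pts)
  seg <- if (isTRUE(ch$closed)) rbind(pts, pts[1L, ]) else pts
  lens <- sqrt(rowSums((seg[-1L, , drop = FALSE] - seg[-nrow(seg), , drop = FALSE])^2))
  total <- sum(lens)
  if (isTRUE(ch$closed)) s <- s %% total
  if (s < 0 || s > total)
    stop("detached: arc position lies beyond the open membrane end")
  cum <- c(0, cumsum(lens))
  k <- findInterval(s, cum, rightmost.closed = TRUE)
  k <- min(k, length(lens))
  t <- (s - cum[k]) / lens[k]
  p <- seg[k, ] + t * (seg[k + 1L, ] - seg[k, ])
  tan <- (seg[k + 1L, ] - seg[k, ]) / lens[k]
  list(point = p, tangent = tan, normal = c(-tan[2L], tan[1L]))
}

#' Attach a membrane-bound protein to a membrane
#'
#' Registers a rail constraint: the protein's wheel system rides the
#' membrane centerline, its center held at the binding surface offset along
#' the local membrane normal, its sprite Y axis aligned to that normal (plus
#' the binding rotation), free to slide tangentially. Sidedness follows the
#' clockwise vesicle convention: the exterior side of the sprite faces
#' outward on a clockwise-drawn vesicle.
#'
#' @param scene an [mp_scene].
#' @param protein_instance instance id of a membrane-bound ingredient.
#' @param membrane chain id returned by [mp_draw_membrane].
#' @param arc_position position along the membrane, nm from its start.
#' @return rail constraint id.
#' @export
mp_attach_to_membrane <- function(scene, protein_instance, membrane,
                                  arc_position) {
  w <- scene$world
  id <- resolve_selector(scene, protein_instance)
  ing <- get_ingredient(scene, w$ingredient[id])
  if (!identical(ing$kind, "membrane_bound"))
    stop("kind error: only membrane-bound ingredients ride a rail")
  ch <- w$chains[[membrane]]
  if (is.null(ch) || !identical(ch$type, "membrane"))
    stop("unknown membrane chain")
  loc <- chain_point_at(w, ch, arc_position)
  off <- ing$binding$surface_offset
  rot <- ing$binding$rotation
  w$x[id] <- loc$point[1L] + loc$normal[1L] * off
  w$y[id] <- loc$point[2L] + loc$normal[2L] * off
  w$angle[id] <- atan2(-loc$normal[1L], loc$normal[2L]) + rot
  w$layer[id] <- w$layer[ch$bodies[1L]]
  world_add_rail(w, id, membrane, off, rot)
}
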