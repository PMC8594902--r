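# Scene state and the painting toolset over the physics world.

#' Create an empty scene
#'
#' A scene couples a canvas (in nm, origin at the lower-left corner, Y-up),
#' an ingredient palette organized by compartment, and a physics world.
#'
#' @param width,height canvas size in nm.
#' @param background background RGB triple in `[0, 1]`.
#' @param seed RNG seed forwarded to the world (diffusion, layer jumps).
#' @param ... further arguments to [mp_world].
#' @return environment of class `mp_scene`.
#' @export
mp_scene <- function(width = 500, height = 500,
                     background = c(0.12, 0.12, 0.16), seed = 1L, ...) {
  s <- new.env(parent = emptyenv())
  s$canvas <- c(width = width, height = height)
  s$background_color <- background
  s$world <- mp_world(rng_seed = seed, ...)
  s$palette <- list()
  s$compartments <- list()
  s$groups <- list()
  s$lock_regions <- list()
  s$measurements <- list()
  s$backgrounds <- list()
  s$fills <- list()          # closed-vesicle interior fills
  s$next_excl <- 0L
  s$next_lock <- 0L
  s$log <- list()
  class(s) <- "mp_scene"
  s
}

#' @export
print.mp_scene <- function(x, ...) {
  cat(sprintf("<mp_scene: %g x %g nm canvas, %d ingredients, %d instances>\n",
              x$canvas[1L], x$canvas[2L], length(x$palette),
              sum(x$world$alive[seq_len(x$world$n)])))
  invisible(x)
}

#' Register an ingredient in the scene palette
#'
#' @param scene an [mp_scene].
#' @param ingredient an [mp_ingredient].
#' @export
mp_add_ingredient <- function(scene, ingredient) {
  stopifnot(inherits(ingredient, "mp_ingredient"))
  scene$palette[[ingredient$name]] <- ingredient
  comp <- ingredient$compartment %||% "cytoplasm"
  scene$compartments[[comp]] <- union(scene$compartments[[comp]], ingredient$name)
  invisible(scene)
}

get_ingredient <- function(scene, name) {
  ing <- scene$palette[[name]]
  if (is.null(ing)) stop(sprintf("unknown ingredient '%s'", name))
  ing
}

# largest collider diameter of a body (for local-settle radii)
body_bound_radius <- function(w, id) {
  r <- 0
  for (f in w$fixtures[[id]]) {
    off <- sqrt(f$ox^2 + f$oy^2)
    fr <- if (f$kind == 0L) f$p1
          else if (f$kind == 1L) sqrt(f$p1^2 + f$p2^2)
          else sqrt(max(rowSums(f$verts^2)))
    r <- max(r, off + fr)
  }
  r
}

# Settle only the neighbourhood of `center`: bodies outside `radius` are
# frozen for the duration. `only` restricts motion to the given ids.
local_settle <- function(scene, center, radius, max_steps = 50L, only = NULL) {
  w <- scene$world
  ids <- world_alive_ids(w)
  d <- sqrt((w$x[ids] - center[1L])^2 + (w$y[ids] - center[2L])^2)
  far <- ids[d > radius]
  old <- w$frozen[far]
  w$frozen[far] <- TRUE
  if (!is.null(only)) {
    others <- setdiff(ids, c(far, only))
    old2 <- w$frozen[others]
    w$frozen[others] <- TRUE
    on.exit(w$frozen[others] <- old2, add = TRUE)
  }
  on.exit(w$frozen[far] <- old, add = TRUE)
  mp_settle(w, max_steps = max_steps)
  invisible(scene)
}

#' Paint an ingredient into the scene
#'
#' Creates a rigid body at the requested position, then runs a bounded local
#' settle (new body first, then its neighbourhood) so overlaps resolve with
#' the existing paint left essentially untouched. Membrane-bound ingredients
#' painted with no membrane nearby are placed as free bodies with a warning;
#' use [mp_attach_to_membrane] to put them on a rail.
#'
#' @param scene an [mp_scene].
#' @param ingredient_name palette name.
#' @param position length-2 position in nm (inside the canvas).
#' @param layer depth layer 0 (front), 1, or 2.
#' @param angle initial rotation, rad.
#' @param settle run the local settle (disable for scripted exact placement).
#' @return the new instance id (integer).
#' @export
mp_paint <- function(scene, ingredient_name, position, layer = 0L, angle = 0,
                     settle = TRUE) {
  ing <- get_ingredient(scene, ingredient_name)
  if (position[1L] < 0 || position[1L] > scene$canvas[1L] ||
      position[2L] < 0 || position[2L] > scene$canvas[2L])
    stop("position outside the canvas")
  if (identical(ing$kind, "membrane_bound"))
    warning("membrane-bound ingredient painted without a membrane: placed as a free body")
  w <- scene$world
  id <- world_add_body(w, ing, position = position, angle = angle,
                       layer = layer)
  if (settle && sum(w$alive[seq_len(w$n)]) > 1L) {
    r <- 3 * 2 * body_bound_radius(w, id)
    local_settle(scene, position, r, max_steps = 50L, only = id)
    local_settle(scene, position, r, max_steps = 10L)
  }
  id
}

resolve_selector <- function(scene, selector) {
  w <- scene$world
  if (is.numeric(selector)) {
    ids <- as.integer(selector)
    if (any(ids < 1L | ids > w$n) || !all(w$alive[ids]))
      stop("unknown instance id")
    return(ids)
  }
  if (is.character(selector)) {
    if (is.null(scene$palette[[selector]]))
      stop(sprintf("unknown ingredient '%s'", selector))
    return(which(w$alive[seq_len(w$n)] & w$ingredient[seq_len(w$n)] == selector))
  }
  stop("selector must be instance ids or an ingredient name")
}

#' Erase instances
#'
#' Removes the selected bodies together with any constraint that references
#' them. Fiber and membrane chains are re-hinged: erasing an interior subunit
#' splits the chain into two valid chains (springs spanning the gap are
#' dropped).
#'
#' @param scene an [mp_scene].
#' @param selector instance id(s) or an ingredient name (all instances).
#' @return number of instances removed.
#' @export
mp_erase <- function(scene, selector) {
  ids <- resolve_selector(scene, selector)
  w <- scene$world
  if (!length(ids)) return(0L)
  w$alive[ids] <- FALSE
  w$pinned[ids] <- FALSE
  keep_h <- !(w$hinges[, 1L] %in% ids | w$hinges[, 2L] %in% ids)
  w$hinges <- w$hinges[keep_h, , drop = FALSE]
  keep_s <- !(w$springs[, 1L] %in% ids | w$springs[, 2L] %in% ids)
  w$springs <- w$springs[keep_s, , drop = FALSE]
  if (nrow(w$pintos)) {
    keep_p <- !(w$pintos[, 1L] %in% ids | w$pintos[, 4L] %in% ids)
    w$pintos <- w$pintos[keep_p, , drop = FALSE]
  }
  w$rails <- Filter(function(r) !(r$body %in% ids), w$rails)
  touched <- unique(w$chain[ids])
  for (ci in setdiff(touched, 0L)) rebuild_chain(scene, ci)
  for (li in seq_along(scene$lock_regions)) {
    lr <- scene$lock_regions[[li]]
    if (!is.null(lr) && any(ids %in% lr$members)) {
      message("lock region ", li, ": hulls recomputed after erase")
      relock_region(scene, li)
    }
  }
  length(ids)
}

# Split a chain at erased bodies: consecutive runs of surviving subunits
# become independent chains; cross-piece springs are dropped.
rebuild_chain <- function(scene, chain_id) {
  w <- scene$world
  ch <- w$chains[[chain_id]]
  if (is.null(ch)) return(invisible(NULL))
  alive <- w$alive[ch$bodies]
  runs <- split(ch$bodies[alive], cumsum(!alive)[alive])
  was_closed <- isTRUE(ch$closed) && all(alive)
  if (!was_closed && isTRUE(ch$closed) && length(runs) > 1L) {
    # a broken ring is one open chain: join the wrap-around runs
    first <- runs[[1L]]; last <- runs[[length(runs)]]
    if (alive[1L] && alive[length(alive)]) {
      runs[[1L]] <- c(last, first)
      runs[[length(runs)]] <- NULL
    }
  }
  w$chains[chain_id] <- list(NULL)   # keep the slot so later ids stay valid
  piece_ids <- integer(0)
  for (run in runs) {
    if (!length(run)) next
    nid <- length(w$chains) + 1L
    w$chains[[nid]] <- list(bodies = run, closed = FALSE, type = ch$type,
                            spacing = ch$spacing, ingredient = ch$ingredient)
    w$chain[run] <- nid
    w$subidx[run] <- seq_along(run)
    piece_ids <- c(piece_ids, nid)
  }
  # drop springs whose endpoints landed in different pieces
  if (nrow(w$springs)) {
    ok <- w$chain[w$springs[, 1L]] == w$chain[w$springs[, 2L]]
    w$springs <- w$springs[ok, , drop = FALSE]
  }
  # retag surviving hinges' chain column
  if (nrow(w$hinges)) {
    w$hinges[, 7L] <- w$chain[w$hinges[, 1L]]
    ok <- w$chain[w$hinges[, 1L]] == w$chain[w$hinges[, 2L]]
    w$hinges <- w$hinges[ok, , drop = FALSE]
  }
  # fills tied to the broken vesicle are dropped
  scene$fills <- Filter(function(f) f$chain != chain_id, scene$fills)
  invisible(piece_ids)
}

#' Pin and unpin instances
#'
#' Pinned bodies are frozen at their current pose: immobile under stepping
#' and diffusion until unpinned. To pin a whole group, pass its member ids.
#'
#' @param scene an [mp_scene].
#' @param selector instance id(s) or ingredient name.
#' @export
mp_pin <- function(scene, selector) {
  ids <- resolve_selector(scene, selector)
  w <- scene$world
  w$pinned[ids] <- TRUE
  w$pin_x[ids] <- w$x[ids]
  w$pin_y[ids] <- w$y[ids]
  invisible(ids)
}

#' @rdname mp_pin
#' @export
mp_unpin <- function(scene, selector) {
  ids <- resolve_selector(scene, selector)
  w <- scene$world
  w$pinned[ids] <- FALSE
  w$pin_x[ids] <- NA_real_
  w$pin_y[ids] <- NA_real_
  invisible(ids)
}

#' Constrain the distance between two local points
#'
#' The pin-to tool: anchors a point in each sprite and keeps their separation
#' at its current value. The constraint is isotropic (pure distance, no angle
#' coupling): with zero separation the bodies rotate freely about the shared
#' point.
#'
#' @param scene an [mp_scene].
#' @param a,b instance ids (must differ).
#' @param local_pa,local_pb anchor points in each body's local nm frame.
#' @return constraint id.
#' @export
mp_pin_to <- function(scene, a, local_pa, b, local_pb) {
  if (a == b) stop("cannot pin an instance to itself")
  w <- scene$world
  ids <- resolve_selector(scene, c(a, b))
  rotp <- function(th, p) c(cos(th) * p[1L] - sin(th) * p[2L],
                            sin(th) * p[1L] + cos(th) * p[2L])
  pa <- c(w$x[a], w$y[a]) + rotp(w$angle[a], local_pa)
  pb <- c(w$x[b], w$y[b]) + rotp(w$angle[b], local_pb)
  world_add_pinto(w, a, local_pa, b, local_pb, sqrt(sum((pa - pb)^2)))
}

#' Group instances into a reusable brush
#'
#' Stores member poses relative to the selection centroid. [mp_stamp]
#' instantiates fresh copies at a new pose; internal pin-to constraints are
#' copied, and members remain individually dynamic afterwards.
#'
#' @param scene an [mp_scene].
#' @param instance_ids members (>= 1).
#' @return group id.
#' @export
mp_group <- function(scene, instance_ids) {
  ids <- resolve_selector(scene, instance_ids)
  if (!length(ids)) stop("empty selection")
  w <- scene$world
  cen <- c(mean(w$x[ids]), mean(w$y[ids]))
  gid <- length(scene$groups) + 1L
  scene$next_excl <- scene$next_excl + 1L
  w$excl[ids] <- scene$next_excl
  w$group_id[ids] <- gid
  pintos <- NULL
  if (nrow(w$pintos)) {
    internal <- w$pintos[, 1L] %in% ids & w$pintos[, 4L] %in% ids
    pintos <- w$pintos[internal, , drop = FALSE]
  }
  scene$groups[[gid]] <- list(
    members = ids,
    ingredient = w$ingredient[ids],
    layer = w$layer[ids],
    offsets = cbind(w$x[ids] - cen[1L], w$y[ids] - cen[2L]),
    angles = w$angle[ids],
    pintos = pintos)
  gid
}

#' @rdname mp_group
#' @param group_id id returned by [mp_group].
#' @param position,angle pose of the stamped copy (centroid placement).
#' @param settle run a local settle around the stamp.
#' @return `mp_stamp`: integer ids of the new instances.
#' @export
mp_stamp <- function(scene, group_id, position, angle = 0, settle = TRUE) {
  g <- scene$groups[[group_id]]
  if (is.null(g)) stop("unknown group")
  w <- scene$world
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  scene$next_excl <- scene$next_excl + 1L
  new_ids <- integer(length(g$members))
  for (i in seq_along(g$members)) {
    ing <- get_ingredient(scene, g$ingredient[i])
    pos <- position + as.numeric(R %*% g$offsets[i, ])
    new_ids[i] <- world_add_body(w, ing, position = pos,
                                 angle = g$angles[i] + angle,
                                 layer = g$layer[i])
    w$excl[new_ids[i]] <- scene$next_excl
    w$group_id[new_ids[i]] <- group_id
  }
  if (!is.null(g$pintos) && nrow(g$pintos)) {
    remap <- stats::setNames(new_ids, g$members)
    for (k in seq_len(nrow(g$pintos))) {
      row <- g$pintos[k, ]
      world_add_pinto(w, remap[[as.character(row[1L])]], row[2:3],
                      remap[[as.character(row[4L])]], row[5:6], row[7L])
    }
  }
  if (settle) {
    r <- 2 * max(sqrt(rowSums(g$offsets^2)) +
                   vapply(new_ids, function(i) body_bound_radius(w, i), 0))
    local_settle(scene, position, max(r, 10), max_steps = 30L)
  }
  new_ids
}

#' Lock a region of the scene
#'
#' Member physics is switched off (bodies frozen, internal collisions
#' disabled) and the region is represented by simplified colliders: member
#' centers are clustered by flat-kernel mean shift (8 nm cutoff) and each
#' cluster is enveloped by a Graham convex hull dilated by the cluster's
#' largest collider radius. The hulls exclude outside bodies.
#'
#' @param scene an [mp_scene].
#' @param instance_ids members.
#' @param bandwidth mean-shift bandwidth in nm.
#' @return lock region id (invisible no-op with a message if all members are
#'   already locked).
#' @export
mp_lock <- function(scene, instance_ids, bandwidth = 8) {
  ids <- resolve_selector(scene, instance_ids)
  w <- scene$world
  already <- w$lock_id[ids] > 0L
  if (all(already)) {
    message("all selected instances are already locked; no-op")
    return(invisible(w$lock_id[ids[1L]]))
  }
  if (any(already)) {
    message("skipping ", sum(already), " already-locked instance(s)")
    ids <- ids[!already]
  }
  scene$next_lock <- scene$next_lock + 1L
  lid <- scene$next_lock
  w$locked[ids] <- TRUE
  w$lock_id[ids] <- lid
  scene$lock_regions[[lid]] <- list(members = ids, hull_bodies = integer(0),
                                    bandwidth = bandwidth)
  relock_region(scene, lid)
  lid
}

# (re)compute the hull collider bodies for a lock region
relock_region <- function(scene, lid) {
  w <- scene$world
  lr <- scene$lock_regions[[lid]]
  if (is.null(lr)) return(invisible(NULL))
  for (hb in lr$hull_bodies) w$alive[hb] <- FALSE
  members <- lr$members[w$alive[lr$members]]
  lr$members <- members
  if (!length(members)) {
    scene$lock_regions[lid] <- list(NULL)
    return(invisible(NULL))
  }
  centers <- cbind(w$x[members], w$y[members])
  clusters <- mp_mean_shift(centers, bandwidth = lr$bandwidth)
  hull_bodies <- integer(0)
  th <- seq(0, 2 * pi, length.out = 17L)[-17L]
  for (cl in clusters) {
    mids <- members[cl]
    rmax <- max(vapply(mids, function(i) body_bound_radius(w, i), 0))
    pts <- do.call(rbind, lapply(mids, function(i)
      cbind(w$x[i] + rmax * cos(th), w$y[i] + rmax * sin(th))))
    hull <- mp_graham_hull(pts, class = "lock")
    hb <- world_add_body(w, fixtures = collider_to_fixtures(hull, role = "hull"),
                         position = c(0, 0), locked = TRUE,
                         name = sprintf(".lockhull-%d", lid))
    w$lock_id[hb] <- lid
    hull_bodies <- c(hull_bodies, hb)
  }
  lr$hull_bodies <- hull_bodies
  scene$lock_regions[[lid]] <- lr
  invisible(hull_bodies)
}

#' @rdname mp_lock
#' @param lock_id id returned by [mp_lock].
#' @export
mp_unlock <- function(scene, lock_id) {
  lr <- scene$lock_regions[[lock_id]]
  if (is.null(lr)) stop("unknown lock region")
  w <- scene$world
  for (hb in lr$hull_bodies) w$alive[hb] <- FALSE
  w$locked[lr$members] <- FALSE
  w$lock_id[lr$members] <- 0L
  scene$lock_regions[lock_id] <- list(NULL)
  invisible(lr$members)
}

#' Measure the distance between two instances
#'
#' Euclidean center-to-center distance in nm. The pair is registered so the
#' measurement can be re-read (live) after further simulation via
#' [mp_measurements].
#'
#' @param scene an [mp_scene].
#' @param a,b instance ids.
#' @export
mp_measure <- function(scene, a, b) {
  resolve_selector(scene, c(a, b))
  w <- scene$world
  key <- paste0(a, "-", b)
  scene$measurements[[key]] <- c(a = a, b = b)
  sqrt((w$x[a] - w$x[b])^2 + (w$y[a] - w$y[b])^2)
}

#' @rdname mp_measure
#' @return `mp_measurements`: data.frame of all registered pairs with their
#'   current distances.
#' @export
mp_measurements <- function(scene) {
  w <- scene$world
  if (!length(scene$measurements))
    return(data.frame(a = integer(0), b = integer(0), distance = numeric(0)))
  m <- do.call(rbind, scene$measurements)
  data.frame(a = m[, 1L], b = m[, 2L],
             distance = sqrt((w$x[m[, 1L]] - w$x[m[, 2L]])^2 +
                             (w$y[m[, 1L]] - w$y[m[, 2L]])^2),
             row.names = NULL)
}

#' Live instance count of an ingredient
#'
#' @param scene an [mp_scene].
#' @param ingredient_name palette name.
#' @export
mp_copy_number <- function(scene, ingredient_name) {
  get_ingredient(scene, ingredient_name)
  w <- scene$world
  sum(w$alive[seq_len(w$n)] & w$ingredient[seq_len(w$n)] == ingredient_name)
}

#' Register a background image
#'
#' Backgrounds (for example tomogram slices) are composited below the paint
#' in z-order, scaled by their own nm-per-pixel value, with user opacity and
#' rotation.
#'
#' @param scene an [mp_scene].
#' @param image RGB(A) array or a PNG path.
#' @param nm_per_pixel physical scale of the image (> 0).
#' @param opacity in `[0, 1]`.
#' @param rotation rad.
#' @param z z-order (lower = further back).
#' @return background id.
#' @export
mp_set_background <- function(scene, image, nm_per_pixel, opacity = 1,
                              rotation = 0, z = length(scene$backgrounds)) {
  if (nm_per_pixel <= 0) stop("bad scale: nm_per_pixel must be > 0")
  stopifnot(opacity >= 0, opacity <= 1)
  file <- if (is.character(image)) image else NA_character_
  if (is.character(image)) image <- png::readPNG(image)
  id <- length(scene$backgrounds) + 1L
  scene$backgrounds[[id]] <- list(image = image, nm_per_pixel = nm_per_pixel,
                                  opacity = opacity, rotation = rotation,
                                  z = z, file = file)
  id
}

#' Current interior polygon and area of a closed vesicle
#'
#' The compartment fill follows the membrane segments, so the polygon is
#' recomputed from the current segment positions ("stays dynamic").
#'
#' @param scene an [mp_scene].
#' @param chain_id membrane chain id.
#' @return list with `polygon` (current segment centers, clockwise) and
#'   `area` (absolute enclosed area, nm^2).
#' @export
mp_vesicle_polygon <- function(scene, chain_id) {
  w <- scene$world
  ch <- w$chains[[chain_id]]
  if (is.null(ch) || !isTRUE(ch$closed)) stop("not a closed membrane chain")
  mb <- ch$bodies[w$alive[ch$bodies]]
  poly <- cbind(w$x[mb], w$y[mb])
  list(polygon = poly, area = abs(mp_polygon_area(poly)))
}

#' Nudge a selection
#'
#' Rigidly translates an instance, a group, or a whole lock region
#' (including its hull colliders), re-anchoring any pins, then locally
#' settles the surroundings so displaced neighbours are pushed out.
#'
#' @param scene an [mp_scene].
#' @param delta length-2 translation in nm.
#' @param instances,group,lock_region exactly one selector.
#' @export
mp_nudge <- function(scene, delta, instances = NULL, group = NULL,
                     lock_region = NULL) {
  w <- scene$world
  ids <- if (!is.null(instances)) resolve_selector(scene, instances)
    else if (!is.null(group)) {
      g <- scene$groups[[group]]
      if (is.null(g)) stop("unknown group")
      g$members[w$alive[g$members]]
    } else if (!is.null(lock_region)) {
      lr <- scene$lock_regions[[lock_region]]
      if (is.null(lr)) stop("unknown lock region")
      c(lr$members, lr$hull_bodies)
    } else stop("give one of instances, group, lock_region")
  if (!length(ids)) stop("empty selection")
  w$x[ids] <- w$x[ids] + delta[1L]
  w$y[ids] <- w$y[ids] + delta[2L]
  repin <- ids[w$pinned[ids]]
  w$pin_x[repin] <- w$x[repin]
  w$pin_y[repin] <- w$y[repin]
  cen <- c(mean(w$x[ids]), mean(w$y[ids]))
  r <- max(sqrt((w$x[ids] - cen[1L])^2 + (w$y[ids] - cen[2L])^2) +
             vapply(ids, function(i) body_bound_radius(w, i), 0)) +
    sqrt(sum(delta^2)) + 5
  frozen_old <- w$frozen[ids]
  w$frozen[ids] <- TRUE
  local_settle(scene, cen, r, max_steps = 30L)
  w$frozen[ids] <- frozen_old
  invisible(cbind(x = w$x[ids], y = w$y[ids]))
}
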