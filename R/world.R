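# 2.5D physics world: layered rigid bodies, constraints, deterministic
# position-based solver (compiled core in src/solver.cpp).

CLASS_ID <- c(protein = 1L, fiber = 2L, membrane = 3L, lock = 4L)
ROLE_ID <- c(main = 0L, endcircle = 1L, wheel = 2L, box = 3L, spacer = 4L, hull = 5L)

#' Create an empty 2.5D physics world
#'
#' The world is a mutable environment holding rigid bodies on three depth
#' layers (0 = front, 1, 2), their collider fixtures, constraints, the
#' collision-pair toggles, and its own RNG stream (seeded from `rng_seed`,
#' independent of the caller's RNG).
#'
#' @param dt nominal step size (the solver is quasi-static; kept at 1).
#' @param solver_iterations Gauss-Seidel sweeps per step.
#' @param position_tolerance settle tolerance in nm.
#' @param rng_seed integer seed for diffusion and layer jumps.
#' @param diffusion_scale Brownian kick scale in nm^2 per step for a body of
#'   unit collider area; the per-body displacement variance is
#'   `diffusion_scale / sqrt(area)` so large assemblies jitter less.
#' @return An environment of class `mp_world`.
#' @export
mp_world <- function(dt = 1, solver_iterations = 8L, position_tolerance = 0.01,
                     rng_seed = 1L, diffusion_scale = 0.05) {
  stopifnot(dt > 0, solver_iterations >= 1L)
  w <- new.env(parent = emptyenv())
  w$n <- 0L
  w$x <- w$y <- w$angle <- numeric(0)
  w$layer <- w$excl <- w$lock_id <- w$chain <- w$subidx <- integer(0)
  w$rail_chain <- integer(0)   # membrane chain a railed protein rides (0 = none)
  w$alive <- w$locked <- w$pinned <- w$frozen <- logical(0)
  w$pin_x <- w$pin_y <- numeric(0)
  w$area <- w$k2 <- numeric(0)
  w$ingredient <- character(0)
  w$group_id <- integer(0)
  w$fixtures <- list()
  w$hinges <- matrix(numeric(0), ncol = 7L)  # a b ax ay bx by chain
  w$springs <- matrix(numeric(0), ncol = 5L) # a b rest stiff chain
  w$pintos <- matrix(numeric(0), ncol = 7L)  # a ax ay b bx by dist
  w$rails <- list()
  w$chains <- list()
  w$toggles <- c(protein_protein = TRUE, fiber_protein = TRUE,
                 fiber_fiber = TRUE, membrane_membrane = TRUE)
  w$config <- list(dt = dt, solver_iterations = as.integer(solver_iterations),
                   position_tolerance = position_tolerance,
                   rng_seed = as.integer(rng_seed),
                   diffusion_scale = diffusion_scale,
                   spring_stiffness = 0.5)
  w$rng <- NULL
  w$last_max_corr <- NA_real_
  class(w) <- "mp_world"
  with_world_rng(w, NULL)  # materialize the stream
  w
}

#' @export
print.mp_world <- function(x, ...) {
  cat(sprintf("<mp_world: %d bodies (%d alive), %d hinges, %d springs, %d pin-tos, %d rails>\n",
              x$n, sum(x$alive), nrow(x$hinges), nrow(x$springs),
              nrow(x$pintos), length(x$rails)))
  invisible(x)
}

# Evaluate expr under the world's private RNG stream.
with_world_rng <- function(w, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    w$rng <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (is.null(w$rng)) set.seed(w$config$rng_seed)
  else assign(".Random.seed", w$rng, globalenv())
  expr
}

# fixture constructor (body-local)
make_fixture <- function(kind, ox = 0, oy = 0, p1 = 0, p2 = 0, lang = 0,
                         class = "protein", role = "main", verts = NULL) {
  list(kind = kind, ox = ox, oy = oy, p1 = p1, p2 = p2, lang = lang,
       class = unname(CLASS_ID[[class]]), role = unname(ROLE_ID[[role]]),
       verts = verts)
}

collider_to_fixtures <- function(col, role = "main") {
  switch(col$variant,
    circle = list(make_fixture(0L, col$center[1L], col$center[2L],
                               p1 = col$radius, class = col$collision_class,
                               role = role)),
    rect = list(make_fixture(1L, col$center[1L], col$center[2L],
                             p1 = col$width / 2, p2 = col$height / 2,
                             lang = col$angle, class = col$collision_class,
                             role = role)),
    polygon = list(make_fixture(2L, class = col$collision_class, role = role,
                                verts = col$vertices)))
}

ingredient_fixtures <- function(ing) {
  fx <- collider_to_fixtures(ing$main_collider, role = "main")
  if (identical(ing$kind, "membrane_bound") && !is.null(ing$membrane_colliders)) {
    mc <- ing$membrane_colliders
    for (nm in c("exterior_box", "interior_box"))
      if (!is.null(mc[[nm]]))
        fx <- c(fx, collider_to_fixtures(mc[[nm]], role = "box"))
    for (wl in mc$wheels)
      fx <- c(fx, collider_to_fixtures(wl, role = "wheel"))
  }
  if (identical(ing$kind, "fiber") && !is.null(ing$end_circles)) {
    for (ec in ing$end_circles)
      fx <- c(fx, collider_to_fixtures(ec, role = "endcircle"))
  }
  fx
}

# Add a rigid body instantiating `ingredient` (or a bare collider for
# infrastructure bodies like lock hulls). Returns the body id.
world_add_body <- function(w, ingredient = NULL, position = c(0, 0), angle = 0,
                           layer = 0L, fixtures = NULL, locked = FALSE,
                           name = if (is.null(ingredient)) "" else ingredient$name) {
  if (!layer %in% 0:2) stop("layer must be 0, 1, or 2")
  id <- w$n + 1L
  w$n <- id
  w$x[id] <- position[1L]; w$y[id] <- position[2L]; w$angle[id] <- angle
  w$layer[id] <- as.integer(layer)
  w$alive[id] <- TRUE
  w$locked[id] <- locked
  w$pinned[id] <- FALSE
  w$frozen[id] <- FALSE
  w$pin_x[id] <- NA_real_; w$pin_y[id] <- NA_real_
  w$excl[id] <- 0L; w$lock_id[id] <- 0L
  w$chain[id] <- 0L; w$subidx[id] <- 0L
  w$rail_chain[id] <- 0L
  w$group_id[id] <- 0L
  w$ingredient[id] <- name
  fx <- if (!is.null(fixtures)) fixtures
        else if (!is.null(ingredient)) ingredient_fixtures(ingredient)
        else list()
  w$fixtures[[id]] <- fx
  main <- if (!is.null(ingredient)) ingredient$main_collider
          else if (length(fx) && !is.null(fx[[1L]]$verts))
            mp_polygon_collider(fx[[1L]]$verts)
          else NULL
  if (is.null(main)) {
    w$area[id] <- 1; w$k2[id] <- 1
  } else {
    w$area[id] <- collider_area(main)
    w$k2[id] <- switch(main$variant,
                       circle = main$radius^2 / 2,
                       rect = (main$width^2 + main$height^2) / 12,
                       polygon = collider_radius(main)^2 / 2)
  }
  id
}

world_alive_ids <- function(w) which(w$alive[seq_len(w$n)])

# Flatten the live world into the arrays the compiled solver consumes.
world_flatten <- function(w) {
  ids <- world_alive_ids(w)
  nb <- length(ids)
  map <- integer(w$n)          # id -> 0-based compact index (+1)
  map[ids] <- seq_len(nb)
  invm <- 1 / w$area[ids]
  invI <- 1 / (w$area[ids] * w$k2[ids])
  immobile <- w$locked[ids] | w$pinned[ids] | w$frozen[ids]
  invm[immobile] <- 0
  invI[immobile] <- 0

  fb <- integer(0); fk <- integer(0); fcl <- integer(0); fro <- integer(0)
  fox <- foy <- fp1 <- fp2 <- flang <- numeric(0)
  fpoly <- list()
  for (i in seq_len(nb)) {
    for (f in w$fixtures[[ids[i]]]) {
      fb <- c(fb, i - 1L); fk <- c(fk, f$kind)
      fox <- c(fox, f$ox); foy <- c(foy, f$oy)
      fp1 <- c(fp1, f$p1); fp2 <- c(fp2, f$p2); flang <- c(flang, f$lang)
      fcl <- c(fcl, f$class); fro <- c(fro, f$role)
      fpoly[[length(fb)]] <- if (is.null(f$verts)) matrix(0, 0L, 2L) else f$verts
    }
  }
  fixtures <- data.frame(body = fb, kind = fk, ox = fox, oy = foy,
                         p1 = fp1, p2 = fp2, lang = flang,
                         class = fcl, role = fro)

  remap_con <- function(m, cols) {
    if (!nrow(m)) return(m[, cols_keep(m, cols), drop = FALSE])
    ok <- rep(TRUE, nrow(m))
    for (cn in cols) ok <- ok & w$alive[m[, cn]]
    m <- m[ok, , drop = FALSE]
    for (cn in cols) m[, cn] <- map[m[, cn]] - 1L
    m
  }
  cols_keep <- function(m, cols) seq_len(ncol(m))
  hinges <- remap_con(w$hinges, c(1L, 2L))[, 1:6, drop = FALSE]
  springs <- remap_con(w$springs, c(1L, 2L))[, 1:4, drop = FALSE]
  pintos <- remap_con(w$pintos, c(1L, 4L))

  nchain <- length(w$chains)
  chain_len <- integer(nchain); chain_closed <- logical(nchain)
  for (ci in seq_len(nchain)) {
    ch <- w$chains[[ci]]
    if (is.null(ch)) { chain_len[ci] <- 0L; next }
    chain_len[ci] <- length(ch$bodies)
    chain_closed[ci] <- isTRUE(ch$closed)
  }

  rails <- list()
  for (r in w$rails) {
    if (is.null(r) || !w$alive[r$body]) next
    ch <- w$chains[[r$chain]]
    if (is.null(ch)) next
    cb <- ch$bodies[w$alive[ch$bodies]]
    if (length(cb) < 2L) next
    rails[[length(rails) + 1L]] <-
      list(body = map[r$body] - 1L, chain_bodies = as.integer(map[cb] - 1L),
           closed = isTRUE(ch$closed), offset = r$offset, rotation = r$rotation)
  }

  sd_pos <- sqrt(w$config$diffusion_scale / sqrt(w$area[ids]))
  sd_ang <- sd_pos / sqrt(w$area[ids])

  list(ids = ids, invm = invm, invI = invI, fixtures = fixtures,
       fpoly = fpoly, hinges = hinges, springs = springs, pintos = pintos,
       rails = rails, chain_len = chain_len, chain_closed = chain_closed,
       sd_pos = sd_pos, sd_ang = sd_ang)
}

#' Advance the world
#'
#' Runs `n_steps` solver steps: an optional Brownian kick, then
#' `solver_iterations` sweeps of overlap resolution and constraint
#' projection. Locked, pinned, and frozen bodies are infinite-mass and do not
#' move. Deterministic given the world's seed.
#'
#' @param world an [mp_world].
#' @param n_steps number of steps.
#' @param diffuse apply diffusion kicks (uses the world's RNG stream).
#' @param collisions enable pairwise overlap resolution.
#' @return the world, invisibly; `world$last_max_corr` holds the largest
#'   position correction of the final step.
#' @export
mp_step <- function(world, n_steps = 1L, diffuse = FALSE, collisions = TRUE) {
  w <- world
  fl <- world_flatten(w)
  ids <- fl$ids
  if (!length(ids)) { w$last_max_corr <- 0; return(invisible(w)) }
  run <- function() {
    .pbd_step(w$x[ids], w$y[ids], w$angle[ids],
              w$layer[ids], fl$invm, fl$invI,
              w$excl[ids], w$lock_id[ids], w$chain[ids], w$subidx[ids],
              w$rail_chain[ids],
              fl$chain_len, fl$chain_closed,
              fl$fixtures, fl$fpoly,
              fl$hinges, fl$springs, fl$pintos, fl$rails,
              unname(w$toggles),
              as.integer(n_steps), w$config$solver_iterations,
              diffuse, fl$sd_pos, fl$sd_ang, collisions)
  }
  res <- if (diffuse) with_world_rng(w, run()) else run()
  w$x[ids] <- res$x; w$y[ids] <- res$y; w$angle[ids] <- res$angle
  w$last_max_corr <- res$max_corr
  invisible(w)
}

#' Diffuse free bodies
#'
#' Convenience wrapper: [mp_step] with Brownian kicks enabled. Each unlocked,
#' unpinned body receives a Gaussian displacement with variance
#' `diffusion_scale / sqrt(collider area)` plus a small angular kick,
#' reproducibly from the world's seed.
#'
#' @inheritParams mp_step
#' @export
mp_diffuse <- function(world, n_steps = 1L) {
  mp_step(world, n_steps = n_steps, diffuse = TRUE)
}

#' Settle the world to rest
#'
#' Steps without diffusion until the largest position correction drops below
#' the configured tolerance or `max_steps` is reached.
#'
#' @param world an [mp_world].
#' @param max_steps step cap.
#' @param tol override of `position_tolerance`.
#' @return the world, invisibly; attribute-free (`world$last_max_corr`
#'   reports the residual).
#' @export
mp_settle <- function(world, max_steps = 200L, tol = NULL) {
  tol <- tol %||% world$config$position_tolerance
  for (i in seq_len(max_steps)) {
    mp_step(world, 1L)
    if (world$last_max_corr < tol) break
  }
  invisible(world)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Can two bodies collide?
#'
#' Implements the layer-collision-matrix predicate: false if the bodies share
#' a lock region, if the layers differ and one of them is the front layer, if
#' they carry the same group stamp, or if no fixture class pair is enabled by
#' the collision toggles (protein-protein, fiber-protein, fiber-fiber,
#' membrane-membrane; protein-membrane and fiber-membrane are off by design;
#' lock hulls collide with everything). Symmetric by construction.
#'
#' @param world an [mp_world].
#' @param a,b body ids.
#' @return logical flag.
#' @export
mp_collidable <- function(world, a, b) {
  w <- world
  if (a == b) return(FALSE)
  if (w$lock_id[a] > 0L && w$lock_id[a] == w$lock_id[b]) return(FALSE)
  if ((w$rail_chain[a] > 0L && w$rail_chain[a] == w$chain[b]) ||
      (w$rail_chain[b] > 0L && w$rail_chain[b] == w$chain[a])) return(FALSE)
  if (w$layer[a] != w$layer[b] && (w$layer[a] == 0L || w$layer[b] == 0L))
    return(FALSE)
  if (w$excl[a] > 0L && w$excl[a] == w$excl[b]) return(FALSE)
  if (w$chain[a] > 0L && w$chain[a] == w$chain[b]) {
    d <- abs(w$subidx[a] - w$subidx[b])
    ch <- w$chains[[w$chain[a]]]
    if (isTRUE(ch$closed)) d <- min(d, length(ch$bodies) - d)
    if (d <= 1L) return(FALSE)
  }
  ca <- unique(vapply(w$fixtures[[a]], `[[`, 0L, "class"))
  cb <- unique(vapply(w$fixtures[[b]], `[[`, 0L, "class"))
  tg <- w$toggles
  for (c1 in ca) for (c2 in cb) {
    if (c1 == 4L || c2 == 4L) return(TRUE)
    lo <- min(c1, c2); hi <- max(c1, c2)
    ok <- if (lo == 1L && hi == 1L) tg[["protein_protein"]]
          else if (lo == 1L && hi == 2L) tg[["fiber_protein"]]
          else if (lo == 2L && hi == 2L) tg[["fiber_fiber"]]
          else if (lo == 3L && hi == 3L) tg[["membrane_membrane"]]
          else FALSE
    if (ok) return(TRUE)
  }
  FALSE
}

#' Toggle collision pairs
#'
#' @param world an [mp_world].
#' @param protein_protein,fiber_protein,fiber_fiber,membrane_membrane
#'   logical or NULL (leave unchanged).
#' @export
mp_set_collisions <- function(world, protein_protein = NULL,
                              fiber_protein = NULL, fiber_fiber = NULL,
                              membrane_membrane = NULL) {
  vals <- list(protein_protein = protein_protein, fiber_protein = fiber_protein,
               fiber_fiber = fiber_fiber, membrane_membrane = membrane_membrane)
  for (nm in names(vals)) if (!is.null(vals[[nm]]))
    world$toggles[[nm]] <- isTRUE(vals[[nm]])
  invisible(world)
}

# world-space geometry of a collider posed at (position, angle)
collider_world_geo <- function(col, position = c(0, 0), angle = 0) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  switch(col$variant,
    circle = list(kind = 0L,
                  geo = c(position + R %*% col$center, col$radius)),
    rect = {
      cen <- position + as.numeric(R %*% col$center)
      a <- angle + col$angle
      ex <- c(cos(a), sin(a)) * col$width / 2
      ey <- c(-sin(a), cos(a)) * col$height / 2
      list(kind = 1L, geo = rbind(cen - ex - ey, cen + ex - ey,
                                  cen + ex + ey, cen - ex + ey))
    },
    polygon = list(kind = 1L,
                   geo = t(position + R %*% t(col$vertices))))
}

#' Minimum-translation resolution of one collider pair
#'
#' Narrow-phase primitive: computes the minimum translation vector separating
#' two posed colliders and splits it by inverse mass (equal masses: 50/50;
#' an infinite-mass partner takes none of the correction). Rotation is never
#' changed by overlap resolution.
#'
#' @param col_a,col_b `mp_collider` objects (body-local coordinates).
#' @param pose_a,pose_b lists `list(position = c(x, y), angle = rad)`.
#' @param invmass_a,invmass_b inverse masses (0 = immobile).
#' @return list with `overlap` (depth, 0 when separated), `axis` (unit vector
#'   from a to b) and `correction_a`, `correction_b` (displacements to apply).
#' @export
mp_resolve_pair <- function(col_a, pose_a, col_b, pose_b,
                            invmass_a = 1, invmass_b = 1) {
  ga <- collider_world_geo(col_a, pose_a$position, pose_a$angle %||% 0)
  gb <- collider_world_geo(col_b, pose_b$position, pose_b$angle %||% 0)
  m <- .mtv_geo(ga$kind, ga$geo, gb$kind, gb$geo)
  depth <- m[3L]
  if (depth <= 0 || invmass_a + invmass_b <= 0)
    return(list(overlap = max(depth, 0), axis = m[1:2],
                correction_a = c(0, 0), correction_b = c(0, 0)))
  sa <- depth * invmass_a / (invmass_a + invmass_b)
  sb <- depth * invmass_b / (invmass_a + invmass_b)
  list(overlap = depth, axis = m[1:2],
       correction_a = -m[1:2] * sa, correction_b = m[1:2] * sb)
}

# constraint registration helpers ------------------------------------------

world_add_hinge <- function(w, a, b, anchor_a, anchor_b, chain = 0L) {
  w$hinges <- rbind(w$hinges, c(a, b, anchor_a, anchor_b, chain))
  nrow(w$hinges)
}

world_add_spring <- function(w, a, b, rest,
                             stiffness = w$config$spring_stiffness,
                             chain = 0L) {
  w$springs <- rbind(w$springs, c(a, b, rest, stiffness, chain))
  nrow(w$springs)
}

world_add_pinto <- function(w, a, local_a, b, local_b, dist) {
  w$pintos <- rbind(w$pintos, c(a, local_a, b, local_b, dist))
  nrow(w$pintos)
}

world_add_rail <- function(w, body, chain, offset, rotation) {
  w$rails[[length(w$rails) + 1L]] <-
    list(body = body, chain = chain, offset = offset, rotation = rotation)
  # the rail projection subsumes the wheel-on-rail contact: a railed protein
  # does not also collide with its own membrane chain (it would fight the
  # projection and act as a motor); other membranes still collide normally
  w$rail_chain[body] <- chain
  length(w$rails)
}

#' Pairwise overlap depth between two live bodies
#'
#' Maximum penetration over all collidable fixture pairs of the two bodies;
#' 0 when separated. Used by the no-overlap invariant tests.
#'
#' @param world an [mp_world].
#' @param a,b body ids.
#' @export
mp_pair_overlap <- function(world, a, b) {
  w <- world
  if (!mp_collidable(w, a, b)) return(0)
  geo_of <- function(id, f) {
    pos <- c(w$x[id], w$y[id]); th <- w$angle[id]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    if (f$kind == 0L) {
      list(kind = 0L, geo = c(pos + R %*% c(f$ox, f$oy), f$p1))
    } else if (f$kind == 1L) {
      cen <- pos + as.numeric(R %*% c(f$ox, f$oy))
      aa <- th + f$lang
      ex <- c(cos(aa), sin(aa)) * f$p1
      ey <- c(-sin(aa), cos(aa)) * f$p2
      list(kind = 1L, geo = rbind(cen - ex - ey, cen + ex - ey,
                                  cen + ex + ey, cen - ex + ey))
    } else {
      list(kind = 1L, geo = t(pos + R %*% t(f$verts)))
    }
  }
  cls_ok <- function(c1, c2) {
    if (c1 == 4L || c2 == 4L) return(TRUE)
    lo <- min(c1, c2); hi <- max(c1, c2)
    if (lo == 1L && hi == 1L) return(w$toggles[["protein_protein"]])
    if (lo == 1L && hi == 2L) return(w$toggles[["fiber_protein"]])
    if (lo == 2L && hi == 2L) return(w$toggles[["fiber_fiber"]])
    if (lo == 3L && hi == 3L) return(w$toggles[["membrane_membrane"]])
    FALSE
  }
  worst <- 0
  for (fa in w$fixtures[[a]]) for (fb in w$fixtures[[b]]) {
    if (!cls_ok(fa$class, fb$class)) next
    ga <- geo_of(a, fa); gb <- geo_of(b, fb)
    m <- .mtv_geo(ga$kind, ga$geo, gb$kind, gb$geo)
    worst <- max(worst, m[3L])
  }
  worst
}
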