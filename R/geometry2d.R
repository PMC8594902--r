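#' @useDynLib mesopaint, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- Contour ---------------------------------------------------------------

#' Create a 2D contour
#'
#' A contour is an ordered set of 2D vertices in nanometres, Y-up, usually
#' centered on its vertex centroid. Closed contours must be simple
#' (non-self-intersecting).
#'
#' @param vertices numeric n x 2 matrix of (x, y) points in nm.
#' @param closed logical; is the contour a closed polygon?
#' @param validate logical; run the (O(n^2)) simplicity check for closed
#'   contours. Internal callers that construct provably simple contours may
#'   disable it.
#' @return An object of class `mp_contour`.
#' @export
mp_contour <- function(vertices, closed = TRUE, validate = TRUE) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stop("vertices must be a numeric n x 2 matrix")
  if (nrow(vertices) >= 2L) {
    d <- sqrt(rowSums((vertices - vertices[c(2:nrow(vertices), 1L), , drop = FALSE])^2))
    if (!closed) d <- d[-length(d)]
    keep <- c(TRUE, d[-length(d)] > 1e-12)
    # drop consecutive duplicates (and, when closed, a last point equal to the first)
    if (closed && nrow(vertices) > 1L &&
        sqrt(sum((vertices[1L, ] - vertices[nrow(vertices), ])^2)) <= 1e-12)
      keep[nrow(vertices)] <- FALSE
    vertices <- vertices[keep, , drop = FALSE]
  }
  if (nrow(vertices) < 3L) stop("a contour needs at least 3 vertices")
  dimnames(vertices) <- NULL
  if (closed && validate && !is_simple_polygon(vertices))
    stop("closed contour is self-intersecting")
  structure(list(vertices = vertices, closed = closed), class = "mp_contour")
}

#' @export
print.mp_contour <- function(x, ...) {
  cat(sprintf("<mp_contour: %d vertices, %s>\n", nrow(x$vertices),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# segment intersection test, proper crossings only (shared endpoints allowed)
segments_cross <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(v[idx[i], ], v[idx[i + 1L], ],
                         v[idx[j], ], v[idx[j + 1L], ])) return(FALSE)
    }
  }
  TRUE
}

shoelace_sum <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])
}

#' Signed and absolute polygon area
#'
#' Shoelace area of a closed contour; positive for counter-clockwise
#' traversal in the Y-up convention.
#'
#' @param contour an [mp_contour] (or bare vertex matrix).
#' @return signed area in nm^2.
#' @export
mp_polygon_area <- function(contour) {
  v <- if (inherits(contour, "mp_contour")) contour$vertices else as.matrix(contour)
  shoelace_sum(v) / 2
}

#' Polygon winding orientation
#'
#' @param contour a closed [mp_contour].
#' @return `"counter-clockwise"` or `"clockwise"` (Y-up shoelace sign).
#' @export
mp_orientation <- function(contour) {
  v <- if (inherits(contour, "mp_contour")) contour$vertices else as.matrix(contour)
  s <- shoelace_sum(v)
  if (abs(s) < 1e-12) stop("degenerate polygon: zero area")
  if (s > 0) "counter-clockwise" else "clockwise"
}

# ---- Contour extraction ----------------------------------------------------

#' Extract the outer contour of an opacity mask
#'
#' Traces the 0.5 iso-level of the alpha channel (marching squares with
#' linear interpolation on the zero-padded grid), keeps the largest closed
#' component, converts pixel units to nm, and recenters on the vertex
#' centroid. Output is counter-clockwise in the Y-up frame (image row 1 is
#' the top of the sprite). Holes and secondary blobs are ignored.
#'
#' @param alpha_mask numeric matrix (rows = image rows top-to-bottom) of
#'   opacities in `[0, 1]`, or a logical matrix.
#' @param nm_per_pixel physical scale, nm per pixel (> 0).
#' @return An [mp_contour], with attributes `nm_per_pixel` and
#'   `centroid_px` (the pre-centering centroid in pixel coordinates).
#' @export
mp_extract_contour <- function(alpha_mask, nm_per_pixel) {
  if (!is.numeric(nm_per_pixel) || length(nm_per_pixel) != 1L || nm_per_pixel <= 0)
    stop("invalid argument: nm_per_pixel must be a positive scalar")
  m <- alpha_mask
  if (is.logical(m)) m <- m * 1
  m <- as.matrix(m)
  if (!any(m >= 0.5)) stop("no opaque region in mask")
  nr <- nrow(m); nc <- ncol(m)
  # grid in (x = column, y = row-flipped) with a zero pad so contours close
  z <- matrix(0, nc + 2L, nr + 2L)
  z[2:(nc + 1L), 2:(nr + 1L)] <- t(m[nr:1, , drop = FALSE])
  cl <- grDevices::contourLines(x = 0:(nc + 1L), y = 0:(nr + 1L), z = z,
                                levels = 0.5)
  if (!length(cl)) stop("no opaque region in mask")
  areas <- vapply(cl, function(p) abs(shoelace_sum(cbind(p$x, p$y)) / 2), 0)
  best <- cl[[which.max(areas)]]
  v <- cbind(best$x, best$y)
  if (nrow(v) > 1L && sqrt(sum((v[1L, ] - v[nrow(v), ])^2)) < 1e-9)
    v <- v[-nrow(v), , drop = FALSE]
  if (shoelace_sum(v) < 0) v <- v[nrow(v):1, , drop = FALSE]
  v <- v * nm_per_pixel
  centroid <- colMeans(v)
  v <- sweep(v, 2L, centroid)
  ct <- mp_contour(v, closed = TRUE, validate = FALSE)
  attr(ct, "nm_per_pixel") <- nm_per_pixel
  attr(ct, "centroid_px") <- centroid / nm_per_pixel
  ct
}

# ---- Eigen frame -----------------------------------------------------------

#' Principal-axis frame of a contour
#'
#' Eigen-decomposes the 2 x 2 covariance matrix of the contour vertices.
#' The major axis comes first and carries a deterministic sign: non-negative
#' X component, ties broken toward non-negative Y. The minor axis is the
#' major axis rotated +90 degrees.
#'
#' @param contour an [mp_contour].
#' @return `mp_eigen_frame`: list with `center` (vertex centroid, nm),
#'   `axes` (2 x 2 matrix, columns = major then minor unit vectors) and
#'   `values` (eigenvalues, nm^2, major first).
#' @export
mp_eigen_frame <- function(contour) {
  v <- if (inherits(contour, "mp_contour")) contour$vertices else as.matrix(contour)
  if (nrow(v) < 3L) stop("need at least 3 vertices")
  center <- colMeans(v)
  d <- sweep(v, 2L, center)
  cv <- crossprod(d) / nrow(d)
  e <- eigen(cv, symmetric = TRUE)
  values <- e$values
  if (values[2L] < 1e-12) {
    warning("degenerate (near-collinear) contour: minor eigenvalue clamped")
    values[2L] <- 1e-12
  }
  major <- e$vectors[, 1L]
  s <- if (abs(major[1L]) > 1e-12) sign(major[1L]) else sign(major[2L])
  if (s == 0) s <- 1
  major <- major * s
  minor <- c(-major[2L], major[1L])
  structure(list(center = center,
                 axes = cbind(major = major, minor = minor),
                 values = values),
            class = "mp_eigen_frame")
}

# ---- Collider shapes -------------------------------------------------------

mp_circle <- function(center, radius, class = "protein") {
  stopifnot(radius > 0)
  structure(list(variant = "circle", center = as.numeric(center),
                 radius = radius, collision_class = class),
            class = "mp_collider")
}

mp_rect <- function(center, width, height, angle, class = "protein") {
  stopifnot(width > 0, height > 0)
  structure(list(variant = "rect", center = as.numeric(center),
                 width = width, height = height, angle = angle,
                 collision_class = class),
            class = "mp_collider")
}

mp_polygon_collider <- function(vertices, class = "lock") {
  vertices <- as.matrix(vertices)
  stopifnot(nrow(vertices) >= 3L)
  structure(list(variant = "polygon", vertices = vertices,
                 collision_class = class),
            class = "mp_collider")
}

#' @export
print.mp_collider <- function(x, ...) {
  desc <- switch(x$variant,
    circle = sprintf("circle r=%.3g nm at (%.3g, %.3g)", x$radius,
                     x$center[1L], x$center[2L]),
    rect = sprintf("rect %.3g x %.3g nm at (%.3g, %.3g), angle %.3g rad",
                   x$width, x$height, x$center[1L], x$center[2L], x$angle),
    polygon = sprintf("polygon, %d vertices", nrow(x$vertices)))
  cat(sprintf("<mp_collider: %s, class %s>\n", desc, x$collision_class))
  invisible(x)
}

collider_area <- function(col) {
  switch(col$variant,
         circle = pi * col$radius^2,
         rect = col$width * col$height,
         polygon = abs(mp_polygon_area(col$vertices)))
}

# bounding-circle radius about the collider's own center
collider_radius <- function(col) {
  switch(col$variant,
         circle = col$radius,
         rect = sqrt(col$width^2 + col$height^2) / 2,
         polygon = {
           c0 <- colMeans(col$vertices)
           sqrt(max(rowSums(sweep(col$vertices, 2L, c0)^2)))
         })
}

#' Choose the main proxy collider for a contour
#'
#' If the ratio of the covariance eigenvalues is below `threshold` the shape
#' is treated as isotropic and a circle collider is used; otherwise an
#' oriented rectangle aligned with the eigen frame. Collider sizes come from
#' the projected contour extents along the eigenvectors: the circle radius is
#' the maximum projected extent on the major axis, the rectangle width/height
#' are the full extents on the major/minor axes.
#'
#' @param frame an `mp_eigen_frame` of `contour`.
#' @param contour the [mp_contour] being summarized.
#' @param threshold eigenvalue comparison threshold (default 1.15).
#' @param class collision class tag for the resulting collider.
#' @param mode `"ratio"` (default) compares `lambda1/lambda2` with
#'   `threshold`; `"difference"` compares `lambda1 - lambda2` (nm^2), kept
#'   for completeness but not scale-invariant.
#' @return An `mp_collider` (circle or rect variant).
#' @export
mp_select_collider <- function(frame, contour, threshold = 1.15,
                               class = "protein",
                               mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  v <- if (inherits(contour, "mp_contour")) contour$vertices else as.matrix(contour)
  proj <- sweep(v, 2L, frame$center) %*% frame$axes
  iso <- if (mode == "ratio") {
    frame$values[1L] / frame$values[2L] < threshold
  } else {
    frame$values[1L] - frame$values[2L] < threshold
  }
  if (iso) {
    mp_circle(frame$center, radius = max(abs(proj[, 1L])), class = class)
  } else {
    w <- diff(range(proj[, 1L]))
    h <- diff(range(proj[, 2L]))
    ang <- atan2(frame$axes[2L, 1L], frame$axes[1L, 1L])
    if (h > w) { tmp <- w; w <- h; h <- tmp; ang <- ang + pi / 2 }
    mp_rect(frame$center, width = w, height = h, angle = ang, class = class)
  }
}

# ---- Graham hull -----------------------------------------------------------

#' Convex hull by Graham scan
#'
#' @param points numeric n x 2 matrix (n >= 3, not all collinear).
#' @param class collision class for the resulting polygon collider.
#' @return An `mp_collider` polygon: convex, counter-clockwise,
#'   minimal vertex set (collinear boundary points removed).
#' @export
mp_graham_hull <- function(points, class = "lock") {
  p <- unique(as.matrix(points))
  if (nrow(p) < 3L) stop("degenerate hull: fewer than 3 distinct points")
  i0 <- order(p[, 2L], p[, 1L])[1L]
  pivot <- p[i0, ]
  rest <- p[-i0, , drop = FALSE]
  ang <- atan2(rest[, 2L] - pivot[2L], rest[, 1L] - pivot[1L])
  d <- rowSums(sweep(rest, 2L, pivot)^2)
  rest <- rest[order(ang, d), , drop = FALSE]
  stack <- list(pivot, rest[1L, ])
  for (i in 2:nrow(rest)) {
    pt <- rest[i, ]
    while (length(stack) >= 2L) {
      a <- stack[[length(stack) - 1L]]
      b <- stack[[length(stack)]]
      if (cross2(b - a, pt - a) <= 1e-12) {
        stack[[length(stack)]] <- NULL   # pop right turns and collinears
      } else break
    }
    stack[[length(stack) + 1L]] <- pt
  }
  if (length(stack) < 3L) stop("degenerate hull: collinear points")
  mp_polygon_collider(do.call(rbind, stack), class = class)
}

#' Test whether points lie inside or on a convex polygon
#'
#' @param points n x 2 matrix.
#' @param hull counter-clockwise convex polygon (matrix or polygon collider).
#' @param tol slack in nm.
#' @return logical vector.
#' @export
mp_in_convex <- function(points, hull, tol = 1e-9) {
  v <- if (inherits(hull, "mp_collider")) hull$vertices else as.matrix(hull)
  p <- as.matrix(points)
  if (ncol(p) != 2L) p <- matrix(p, ncol = 2L)
  n <- nrow(v)
  ok <- rep(TRUE, nrow(p))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    s <- (b[1L] - a[1L]) * (p[, 2L] - a[2L]) - (b[2L] - a[2L]) * (p[, 1L] - a[1L])
    ok <- ok & (s >= -tol)
  }
  ok
}

# ---- Mean-shift clustering -------------------------------------------------

#' Flat-kernel mean-shift clustering of 2D points
#'
#' Each point ascends to the mean of the points within `bandwidth` of its
#' current position until the shift falls below `tol` nm or `max_iter`
#' iterations. Modes closer than `bandwidth / 2` are merged; every point is
#' assigned to exactly one cluster.
#'
#' @param points n x 2 matrix (n >= 1).
#' @param bandwidth flat kernel window radius in nm (default 8, the lock
#'   tool's clustering cutoff).
#' @param tol convergence tolerance in nm.
#' @param max_iter iteration cap.
#' @return list of integer index vectors, one per cluster.
#' @export
mp_mean_shift <- function(points, bandwidth = 8, tol = 0.01, max_iter = 200L) {
  p <- as.matrix(points)
  if (length(p) == 2L && ncol(p) == 1L) p <- matrix(p, ncol = 2L)
  n <- nrow(p)
  if (n < 1L) stop("need at least one point")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  modes <- p
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    d2 <- outer(rowSums(modes[active, , drop = FALSE]^2), rowSums(p^2), "+") -
      2 * modes[active, , drop = FALSE] %*% t(p)
    within <- d2 <= bandwidth^2 + 1e-12
    newm <- within %*% p / rowSums(within)
    shift <- sqrt(rowSums((newm - modes[active, , drop = FALSE])^2))
    modes[active, ] <- newm
    act <- which(active)
    active[act[shift < tol]] <- FALSE
  }
  # merge modes within bandwidth/2 (greedy, in index order for determinism)
  cluster <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (!is.null(centers)) {
      dd <- sqrt(rowSums(sweep(centers, 2L, modes[i, ])^2))
      k <- which(dd < bandwidth / 2)
      if (length(k)) { cluster[i] <- k[1L]; assigned <- TRUE }
    }
    if (!assigned) {
      centers <- rbind(centers, modes[i, ])
      cluster[i] <- nrow(centers)
    }
  }
  unname(split(seq_len(n), cluster))
}

# ---- Triangulation ---------------------------------------------------------

point_in_triangle <- function(p, a, b, c, eps = 1e-12) {
  d1 <- cross2(b - a, p - a)
  d2 <- cross2(c - b, p - b)
  d3 <- cross2(a - c, p - c)
  (d1 >= -eps & d2 >= -eps & d3 >= -eps)
}

#' Ear-clipping triangulation of a simple polygon
#'
#' Classic ear clipping: repeatedly remove a convex vertex whose triangle
#' contains no other remaining vertex. Works for any simple polygon
#' (convex or concave), either winding.
#'
#' @param polygon a closed [mp_contour] or vertex matrix.
#' @return list of `n - 2` triangles (3 x 2 matrices); total area equals the
#'   polygon area to 1e-6 relative.
#' @export
mp_triangulate <- function(polygon) {
  v <- if (inherits(polygon, "mp_contour")) polygon$vertices else as.matrix(polygon)
  n <- nrow(v)
  if (n < 3L) stop("need at least 3 vertices")
  if (shoelace_sum(v) < 0) v <- v[n:1, , drop = FALSE]   # work in CCW
  idx <- seq_len(n)
  tris <- vector("list", n - 2L)
  k <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      ip <- idx[if (i == 1L) m else i - 1L]
      ic <- idx[i]
      inx <- idx[if (i == m) 1L else i + 1L]
      a <- v[ip, ]; b <- v[ic, ]; cc <- v[inx, ]
      if (cross2(b - a, cc - a) <= 1e-12) next   # reflex or degenerate
      others <- setdiff(idx, c(ip, ic, inx))
      blocked <- FALSE
      for (j in others) {
        if (point_in_triangle(v[j, ], a, b, cc)) { blocked <- TRUE; break }
      }
      if (blocked) next
      k <- k + 1L
      tris[[k]] <- rbind(a, b, cc)
      idx <- idx[-i]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L)
        stop("triangulation failed: polygon is self-intersecting or degenerate")
    } else guard <- 0L
  }
  k <- k + 1L
  tris[[k]] <- v[idx, , drop = FALSE]
  dimnames(tris[[k]]) <- NULL
  lapply(tris[seq_len(k)], function(t) { dimnames(t) <- NULL; t })
}

triangle_area <- function(t) abs(cross2(t[2L, ] - t[1L, ], t[3L, ] - t[1L, ])) / 2

# point-in-polygon for arbitrary simple polygons (even-odd rule)
point_in_polygon <- function(p, v) {
  n <- nrow(v)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((v[i, 2L] > p[2L]) != (v[j, 2L] > p[2L]) &&
        p[1L] < (v[j, 1L] - v[i, 1L]) * (p[2L] - v[i, 2L]) /
          (v[j, 2L] - v[i, 2L]) + v[i, 1L])
      inside <- !inside
    j <- i
  }
  inside
}
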