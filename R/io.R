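# Readers/writers: recipe JSON, line-oriented scene files, zip bundles,
# PDB/mmCIF structures, PNG sprites, deterministic raster rendering.

FORMAT_VERSION <- 1L

rgb_to_hex <- function(col) grDevices::rgb(col[1L], col[2L], col[3L])
hex_to_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255

# best-effort alias map for historical CellPACK-style recipe keys
RECIPE_ALIASES <- c(sprite = "sprite", file = "sprite", png = "sprite",
                    image = "sprite", pixels = "nm_per_pixel",
                    nmPerPixel = "nm_per_pixel", type = "kind",
                    ingtype = "kind", molarity = "molarity")

canon_keys <- function(def) {
  nm <- names(def)
  hit <- nm %in% names(RECIPE_ALIASES) & !RECIPE_ALIASES[nm] %in% nm
  if (any(hit)) {
    mapped <- RECIPE_ALIASES[nm[hit]]
    message("recipe reader: mapping legacy key(s) ",
            paste(nm[hit], "->", mapped, collapse = ", "))
    names(def)[hit] <- mapped
  }
  def
}

ingredient_def <- function(ing, sprite_file) {
  def <- list(name = ing$name, kind = ing$kind,
              sprite = sprite_file,
              nm_per_pixel = ing$sprite$nm_per_pixel,
              color = rgb_to_hex(ing$color))
  if (!is.null(ing$binding))
    def$binding <- ing$binding[c("thickness", "surface_offset", "padding", "rotation")]
  if (!is.null(ing$fiber))
    def$fiber <- list(spacing = ing$fiber$spacing,
                      subunit_rotation = ing$fiber$subunit_rotation,
                      n_springs = ing$fiber$n_springs,
                      angle_limit = ing$fiber$angle_limit)
  def
}

ingredient_from_def <- function(def, dir, compartment) {
  def <- canon_keys(def)
  for (k in c("name", "kind", "sprite", "nm_per_pixel"))
    if (is.null(def[[k]]))
      stop(sprintf("recipe parse error at ingredient '%s': missing key '%s'",
                   def$name %||% "?", k))
  sprite_path <- file.path(dir, def$sprite)
  if (!file.exists(sprite_path))
    stop(sprintf("resolution error: sprite file '%s' not found", def$sprite))
  binding <- if (!is.null(def$binding))
    mp_binding(def$binding$thickness, def$binding$surface_offset %||% 0,
               def$binding$padding %||% 0.5, def$binding$rotation %||% 0)
  fiber <- if (!is.null(def$fiber))
    mp_fiber_spec(def$fiber$spacing, def$fiber$subunit_rotation %||% 0,
                  def$fiber$n_springs %||% 3L, def$fiber$angle_limit)
  mp_ingredient_from_image(sprite_path, def$nm_per_pixel, def$kind,
                           binding = binding, fiber = fiber,
                           name = def$name,
                           color = if (is.null(def$color)) c(0.62, 0.66, 0.74)
                                   else hex_to_rgb(def$color),
                           compartment = compartment)
}

#' Load a recipe
#'
#' Recipes are JSON dictionaries of compartments, each holding ingredient
#' definitions (kind, sprite file, scale, color, binding/fiber parameters);
#' see the format notes in `docs/formats.md`. Sprite files resolve relative
#' to the recipe file. Unknown keys are preserved and written back on save;
#' a few legacy CellPACK-style key spellings are accepted with a message.
#'
#' @param path recipe JSON file.
#' @return `mp_recipe`: list with `name`, `defs` (the parsed, canonicalized
#'   definitions), `ingredients` (named list of [mp_ingredient]), `dir`.
#' @export
mp_load_recipe <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("recipe parse error in '%s': %s", path,
                                 conditionMessage(e))))
  if (is.null(raw$compartments))
    stop("recipe parse error at $.compartments: missing")
  ingredients <- list()
  for (comp in raw$compartments) {
    if (is.null(comp$name)) stop("recipe parse error: compartment without name")
    for (def in comp$ingredients) {
      ing <- ingredient_from_def(def, dirname(path), comp$name)
      if (!is.null(ingredients[[ing$name]]))
        stop(sprintf("duplicate ingredient name '%s'", ing$name))
      ingredients[[ing$name]] <- ing
    }
  }
  structure(list(name = raw$name %||% "recipe", defs = raw,
                 ingredients = ingredients, dir = dirname(path)),
            class = "mp_recipe")
}

#' @rdname mp_load_recipe
#' @param recipe an `mp_recipe`.
#' @param path output JSON path; referenced sprite PNGs are copied/written
#'   next to it so the recipe stays resolvable.
#' @export
mp_save_recipe <- function(recipe, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  defs <- recipe$defs
  for (ci in seq_along(defs$compartments)) {
    for (ii in seq_along(defs$compartments[[ci]]$ingredients)) {
      def <- canon_keys(defs$compartments[[ci]]$ingredients[[ii]])
      src <- file.path(recipe$dir, def$sprite)
      dst <- file.path(dirname(path), def$sprite)
      if (!file.exists(dst)) {
        dir.create(dirname(dst), showWarnings = FALSE, recursive = TRUE)
        if (file.exists(src)) file.copy(src, dst)
        else {
          ing <- recipe$ingredients[[def$name]]
          if (!is.null(ing)) png::writePNG(ing$sprite$image, dst)
        }
      }
      defs$compartments[[ci]]$ingredients[[ii]] <- def
    }
  }
  defs$format_version <- defs$format_version %||% FORMAT_VERSION
  jsonlite::write_json(defs, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Build a recipe object from in-memory ingredients
#'
#' @param ingredients list of [mp_ingredient].
#' @param name recipe name.
#' @param dir directory sprites will live in once saved.
#' @export
mp_recipe <- function(ingredients, name = "recipe", dir = ".") {
  ingredients <- stats::setNames(ingredients,
                                 vapply(ingredients, `[[`, "", "name"))
  comps <- split(ingredients,
                 vapply(ingredients, function(i) i$compartment %||% "cytoplasm", ""))
  defs <- list(format_version = FORMAT_VERSION, name = name,
               compartments = lapply(names(comps), function(cn) {
                 list(name = cn, ingredients = lapply(unname(comps[[cn]]), function(ing)
                   ingredient_def(ing, file.path("sprites",
                                                 paste0(ing$name, ".png")))))
               }))
  structure(list(name = name, defs = defs, ingredients = ingredients,
                 dir = dir), class = "mp_recipe")
}

# ---- Scene files -----------------------------------------------------------

fmt_num <- function(x, digits = 3) round(unname(x), digits)

#' Save and load scenes
#'
#' The scene file is line-oriented JSON (one record per line, diff-friendly):
#' a header with canvas/background/seed, then instance records (ingredient,
#' color, position to 3 decimals, angle, layer) in canonical id order,
#' followed by chain, hinge, spring, pin, pin-to, rail, group, lock,
#' measurement and background records. Loading restores exact poses with no
#' settling; lock hulls are recomputed deterministically from the members.
#'
#' @param scene an [mp_scene].
#' @param path scene text file.
#' @export
mp_save_scene <- function(scene, path) {
  w <- scene$world
  ids <- world_alive_ids(w)
  ids <- ids[!startsWith(w$ingredient[ids], ".")]   # hulls are derived state
  remap <- stats::setNames(seq_along(ids), ids)
  rid <- function(i) unname(remap[as.character(i)])
  lines <- character(0)
  add <- function(rec) {
    lines[[length(lines) + 1L]] <<-
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  }
  add(list(type = "header", format_version = FORMAT_VERSION,
           canvas = unname(scene$canvas),
           background = unname(scene$background_color),
           seed = w$config$rng_seed))
  for (i in ids) {
    ing <- scene$palette[[w$ingredient[i]]]
    add(list(type = "instance", id = rid(i), ingredient = w$ingredient[i],
             color = if (!is.null(ing)) rgb_to_hex(ing$color) else "#9EA8BD",
             position = fmt_num(c(w$x[i], w$y[i])),
             angle = fmt_num(w$angle[i], 6), layer = w$layer[i]))
  }
  for (ci in seq_along(w$chains)) {
    ch <- w$chains[[ci]]
    if (is.null(ch)) next
    alive <- ch$bodies[w$alive[ch$bodies]]
    if (!length(alive)) next
    add(list(type = "chain", id = ci, chain_type = ch$type,
             ingredient = ch$ingredient, spacing = ch$spacing,
             closed = isTRUE(ch$closed),
             bodies = vapply(alive, rid, 0L)))
  }
  if (nrow(w$hinges)) for (k in seq_len(nrow(w$hinges))) {
    h <- w$hinges[k, ]
    add(list(type = "hinge", a = rid(h[1L]), b = rid(h[2L]),
             pa = fmt_num(h[3:4]), pb = fmt_num(h[5:6]), chain = h[7L]))
  }
  if (nrow(w$springs)) for (k in seq_len(nrow(w$springs))) {
    s <- w$springs[k, ]
    add(list(type = "spring", a = rid(s[1L]), b = rid(s[2L]),
             rest = fmt_num(s[3L]), stiffness = s[4L], chain = s[5L]))
  }
  for (i in ids[w$pinned[ids]]) add(list(type = "pin", id = rid(i)))
  if (nrow(w$pintos)) for (k in seq_len(nrow(w$pintos))) {
    p <- w$pintos[k, ]
    add(list(type = "pinto", a = rid(p[1L]), pa = fmt_num(p[2:3]),
             b = rid(p[4L]), pb = fmt_num(p[5:6]), dist = fmt_num(p[7L])))
  }
  for (r in w$rails) {
    if (is.null(r) || !w$alive[r$body]) next
    add(list(type = "rail", body = rid(r$body), chain = r$chain,
             offset = r$offset, rotation = r$rotation))
  }
  for (gi in seq_along(scene$groups)) {
    g <- scene$groups[[gi]]
    if (is.null(g)) next
    live <- w$alive[g$members]
    add(list(type = "group", id = gi,
             members = vapply(g$members[live], rid, 0L),
             ingredient = g$ingredient[live], layer = g$layer[live],
             offsets = unname(apply(g$offsets[live, , drop = FALSE], 1L, fmt_num,
                                    simplify = FALSE)),
             angles = fmt_num(g$angles[live], 6)))
  }
  for (li in seq_along(scene$lock_regions)) {
    lr <- scene$lock_regions[[li]]
    if (is.null(lr)) next
    add(list(type = "lock", id = li,
             members = vapply(lr$members[w$alive[lr$members]], rid, 0L),
             bandwidth = lr$bandwidth))
  }
  for (m in scene$measurements)
    add(list(type = "measurement", a = rid(m[1L]), b = rid(m[2L])))
  for (fl in scene$fills)
    add(list(type = "fill", chain = fl$chain, name = fl$name,
             color = rgb_to_hex(fl$color)))
  for (bg in scene$backgrounds) {
    if (is.na(bg$file)) {
      warning("background without a source file cannot be serialized; skipped")
      next
    }
    add(list(type = "background", file = bg$file,
             nm_per_pixel = bg$nm_per_pixel, opacity = bg$opacity,
             rotation = bg$rotation, z = bg$z))
  }
  writeLines(unlist(lines), path)
  invisible(path)
}

#' @rdname mp_save_scene
#' @param recipe an `mp_recipe` (or named list of [mp_ingredient]) providing
#'   every ingredient the scene references.
#' @return `mp_load_scene`: the reconstructed [mp_scene].
#' @export
mp_load_scene <- function(path, recipe) {
  ingredients <- if (inherits(recipe, "mp_recipe")) recipe$ingredients else recipe
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON,
                 simplifyVector = TRUE)
  types <- vapply(recs, `[[`, "", "type")
  hdr <- recs[[which(types == "header")[1L]]]
  scene <- mp_scene(width = hdr$canvas[1L], height = hdr$canvas[2L],
                    background = hdr$background, seed = hdr$seed)
  for (ing in ingredients) mp_add_ingredient(scene, ing)
  w <- scene$world
  for (r in recs[types == "instance"]) {
    ing <- ingredients[[r$ingredient]]
    if (is.null(ing))
      stop(sprintf("load error: instance references unknown ingredient '%s'",
                   r$ingredient))
    id <- world_add_body(w, ing, position = r$position, angle = r$angle,
                         layer = r$layer)
    stopifnot(id == r$id)
  }
  for (r in recs[types == "chain"]) {
    cid <- r$id
    w$chains[[cid]] <- list(bodies = as.integer(r$bodies),
                            closed = isTRUE(r$closed), type = r$chain_type,
                            spacing = r$spacing, ingredient = r$ingredient)
    w$chain[r$bodies] <- cid
    w$subidx[r$bodies] <- seq_along(r$bodies)
    if (identical(r$chain_type, "membrane")) {
      ing <- ingredients[[r$ingredient]]
      thickness <- ing$main_collider$height
      spacer_r <- thickness / 2
      spacers <- list(
        make_fixture(0L, 0, +(thickness / 2 + spacer_r), p1 = spacer_r,
                     class = "membrane", role = "spacer"),
        make_fixture(0L, 0, -(thickness / 2 + spacer_r), p1 = spacer_r,
                     class = "membrane", role = "spacer"))
      for (b in r$bodies)
        w$fixtures[[b]] <- retag_membrane(c(w$fixtures[[b]], spacers))
    }
  }
  for (r in recs[types == "hinge"])
    world_add_hinge(w, r$a, r$b, r$pa, r$pb, chain = r$chain)
  for (r in recs[types == "spring"])
    world_add_spring(w, r$a, r$b, r$rest, r$stiffness, chain = r$chain)
  for (r in recs[types == "pin"]) mp_pin(scene, r$id)
  for (r in recs[types == "pinto"])
    world_add_pinto(w, r$a, r$pa, r$b, r$pb, r$dist)
  for (r in recs[types == "rail"])
    world_add_rail(w, r$body, r$chain, r$offset, r$rotation)
  for (r in recs[types == "group"]) {
    scene$next_excl <- scene$next_excl + 1L
    w$excl[r$members] <- scene$next_excl
    w$group_id[r$members] <- r$id
    off <- r$offsets
    if (is.list(off)) off <- do.call(rbind, off)
    scene$groups[[r$id]] <- list(
      members = as.integer(r$members), ingredient = r$ingredient,
      layer = as.integer(r$layer),
      offsets = matrix(as.numeric(off), ncol = 2L),
      angles = r$angles, pintos = NULL)
  }
  for (r in recs[types == "fill"]) {
    fid <- length(scene$fills) + 1L
    scene$fills[[fid]] <- list(chain = r$chain, name = r$name,
                               color = hex_to_rgb(r$color))
  }
  for (r in recs[types == "lock"]) {
    scene$next_lock <- max(scene$next_lock, r$id)
    w$locked[r$members] <- TRUE
    w$lock_id[r$members] <- r$id
    scene$lock_regions[[r$id]] <- list(members = as.integer(r$members),
                                       hull_bodies = integer(0),
                                       bandwidth = r$bandwidth)
    relock_region(scene, r$id)
  }
  for (r in recs[types == "measurement"]) mp_measure(scene, r$a, r$b)
  for (r in recs[types == "background"]) {
    f <- r$file
    if (!file.exists(f)) f <- file.path(dirname(path), basename(f))
    if (file.exists(f))
      mp_set_background(scene, f, r$nm_per_pixel, r$opacity, r$rotation, r$z)
    else warning(sprintf("background file '%s' not found; skipped", r$file))
  }
  scene
}

# ---- Bundles ---------------------------------------------------------------

#' Zip-bundle a scene with its recipe and sprites
#'
#' The bundle is hermetic: `scene.txt`, `recipe.json`, and every sprite PNG
#' travel together, so `mp_load_bundle` works in an empty directory.
#'
#' @param scene an [mp_scene].
#' @param recipe the `mp_recipe` backing the scene.
#' @param path output `.zip` path.
#' @export
mp_bundle <- function(scene, recipe, path) {
  stage <- tempfile("mp_bundle_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  mp_save_recipe(recipe, file.path(stage, "recipe.json"))
  mp_save_scene(scene, file.path(stage, "scene.txt"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (file.exists(path)) unlink(path)
  path <- file.path(normalizePath(dirname(path)), basename(path))
  files <- list.files(stage, recursive = TRUE)
  zip::zip(zipfile = path, files = files, root = stage,
           include_directories = FALSE, mode = "mirror")
  invisible(path)
}

#' @rdname mp_bundle
#' @return `mp_load_bundle`: list with `scene` and `recipe`.
#' @export
mp_load_bundle <- function(path) {
  stage <- tempfile("mp_unbundle_")
  dir.create(stage)
  ok <- tryCatch({ zip::unzip(path, exdir = stage); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("archive error: cannot read bundle '%s'", path))
  rj <- file.path(stage, "recipe.json")
  st <- file.path(stage, "scene.txt")
  if (!file.exists(rj)) stop("archive error: bundle has no recipe.json")
  if (!file.exists(st)) stop("archive error: bundle has no scene.txt")
  recipe <- mp_load_recipe(rj)
  scene <- mp_load_scene(st, recipe)
  list(scene = scene, recipe = recipe)
}

# ---- Structures ------------------------------------------------------------

#' Read an atomic structure (PDB or mmCIF)
#'
#' Minimal structural reader: ATOM/HETATM coordinates, element symbols with
#' standard van der Waals radii, first model only. For PDB files carrying
#' REMARK 350 biological-assembly matrices the assembly is expanded when
#' `expand_assembly = TRUE`; mmCIF files load the asymmetric unit. CA-only
#' traces get a per-residue pseudo-atom radius.
#'
#' @param path `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param expand_assembly apply BIOMT operators when present (PDB).
#' @return an [mp_structure] (coordinates in Angstrom).
#' @export
mp_read_structure <- function(path, expand_assembly = TRUE) {
  if (!file.exists(path)) stop(sprintf("format error: no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("format error: empty structure file")
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
    any(startsWith(lines[seq_len(min(5L, length(lines)))], "data_"))
  st <- if (is_cif) read_mmcif(lines) else read_pdb(lines, expand_assembly)
  if (nrow(st$positions) == 0L) stop("format error: no atoms found")
  st
}

read_pdb <- function(lines, expand_assembly) {
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1L] - 1L)]   # first model only
  at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (!length(at)) stop("format error: no ATOM/HETATM records")
  x <- as.numeric(substr(at, 31L, 38L))
  y <- as.numeric(substr(at, 39L, 46L))
  z <- as.numeric(substr(at, 47L, 54L))
  elem <- trimws(substr(at, 77L, 78L))
  name <- trimws(substr(at, 13L, 16L))
  miss <- elem == ""
  elem[miss] <- substr(gsub("[0-9]", "", name[miss]), 1L, 1L)
  chain <- substr(at, 22L, 22L)
  pos <- cbind(x, y, z)
  assembly <- "asym"
  if (expand_assembly) {
    bm <- lines[grepl("^REMARK 350   BIOMT", lines)]
    if (length(bm) >= 3L) {
      nops <- length(bm) / 3L
      allpos <- NULL; allel <- NULL; allch <- NULL
      for (k in seq_len(nops)) {
        rows <- bm[(3L * (k - 1L) + 1L):(3L * k)]
        mats <- t(vapply(rows, function(r)
          as.numeric(strsplit(trimws(substr(r, 24L, 200L)), "\\s+")[[1L]][1:4]),
          numeric(4L)))
        R <- mats[, 1:3]; tr <- mats[, 4L]
        p2 <- pos %*% t(R) + matrix(tr, nrow(pos), 3L, byrow = TRUE)
        allpos <- rbind(allpos, p2)
        allel <- c(allel, elem); allch <- c(allch, chain)
      }
      if (nops > 1L) {
        pos <- allpos; elem <- allel; chain <- allch
        assembly <- "biological"
      }
    }
  }
  st <- mp_structure(pos, elements = elem, chains = chain,
                     assembly_id = assembly)
  if (all(name[!miss] == "CA" | elem == "CA") && all(name == "CA")) {
    attr(st, "ca_only") <- TRUE
    st$radii <- rep(CA_ONLY_RADIUS, nrow(st$positions))
  }
  st
}

read_mmcif <- function(lines) {
  loop_at <- grep("^\\s*loop_\\s*$", lines)
  for (start in loop_at) {
    i <- start + 1L
    fields <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(fields, "_atom_site."))) next
    key <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
          startsWith(ln, "loop_") || startsWith(ln, "data_")) break
      rows[[length(rows) + 1L]] <- strsplit(ln, "\\s+")[[1L]]
      i <- i + 1L
    }
    if (!length(rows)) stop("format error: empty _atom_site loop")
    tab <- do.call(rbind, rows)
    colnames(tab) <- key[seq_len(ncol(tab))]
    getcol <- function(nm) if (nm %in% colnames(tab)) tab[, nm] else NULL
    model <- getcol("pdbx_PDB_model_num")
    keep <- if (is.null(model)) rep(TRUE, nrow(tab)) else model == model[1L]
    pos <- cbind(as.numeric(tab[keep, "Cartn_x"]),
                 as.numeric(tab[keep, "Cartn_y"]),
                 as.numeric(tab[keep, "Cartn_z"]))
    elem <- getcol("type_symbol")
    elem <- if (is.null(elem)) rep("C", sum(keep)) else elem[keep]
    ch <- getcol("auth_asym_id") %||% getcol("label_asym_id")
    ch <- if (is.null(ch)) rep("A", sum(keep)) else ch[keep]
    return(mp_structure(pos, elements = elem, chains = ch))
  }
  stop("format error: no _atom_site loop in mmCIF file")
}

# ---- Rendering -------------------------------------------------------------

# alpha-blend sprite pixels into the canvas (nearest-neighbour inverse map)
blend_sprite <- function(img, sprite, pos_px, angle, scale_px, tint, tint_frac) {
  sp <- sprite$image
  sh <- dim(sp)[1L]; sw <- dim(sp)[2L]
  H <- dim(img)[1L]; W <- dim(img)[2L]
  rad <- 0.5 * sqrt(sh^2 + sw^2) * scale_px
  r0 <- max(1L, floor(pos_px[2L] - rad)); r1 <- min(H, ceiling(pos_px[2L] + rad))
  c0 <- max(1L, floor(pos_px[1L] - rad)); c1 <- min(W, ceiling(pos_px[1L] + rad))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  # canvas pixel -> sprite pixel: undo translation, rotation, scale (Y down)
  dx <- outer(rep(1, length(rows)), cols - pos_px[1L])
  dy <- outer(rows - pos_px[2L], rep(1, length(cols)))
  ca <- cos(angle); sa <- sin(angle)
  sx <- ( ca * dx - sa * dy) / scale_px + sprite$anchor[1L]
  sy <- ( sa * dx + ca * dy) / scale_px + (sh - sprite$anchor[2L])
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= sh & sj >= 1 & sj <= sw
  if (!any(ok)) return(img)
  lin <- (sj[ok] - 1L) * sh + si[ok]
  a <- sp[, , 4L][lin]
  sel <- a > 0
  if (!any(sel)) return(img)
  okidx <- which(ok)[sel]
  a <- a[sel]
  for (chn in 1:3) {
    src <- sp[, , chn][lin][sel]
    src <- src * (1 - tint_frac) + tint[chn] * tint_frac
    pane <- img[rows, cols, chn]
    pane[okidx] <- pane[okidx] * (1 - a) + src * a
    img[rows, cols, chn] <- pane
  }
  img
}

#' Render the scene to a raster image
#'
#' Deterministic painter's-algorithm rendering: background color, then
#' background images by z-order, closed-compartment fills under their
#' membranes, then sprites back-to-front by layer with progressive depth
#' cueing (layer 2 blended 60% toward the background color, layer 1 by 30%,
#' layer 0 drawn at full color), and an optional scale bar. Rendering never
#' mutates the scene; identical inputs give identical bytes.
#'
#' @param scene an [mp_scene].
#' @param path optional output PNG path.
#' @param pixels_per_nm raster resolution (> 0).
#' @param scale_bar_nm optional scale-bar length in nm (drawn bottom left).
#' @return the RGB image array, invisibly.
#' @export
mp_render <- function(scene, path = NULL, pixels_per_nm = 0.5,
                      scale_bar_nm = NULL) {
  if (pixels_per_nm <= 0) stop("pixels_per_nm must be > 0")
  W <- unname(ceiling(scene$canvas[1L] * pixels_per_nm))
  H <- unname(ceiling(scene$canvas[2L] * pixels_per_nm))
  if (W < 1 || H < 1) stop("zero-size canvas")
  bgc <- scene$background_color
  img <- array(rep(bgc, each = H * W), dim = c(H, W, 3L))
  to_px <- function(p) c(p[1L] * pixels_per_nm,
                         H - p[2L] * pixels_per_nm)   # nm (Y-up) -> px
  # background images, centered on the canvas, by z-order
  bgs <- scene$backgrounds
  if (length(bgs)) {
    for (bg in bgs[order(vapply(bgs, `[[`, 0, "z"))]) {
      if (bg$opacity <= 0) next
      bim <- bg$image
      if (length(dim(bim)) == 2L) bim <- array(rep(bim, 3L), c(dim(bim), 3L))
      if (dim(bim)[3L] == 3L) {
        bim <- array(c(bim, array(1, dim(bim)[1:2])), c(dim(bim)[1:2], 4L))
      }
      spr <- list(image = bim, anchor = c(dim(bim)[2L], dim(bim)[1L]) / 2)
      bim[, , 4L] <- bim[, , 4L] * bg$opacity
      spr$image <- bim
      img <- blend_sprite(img, spr, c(W / 2, H / 2), bg$rotation,
                          bg$nm_per_pixel * pixels_per_nm, c(0, 0, 0), 0)
    }
  }
  # compartment fills under the membranes (dynamic: follow the segments)
  for (fl in scene$fills) {
    ch <- scene$world$chains[[fl$chain]]
    if (is.null(ch)) next
    poly <- mp_vesicle_polygon(scene, fl$chain)$polygon
    fillc <- fl$color * 0.35 + bgc * 0.65
    vpx <- t(apply(poly, 1L, to_px))
    rr <- pmax(1L, pmin(H, round(vpx[, 2L])))
    r0 <- min(rr); r1 <- max(rr)
    for (row in r0:r1) {
      # even-odd scanline fill
      ycut <- row
      xs <- numeric(0)
      n <- nrow(vpx)
      for (k in seq_len(n)) {
        p1 <- vpx[k, ]; p2 <- vpx[if (k == n) 1L else k + 1L, ]
        if ((p1[2L] > ycut) != (p2[2L] > ycut)) {
          xs <- c(xs, p1[1L] + (ycut - p1[2L]) / (p2[2L] - p1[2L]) *
                    (p2[1L] - p1[1L]))
        }
      }
      xs <- sort(xs)
      if (length(xs) >= 2L) for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        cset <- max(1L, ceiling(xs[k])):min(W, floor(xs[k + 1L]))
        if (length(cset) && cset[1L] <= cset[length(cset)])
          for (chn in 1:3) img[row, cset, chn] <- fillc[chn]
      }
    }
  }
  # sprites, back to front
  w <- scene$world
  cue <- c(`0` = 0, `1` = 0.3, `2` = 0.6)
  for (lay in c(2L, 1L, 0L)) {
    for (id in world_alive_ids(w)) {
      if (w$layer[id] != lay) next
      ing <- scene$palette[[w$ingredient[id]]]
      if (is.null(ing)) next
      img <- blend_sprite(img, ing$sprite, to_px(c(w$x[id], w$y[id])),
                          w$angle[id],
                          ing$sprite$nm_per_pixel * pixels_per_nm,
                          bgc, cue[[as.character(lay)]])
    }
  }
  if (!is.null(scale_bar_nm)) {
    len <- round(scale_bar_nm * pixels_per_nm)
    rows <- max(1L, H - 12L):max(1L, H - 8L)
    cols <- 10:min(W, 10L + len)
    for (chn in 1:3) img[rows, cols, chn] <- 1
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
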