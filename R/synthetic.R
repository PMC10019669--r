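# Seeded generator of synthetic H&E-like tiles with per-gland ground truth.
#
# Tiles emulate the gross architecture that distinguishes histological classes
# of prostate tissue: white gland lumina, a hematoxylin-purple epithelial wall
# around each lumen, and eosin-pink stroma elsewhere. Morphology is controlled
# per class: benign tissue has a few large, round, thin-walled glands; atrophy
# has small thin-walled glands; HGPIN has thickened epithelium; Gleason 3 has
# many small discrete glands; Gleason 4 cribriform is one large epithelial mass
# perforated by multiple lumina; Gleason 4 non-cribriform is fused glands with
# shared epithelium; Gleason 5 is epithelial sheets with no lumen.

#' Default stain colors of the synthetic renderer
#'
#' Flat RGB fills per tissue class, approximating eosin-pink stroma,
#' hematoxylin-purple epithelium and white lumen/background.
#'
#' @return 3 x 3 integer matrix, one row per tissue class (stroma, epithelium,
#'   lumen), columns R, G, B
#' @export
default_stain_colors <- function() {
  m <- rbind(
    stroma     = c(230L, 150L, 170L),
    epithelium = c(120L, 80L, 160L),
    lumen      = c(245L, 245L, 245L)
  )
  colnames(m) <- c("R", "G", "B")
  m
}

# Per-class morphology defaults, in pixels at a 512 px reference tile.
# Free modeling choices (no published quantitative morphology exists per
# class); frozen here and documented in the vignette. Radii, walls and mass
# radii scale linearly with tile size, gland counts with tile area.
synthetic_class_table <- function() {
  list(
    benign          = list(count = c(2, 4),   radius = c(40, 60),  wall = c(8, 14),  ecc = c(0, 0.25)),
    atrophy         = list(count = c(8, 14),  radius = c(18, 32),  wall = c(3, 6),   ecc = c(0, 0.35)),
    HGPIN           = list(count = c(2, 4),   radius = c(35, 50),  wall = c(14, 22), ecc = c(0, 0.25)),
    seminal_vesicle = list(count = c(1, 2),   radius = c(45, 65),  wall = c(12, 20), ecc = c(0.2, 0.5)),
    G3              = list(count = c(14, 24), radius = c(8, 16),   wall = c(7, 12),  ecc = c(0, 0.4)),
    G4CG            = list(count = c(1, 1),   radius = c(9, 15),   wall = c(10, 16), ecc = c(0, 0.2),
                           mass_radius = c(90, 140)),
    G4NC            = list(count = c(9, 16),  radius = c(10, 20),  wall = c(12, 20), ecc = c(0.2, 0.6)),
    G5              = list(count = c(2, 4),   radius = c(0, 0),    wall = c(0, 0),   ecc = c(0, 0.3),
                           mass_radius = c(80, 140))
  )
}

#' Synthetic class morphology defaults
#'
#' Default gland-count, lumen-radius, wall-thickness and eccentricity ranges
#' for a class, scaled to the requested tile size (radii and walls scale with
#' tile edge length, counts with tile area, relative to the 512 px reference).
#'
#' @param class_label one of [annotation_classes()]
#' @param tile_size_px tile edge length in pixels
#' @return list with elements `count`, `radius`, `wall`, `ecc` and, for the
#'   mass-based classes (G4CG, G5), `mass_radius`
#' @export
synthetic_class_defaults <- function(class_label, tile_size_px = 512) {
  tab <- synthetic_class_table()
  if (!class_label %in% names(tab)) {
    stopf("unknown class_label '%s'; expected one of: %s",
          class_label, paste(annotation_classes(), collapse = ", "))
  }
  d <- tab[[class_label]]
  s <- tile_size_px / 512
  d$radius <- d$radius * s
  d$wall <- d$wall * s
  if (!is.null(d$mass_radius)) d$mass_radius <- d$mass_radius * s
  d$count <- pmax(1L, as.integer(round(d$count * s^2)))
  d
}

#' Specify a synthetic H&E tile
#'
#' Builds the parameter object consumed by [generate_tile()]. All ranges are
#' sampled uniformly per gland. Omitted morphology arguments fall back to the
#' class defaults of [synthetic_class_defaults()] at the requested tile size.
#'
#' @param class_label one of [annotation_classes()]
#' @param tile_size_px tile edge length in pixels (>= 128); default 3000, the
#'   size at which whole slides are tiled
#' @param gland_count_range integer pair, number of glands (masses for
#'   G4CG/G5)
#' @param lumen_radius_px_range real pair, equivalent-circle lumen radius
#' @param wall_thickness_px_range real pair, epithelial wall thickness
#' @param lumen_eccentricity_range real pair in `[0, 1)`
#' @param cribriform_lumina_per_gland lumina punched into each G4CG mass
#' @param mass_radius_px_range real pair, epithelial mass radius (G4CG and G5
#'   only)
#' @param stain_colors 3 x 3 RGB matrix as in [default_stain_colors()]
#' @param noise_sd per-pixel Gaussian RGB noise, as a fraction of 255
#' @param blur if `TRUE`, a 1 px Gaussian blur mimics scanner softness
#' @param seed optional default seed used when [generate_tile()] is called
#'   without one
#' @return object of class `synthetic_tile_spec`
#' @export
synthetic_tile_spec <- function(class_label,
                                tile_size_px = 3000,
                                gland_count_range = NULL,
                                lumen_radius_px_range = NULL,
                                wall_thickness_px_range = NULL,
                                lumen_eccentricity_range = NULL,
                                cribriform_lumina_per_gland = 5,
                                mass_radius_px_range = NULL,
                                stain_colors = default_stain_colors(),
                                noise_sd = 0.02,
                                blur = TRUE,
                                seed = NULL) {
  d <- synthetic_class_defaults(class_label, tile_size_px)
  if (tile_size_px < 128) stopf("tile_size_px must be >= 128")
  spec <- list(
    class_label = class_label,
    tile_size_px = as.integer(tile_size_px),
    gland_count_range = if (is.null(gland_count_range)) d$count else as.integer(gland_count_range),
    lumen_radius_px_range = if (is.null(lumen_radius_px_range)) d$radius else lumen_radius_px_range,
    wall_thickness_px_range = if (is.null(wall_thickness_px_range)) d$wall else wall_thickness_px_range,
    lumen_eccentricity_range = if (is.null(lumen_eccentricity_range)) d$ecc else lumen_eccentricity_range,
    cribriform_lumina_per_gland = as.integer(cribriform_lumina_per_gland),
    mass_radius_px_range = if (is.null(mass_radius_px_range)) d$mass_radius else mass_radius_px_range,
    stain_colors = stain_colors,
    noise_sd = noise_sd,
    blur = isTRUE(blur),
    seed = seed
  )
  for (rng in c("gland_count_range", "lumen_radius_px_range",
                "wall_thickness_px_range", "lumen_eccentricity_range")) {
    v <- spec[[rng]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2] || v[1] < 0)
      stopf("%s must be a non-decreasing non-negative pair", rng)
  }
  if (any(spec$lumen_eccentricity_range >= 1)) stopf("eccentricity must be < 1")
  if (spec$noise_sd < 0 || spec$noise_sd > 1) stopf("noise_sd must be in [0, 1]")
  structure(spec, class = "synthetic_tile_spec")
}

# Logical mask of an ellipse over the full tile, by pixel-center membership
# (no anti-aliasing). Center (cx, cy) in 0-based continuous coordinates,
# semi-axes a >= b, orientation theta.
rasterize_ellipse <- function(size, cx, cy, a, b, theta) {
  r0 <- max(1L, floor(cy - a) + 1L); r1 <- min(size, ceiling(cy + a) + 1L)
  c0 <- max(1L, floor(cx - a) + 1L); c1 <- min(size, ceiling(cx + a) + 1L)
  mask <- matrix(FALSE, size, size)
  if (r0 > r1 || c0 > c1) return(mask)
  ys <- (r0:r1) - 0.5 - cy
  xs <- (c0:c1) - 0.5 - cx
  ct <- cos(theta); st <- sin(theta)
  u <- (outer(ys, xs, function(y, x) (x * ct + y * st))) / a
  v <- (outer(ys, xs, function(y, x) (-x * st + y * ct))) / b
  mask[r0:r1, c0:c1] <- (u^2 + v^2) <= 1
  mask
}

# Ellipse semi-axes with area pi*r^2 at eccentricity e.
ellipse_axes <- function(r, e) {
  k <- (1 - e^2)^0.25
  c(a = r / k, b = r * k)
}

# Sample one gland's geometry from the spec ranges.
sample_gland_geometry <- function(spec) {
  r <- stats::runif(1, spec$lumen_radius_px_range[1], spec$lumen_radius_px_range[2])
  w <- stats::runif(1, spec$wall_thickness_px_range[1], spec$wall_thickness_px_range[2])
  e <- stats::runif(1, spec$lumen_eccentricity_range[1], spec$lumen_eccentricity_range[2])
  theta <- stats::runif(1, 0, pi)
  ax <- ellipse_axes(r, e)
  list(r = r, w = w, e = e, theta = theta, a = ax["a"], b = ax["b"],
       bound = ax["a"] + w)
}

#' Generate a synthetic H&E tile
#'
#' Renders one tile from a [synthetic_tile_spec()]: an RGB image, the exact
#' per-pixel tissue partition it was rendered from, and a ground-truth table
#' with one row per gland. Generation is a pure function of `(spec, seed)`:
#' identical inputs yield bit-identical outputs, and the caller's RNG state is
#' left untouched.
#'
#' Placement uses rejection sampling (at most 100 attempts per gland);
#' discrete-gland classes forbid overlap, G4NC forbids only lumen overlap so
#' that epithelial walls fuse, and G4CG/G5 place one or more large epithelial
#' masses (perforated by lumina for G4CG, solid for G5).
#'
#' @param spec a [synthetic_tile_spec()]
#' @param seed integer seed; defaults to `spec$seed`
#' @return list of class `synthetic_tile` with elements `rgb` (integer array,
#'   0-255), `class_map` (integer matrix; 1 = stroma, 2 = epithelium,
#'   3 = lumen), `glands` (data.frame: `gland_id, center_x, center_y,
#'   lumen_area_px2, epithelial_area_px2, wall_thickness_px, touches_edge`),
#'   `spec`, and `seed`
#' @export
generate_tile <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "synthetic_tile_spec")) stopf("spec must be a synthetic_tile_spec")
  if (is.null(seed)) stopf("a seed is required (argument or spec$seed)")
  tile <- with_seed(seed, generate_tile_impl(spec))
  tile$seed <- as.integer(seed)
  tile
}

generate_tile_impl <- function(spec) {
  size <- spec$tile_size_px
  cls <- spec$class_label
  class_map <- matrix(1L, size, size)  # stroma everywhere
  epi_masks <- list()
  lumen_masks <- list()
  truth <- list()

  n_glands <- if (spec$gland_count_range[1] == spec$gland_count_range[2]) {
    spec$gland_count_range[1]
  } else {
    sample(spec$gland_count_range[1]:spec$gland_count_range[2], 1)
  }

  if (cls %in% c("G4CG", "G5")) {
    placed <- place_masses(spec, n_glands, size, allow_overlap = (cls == "G5"))
    gid <- 0L
    for (m in placed) {
      mass_mask <- rasterize_ellipse(size, m$cx, m$cy, m$a, m$b, m$theta)
      epi_masks[[length(epi_masks) + 1L]] <- mass_mask
      if (cls == "G4CG") {
        lum <- place_cribriform_lumina(spec, m, size)
        mass_epi_px <- sum(mass_mask) - sum(vapply(lum, function(l) sum(l$mask), numeric(1)))
        for (l in lum) {
          gid <- gid + 1L
          lumen_masks[[gid]] <- l$mask
          truth[[gid]] <- data.frame(
            gland_id = gid, center_x = l$cx, center_y = l$cy,
            lumen_area_px2 = sum(l$mask),
            epithelial_area_px2 = mass_epi_px / length(lum),
            wall_thickness_px = NA_real_,
            touches_edge = mask_touches_edge(l$mask))
        }
      }
    }
  } else {
    placed <- place_discrete_glands(spec, n_glands, size,
                                    allow_epi_overlap = (cls == "G4NC"))
    for (i in seq_along(placed)) {
      g <- placed[[i]]
      outer_mask <- rasterize_ellipse(size, g$cx, g$cy, g$a + g$w, g$b + g$w, g$theta)
      lumen_mask <- rasterize_ellipse(size, g$cx, g$cy, g$a, g$b, g$theta)
      epi_masks[[i]] <- outer_mask & !lumen_mask
      lumen_masks[[i]] <- lumen_mask
      truth[[i]] <- data.frame(
        gland_id = i, center_x = g$cx, center_y = g$cy,
        lumen_area_px2 = sum(lumen_mask),
        epithelial_area_px2 = sum(epi_masks[[i]]),
        wall_thickness_px = g$w,
        touches_edge = mask_touches_edge(lumen_mask))
    }
  }

  # two-pass paint: all epithelium first, then all lumina, so lumina survive
  # under fused/overlapping epithelium
  for (m in epi_masks) class_map[m] <- 2L
  for (m in lumen_masks) class_map[m] <- 3L

  glands <- if (length(truth)) do.call(rbind, truth) else data.frame(
    gland_id = integer(), center_x = numeric(), center_y = numeric(),
    lumen_area_px2 = numeric(), epithelial_area_px2 = numeric(),
    wall_thickness_px = numeric(), touches_edge = logical())

  rgb <- render_rgb(class_map, spec)
  structure(list(rgb = rgb, class_map = class_map, glands = glands,
                 spec = spec, seed = NULL),
            class = "synthetic_tile")
}

mask_touches_edge <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) || any(mask[, 1]) || any(mask[, ncol(mask)])
}

# Rejection-sample discrete gland positions. Glands are placed largest-first;
# non-G4NC classes require disjoint bounding ellipses, G4NC requires only
# disjoint lumina (epithelium may fuse). Fails after 100 attempts per gland.
place_discrete_glands <- function(spec, n, size, allow_epi_overlap) {
  geoms <- lapply(seq_len(n), function(i) sample_gland_geometry(spec))
  geoms <- geoms[order(vapply(geoms, function(g) g$bound, numeric(1)), decreasing = TRUE)]
  placed <- list()
  for (g in geoms) {
    margin <- g$bound + 2
    if (2 * margin >= size) stopf("gland too large for tile (bound %.0f px)", g$bound)
    ok <- FALSE
    for (attempt in seq_len(100)) {
      cx <- stats::runif(1, margin, size - margin)
      cy <- stats::runif(1, margin, size - margin)
      clash <- FALSE
      for (p in placed) {
        d <- sqrt((cx - p$cx)^2 + (cy - p$cy)^2)
        lim <- if (allow_epi_overlap) (g$a + p$a + 8) else (g$bound + p$bound + 4)
        if (d < lim) { clash <- TRUE; break }
      }
      if (!clash) { g$cx <- cx; g$cy <- cy; placed[[length(placed) + 1L]] <- g; ok <- TRUE; break }
    }
    if (!ok) stopf("could not place gland after 100 attempts: spec is over-dense")
  }
  placed
}

# Place G4CG/G5 epithelial masses. G4CG masses must not overlap (each is one
# cribriform gland); G5 sheets may fuse freely.
place_masses <- function(spec, n, size, allow_overlap = FALSE) {
  rng <- spec$mass_radius_px_range
  placed <- list()
  for (i in seq_len(n)) {
    r <- stats::runif(1, rng[1], rng[2])
    e <- stats::runif(1, spec$lumen_eccentricity_range[1], spec$lumen_eccentricity_range[2])
    theta <- stats::runif(1, 0, pi)
    ax <- ellipse_axes(r, e)
    bound <- ax["a"]
    margin <- min(bound + 2, size / 2 - 1)
    ok <- FALSE
    for (attempt in seq_len(100)) {
      cx <- stats::runif(1, margin, size - margin)
      cy <- stats::runif(1, margin, size - margin)
      clash <- !allow_overlap && any(vapply(placed, function(p)
        sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < bound + p$bound + 4, logical(1)))
      if (!clash) {
        placed[[length(placed) + 1L]] <- list(cx = cx, cy = cy, a = ax["a"], b = ax["b"],
                                              theta = theta, bound = bound)
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place epithelial mass after 100 attempts: spec is over-dense")
  }
  placed
}

# Punch cribriform lumina into a mass: non-overlapping small ellipses whose
# bounding circles stay well inside the mass ellipse.
place_cribriform_lumina <- function(spec, mass, size) {
  k <- spec$cribriform_lumina_per_gland
  out <- list()
  for (i in seq_len(k)) {
    ok <- FALSE
    for (attempt in seq_len(100)) {
      r <- stats::runif(1, spec$lumen_radius_px_range[1], spec$lumen_radius_px_range[2])
      # position in the mass's unit-ellipse coordinates, shrunk so the lumen
      # plus a wall margin stays interior
      shrink <- 1 - (r + 6) / mass$b
      if (shrink <= 0.05) next
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * shrink
      ct <- cos(mass$theta); st <- sin(mass$theta)
      ux <- rad * cos(ang) * mass$a; uy <- rad * sin(ang) * mass$b
      cx <- mass$cx + ux * ct - uy * st
      cy <- mass$cy + ux * st + uy * ct
      clash <- any(vapply(out, function(p)
        sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < r + p$r + 5, logical(1)))
      if (!clash) {
        out[[length(out) + 1L]] <- list(
          cx = cx, cy = cy, r = r,
          mask = rasterize_ellipse(size, cx, cy, r, r, 0))
        ok <- TRUE
        break
      }
    }
    if (!ok) stopf("could not place cribriform lumen after 100 attempts: spec is over-dense")
  }
  out
}

# Flat class fills + Gaussian RGB noise (sd = noise_sd * 255) + optional 1 px
# Gaussian blur, rounded back to 8-bit integers.
render_rgb <- function(class_map, spec) {
  size <- nrow(class_map)
  cols <- spec$stain_colors
  rgb <- array(0, dim = c(size, ncol(class_map), 3))
  for (ch in 1:3) {
    base <- matrix(cols[, ch][class_map], size, ncol(class_map))
    if (spec$noise_sd > 0)
      base <- base + stats::rnorm(length(base), 0, spec$noise_sd * 255)
    rgb[, , ch] <- base
  }
  if (spec$blur) {
    for (ch in 1:3)
      rgb[, , ch] <- EBImage::imageData(EBImage::gblur(rgb[, , ch], sigma = 1))
  }
  array(as.integer(clamp(round(rgb), 0, 255)), dim = dim(rgb))
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_class` tiles per spec into one directory per class, with each
#' tile's RGB image, its tissue class map, a combined ground-truth gland table
#' and a manifest. Per-tile seeds are derived deterministically from the master
#' seed, the class label and the tile index, so the same call always produces
#' byte-identical files.
#'
#' @param specs list of [synthetic_tile_spec()] objects (one per class)
#' @param n_per_class tiles to generate per spec (>= 1)
#' @param out_dir output directory; must be empty or absent unless
#'   `overwrite = TRUE`
#' @param seed master integer seed
#' @param overwrite allow writing into an existing non-empty directory
#' @return the manifest data.frame (`tile_id, class, path, mask_path, seed`),
#'   invisibly; also written as `manifest.csv` alongside `ground_truth.csv`
#' @export
generate_dataset <- function(specs, n_per_class, out_dir, seed, overwrite = FALSE) {
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stopf("out_dir '%s' exists and is not empty; use overwrite = TRUE", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  truth <- list()
  for (spec in specs) {
    cls <- spec$class_label
    cls_dir <- file.path(out_dir, cls)
    dir.create(cls_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      tile_seed <- derive_seed(seed, cls, i)
      tile <- generate_tile(spec, seed = tile_seed)
      tile_id <- sprintf("%s_%03d", cls, i)
      img_path <- file.path(cls_dir, paste0(tile_id, ".png"))
      mask_path <- file.path(cls_dir, paste0(tile_id, "_mask.png"))
      write_rgb_png(tile$rgb, img_path)
      write_mask_png(tile$class_map, mask_path)
      manifest[[length(manifest) + 1L]] <- data.frame(
        tile_id = tile_id, class = cls, path = img_path,
        mask_path = mask_path, seed = tile_seed)
      if (nrow(tile$glands) > 0) {
        g <- tile$glands
        g$tile_id <- tile_id
        truth[[length(truth) + 1L]] <- g
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  gt <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gland_id = integer(), tile_id = character())
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(manifest)
}
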