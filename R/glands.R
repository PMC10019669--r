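# Gland segmentation from tissue class maps and per-gland morphometry.
#
# A gland is seeded by each interior lumen component (8-connected, not
# touching the tile border, at least `min_lumen_px` pixels). Epithelium pixels
# within a bounded geodesic distance of a lumen are assigned to their nearest
# lumen, forming the gland's epithelial ring. Six features are computed per
# gland: epithelial area, roundness and wall thickness; luminal area and
# roundness; and cell fraction (percent epithelium of total gland area).

#' Segment glands from a tissue class map
#'
#' Each interior lumen component of at least `min_lumen_px` pixels seeds one
#' gland; lumen components touching the tile border are excluded (their gland
#' is clipped, so its features would be unrepresentative). Epithelium pixels
#' within Euclidean distance `max_ring_distance_px` of a kept lumen are
#' assigned to their nearest lumen by geodesic propagation through epithelium
#' (deterministic tie resolution); glands whose ring comes up empty are
#' dropped.
#'
#' @param map integer class map (1 = stroma, 2 = epithelium, 3 = lumen)
#' @param min_lumen_px minimum lumen component size in pixels (default 8)
#' @param max_ring_distance_px maximum geodesic distance from lumen at which
#'   epithelium still belongs to the gland (default 20)
#' @return list of `gland` objects: `gland_id`, `lumen_idx` and `ring_idx`
#'   (matrix indices into `map`), and `dim` (the map dimensions); empty list
#'   for lumenless tiles
#' @export
find_glands <- function(map, min_lumen_px = 8, max_ring_distance_px = 20) {
  lab <- label_components(map == 3L, connectivity = 8)
  if (max(lab) == 0) return(list())
  areas <- label_areas(lab)
  drop <- union(labels_touching_border(lab),
                as.integer(names(areas)[areas < min_lumen_px]))
  keep <- setdiff(seq_len(max(lab)), drop)
  if (!length(keep)) return(list())

  seeds <- matrix(0L, nrow(map), ncol(map))
  for (k in seq_along(keep)) seeds[lab == keep[k]] <- k
  allowed <- map == 2L
  # geodesic Voronoi of the lumen seeds through epithelium, then a Euclidean
  # distance cutoff to the kept lumina
  prop <- EBImage::imageData(EBImage::propagate(
    EBImage::Image(matrix(0, nrow(map), ncol(map))),
    seeds = seeds, mask = allowed | seeds > 0))
  dlum <- EBImage::imageData(EBImage::distmap(
    matrix(as.numeric(seeds == 0L), nrow(map), ncol(map))))
  within <- dlum <= max_ring_distance_px

  glands <- list()
  for (k in seq_along(keep)) {
    lumen_idx <- which(lab == keep[k])
    ring_idx <- which(prop == k & allowed & within)
    if (!length(ring_idx)) next
    glands[[length(glands) + 1L]] <- structure(
      list(gland_id = length(glands) + 1L, lumen_idx = lumen_idx,
           ring_idx = ring_idx, dim = dim(map)),
      class = "gland")
  }
  glands
}

#' Morphometric features of one gland
#'
#' Areas are pixel counts. Roundness is the isoperimetric ratio `4*pi*A / P^2`
#' clipped to 1, with `P` the Kulpa-corrected outer contour length: for the
#' lumen, its own boundary; for the epithelium, the outer boundary of ring
#' plus lumen (so epithelial roundness reflects both wall fullness and outline
#' shape). Wall thickness is the mean, over the gland's outer boundary pixels,
#' of Euclidean distance to the nearest lumen pixel. Cell fraction is
#' `100 * epithelial_area / (epithelial_area + luminal_area)`.
#'
#' @param gland a gland from [find_glands()]
#' @return one-row data.frame: `epithelial_area, epithelial_roundness,
#'   wall_thickness, luminal_area, luminal_roundness, cell_fraction`
#' @export
compute_gland_features <- function(gland) {
  if (length(gland$lumen_idx) < 2 || length(gland$ring_idx) < 2)
    stopf("degenerate gland: lumen and ring must each have >= 2 pixels")
  d <- gland$dim
  pos <- arrayInd(c(gland$lumen_idx, gland$ring_idx), d)
  r0 <- max(1L, min(pos[, 1]) - 2L); r1 <- min(d[1], max(pos[, 1]) + 2L)
  c0 <- max(1L, min(pos[, 2]) - 2L); c1 <- min(d[2], max(pos[, 2]) + 2L)
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  crop_index <- function(idx) {
    p <- arrayInd(idx, d)
    (p[, 2] - c0) * nr + (p[, 1] - r0 + 1L)
  }
  lumen <- matrix(FALSE, nr, nc); lumen[crop_index(gland$lumen_idx)] <- TRUE
  ring <- matrix(FALSE, nr, nc); ring[crop_index(gland$ring_idx)] <- TRUE

  lumen_area <- sum(lumen)
  epi_area <- sum(ring)
  filled <- fill_holes(ring | lumen)
  p_outer <- region_perimeter(filled)
  p_lumen <- region_perimeter(lumen)
  roundness <- function(a, p) min(1, 4 * pi * a / p^2)

  # Euclidean distance of every pixel to the nearest lumen pixel
  dmap <- EBImage::imageData(EBImage::distmap(
    matrix(as.numeric(!lumen), nr, nc)))
  eroded <- EBImage::imageData(EBImage::erode(
    matrix(as.numeric(filled), nr, nc), EBImage::makeBrush(3, "box"))) > 0
  boundary <- filled & !eroded
  wall <- mean(dmap[boundary])

  data.frame(
    epithelial_area = epi_area,
    epithelial_roundness = roundness(epi_area, p_outer),
    wall_thickness = wall,
    luminal_area = lumen_area,
    luminal_roundness = roundness(lumen_area, p_lumen),
    cell_fraction = 100 * epi_area / (epi_area + lumen_area)
  )
}

#' Feature table of all glands in a tile
#'
#' @param glands list from [find_glands()]
#' @return data.frame with one row per gland (`gland_id` plus the six features
#'   of [compute_gland_features()]); zero rows when there are no glands
#' @export
gland_feature_table <- function(glands) {
  if (!length(glands)) {
    return(data.frame(gland_id = integer(), epithelial_area = numeric(),
                      epithelial_roundness = numeric(), wall_thickness = numeric(),
                      luminal_area = numeric(), luminal_roundness = numeric(),
                      cell_fraction = numeric()))
  }
  rows <- lapply(glands, function(g) cbind(gland_id = g$gland_id,
                                           compute_gland_features(g)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gland_feature_names <- function() {
  c("epithelial_area", "epithelial_roundness", "wall_thickness",
    "luminal_area", "luminal_roundness", "cell_fraction")
}

#' Names of the 24 tile feature slots
#'
#' Eight pathomic features (two whole-tile area fractions plus six per-gland
#' features) each summarized as mean, median and variance: 24 slots per tile.
#'
#' @return character vector of length 24
#' @export
feature_slot_names <- function() {
  feats <- c("stromal_area_fraction", "epithelial_area_fraction",
             gland_feature_names())
  as.vector(t(outer(feats, c("mean", "median", "var"), paste, sep = "_")))
}

#' Summarize a tile into its 24-slot feature vector
#'
#' Whole-tile stromal and epithelial area fractions are class pixel counts over
#' total tile pixels; being single values per tile, they fill their mean and
#' median slots with the value and their variance slot with 0. The six
#' per-gland features are summarized over the tile's glands by unweighted
#' mean, median and population variance (n denominator, so a one-gland tile
#' has variance 0). Tiles without glands emit 0 for all 18 gland slots.
#'
#' @param map integer class map of the tile
#' @param glands list from [find_glands()] (or a precomputed
#'   [gland_feature_table()] data.frame)
#' @return one-row data.frame: the 24 slots of [feature_slot_names()] plus
#'   `gland_count` (bookkeeping, not a classifier input)
#' @export
summarize_tile <- function(map, glands) {
  total <- length(map)
  ft <- if (is.data.frame(glands)) glands else gland_feature_table(glands)
  pop_var <- function(x) mean((x - mean(x))^2)
  out <- list(
    stromal_area_fraction_mean = sum(map == 1L) / total,
    stromal_area_fraction_median = sum(map == 1L) / total,
    stromal_area_fraction_var = 0,
    epithelial_area_fraction_mean = sum(map == 2L) / total,
    epithelial_area_fraction_median = sum(map == 2L) / total,
    epithelial_area_fraction_var = 0
  )
  for (f in gland_feature_names()) {
    v <- ft[[f]]
    if (is.null(v) || !length(v)) {
      out[[paste0(f, "_mean")]] <- 0
      out[[paste0(f, "_median")]] <- 0
      out[[paste0(f, "_var")]] <- 0
    } else {
      out[[paste0(f, "_mean")]] <- mean(v)
      out[[paste0(f, "_median")]] <- stats::median(v)
      out[[paste0(f, "_var")]] <- pop_var(v)
    }
  }
  res <- as.data.frame(out)[, feature_slot_names()]
  res$gland_count <- nrow(ft)
  res
}

#' Extract the tile feature vector straight from an RGB tile
#'
#' Runs [segment_tile()], [find_glands()] and [summarize_tile()] in sequence.
#'
#' @param rgb integer RGB array (0-255)
#' @param downsample_factor block-mean reduction before segmentation
#' @param min_lumen_px,max_ring_distance_px gland segmentation parameters
#' @param ... further arguments passed to [segment_tile()]
#' @return one-row data.frame as from [summarize_tile()]
#' @export
extract_tile_features <- function(rgb, downsample_factor = 1,
                                  min_lumen_px = 8, max_ring_distance_px = 20,
                                  ...) {
  map <- segment_tile(rgb, downsample_factor = downsample_factor, ...)
  glands <- find_glands(map, min_lumen_px, max_ring_distance_px)
  summarize_tile(map, glands)
}

#' Fit and apply z-score normalization
#'
#' `zscore_fit` computes per-column means and standard deviations on training
#' rows only; `zscore_apply` standardizes any matrix with the stored
#' parameters (held-out rows are never refit); `zscore_invert` undoes the
#' transform. Constant columns (sd = 0) use a sentinel sd of 1 and are flagged,
#' so they transform to all zeros.
#'
#' @param x numeric matrix or all-numeric data.frame (>= 2 rows for fitting)
#' @param params a fit from `zscore_fit`
#' @return `zscore_fit`: list with `mean`, `sd`, `constant` (logical flags);
#'   `zscore_apply`/`zscore_invert`: matrix of the same shape as `x`
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need >= 2 rows to fit z-score parameters")
  if (any(!is.finite(x))) stopf("non-finite values in feature matrix")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  constant <- sd == 0
  sd[constant] <- 1
  list(mean = mu, sd = sd, constant = constant)
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(x, params) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stopf("non-finite values in feature matrix")
  if (ncol(x) != length(params$mean)) stopf("column count does not match fit")
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}

#' @rdname zscore_fit
#' @export
zscore_invert <- function(x, params) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$sd, "*"), 2, params$mean, "+")
}

#' Z-score parameters as a JSON sidecar
#'
#' @param params a [zscore_fit()] result
#' @param path JSON file path
#' @return `read_zscore_params` returns the parameter list; the writer returns
#'   `path` invisibly
#' @export
write_zscore_params <- function(params, path) {
  jsonlite::write_json(lapply(params, as.vector), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_zscore_params
#' @export
read_zscore_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(mean = as.numeric(p$mean), sd = as.numeric(p$sd),
       constant = as.logical(p$constant))
}
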