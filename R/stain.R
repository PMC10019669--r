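# Stain color deconvolution and stroma/epithelium/lumen pixel classification.
#
# H&E stain amounts mix linearly in optical-density (OD) space, so the RGB
# image is converted to OD and unmixed against a matrix of unit-norm stain OD
# vectors. Pixels with near-zero total OD are lumen/background; stained pixels
# are epithelium when the hematoxylin concentration dominates eosin, stroma
# otherwise.

#' Standard H&E stain vectors
#'
#' Unit-norm optical-density vectors for hematoxylin and eosin (the widely
#' published values H = (0.65, 0.70, 0.29), E = (0.07, 0.99, 0.11), each
#' normalized), with the residual channel as their normalized cross product.
#'
#' @param hematoxylin,eosin length-3 OD direction vectors; normalized
#'   internally
#' @return 3 x 3 matrix with unit-norm columns `hematoxylin, eosin, residual`
#' @export
he_stain_vectors <- function(hematoxylin = c(0.65, 0.70, 0.29),
                             eosin = c(0.07, 0.99, 0.11)) {
  unit <- function(v) v / sqrt(sum(v^2))
  h <- unit(hematoxylin); e <- unit(eosin)
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  m <- cbind(hematoxylin = h, eosin = e, residual = unit(r))
  rownames(m) <- c("R", "G", "B")
  m
}

#' RGB to optical density
#'
#' Per channel, `OD = -log10((I + 1) / 256)` for 8-bit intensities `I`; the
#' +1 offset keeps pure black finite and makes pure white map to OD
#' `-log10(256/256) = 0`.
#'
#' @param rgb integer RGB array (0-255)
#' @return numeric array of non-negative optical densities, same shape
#' @export
rgb_to_od <- function(rgb) {
  -log10((rgb + 1) / 256)
}

#' Unmix optical densities into stain concentrations
#'
#' Solves the 3 x 3 linear system `od = M %*% conc` per pixel, where `M` holds
#' the stain OD vectors as columns. Negative concentrations (noise outside the
#' stain simplex) are clipped to zero.
#'
#' @param od OD array from [rgb_to_od()]
#' @param vectors stain matrix from [he_stain_vectors()]
#' @param clip clip negative concentrations to 0 (default `TRUE`)
#' @return array of concentrations with channels `hematoxylin, eosin, residual`
#' @export
deconvolve_stains <- function(od, vectors = he_stain_vectors(), clip = TRUE) {
  if (rcond(vectors) < 1e-12) stopf("stain matrix is singular or near-singular")
  d <- dim(od)
  flat <- matrix(od, ncol = 3)
  conc <- flat %*% t(solve(vectors))
  if (clip) conc[conc < 0] <- 0
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, colnames(vectors))
  out
}

#' Recompose optical densities from stain concentrations
#'
#' Inverse of [deconvolve_stains()] for non-negative concentrations:
#' `od = conc %*% t(M)` per pixel.
#'
#' @param conc concentration array
#' @param vectors stain matrix
#' @return OD array
#' @export
compose_od <- function(conc, vectors = he_stain_vectors()) {
  d <- dim(conc)
  array(matrix(conc, ncol = 3) %*% t(vectors), dim = d)
}

#' Classify pixels into stroma, epithelium and lumen
#'
#' Lumen/background where the total OD (sum over RGB channels) is below
#' `white_od_threshold`; otherwise epithelium where the hematoxylin
#' concentration strictly exceeds eosin, else stroma (ties break to stroma).
#'
#' @param conc concentrations from [deconvolve_stains()]
#' @param od OD array from [rgb_to_od()] (for the total-OD lumen rule)
#' @param white_od_threshold total-OD threshold below which a pixel is lumen
#'   (default 0.15)
#' @return integer class map matrix (1 = stroma, 2 = epithelium, 3 = lumen; see
#'   [tissue_classes()])
#' @export
classify_pixels <- function(conc, od, white_od_threshold = 0.15) {
  total <- od[, , 1] + od[, , 2] + od[, , 3]
  map <- matrix(1L, nrow(total), ncol(total))
  map[conc[, , 1] > conc[, , 2]] <- 2L
  map[total < white_od_threshold] <- 3L
  map
}

#' Clean a tissue class map
#'
#' Three passes that remove segmentation noise while preserving the partition:
#' a 3 x 3 majority (mode) filter (ties keep the original label); epithelium or
#' lumen connected components smaller than `min_object_px` reassigned to the
#' majority label of their surrounding pixels; lumen components smaller than
#' `max_hole_px` that are entirely surrounded by epithelium filled as
#' epithelium. Idempotent on clean maps.
#'
#' @param map integer class map (1 = stroma, 2 = epithelium, 3 = lumen)
#' @param min_object_px minimum epithelium/lumen object size (default 30)
#' @param max_hole_px maximum lumen-hole size filled inside epithelium
#'   (default 50)
#' @return cleaned integer class map (still a partition)
#' @export
clean_class_map <- function(map, min_object_px = 30, max_hole_px = 50) {
  map <- mode_filter3(map)
  # small epithelium/lumen objects -> surrounding majority
  for (cls in c(2L, 3L)) {
    lab <- label_components(map == cls, connectivity = 8)
    if (max(lab) == 0) next
    areas <- label_areas(lab)
    small <- as.integer(names(areas)[areas < min_object_px])
    for (id in small) {
      obj <- lab == id
      ring <- EBImage::imageData(EBImage::dilate(
        matrix(as.numeric(obj), nrow(obj), ncol(obj)),
        EBImage::makeBrush(3, "box"))) > 0 & !obj
      nb <- map[ring]
      nb <- nb[nb != cls]
      map[obj] <- if (length(nb)) as.integer(names(which.max(table(nb)))) else 1L
    }
  }
  # small lumen holes fully inside epithelium -> epithelium
  lab <- label_components(map == 3L, connectivity = 8)
  if (max(lab) > 0) {
    areas <- label_areas(lab)
    border_ids <- labels_touching_border(lab)
    for (id in as.integer(names(areas)[areas < max_hole_px])) {
      if (id %in% border_ids) next
      obj <- lab == id
      ring <- EBImage::imageData(EBImage::dilate(
        matrix(as.numeric(obj), nrow(obj), ncol(obj)),
        EBImage::makeBrush(3, "box"))) > 0 & !obj
      if (all(map[ring] == 2L)) map[obj] <- 2L
    }
  }
  map
}

# 3x3 majority filter over a small-integer label matrix; ties (including the
# center's own count) keep the original label.
mode_filter3 <- function(map) {
  w <- matrix(1, 3, 3)
  counts <- lapply(sort(unique(as.vector(map))), function(cls) {
    EBImage::imageData(EBImage::filter2(matrix(as.numeric(map == cls),
                                               nrow(map), ncol(map)),
                                        w, boundary = "replicate"))
  })
  classes <- sort(unique(as.vector(map)))
  best <- counts[[1]]
  best_cls <- matrix(classes[1], nrow(map), ncol(map))
  if (length(classes) > 1) {
    for (k in 2:length(classes)) {
      better <- counts[[k]] > best + 1e-9
      best[better] <- counts[[k]][better]
      best_cls[better] <- classes[k]
    }
  }
  # strict-majority requirement: keep original label unless some class strictly
  # dominates the original's own neighborhood count
  orig_count <- matrix(0, nrow(map), ncol(map))
  for (k in seq_along(classes)) {
    sel <- map == classes[k]
    orig_count[sel] <- counts[[k]][sel]
  }
  out <- map
  change <- best > orig_count + 1e-9
  out[change] <- best_cls[change]
  matrix(as.integer(out), nrow(map), ncol(map))
}

#' Segment an RGB tile into tissue classes
#'
#' Convenience pipeline: optional block-mean down-sampling, OD conversion,
#' stain deconvolution, pixel classification, and cleanup filtering.
#'
#' @param rgb integer RGB array (0-255)
#' @param vectors stain matrix (default [he_stain_vectors()])
#' @param white_od_threshold total-OD lumen threshold (default 0.15)
#' @param downsample_factor block-mean reduction applied before segmentation
#'   (default 1; whole-slide tiles at full scan resolution use 8)
#' @param clean apply [clean_class_map()] (default `TRUE`)
#' @param min_object_px,max_hole_px cleanup parameters, at the down-sampled
#'   scale
#' @return integer class map at the down-sampled size
#' @export
segment_tile <- function(rgb, vectors = he_stain_vectors(),
                         white_od_threshold = 0.15, downsample_factor = 1,
                         clean = TRUE, min_object_px = 30, max_hole_px = 50) {
  if (downsample_factor > 1) rgb <- downsample_image(rgb, downsample_factor)
  od <- rgb_to_od(rgb)
  conc <- deconvolve_stains(od, vectors)
  map <- classify_pixels(conc, od, white_od_threshold)
  if (clean) map <- clean_class_map(map, min_object_px, max_hole_px)
  map
}
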