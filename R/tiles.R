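# Tile grid construction, annotation-mask coverage, and tile selection.
#
# Slides are divided into non-overlapping half-open pixel boxes (0-based,
# row-major). A tile is eligible for a class when strictly more than half of
# its pixels carry that class's annotation after non-tissue removal; a fixed
# per-ROI quota is sampled from eligible tiles, ROIs too small for the quota
# are dropped entirely, and unlabeled benign tissue is sampled per slide.

#' Build the tile grid over a slide
#'
#' Divides a `slide_width` x `slide_height` slide into `tile_size` tiles,
#' recording x- and y-coordinate look-up tables from grid column/row to pixel
#' ranges. Boxes are half-open `[x0, x1) x [y0, y1)` in 0-based slide
#' coordinates; boxes in the last column/row are clipped at the slide edge.
#'
#' @param slide_width,slide_height slide dimensions in pixels
#' @param tile_size tile edge length in pixels (`1 <= tile_size <=` slide dims)
#' @return object of class `coord_lookup`: list with data.frames `x`
#'   (`grid_col, x0, x1`) and `y` (`grid_row, y0, y1`), plus `tile_size` and
#'   `slide_dims`
#' @export
build_tile_grid <- function(slide_width, slide_height, tile_size) {
  if (slide_width <= 0 || slide_height <= 0) stopf("slide dimensions must be positive")
  if (tile_size < 1) stopf("tile_size must be >= 1")
  if (tile_size > slide_width || tile_size > slide_height)
    stopf("tile_size exceeds slide dimensions")
  ncols <- ceiling(slide_width / tile_size)
  nrows <- ceiling(slide_height / tile_size)
  x0 <- (seq_len(ncols) - 1L) * tile_size
  y0 <- (seq_len(nrows) - 1L) * tile_size
  structure(list(
    x = data.frame(grid_col = seq_len(ncols) - 1L, x0 = x0,
                   x1 = pmin(x0 + tile_size, slide_width)),
    y = data.frame(grid_row = seq_len(nrows) - 1L, y0 = y0,
                   y1 = pmin(y0 + tile_size, slide_height)),
    tile_size = as.integer(tile_size),
    slide_dims = c(width = as.integer(slide_width), height = as.integer(slide_height))
  ), class = "coord_lookup")
}

#' Pixel box of a grid cell, and the inverse lookup
#'
#' `tile_box` maps 0-based grid coordinates to the half-open pixel box
#' `c(x0, y0, x1, y1)`; `grid_coords` maps a box back to its grid coordinates
#' (the round trip is the identity).
#'
#' @param lookup a [build_tile_grid()] result
#' @param grid_col,grid_row 0-based grid coordinates
#' @param box half-open pixel box `c(x0, y0, x1, y1)`
#' @return `tile_box`: numeric box; `grid_coords`: `c(grid_col, grid_row)`
#' @export
tile_box <- function(lookup, grid_col, grid_row) {
  xi <- match(grid_col, lookup$x$grid_col)
  yi <- match(grid_row, lookup$y$grid_row)
  if (is.na(xi) || is.na(yi)) stopf("grid coordinates out of range")
  c(x0 = lookup$x$x0[xi], y0 = lookup$y$y0[yi],
    x1 = lookup$x$x1[xi], y1 = lookup$y$y1[yi])
}

#' @rdname tile_box
#' @export
grid_coords <- function(lookup, box) {
  xi <- which(lookup$x$x0 == box[1])
  yi <- which(lookup$y$y0 == box[2])
  if (length(xi) != 1 || length(yi) != 1) stopf("box does not align with the grid")
  c(grid_col = lookup$x$grid_col[xi], grid_row = lookup$y$grid_row[yi])
}

#' Non-tissue mask of an RGB image
#'
#' Marks background, lumen and bright artifacts: after 3 x 3 median smoothing
#' of each channel, a pixel is non-tissue when `min(R, G, B) >= threshold`.
#' The mask is subtracted from every annotation class mask before tile
#' selection so that only representative tissue is counted.
#'
#' @param rgb integer RGB array (0-255)
#' @param threshold 8-bit brightness threshold (default 220)
#' @return logical matrix, `TRUE` where non-tissue
#' @export
compute_non_tissue_mask <- function(rgb, threshold = 220) {
  sm <- array(0, dim = dim(rgb))
  for (ch in 1:3) {
    sm[, , ch] <- EBImage::imageData(
      EBImage::medianFilter(rgb[, , ch] / 255, size = 1)) * 255
  }
  pmin(sm[, , 1], pmin(sm[, , 2], sm[, , 3])) >= threshold
}

#' Fraction of a pixel box covered by a mask
#'
#' Exact ratio of set mask pixels inside the half-open box to the box area.
#'
#' @param box half-open pixel box `c(x0, y0, x1, y1)`, 0-based
#' @param mask logical matrix at slide resolution (rows = y, cols = x)
#' @return real in `[0, 1]`
#' @export
compute_mask_fraction <- function(box, mask) {
  x0 <- box[1]; y0 <- box[2]; x1 <- box[3]; y1 <- box[4]
  if (x1 <= x0 || y1 <= y0) stopf("empty box")
  if (x0 < 0 || y0 < 0 || y1 > nrow(mask) || x1 > ncol(mask))
    stopf("box outside slide bounds")
  sum(mask[(y0 + 1):y1, (x0 + 1):x1]) / ((x1 - x0) * (y1 - y0))
}

# Full-size (non-clipped) grid boxes as a data.frame; clipped edge boxes are
# kept in the grid for bookkeeping but are never eligible for selection.
full_size_boxes <- function(lookup) {
  ts <- lookup$tile_size
  xs <- lookup$x[lookup$x$x1 - lookup$x$x0 == ts, ]
  ys <- lookup$y[lookup$y$y1 - lookup$y$y0 == ts, ]
  g <- expand.grid(xi = seq_len(nrow(xs)), yi = seq_len(nrow(ys)))
  data.frame(grid_col = xs$grid_col[g$xi], grid_row = ys$grid_row[g$yi],
             x0 = xs$x0[g$xi], y0 = ys$y0[g$yi],
             x1 = xs$x1[g$xi], y1 = ys$y1[g$yi])
}

# Eligible tiles of one mask: full-size boxes whose coverage fraction is
# strictly greater than the threshold, ordered by (grid_row, grid_col).
eligible_tiles <- function(mask, lookup, threshold) {
  boxes <- full_size_boxes(lookup)
  frac <- vapply(seq_len(nrow(boxes)), function(i)
    compute_mask_fraction(unlist(boxes[i, c("x0", "y0", "x1", "y1")]), mask),
    numeric(1))
  out <- boxes[frac > threshold, , drop = FALSE]
  out$in_mask_fraction <- frac[frac > threshold]
  out[order(out$grid_row, out$grid_col), , drop = FALSE]
}

#' Select labeled tiles from annotation masks
#'
#' For each annotated class, each connected region of interest (ROI) is
#' intersected with the tile grid; tiles whose in-ROI pixel fraction is
#' strictly greater than `threshold` are eligible, and exactly `per_roi_quota`
#' of them are sampled without replacement (seeded). ROIs with fewer than
#' `per_roi_quota` eligible tiles are excluded entirely. Unlabeled benign
#' tissue is sampled per slide instead: up to `benign_per_slide` eligible
#' benign tiles. The non-tissue mask is removed from every class mask first.
#' Selection is deterministic in `seed` and independent of the order in which
#' masks are supplied.
#'
#' @param mask_set named list of logical class masks at slide resolution (names
#'   from [annotation_classes()]), optionally with a `non_tissue` element
#' @param lookup a [build_tile_grid()] over the same slide
#' @param threshold coverage threshold (strict `>`; default 0.5)
#' @param per_roi_quota tiles sampled per ROI (default 5)
#' @param benign_per_slide benign tiles sampled per slide (default 15)
#' @param seed integer seed
#' @param slide_id slide identifier recorded in the output
#' @return data.frame of tile records: `slide_id, grid_col, grid_row, x0, y0,
#'   x1, y1, label, in_mask_fraction, roi_id`
#' @export
select_roi_tiles <- function(mask_set, lookup, threshold = 0.5,
                             per_roi_quota = 5, benign_per_slide = 15,
                             seed = 1, slide_id = "slide") {
  non_tissue <- mask_set$non_tissue
  classes <- intersect(annotation_classes(), names(mask_set))
  records <- list()
  for (cls in classes) {
    mask <- mask_set[[cls]]
    if (!is.null(non_tissue)) mask <- mask & !non_tissue
    if (!any(mask)) next
    if (cls == "benign") {
      elig <- eligible_tiles(mask, lookup, threshold)
      if (nrow(elig) == 0) next
      k <- min(benign_per_slide, nrow(elig))
      idx <- with_seed(derive_seed(seed, cls, 0L),
                       sample(seq_len(nrow(elig)), k))
      sel <- elig[sort(idx), , drop = FALSE]
      sel$label <- cls
      sel$roi_id <- 0L
      records[[length(records) + 1L]] <- sel
    } else {
      lab <- label_components(mask, connectivity = 8)
      for (roi in seq_len(max(lab, 0))) {
        elig <- eligible_tiles(lab == roi, lookup, threshold)
        if (nrow(elig) < per_roi_quota) next  # ROI too small for the quota
        idx <- with_seed(derive_seed(seed, cls, roi),
                         sample(seq_len(nrow(elig)), per_roi_quota))
        sel <- elig[sort(idx), , drop = FALSE]
        sel$label <- cls
        sel$roi_id <- roi
        records[[length(records) + 1L]] <- sel
      }
    }
  }
  if (!length(records)) {
    return(data.frame(slide_id = character(), grid_col = integer(),
                      grid_row = integer(), x0 = integer(), y0 = integer(),
                      x1 = integer(), y1 = integer(), label = character(),
                      in_mask_fraction = numeric(), roi_id = integer()))
  }
  out <- do.call(rbind, records)
  out <- cbind(slide_id = slide_id, out)
  rownames(out) <- NULL
  out[, c("slide_id", "grid_col", "grid_row", "x0", "y0", "x1", "y1",
          "label", "in_mask_fraction", "roi_id")]
}

#' Split a tile into sub-tiles under the coverage rule
#'
#' Divides a tile box into `sub_size` sub-tiles on an evenly spaced anchor
#' grid (`ceiling(tile/sub_size)` anchors per axis, overlapping when
#' `sub_size` does not divide the tile size; a 3000 px tile with 1024 px
#' sub-tiles uses offsets 0, 988, 1976 per axis). Sub-tiles whose in-mask
#' fraction is strictly greater than `threshold` are returned, so a fully
#' masked 3000 px tile yields 9 sub-tiles.
#'
#' @param box parent tile box `c(x0, y0, x1, y1)` (half-open, 0-based)
#' @param mask logical class mask at slide resolution
#' @param sub_size sub-tile edge length (default 1024, `<=` tile size)
#' @param threshold coverage threshold (strict `>`; default 0.5)
#' @return data.frame of sub-tile boxes `x0, y0, x1, y1, in_mask_fraction`
#' @export
subtile <- function(box, mask, sub_size = 1024, threshold = 0.5) {
  tw <- box[3] - box[1]; th <- box[4] - box[2]
  if (sub_size > min(tw, th)) stopf("sub_size exceeds tile size")
  offs <- function(total) {
    n <- ceiling(total / sub_size)
    if (n == 1) 0 else round(seq(0, total - sub_size, length.out = n))
  }
  ox <- offs(tw); oy <- offs(th)
  g <- expand.grid(ox = ox, oy = oy)
  out <- data.frame(x0 = box[1] + g$ox, y0 = box[2] + g$oy)
  out$x1 <- out$x0 + sub_size
  out$y1 <- out$y0 + sub_size
  frac <- vapply(seq_len(nrow(out)), function(i)
    compute_mask_fraction(unlist(out[i, ]), mask), numeric(1))
  out$in_mask_fraction <- frac
  out[frac > threshold, , drop = FALSE]
}
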