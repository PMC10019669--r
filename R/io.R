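# Class taxonomy, color palettes, and image/table I/O.

#' Annotation classes
#'
#' The eight histological annotation classes: unlabeled benign tissue, atrophy,
#' high-grade prostatic intraepithelial neoplasia (HGPIN), seminal vesicle,
#' Gleason pattern 3 (G3), Gleason pattern 4 cribriform (G4CG) and
#' non-cribriform (G4NC), and Gleason pattern 5 (G5).
#'
#' @return character vector of the eight class names, in canonical order
#' @export
annotation_classes <- function() {
  c("benign", "atrophy", "HGPIN", "seminal_vesicle", "G3", "G4CG", "G4NC", "G5")
}

#' Tissue classes of the pixel-level segmentation
#'
#' @return character vector `c("stroma", "epithelium", "lumen")`; integer class
#'   maps use 1, 2, 3 in this order
#' @export
tissue_classes <- function() c("stroma", "epithelium", "lumen")

#' Display palette for annotation and model classes
#'
#' Fixed color table used for annotation masks, synthetic-tile manifests and
#' rendered prediction maps. Includes the eight annotation classes plus the
#' merged model classes (NC, CA, HG, LG) and a background color.
#'
#' @return named list of RGB triples (0-255 integers)
#' @export
annotation_palette <- function() {
  list(
    benign          = c(60L, 160L, 60L),
    atrophy         = c(140L, 205L, 140L),
    HGPIN           = c(0L, 160L, 160L),
    seminal_vesicle = c(150L, 150L, 40L),
    G3              = c(250L, 220L, 0L),
    G4CG            = c(250L, 140L, 0L),
    G4NC            = c(230L, 80L, 30L),
    G5              = c(180L, 0L, 0L),
    NC              = c(60L, 160L, 60L),
    CA              = c(200L, 30L, 30L),
    HG              = c(180L, 0L, 60L),
    LG              = c(250L, 220L, 0L),
    background      = c(255L, 255L, 255L)
  )
}

#' Read and write 8-bit RGB images as PNG
#'
#' Images are held in memory as `height x width x 3` integer arrays with values
#' in 0-255 (rows = y from the top, columns = x).
#'
#' @param img integer RGB array
#' @param path file path
#' @return `read_rgb_png` returns the integer array; `write_rgb_png` returns
#'   `path` invisibly
#' @export
write_rgb_png <- function(img, path) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) stopf("expected an RGB array")
  png::writePNG(array(clamp(round(img), 0, 255) / 255, dim = dim(img)), path)
  invisible(path)
}

#' @rdname write_rgb_png
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' Read and write class-index masks as PNG
#'
#' A mask or class map is an integer matrix of class indices. It is stored as a
#' single-channel 8-bit PNG whose pixel value is the class index itself, with
#' the index-to-class mapping carried separately (see [annotation_palette()] and
#' [tissue_classes()]); this round-trips losslessly for up to 255 classes.
#'
#' @param mask integer matrix with values in 0-255
#' @param path file path
#' @return `read_mask_png` returns the integer matrix; `write_mask_png` returns
#'   `path` invisibly
#' @export
write_mask_png <- function(mask, path) {
  if (any(mask < 0 | mask > 255)) stopf("mask indices must be in 0-255")
  png::writePNG(matrix(as.integer(mask), nrow(mask), ncol(mask)) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Write and read tile manifests
#'
#' A tile manifest is a data frame with one row per tile record:
#' `slide_id, grid_col, grid_row, x0, y0, x1, y1, label, in_mask_fraction`
#' (pixel boxes are half-open, 0-based). Written as plain CSV with a header.
#'
#' @param manifest data.frame of tile records
#' @param path file path
#' @return `read_tile_manifest` returns the data.frame; the writer returns
#'   `path` invisibly
#' @export
write_tile_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tile_manifest
#' @export
read_tile_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
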