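# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators behave as pure functions of their
#' arguments without perturbing the session's random stream.
#'
#' @param seed single integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable integer seed derived from a master seed plus arbitrary string/integer
# context (class name, tile index, learner index ...). Plain 32-bit modular
# arithmetic on doubles (exact below 2^53); result in [1, 2^31 - 2].
derive_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.numeric(master) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# value clamped into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Block-mean image down-sampling
#'
#' Reduces an image by an integer factor, replacing each `factor` x `factor`
#' block by its mean. Whole-slide scans are reduced this way before stain
#' segmentation and morphometry; tile/mask coverage bookkeeping always happens
#' at full resolution.
#'
#' @param img numeric matrix, or array with a third (channel) dimension
#' @param factor integer reduction factor >= 1; trailing rows/columns that do
#'   not fill a complete block are dropped
#' @return matrix or array of the reduced size
#' @export
downsample_image <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stopf("downsample factor must be >= 1")
  if (factor == 1L) return(img)
  ds2 <- function(m) {
    nr <- (nrow(m) %/% factor) * factor
    nc <- (ncol(m) %/% factor) * factor
    if (nr < factor || nc < factor) stopf("image smaller than one block")
    m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
    a <- array(m, dim = c(factor, nr %/% factor, factor, nc %/% factor))
    colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
  }
  if (length(dim(img)) == 3) {
    ch <- lapply(seq_len(dim(img)[3]), function(k) ds2(img[, , k]))
    out <- array(0, dim = c(dim(ch[[1]]), length(ch)))
    for (k in seq_along(ch)) out[, , k] <- ch[[k]]
    out
  } else {
    ds2(img)
  }
}

# Connected-component labeling of a logical/0-1 matrix. EBImage::bwlabel is
# 4-connected; for 8-connectivity, 4-connected labels that touch diagonally are
# merged with a union-find pass over the label adjacency pairs.
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal pairs
  c1 <- lab[-nr, -1]; d1 <- lab[-1, -nc]   # down-left diagonal pairs
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c1), as.vector(d1))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Pixel areas of each label in a label matrix; names are label ids.
label_areas <- function(lab) {
  tab <- tabulate(lab[lab > 0])
  stats::setNames(tab, seq_along(tab))
}

# TRUE for labels whose pixels touch the matrix border.
labels_touching_border <- function(lab) {
  border <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  sort(unique(border[border > 0]))
}

# Outer-contour perimeter of a single-object logical mask. The boundary pixel
# chain from EBImage::ocontour is smoothed (each vertex averaged with its
# k-th neighbors) before summing polygon edge lengths: raw chain-code length
# overestimates smooth boundaries by ~5.5% from pixel quantization, while the
# smoothed polygon tracks digitized discs and ellipses within ~1% for radii
# >= 20 px. Very short contours (< 8 points) fall back to Kulpa-corrected
# chain length.
region_perimeter <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  oc <- EBImage::ocontour(lab)
  if (length(oc) == 0) return(NA_real_)
  # outer contour of the largest object (holes are not traced by ocontour)
  sizes <- label_areas(EBImage::imageData(lab))
  pts <- oc[[which.max(sizes)]]
  n <- nrow(pts)
  if (n < 3) return(NA_real_)
  if (n < 8) {
    steps <- diff(rbind(pts, pts[1, , drop = FALSE]))
    return(0.948 * sum(sqrt(rowSums(steps^2))))
  }
  k <- 2L
  sm <- pts
  for (j in 1:2) {
    sm[, j] <- (pts[((seq_len(n) - 1 - k) %% n) + 1, j] + pts[, j] +
                  pts[((seq_len(n) - 1 + k) %% n) + 1, j]) / 3
  }
  sum(sqrt(rowSums((sm - sm[c(2:n, 1), , drop = FALSE])^2)))
}

# Fill holes of a mask (logical matrix): background components that do not
# touch the matrix border are interior and get filled.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4)
  outside <- labels_touching_border(bg)
  interior <- bg > 0 & !(bg %in% outside)
  mask | interior
}
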