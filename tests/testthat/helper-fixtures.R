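# Shared fixtures: small synthetic specs, hand-built geometry, and independent
# brute-force oracles used against the package's vectorized implementations.

# class map containing a digital disc of lumen (3) in stroma (1), optionally
# wrapped in an epithelial (2) annulus out to radius R
disc_map <- function(size, cx, cy, r, R = NULL) {
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)  # cols = x
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size) # rows = y
  d2 <- (xs - cx)^2 + (ys - cy)^2
  map <- matrix(1L, size, size)
  if (!is.null(R)) map[d2 <= R^2] <- 2L
  map[d2 <= r^2] <- 3L
  map
}

# axis-aligned ellipse lumen (semi-axes a, b) with epithelial margin w
ellipse_map <- function(size, cx, cy, a, b, w) {
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)
  map <- matrix(1L, size, size)
  map[((xs - cx) / (a + w))^2 + ((ys - cy) / (b + w))^2 <= 1] <- 2L
  map[((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1] <- 3L
  map
}

# exact ellipse perimeter by numeric quadrature of the arc-length integral
ellipse_perimeter_exact <- function(a, b) {
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-10)$value
}

# brute-force per-pixel loop oracle for box coverage fractions
brute_fraction <- function(box, mask) {
  hits <- 0L
  for (x in (box[1] + 1):box[3])
    for (y in (box[2] + 1):box[4])
      if (mask[y, x]) hits <- hits + 1L
  hits / ((box[3] - box[1]) * (box[4] - box[2]))
}

# plain queue-based flood fill (8-connected) counting components of a logical
# mask; independent of the package's labeling path
flood_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask)) {
          q <- (c2 - 1L) * nrow(mask) + rr
          if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
    }
  }
  count
}

# small shared synthetic feature dataset, built once per session
.fixture_env <- new.env(parent = emptyenv())
shared_small_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- synthetic_feature_dataset(
      n_per_class = 12, classes = c("benign", "atrophy", "G3", "G4NC"),
      tile_size_px = 256, seed = 7)
  }
  .fixture_env$ds
}
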