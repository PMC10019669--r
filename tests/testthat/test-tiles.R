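test_that("tile grids cover the slide with clipped edge boxes", {
  g <- build_tile_grid(9000, 6000, 3000)
  expect_equal(nrow(g$x), 3)
  expect_equal(nrow(g$y), 2)
  expect_true(all(g$x$x1 - g$x$x0 == 3000))
  expect_true(all(g$y$y1 - g$y$y0 == 3000))

  g2 <- build_tile_grid(7000, 3000, 3000)
  expect_equal(nrow(g2$x), 3)
  expect_equal(nrow(g2$y), 1)
  expect_equal(g2$x$x1[3] - g2$x$x0[3], 1000)  # last column clipped

  g3 <- build_tile_grid(3000, 3000, 3000)
  expect_equal(unname(tile_box(g3, 0, 0)), c(0, 0, 3000, 3000))

  # grid boxes are disjoint and conserve pixel count
  areas <- outer(g$y$y1 - g$y$y0, g$x$x1 - g$x$x0)
  expect_equal(sum(areas), 9000 * 6000)

  expect_error(build_tile_grid(0, 100, 10), "positive")
  expect_error(build_tile_grid(100, 100, 200), "exceeds")
})

test_that("grid coordinates and pixel boxes round-trip", {
  g <- build_tile_grid(1000, 700, 300)
  for (col in g$x$grid_col) for (row in g$y$grid_row) {
    box <- tile_box(g, col, row)
    expect_equal(unname(grid_coords(g, box)), c(col, row))
  }
})

test_that("mask fractions are exact and match a brute-force pixel loop", {
  mask <- matrix(TRUE, 100, 100)
  expect_equal(compute_mask_fraction(c(10, 10, 20, 20), mask), 1.0)
  half <- matrix(FALSE, 100, 100); half[, 1:50] <- TRUE  # straight vertical edge
  expect_equal(compute_mask_fraction(c(40, 40, 60, 60), half), 0.5)
  expect_error(compute_mask_fraction(c(10, 10, 10, 20), mask), "empty box")
  expect_error(compute_mask_fraction(c(90, 90, 110, 110), mask), "bounds")

  set.seed(5)
  rmask <- matrix(runif(64 * 64) < 0.4, 64, 64)
  for (i in 1:20) {
    x0 <- sample(0:56, 1); y0 <- sample(0:56, 1)
    w <- sample(1:8, 1); h <- sample(1:8, 1)
    box <- c(x0, y0, x0 + w, y0 + h)
    expect_equal(compute_mask_fraction(box, rmask), brute_fraction(box, rmask))
  }
})

test_that("non-tissue masking flags white areas and spares stained tissue", {
  white <- array(255L, dim = c(32, 32, 3))
  expect_true(all(compute_non_tissue_mask(white)))
  pink <- array(0L, dim = c(32, 32, 3))
  pink[, , 1] <- 230L; pink[, , 2] <- 150L; pink[, , 3] <- 170L
  expect_false(any(compute_non_tissue_mask(pink)))
  # on a noise-free synthetic tile, non-tissue covers the rendered lumen
  spec <- synthetic_tile_spec("benign", tile_size_px = 256, noise_sd = 0,
                              blur = FALSE)
  tile <- generate_tile(spec, seed = 4)
  nt <- compute_non_tissue_mask(tile$rgb)
  expect_true(all(nt[tile$class_map == 3L]))
})

test_that("ROI tile selection enforces the strict majority rule and quotas", {
  # 1000 x 1000 slide on a 10 x 10 grid of 100 px tiles
  g <- build_tile_grid(1000, 1000, 100)
  mask <- matrix(FALSE, 1000, 1000)
  # ROI A: a 400 x 300 block fully covering 12 tiles
  mask[101:400, 101:500] <- TRUE
  masks <- list(G3 = mask)
  sel <- select_roi_tiles(masks, g, per_roi_quota = 5, seed = 99)
  expect_equal(nrow(sel), 5)
  expect_true(all(sel$in_mask_fraction == 1))
  # reproducible and independent of mask list order
  sel2 <- select_roi_tiles(list(extra = NULL, G3 = mask)[c("G3", "extra")],
                           g, per_roi_quota = 5, seed = 99)
  expect_equal(sel$grid_col, sel2$grid_col)
  expect_equal(sel$grid_row, sel2$grid_row)

  # ROI with only 3 eligible tiles is excluded entirely
  small <- matrix(FALSE, 1000, 1000)
  small[701:800, 101:400] <- TRUE  # 3 fully covered tiles
  expect_equal(nrow(select_roi_tiles(list(G3 = small), g, seed = 1)), 0)

  # a box exactly half covered is NOT eligible (strict >)
  edge <- matrix(FALSE, 1000, 1000)
  edge[, 1:150] <- TRUE  # second tile column covered exactly 50%
  elig <- histomorph:::eligible_tiles(edge, g, 0.5)
  expect_true(all(elig$grid_col == 0))
})

test_that("eligible tiles equal an exhaustive scan of every grid box", {
  g <- build_tile_grid(1000, 1000, 100)
  set.seed(21)
  mask <- matrix(runif(1000 * 1000) < 0.5, 1000, 1000)
  elig <- histomorph:::eligible_tiles(mask, g, 0.5)
  manual <- list()
  for (row in 0:9) for (col in 0:9) {
    box <- c(col * 100, row * 100, (col + 1) * 100, (row + 1) * 100)
    if (brute_fraction(box, mask) > 0.5)
      manual[[length(manual) + 1L]] <- c(col, row)
  }
  manual <- do.call(rbind, manual)
  expect_equal(nrow(elig), nrow(manual))
  expect_equal(elig$grid_col, manual[, 1])
  expect_equal(elig$grid_row, manual[, 2])
})

test_that("selection is monotone in the threshold", {
  g <- build_tile_grid(800, 800, 100)
  set.seed(8)
  mask <- matrix(runif(800 * 800) < 0.55, 800, 800)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(histomorph:::eligible_tiles(mask, g, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("benign tissue is sampled per slide with the slide-level quota", {
  g <- build_tile_grid(1000, 1000, 100)
  mask <- matrix(TRUE, 1000, 1000)  # all 100 tiles eligible
  sel <- select_roi_tiles(list(benign = mask), g, benign_per_slide = 15, seed = 3)
  expect_equal(nrow(sel), 15)
  expect_true(all(sel$label == "benign"))
  # shortfall: fewer eligible tiles than the quota takes all of them
  few <- matrix(FALSE, 1000, 1000); few[1:200, 1:200] <- TRUE
  sel2 <- select_roi_tiles(list(benign = few), g, benign_per_slide = 15, seed = 3)
  expect_equal(nrow(sel2), 4)
})

test_that("sub-tiling uses the overlapping 3x3 anchor layout", {
  mask <- matrix(TRUE, 3000, 3000)
  sub <- subtile(c(0, 0, 3000, 3000), mask, sub_size = 1024)
  expect_equal(nrow(sub), 9)
  expect_setequal(unique(sub$x0), c(0, 988, 1976))
  expect_setequal(unique(sub$y0), c(0, 988, 1976))
  expect_true(all(sub$x1 - sub$x0 == 1024))

  empty <- matrix(FALSE, 3000, 3000)
  expect_equal(nrow(subtile(c(0, 0, 3000, 3000), empty, 1024)), 0)
  expect_error(subtile(c(0, 0, 500, 500), mask, 1024), "exceeds")

  # half-masked tile: counts equal a direct per-sub-box fraction check
  half <- matrix(FALSE, 3000, 3000); half[, 1:1600] <- TRUE
  sub2 <- subtile(c(0, 0, 3000, 3000), half, 1024)
  manual <- 0L
  for (ox in c(0, 988, 1976)) for (oy in c(0, 988, 1976)) {
    frac <- sum(half[(oy + 1):(oy + 1024), (ox + 1):(ox + 1024)]) / 1024^2
    if (frac > 0.5) manual <- manual + 1L
  }
  expect_equal(nrow(sub2), manual)
})

test_that("block-mean down-sampling averages exact blocks", {
  m <- matrix(1:16, 4, 4)
  d <- downsample_image(m, 2)
  expect_equal(dim(d), c(2, 2))
  expect_equal(d[1, 1], mean(m[1:2, 1:2]))
  expect_equal(d[2, 2], mean(m[3:4, 3:4]))
  arr <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_equal(downsample_image(arr, 2)[, , 2], downsample_image(arr[, , 2], 2))
})
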