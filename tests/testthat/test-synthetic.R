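test_that("generation is a pure, bit-reproducible function of (spec, seed)", {
  spec <- synthetic_tile_spec("G3", tile_size_px = 256)
  set.seed(123)
  before <- runif(1)
  t1 <- generate_tile(spec, seed = 42)
  t2 <- generate_tile(spec, seed = 42)
  expect_identical(t1$rgb, t2$rgb)
  expect_identical(t1$class_map, t2$class_map)
  expect_identical(t1$glands, t2$glands)
  # caller's RNG stream is untouched
  set.seed(123)
  expect_identical(runif(1), before)
  expect_identical(runif(1), {
    set.seed(123); runif(1); generate_tile(spec, seed = 9); runif(1)
  })
})

test_that("class map is a partition and ground truth records generator parameters", {
  spec <- synthetic_tile_spec("benign", tile_size_px = 256,
                              gland_count_range = c(3, 3),
                              lumen_radius_px_range = c(40, 40),
                              wall_thickness_px_range = c(10, 10),
                              lumen_eccentricity_range = c(0, 0),
                              noise_sd = 0, blur = FALSE)
  tile <- generate_tile(spec, seed = 1)
  expect_true(all(tile$class_map %in% 1:3))
  expect_equal(nrow(tile$glands), 3)
  expect_equal(tile$glands$wall_thickness_px, rep(10, 3))
  # circular lumina of radius 40 rasterize to pi r^2 within 2%
  expect_true(all(abs(tile$glands$lumen_area_px2 / (pi * 40^2) - 1) < 0.02))
  expect_false(any(tile$glands$touches_edge))
  # rendered mask areas agree with the recorded ground truth exactly
  expect_equal(sum(tile$class_map == 3L), sum(tile$glands$lumen_area_px2))
})

test_that("rasterized circles match pi r^2 within 2% for r >= 20", {
  for (r in c(20, 28, 45, 60)) {
    spec <- synthetic_tile_spec("benign", tile_size_px = 256,
                                gland_count_range = c(1, 1),
                                lumen_radius_px_range = c(r, r),
                                wall_thickness_px_range = c(5, 5),
                                lumen_eccentricity_range = c(0, 0),
                                noise_sd = 0, blur = FALSE)
    tile <- generate_tile(spec, seed = r)
    expect_lt(abs(tile$glands$lumen_area_px2 / (pi * r^2) - 1), 0.02)
  }
})

test_that("ground-truth gland count equals lumen component count for discrete classes", {
  for (cls in c("benign", "atrophy", "G3", "G4NC")) {
    spec <- synthetic_tile_spec(cls, tile_size_px = 256, noise_sd = 0, blur = FALSE)
    tile <- generate_tile(spec, seed = 31)
    expect_equal(flood_count(tile$class_map == 3L), nrow(tile$glands),
                 info = cls)
  }
})

test_that("G5 tiles are near-lumenless epithelial sheets", {
  spec <- synthetic_tile_spec("G5", tile_size_px = 512)
  tile <- generate_tile(spec, seed = 7)
  lumen <- sum(tile$class_map == 3L)
  tissue <- sum(tile$class_map != 3L)
  expect_lt(lumen / tissue, 0.01)
  expect_gt(sum(tile$class_map == 2L), 0)
})

test_that("cribriform masses carry the requested number of internal lumina", {
  spec <- synthetic_tile_spec("G4CG", tile_size_px = 384,
                              cribriform_lumina_per_gland = 5,
                              gland_count_range = c(1, 1),
                              noise_sd = 0, blur = FALSE)
  tile <- generate_tile(spec, seed = 3)
  # brute-force flood fill of the lumen class inside the (single) mass
  expect_equal(flood_count(tile$class_map == 3L), 5)
  # all lumina sit inside the epithelial mass: dilating each lumen stays in
  # epithelium or lumen
  expect_true(all(tile$class_map[tile$class_map != 1L] %in% c(2L, 3L)))
  expect_equal(nrow(tile$glands), 5)
})

test_that("specs reject unknown classes and degenerate parameters", {
  expect_error(synthetic_tile_spec("carcinoid"), "unknown class_label")
  expect_error(synthetic_tile_spec("G3", tile_size_px = 64), ">= 128")
  expect_error(synthetic_tile_spec("G3", tile_size_px = 256,
                                   lumen_radius_px_range = c(10, 5)),
               "non-decreasing")
  expect_error(synthetic_tile_spec("G3", tile_size_px = 256,
                                   lumen_eccentricity_range = c(0, 1)),
               "eccentricity")
  # over-dense configurations fail after bounded placement attempts
  spec <- synthetic_tile_spec("benign", tile_size_px = 256,
                              gland_count_range = c(30, 30),
                              lumen_radius_px_range = c(50, 50),
                              wall_thickness_px_range = c(10, 10))
  expect_error(generate_tile(spec, seed = 1), "over-dense")
})

test_that("generate_dataset writes a deterministic per-class layout", {
  specs <- lapply(c("benign", "G3"), synthetic_tile_spec, tile_size_px = 128)
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(specs, n_per_class = 3, out_dir = d1, seed = 42)
  m2 <- generate_dataset(specs, n_per_class = 3, out_dir = d2, seed = 42)
  expect_equal(nrow(m1), 6)
  expect_setequal(list.dirs(d1, recursive = FALSE, full.names = FALSE),
                  c("benign", "G3"))
  # same master seed => byte-identical images
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", n = 1e6),
                     readBin(m2$path[i], "raw", n = 1e6))
  }
  # refuses to clobber without the flag; n_per_class = 0 rejected
  expect_error(generate_dataset(specs, 3, d1, seed = 42), "not empty")
  expect_no_error(generate_dataset(specs, 1, d1, seed = 42, overwrite = TRUE))
  expect_error(generate_dataset(specs, 0, tempfile(), seed = 1), ">= 1")
  unlink(c(d1, d2), recursive = TRUE)
})
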