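# End-to-end synthetic benchmark: generate labeled tiles, run the full
# feature-extraction pipeline on the rendered images (never on the ground
# truth), and train/evaluate the three label schemes on a stratified split.

#' Classes of the default synthetic benchmark
#'
#' Benign and atrophic tissue (mapped to NC by every scheme) plus the four
#' Gleason patterns, so all three label schemes have every model class
#' represented.
#'
#' @return character vector of class names
#' @export
benchmark_classes <- function() {
  c("benign", "atrophy", "G3", "G4CG", "G4NC", "G5")
}

#' Generate the synthetic tile feature dataset
#'
#' Renders `n_per_class` tiles per class with the synthetic generator and runs
#' each rendered RGB image through the full pipeline (stain deconvolution,
#' tissue classification, cleanup, gland segmentation, 24-slot summary).
#' Per-tile seeds derive from `(seed, class, index)`, so the dataset is a pure
#' function of its arguments.
#'
#' @param n_per_class tiles per class
#' @param classes class labels (default [benchmark_classes()])
#' @param tile_size_px synthetic tile edge length (default 384, analyzed at
#'   full resolution)
#' @param seed master integer seed
#' @param noise_sd,blur renderer settings (see [synthetic_tile_spec()])
#' @return data.frame: `tile_id, class, gland_count` plus the 24 feature slots
#' @export
synthetic_feature_dataset <- function(n_per_class = 100,
                                      classes = benchmark_classes(),
                                      tile_size_px = 384, seed = 11,
                                      noise_sd = 0.02, blur = TRUE) {
  rows <- vector("list", length(classes) * n_per_class)
  k <- 0L
  for (cls in classes) {
    spec <- synthetic_tile_spec(cls, tile_size_px = tile_size_px,
                                noise_sd = noise_sd, blur = blur)
    for (i in seq_len(n_per_class)) {
      tile <- generate_tile(spec, seed = derive_seed(seed, cls, i))
      fv <- extract_tile_features(tile$rgb)
      k <- k + 1L
      rows[[k]] <- cbind(tile_id = sprintf("%s_%03d", cls, i), class = cls, fv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified train/test split of a feature dataset
#'
#' Splits tiles within each class: a seeded sample of `round(train_frac * n)`
#' tiles per class trains, the rest test (mirroring a 2/3 - 1/3 design,
#' stratified so every class appears in both splits).
#'
#' @param dataset a [synthetic_feature_dataset()] result
#' @param train_frac fraction of each class used for training (default 2/3)
#' @param seed integer seed
#' @return list of logical vectors `train` and `test` over the dataset rows
#' @export
benchmark_split <- function(dataset, train_frac = 2 / 3, seed = 11) {
  train <- logical(nrow(dataset))
  for (cls in unique(dataset$class)) {
    idx <- which(dataset$class == cls)
    k <- round(train_frac * length(idx))
    if (k < 1 || k >= length(idx)) stopf("class '%s' too small to split", cls)
    pick <- with_seed(derive_seed(seed, "split", cls), sample(idx, k))
    train[pick] <- TRUE
  }
  list(train = train, test = !train)
}

#' Run the full synthetic benchmark
#'
#' Dataset generation, stratified split, z-scoring fitted on the training rows,
#' ensemble training and held-out evaluation for the three label schemes.
#'
#' @param n_per_class tiles per class (default 100)
#' @param seed master integer seed (default 11)
#' @param n_learners ensemble size per scheme (default 100)
#' @param tile_size_px synthetic tile edge length (default 384)
#' @param schemes scheme names to run (default all three)
#' @param dataset optionally, a precomputed [synthetic_feature_dataset()] to
#'   reuse (its generation is the expensive step)
#' @return list with `dataset`, `split`, and `suite` (per-scheme models and
#'   [evaluation_report()]s from [run_scheme_suite()])
#' @export
run_benchmark <- function(n_per_class = 100, seed = 11, n_learners = 100,
                          tile_size_px = 384,
                          schemes = c("all_grades", "hg_vs_lg", "nc_vs_ca"),
                          dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- synthetic_feature_dataset(n_per_class = n_per_class,
                                         tile_size_px = tile_size_px,
                                         seed = seed)
  }
  split <- benchmark_split(dataset, seed = seed)
  slots <- feature_slot_names()
  xtr <- dataset[split$train, slots]
  xte <- dataset[split$test, slots]
  suite <- run_scheme_suite(xtr, dataset$class[split$train],
                            xte, dataset$class[split$test],
                            schemes = schemes, n_learners = n_learners,
                            seed = seed)
  list(dataset = dataset, split = split, suite = suite)
}
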