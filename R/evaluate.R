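# Confusion matrices, one-vs-rest class metrics, and slide prediction maps.

#' Confusion matrix
#'
#' Integer matrix of counts with rows = true class and columns = predicted
#' class, over an explicit class list (so empty classes keep their rows).
#'
#' @param true,predicted equal-length label vectors
#' @param class_list ordered class names; every label must be in this list
#' @return `length(class_list)` square integer matrix
#' @export
confusion_matrix <- function(true, predicted, class_list) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted)) stopf("label vectors differ in length")
  unknown <- setdiff(unique(c(true, predicted)), class_list)
  if (length(unknown)) stopf("labels outside class_list: %s",
                             paste(unknown, collapse = ", "))
  tf <- factor(true, levels = class_list)
  pf <- factor(predicted, levels = class_list)
  m <- table(tf, pf)
  matrix(as.integer(m), nrow = length(class_list),
         dimnames = list(true = class_list, predicted = class_list))
}

#' One-vs-rest metrics from a confusion matrix
#'
#' For each class: sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive
#' predictive value TP/(TP+FP), negative predictive value TN/(TN+FN). A zero
#' denominator yields `NA` with the corresponding `*_defined` flag set to
#' `FALSE` (never silent NaN).
#'
#' @param mat square non-negative integer confusion matrix (rows = true)
#' @return data.frame with one row per class: the four metrics plus their
#'   `_defined` flags
#' @export
per_class_metrics <- function(mat) {
  if (nrow(mat) != ncol(mat)) stopf("confusion matrix must be square")
  if (any(mat < 0)) stopf("confusion matrix must be non-negative")
  n <- sum(mat)
  classes <- rownames(mat)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(mat)))
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    tp <- mat[i, i]
    fn <- sum(mat[i, ]) - tp
    fp <- sum(mat[, i]) - tp
    tn <- n - tp - fn - fp
    ratio <- function(a, b) if (b == 0) NA_real_ else a / b
    data.frame(
      class = classes[i],
      sensitivity = ratio(tp, tp + fn), sensitivity_defined = (tp + fn) > 0,
      specificity = ratio(tn, tn + fp), specificity_defined = (tn + fp) > 0,
      ppv = ratio(tp, tp + fp), ppv_defined = (tp + fp) > 0,
      npv = ratio(tn, tn + fn), npv_defined = (tn + fn) > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluation report for a set of tile predictions
#'
#' Bundles the confusion matrix, per-class one-vs-rest metrics, tile-weighted
#' overall accuracy (trace over total) and the chance level (1 / number of
#' classes).
#'
#' @param true,predicted equal-length label vectors
#' @param class_list ordered class names
#' @return object of class `evaluation_report`: list with `confusion`,
#'   `per_class`, `overall_accuracy`, `chance_level`, `n_tiles`, `class_list`
#' @export
evaluation_report <- function(true, predicted, class_list) {
  cm <- confusion_matrix(true, predicted, class_list)
  n <- sum(cm)
  structure(list(
    confusion = cm,
    per_class = per_class_metrics(cm),
    overall_accuracy = if (n > 0) sum(diag(cm)) / n else NA_real_,
    chance_level = 1 / length(class_list),
    n_tiles = n,
    class_list = class_list
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d tiles, %d classes (chance level %.1f%%)\n",
              x$n_tiles, length(x$class_list), 100 * x$chance_level))
  cat(sprintf("Overall accuracy: %.1f%%\n\n", 100 * x$overall_accuracy))
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  cat("\nPer-class metrics (one-vs-rest):\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    fmt <- function(v, ok) if (!ok || is.na(v)) "  —" else sprintf("%.2f", v)
    cat(sprintf("  %-16s sens %s  spec %s  ppv %s  npv %s\n", pc$class[i],
                fmt(pc$sensitivity[i], pc$sensitivity_defined[i]),
                fmt(pc$specificity[i], pc$specificity_defined[i]),
                fmt(pc$ppv[i], pc$ppv_defined[i]),
                fmt(pc$npv[i], pc$npv_defined[i])))
  }
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per class with the four metrics (undefined metrics become empty
#' fields) plus the overall accuracy; the confusion matrix goes to a second
#' CSV.
#'
#' @param report an [evaluation_report()]
#' @param metrics_path,confusion_path output CSV paths
#' @return `metrics_path`, invisibly
#' @export
write_evaluation_report <- function(report, metrics_path, confusion_path = NULL) {
  pc <- report$per_class
  pc$overall_accuracy <- report$overall_accuracy
  utils::write.csv(pc, metrics_path, row.names = FALSE, na = "")
  if (!is.null(confusion_path))
    utils::write.csv(as.data.frame(report$confusion), confusion_path)
  invisible(metrics_path)
}

#' Render tile predictions onto a slide-sized map
#'
#' Paints each tile's pixel box with the display color of its predicted class;
#' overlapping boxes (e.g. from overlapping sub-tiles) resolve as
#' last-writer-wins in manifest order. Unpainted area uses the palette's
#' `background` color.
#'
#' @param tiles data.frame of tile records with columns `x0, y0, x1, y1`
#'   (half-open, 0-based)
#' @param predictions character/factor vector of predicted classes, one per
#'   tile
#' @param slide_dims `c(width, height)` in pixels
#' @param palette named list of RGB triples (default [annotation_palette()])
#' @param path optional PNG output path
#' @return integer RGB array of the map (invisibly if `path` is given)
#' @export
render_prediction_map <- function(tiles, predictions, slide_dims,
                                  palette = annotation_palette(), path = NULL) {
  predictions <- as.character(predictions)
  if (nrow(tiles) != length(predictions))
    stopf("tiles and predictions differ in length")
  w <- slide_dims[1]; h <- slide_dims[2]
  bg <- palette$background
  if (is.null(bg)) bg <- c(255L, 255L, 255L)
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  for (i in seq_len(nrow(tiles))) {
    b <- c(tiles$x0[i], tiles$y0[i], tiles$x1[i], tiles$y1[i])
    if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h || b[3] <= b[1] || b[4] <= b[2])
      stopf("tile box %d out of slide bounds", i)
    col <- palette[[predictions[i]]]
    if (is.null(col)) stopf("class '%s' missing from palette", predictions[i])
    for (ch in 1:3) img[(b[2] + 1):b[4], (b[1] + 1):b[3], ch] <- col[ch]
  }
  if (!is.null(path)) {
    write_rgb_png(img, path)
    return(invisible(img))
  }
  img
}
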