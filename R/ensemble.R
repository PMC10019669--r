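# Bagged decision-tree ensemble over tile feature vectors, at three levels of
# grading specificity.
#
# The classifier is bootstrap aggregation of unpruned CART trees: each learner
# is fit on a seeded bootstrap resample (with replacement, size n) of the
# training rows, and prediction is the majority vote across learners. Three
# label schemes map the eight annotation classes onto model classes: all
# Gleason patterns (G3/G4CG/G4NC/G5/NC), high- vs low-grade vs benign
# (HG/LG/NC), and cancer vs non-cancer (CA/NC). Non-cancer always pools
# atrophy, HGPIN, seminal vesicle and unlabeled benign tissue.

#' Label schemes
#'
#' Mapping from the eight annotation classes to model classes at a chosen
#' grading specificity:
#' * `all_grades`: G3, G4CG, G4NC, G5, NC
#' * `hg_vs_lg`: HG (G4CG, G4NC, G5), LG (G3), NC
#' * `nc_vs_ca`: CA (G3 and above), NC
#'
#' @param name one of `"all_grades"`, `"hg_vs_lg"`, `"nc_vs_ca"`
#' @return object of class `label_scheme`: list with `name`, `mapping` (named
#'   character vector over the eight annotation classes) and `classes` (ordered
#'   model classes)
#' @export
label_scheme <- function(name = c("all_grades", "hg_vs_lg", "nc_vs_ca")) {
  name <- match.arg(name)
  nc <- c(benign = "NC", atrophy = "NC", HGPIN = "NC", seminal_vesicle = "NC")
  mapping <- switch(name,
    all_grades = c(nc, G3 = "G3", G4CG = "G4CG", G4NC = "G4NC", G5 = "G5"),
    hg_vs_lg   = c(nc, G3 = "LG", G4CG = "HG", G4NC = "HG", G5 = "HG"),
    nc_vs_ca   = c(nc, G3 = "CA", G4CG = "CA", G4NC = "CA", G5 = "CA"))
  classes <- switch(name,
    all_grades = c("G3", "G4CG", "G4NC", "G5", "NC"),
    hg_vs_lg   = c("HG", "LG", "NC"),
    nc_vs_ca   = c("CA", "NC"))
  structure(list(name = name, mapping = mapping[annotation_classes()],
                 classes = classes),
            class = "label_scheme")
}

#' Map annotation labels to model classes
#'
#' @param labels character vector of annotation class labels
#' @param scheme a [label_scheme()]
#' @return factor over the scheme's model classes
#' @export
map_labels <- function(labels, scheme) {
  unknown <- setdiff(unique(labels), names(scheme$mapping))
  if (length(unknown))
    stopf("unknown annotation labels: %s", paste(unknown, collapse = ", "))
  factor(unname(scheme$mapping[labels]), levels = scheme$classes)
}

#' Train a bagged decision-tree ensemble
#'
#' Fits `n_learners` unpruned CART trees (rpart with `cp = 0`, `minsplit = 5`,
#' no cross-validation pruning), each on its own bootstrap resample of the
#' training rows drawn with replacement under a seed derived from the master
#' seed and the learner index. The model stores every per-learner seed, the
#' class list and (optionally) the z-score normalization, so training and
#' prediction are exactly reproducible from `(data, seed)`.
#'
#' @param features numeric matrix or all-numeric data.frame of tile feature
#'   vectors (typically the 24 slots of [feature_slot_names()], already
#'   z-scored)
#' @param labels class labels, one per row (annotation classes if `scheme` is
#'   given, otherwise used as-is)
#' @param scheme optional [label_scheme()] applied to `labels`
#' @param n_learners ensemble size (default 100)
#' @param seed master integer seed
#' @param zscore_params optional stored normalization carried for bookkeeping
#' @return object of class `bagged_ensemble`
#' @export
bag_train <- function(features, labels, scheme = NULL, n_learners = 100,
                      seed = 1, zscore_params = NULL) {
  x <- as.data.frame(features)
  if (!all(vapply(x, is.numeric, logical(1)))) stopf("features must be numeric")
  if (nrow(x) != length(labels)) stopf("feature rows (%d) and labels (%d) differ",
                                       nrow(x), length(labels))
  y <- if (!is.null(scheme)) map_labels(as.character(labels), scheme)
       else factor(labels)
  y <- droplevels(y)
  if (nlevels(y) < 2) stopf("training set must contain >= 2 classes after mapping")
  if (n_learners < 1) stopf("n_learners must be >= 1")

  df <- cbind(x, .class = y)
  n <- nrow(df)
  learners <- vector("list", n_learners)
  boot_seeds <- vapply(seq_len(n_learners), function(b)
    derive_seed(seed, "learner", b), integer(1))
  for (b in seq_len(n_learners)) {
    idx <- with_seed(boot_seeds[b], sample.int(n, n, replace = TRUE))
    d <- df[idx, , drop = FALSE]
    learners[[b]] <- tryCatch(
      rpart::rpart(.class ~ ., data = d, method = "class",
                   control = rpart::rpart.control(cp = 0, minsplit = 5,
                                                  xval = 0, maxsurrogate = 0)),
      error = function(e) {
        # degenerate resamples (e.g. a handful of duplicated rows) can be
        # unfittable; fall back to the resample's class frequencies
        tab <- table(d$.class)
        structure(list(prob = as.numeric(tab) / sum(tab),
                       classes = names(tab)),
                  class = "constant_learner")
      })
  }
  structure(list(
    learners = learners, boot_seeds = boot_seeds,
    n_learners = as.integer(n_learners),
    class_list = levels(y), feature_names = colnames(x),
    scheme = scheme, zscore_params = zscore_params,
    master_seed = as.integer(seed)
  ), class = "bagged_ensemble")
}

#' Predict with a bagged ensemble
#'
#' Majority vote over the learners' predicted classes. Vote fractions sum to 1
#' per row. Ties break to the tied class with the highest mean per-learner
#' class posterior, then to the first tied class in the model's class list.
#'
#' @param object a [bag_train()] model
#' @param features feature matrix/data.frame with the training columns
#' @param ... unused
#' @return list with `labels` (factor over the model's classes) and `votes`
#'   (numeric matrix of per-class vote fractions, rows summing to 1)
#' @export
predict.bagged_ensemble <- function(object, features, ...) {
  x <- as.data.frame(features)
  missing <- setdiff(object$feature_names, colnames(x))
  extra <- setdiff(colnames(x), object$feature_names)
  if (length(missing) || length(extra))
    stopf("feature schema mismatch; missing: [%s], unexpected: [%s]",
          paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  x <- x[, object$feature_names, drop = FALSE]
  k <- length(object$class_list)
  n <- nrow(x)
  votes <- matrix(0, n, k, dimnames = list(NULL, object$class_list))
  post <- matrix(0, n, k, dimnames = list(NULL, object$class_list))
  for (lr in object$learners) {
    p_full <- matrix(0, n, k, dimnames = list(NULL, object$class_list))
    if (inherits(lr, "constant_learner")) {
      p_full[, lr$classes] <- matrix(lr$prob, n, length(lr$classes), byrow = TRUE)
    } else {
      p <- stats::predict(lr, newdata = x, type = "prob")
      p_full[, colnames(p)] <- p
    }
    pred <- max.col(p_full, ties.method = "first")
    votes[cbind(seq_len(n), pred)] <- votes[cbind(seq_len(n), pred)] + 1
    post <- post + p_full
  }
  votes <- votes / object$n_learners
  post <- post / object$n_learners
  lab <- integer(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {
      best <- top[post[i, top] == max(post[i, top])]
      top <- best[1]
    }
    lab[i] <- top[1]
  }
  list(labels = factor(object$class_list[lab], levels = object$class_list),
       votes = votes)
}

#' Save or load a trained ensemble
#'
#' Single-file archive holding the trees, bootstrap seeds, class list, label
#' scheme and z-score parameters.
#'
#' @param model a `bagged_ensemble`
#' @param path file path
#' @return `load_ensemble` returns the model; `save_ensemble` returns `path`
#'   invisibly
#' @export
save_ensemble <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) readRDS(path)

#' Train and evaluate the three label schemes
#'
#' For each requested scheme: labels are mapped, z-score normalization is
#' fitted on the training rows only and applied to both splits, an ensemble is
#' trained, and the held-out predictions are summarized as an
#' [evaluation_report()]. Train and test tiles must be disjoint; when patient
#' ids are supplied, any patient appearing in both splits is an error
#' (patient-level leakage).
#'
#' @param train_features,test_features feature matrices (raw, not yet z-scored)
#' @param train_labels,test_labels annotation class labels
#' @param schemes character vector of scheme names (default all three)
#' @param n_learners ensemble size per scheme
#' @param seed master integer seed
#' @param train_patients,test_patients optional patient ids for the leakage
#'   check
#' @return named list (one element per scheme) of lists with `model`, `report`,
#'   `predictions`
#' @export
run_scheme_suite <- function(train_features, train_labels,
                             test_features, test_labels,
                             schemes = c("all_grades", "hg_vs_lg", "nc_vs_ca"),
                             n_learners = 100, seed = 1,
                             train_patients = NULL, test_patients = NULL) {
  if (nrow(as.data.frame(test_features)) == 0) stopf("empty test set")
  if (!is.null(train_patients) && !is.null(test_patients)) {
    overlap <- intersect(unique(train_patients), unique(test_patients))
    if (length(overlap))
      stopf("patients present in both splits: %s", paste(overlap, collapse = ", "))
  }
  out <- list()
  for (s in schemes) {
    sch <- label_scheme(s)
    zs <- zscore_fit(train_features)
    xtr <- as.data.frame(zscore_apply(train_features, zs))
    xte <- as.data.frame(zscore_apply(test_features, zs))
    model <- bag_train(xtr, train_labels, scheme = sch,
                       n_learners = n_learners,
                       seed = derive_seed(seed, s), zscore_params = zs)
    pred <- predict(model, xte)
    truth <- map_labels(as.character(test_labels), sch)
    report <- evaluation_report(truth, pred$labels, sch$classes)
    out[[s]] <- list(model = model, report = report,
                     predictions = data.frame(true = truth, predicted = pred$labels))
  }
  out
}
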