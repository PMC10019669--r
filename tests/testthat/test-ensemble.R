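test_that("label schemes map the eight annotation classes totally", {
  for (name in c("all_grades", "hg_vs_lg", "nc_vs_ca")) {
    sch <- label_scheme(name)
    expect_setequal(names(sch$mapping), annotation_classes())
    expect_false(any(is.na(sch$mapping)))
    # non-cancer always pools the four benign-side classes
    expect_true(all(sch$mapping[c("benign", "atrophy", "HGPIN",
                                  "seminal_vesicle")] == "NC"))
  }
  expect_setequal(label_scheme("all_grades")$classes, c("G3", "G4CG", "G4NC", "G5", "NC"))
  expect_setequal(label_scheme("hg_vs_lg")$classes, c("HG", "LG", "NC"))
  expect_equal(unname(label_scheme("hg_vs_lg")$mapping["G3"]), "LG")
  expect_setequal(label_scheme("nc_vs_ca")$classes, c("CA", "NC"))
  expect_error(map_labels("weird", label_scheme("nc_vs_ca")), "unknown")
})

make_separable <- function(n = 60, seed = 1) {
  set.seed(seed)
  x <- data.frame(f1 = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                  f2 = rnorm(n))
  list(x = x, y = rep(c("left", "right"), each = n / 2))
}

test_that("bagging is deterministic and separates separable classes", {
  d <- make_separable()
  m1 <- bag_train(d$x, d$y, n_learners = 25, seed = 0)
  expect_equal(as.character(predict(m1, d$x)$labels), d$y)  # training accuracy 1
  m2 <- bag_train(d$x, d$y, n_learners = 25, seed = 0)
  probe <- data.frame(f1 = rnorm(40), f2 = rnorm(40))
  expect_identical(predict(m1, probe)$labels, predict(m2, probe)$labels)
  expect_identical(predict(m1, probe)$votes, predict(m2, probe)$votes)
})

test_that("a single-learner ensemble equals the directly fitted bootstrap tree", {
  d <- make_separable(n = 80, seed = 4)
  m <- bag_train(d$x, d$y, n_learners = 1, seed = 5)
  # oracle: rebuild the same bootstrap resample and fit one tree directly
  idx <- histomorph:::with_seed(histomorph:::derive_seed(5, "learner", 1),
                                sample.int(80, 80, replace = TRUE))
  df <- cbind(d$x, .class = factor(d$y))
  tree <- rpart::rpart(.class ~ ., data = df[idx, ], method = "class",
                       control = rpart::rpart.control(cp = 0, minsplit = 5,
                                                      xval = 0, maxsurrogate = 0))
  probe <- data.frame(f1 = seq(-4, 4, length.out = 30), f2 = 0)
  expect_equal(as.character(predict(m, probe)$labels),
               as.character(predict(tree, probe, type = "class")))
})

test_that("vote fractions are normalized and unanimity gives fraction 1", {
  d <- make_separable()
  m <- bag_train(d$x, d$y, n_learners = 20, seed = 2)
  pr <- predict(m, data.frame(f1 = c(-5, 5), f2 = c(0, 0)))
  expect_equal(unname(rowSums(pr$votes)), c(1, 1))
  expect_equal(unname(pr$votes[1, "left"]), 1)
  expect_equal(unname(pr$votes[2, "right"]), 1)
  set.seed(3)
  pr2 <- predict(m, data.frame(f1 = rnorm(25, 0, 4), f2 = rnorm(25)))
  expect_equal(unname(rowSums(pr2$votes)), rep(1, 25))
})

# assemble a two-learner ensemble from directly fitted trees so the vote tie
# is exact and the posterior tie-break observable
make_tied_ensemble <- function(impure_second = TRUE) {
  lv <- c("A", "B")
  d1 <- data.frame(x = c(-3, -2, -1, 1, 2, 3),
                   .class = factor(c("A", "A", "A", "B", "B", "B"), levels = lv))
  t1 <- rpart::rpart(.class ~ x, data = d1, method = "class",
                     control = rpart::rpart.control(cp = 0, minsplit = 2, xval = 0))
  if (impure_second) {
    d2 <- data.frame(x = c(-3, -2, -1, 1, 2, 3, 4, 5, 6, 7),
                     .class = factor(c("B", "B", "B", "B", "B", "B", "B", "B", "A", "A"),
                                     levels = lv))
  } else {
    d2 <- data.frame(x = c(-3, -2, -1, 1, 2, 3),
                     .class = factor(c("B", "B", "B", "A", "A", "A"), levels = lv))
  }
  t2 <- rpart::rpart(.class ~ x, data = d2, method = "class",
                     control = rpart::rpart.control(
                       cp = 0, minsplit = if (impure_second) 20 else 2, xval = 0))
  structure(list(learners = list(t1, t2), boot_seeds = c(1L, 2L),
                 n_learners = 2L, class_list = lv, feature_names = "x",
                 scheme = NULL, zscore_params = NULL, master_seed = 0L),
            class = "bagged_ensemble")
}

test_that("vote ties break by mean posterior, then class-list order", {
  # learner 1 predicts A with posterior 1; learner 2 is a stump predicting B
  # with posterior 0.8 -> mean posterior favors A
  m <- make_tied_ensemble(impure_second = TRUE)
  pr <- predict(m, data.frame(x = -2))
  expect_equal(unname(pr$votes[1, ]), c(0.5, 0.5))
  expect_equal(as.character(pr$labels), "A")
  # both learners fully confident -> exact posterior tie -> first class wins
  m2 <- make_tied_ensemble(impure_second = FALSE)
  pr2 <- predict(m2, data.frame(x = -2))
  expect_equal(unname(pr2$votes[1, ]), c(0.5, 0.5))
  expect_equal(as.character(pr2$labels), "A")
})

test_that("duplicated constant feature columns do not change predictions", {
  d <- make_separable(n = 60, seed = 8)
  m_plain <- bag_train(d$x, d$y, n_learners = 15, seed = 3)
  x_aug <- cbind(d$x, const1 = 1, const2 = 1)
  m_aug <- bag_train(x_aug, d$y, n_learners = 15, seed = 3)
  probe <- data.frame(f1 = seq(-4, 4, length.out = 21), f2 = 0.3)
  probe_aug <- cbind(probe, const1 = 1, const2 = 1)
  expect_identical(predict(m_plain, probe)$labels, predict(m_aug, probe_aug)$labels)
})

test_that("training and suite preconditions are enforced", {
  d <- make_separable()
  expect_error(bag_train(d$x, rep("one", 60), n_learners = 5, seed = 1),
               ">= 2 classes")
  expect_error(bag_train(d$x, d$y[-1], n_learners = 5, seed = 1), "differ")
  m <- bag_train(d$x, d$y, n_learners = 5, seed = 1)
  expect_error(predict(m, data.frame(wrong = 1)), "schema mismatch")
  ds <- shared_small_dataset()
  slots <- feature_slot_names()
  expect_error(run_scheme_suite(ds[, slots], ds$class,
                                ds[0, slots], character(0)), "empty test set")
  expect_error(run_scheme_suite(ds[1:30, slots], ds$class[1:30],
                                ds[31:48, slots], ds$class[31:48],
                                train_patients = c("p1", "p2"),
                                test_patients = c("p2", "p3")),
               "both splits")
})

test_that("models serialize to a single archive and reload intact", {
  d <- make_separable()
  m <- bag_train(d$x, d$y, n_learners = 10, seed = 6)
  path <- tempfile(fileext = ".rds")
  save_ensemble(m, path)
  m2 <- load_ensemble(path)
  probe <- data.frame(f1 = rnorm(10), f2 = rnorm(10))
  expect_identical(predict(m, probe), predict(m2, probe))
})

test_that("randomly permuted labels score near chance", {
  ds <- shared_small_dataset()
  slots <- feature_slot_names()
  perm <- histomorph:::with_seed(2024, sample(ds$class))
  split <- benchmark_split(ds, seed = 5)
  suite <- run_scheme_suite(ds[split$train, slots], perm[split$train],
                            ds[split$test, slots], perm[split$test],
                            schemes = "nc_vs_ca", n_learners = 50, seed = 5)
  acc <- suite$nc_vs_ca$report$overall_accuracy
  n_test <- suite$nc_vs_ca$report$n_tiles
  # within 3 binomial standard errors of the 50% chance level
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_test) + 1e-9)
})
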