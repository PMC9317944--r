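# metrics, classifier backends, repeated CV, experiment assembly

test_that("compute_metrics matches the worked example and the oracle", {
  cm <- confusion_matrix(truth = rep(c("0", "1"), c(10, 10)),
                         pred = c(rep("0", 8), "1", "1",
                                  rep("1", 9), "0"))
  m <- compute_metrics(cm)
  expect_equal(m[["Acc"]], 0.85)
  # worked example: TP=9 FN=1 TN=8 FP=2
  cm2 <- structure(matrix(c(8, 1, 2, 9), 2,
                          dimnames = list(truth = c("0", "1"),
                                          pred = c("0", "1"))),
                   class = "confusion_matrix")
  m2 <- compute_metrics(cm2)
  expect_equal(as.numeric(m2), unname(oracle_metrics(9, 8, 2, 1)))
  # (TP + TN) / total = 17/20; the six companion statistics below pin the
  # same worked example
  expect_equal(m2[["Acc"]], 0.85)
  expect_equal(m2[["Prec"]], 9 / 11)
  expect_equal(m2[["F1s"]], 18 / 21)
  expect_equal(m2[["TNR"]], 0.80)
  expect_equal(m2[["FNR"]], 0.10)
  expect_equal(m2[["FPR"]], 0.20)
  # random matrices vs the literal re-evaluation + identities
  set.seed(14)
  for (i in 1:50) {
    cnt <- sample(0:30, 4, replace = TRUE)
    if (sum(cnt) == 0 || sum(cnt[c(1, 3)]) == 0 || sum(cnt[c(2, 4)]) == 0 ||
        sum(cnt[c(1, 2)]) == 0 || sum(cnt[c(3, 4)]) == 0) next
    cmx <- structure(matrix(c(cnt[1], cnt[3], cnt[2], cnt[4]), 2,
                            dimnames = list(truth = 0:1, pred = 0:1)),
                     class = "confusion_matrix")
    mx <- compute_metrics(cmx)
    expect_equal(as.numeric(mx),
                 unname(oracle_metrics(cnt[4], cnt[1], cnt[2], cnt[3])))
    expect_equal(mx[["Rec"]] + mx[["FNR"]], 1, tolerance = 1e-12)
    expect_equal(mx[["TNR"]] + mx[["FPR"]], 1, tolerance = 1e-12)
  }
})

test_that("perfect and degenerate confusion matrices behave", {
  perfect <- structure(matrix(c(5, 0, 0, 5), 2,
                              dimnames = list(truth = 0:1, pred = 0:1)),
                       class = "confusion_matrix")
  m <- compute_metrics(perfect)
  expect_equal(unname(m[c("Acc", "Rec", "Prec", "F1s", "TNR")]), rep(1, 5))
  expect_equal(unname(m[c("FNR", "FPR")]), c(0, 0))
  empty <- structure(matrix(0, 2, 2, dimnames = list(truth = 0:1, pred = 0:1)),
                     class = "confusion_matrix")
  expect_error(compute_metrics(empty), "empty")
  # zero denominator -> NaN with a warning, not silent 0
  never_pos <- structure(matrix(c(10, 5, 0, 0), 2,
                                dimnames = list(truth = 0:1, pred = 0:1)),
                         class = "confusion_matrix")
  expect_warning(mp <- compute_metrics(never_pos), "Prec")
  expect_true(is.nan(mp[["Prec"]]))
})

test_that("multi-class metrics use the trace and macro-averaging", {
  cm <- confusion_matrix(truth = c("a", "a", "b", "b", "c", "c"),
                         pred = c("a", "b", "b", "b", "c", "a"))
  m <- compute_metrics(cm)
  expect_identical(attr(m, "averaging"), "macro")
  expect_equal(m[["Acc"]], 4 / 6)
  # macro recall: mean(1/2, 2/2, 1/2)
  expect_equal(m[["Rec"]], mean(c(0.5, 1, 0.5)))
})

test_that("all four families separate distant blobs and are deterministic", {
  ds <- toy_blobs(n_per = 15, gap = 8)
  test <- toy_blobs(n_per = 10, gap = 8, seed = 8)
  for (fam in c("mlp", "svm", "knn", "mnlr")) {
    cfg <- switch(fam,
                  mlp = classifier_config("mlp", N = 200L),
                  svm = classifier_config("svm", C = 10, G = 0.5),
                  knn = classifier_config("knn"),
                  mnlr = classifier_config("mnlr"))
    pred <- train_predict(cfg, ds, test)
    expect_identical(pred, as.character(test$labels), label = fam)
  }
  # seeded MLP training is reproducible
  cfg <- classifier_config("mlp", N = 50L, S = 3L)
  expect_identical(train_predict(cfg, ds, test), train_predict(cfg, ds, test))
})

test_that("KNN returns the label of an exactly matching training sample", {
  ds <- toy_blobs(n_per = 10)
  one <- labeled_dataset(ds$features[c(1, 15), , drop = FALSE],
                         ds$labels[c(1, 15)])
  pred <- train_predict(classifier_config("knn"), ds, one)
  expect_identical(pred, as.character(ds$labels[c(1, 15)]))
  # manhattan distance path
  pred2 <- train_predict(classifier_config("knn", distance = "manhattan"),
                         ds, one)
  expect_identical(pred2, as.character(ds$labels[c(1, 15)]))
})

test_that("train_predict validates dimensionality and presets load", {
  ds <- toy_blobs()
  bad <- labeled_dataset(ds$features[, 1:3], ds$labels)
  expect_error(train_predict(classifier_config("knn"), ds, bad),
               "dimensionality")
  p <- classifier_preset("exp1_face")
  expect_named(p, c("mlp", "svm", "knn", "mnlr"))
  expect_equal(p$mlp$L, 0.2045)
  expect_equal(p$mlp$M, 0.1909)
  expect_equal(p$mlp$H, 59)
  expect_equal(p$svm$C, 1000)
  expect_equal(p$svm$G, 0.1)
  expect_equal(p$knn$k, 1)
  expect_equal(p$mnlr$R, 1e-8)
  expect_equal(classifier_preset("exp1_eyes", "svm")$G, 0.001)
  expect_equal(classifier_preset("exp2_test1_mouth", "mlp")$N, 2000)
  expect_identical(classifier_preset("exp3_test2_mouth", "knn")$distance,
                   "euclidean")
  expect_error(classifier_preset("exp9"), "unknown preset")
})

test_that("stratified folds are disjoint, covering and balanced", {
  set.seed(17)
  labels <- factor(rep(c("a", "b"), c(40, 25)))
  fold <- facesym:::stratified_folds(labels, 5)
  expect_identical(sort(unique(fold)), 1:5)
  expect_identical(length(fold), 65L)
  for (f in 1:5) {
    tab <- table(labels[fold == f])
    expect_equal(unname(tab[["a"]]), 8)
    expect_true(abs(tab[["b"]] - 5) <= 1)
  }
  expect_error(facesym:::stratified_folds(factor(c("a", "a", "b")), 2),
               "fewer than")
})

test_that("repeated k-fold tests every sample once per repeat", {
  ds <- toy_blobs(n_per = 20, gap = 8)
  rep <- repeated_kfold(ds, classifier_config("knn"), k = 5, repeats = 3,
                        seed = 11)
  # confusion counts accumulate to n per repeat, 3n in total
  expect_equal(sum(unclass(rep$confusion)), 3 * 40)
  expect_equal(nrow(rep$per_repeat), 3L)
  expect_equal(nrow(rep$per_fold), 15L)
  expect_equal(rep$mean[["Rec"]] + rep$mean[["FNR"]], 1, tolerance = 1e-12)
  expect_equal(rep$mean[["TNR"]] + rep$mean[["FPR"]], 1, tolerance = 1e-12)
  # deterministic given the seed
  rep2 <- repeated_kfold(ds, classifier_config("knn"), k = 5, repeats = 3,
                         seed = 11)
  expect_identical(rep$per_repeat, rep2$per_repeat)
  expect_error(repeated_kfold(ds, classifier_config("knn"), k = 25,
                              repeats = 1), "fewer than")
})

test_that("a label-leaking feature yields accuracy 1 (harness sanity)", {
  set.seed(19)
  x <- cbind(stats::rnorm(40), rep(c(0, 1), each = 20))  # column 2 leaks
  ds <- labeled_dataset(x, rep(c("0", "1"), each = 20))
  rep <- repeated_kfold(ds, classifier_config("knn"), k = 5, repeats = 2,
                        seed = 3)
  expect_equal(rep$mean[["Acc"]], 1)
})

test_that("experiment assembly caps, collapses, augments and projects", {
  # 4 subjects x 6 images each, 2 healthy + 2 palsy subjects
  lms <- list(); labels <- character(0); subj <- character(0)
  t <- make_template()
  set.seed(23)
  for (s in 1:4) {
    cls <- if (s <= 2) "SL0" else "SL2"
    for (i in 1:6) {
      lm <- if (cls == "SL0") t else
        apply_palsy(t, palsy_perturbation("left", mouth = 10))
      lm <- landmarks51(lm$points + matrix(stats::rnorm(102, sd = 0.5), 51, 2),
                        source_id = sprintf("s%d_i%d", s, i))
      lms <- c(lms, list(lm))
      labels <- c(labels, cls)
      subj <- c(subj, paste0("s", s))
    }
  }
  ds <- assemble_experiment(lms, labels, subj, task = "detect",
                            region = "face", per_subject_cap = 5)
  expect_equal(n_samples(ds), 20L)            # capped at 5 x 4 subjects
  expect_identical(levels(ds$labels), c("0", "1"))
  aug <- assemble_experiment(lms, labels, subj, task = "detect",
                             region = "eyes", per_subject_cap = 5,
                             augment = TRUE)
  expect_equal(n_samples(aug), 60L)           # tripled
  expect_equal(ncol(aug$features), 19L)
  expect_equal(sum(is.na(aug$augmented_from)), 20L)
  # augmented rows reproduce their parent's features (tilt-corrected):
  # the two rotations of original row i sit at rows 20 + 2(i-1) + {1,2}
  for (i in c(1L, 7L)) {
    for (j in 20L + 2L * (i - 1L) + 1:2)
      expect_lt(max(abs(aug$features[j, ] - aug$features[i, ])), 1e-6)
  }
  expect_error(assemble_experiment(lms, labels, subj, task = "two_level"),
               "SL1/SL2")
})
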