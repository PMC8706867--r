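# Shared synthetic labeled data for the classifier tests
.lab <- gen_labeled(labeled_spec(n_pos = 40L, n_neg = 60L,
                                 effect_size = 2.5, n_informative = 10L,
                                 seed = 42L))

test_that("metric suite handles degenerate confusion matrices", {
  m <- metrics_from_cm(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(m$acc, 1)
  expect_true(is.na(m$sen))      # no positives: sensitivity undefined
  expect_true(is.na(m$mcc))
  m2 <- metrics_from_cm(confusion_matrix(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(m2$mcc, 1)
  expect_equal(m2$acc, 1)
})

test_that("stratified split is 6:4 within each class and disjoint", {
  labels <- factor(rep(c("positive", "negative"), c(40, 60)),
                   levels = c("negative", "positive"))
  sp <- stratified_split(labels, train_frac = 0.6, seed = 3L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_equal(sort(c(sp$train, sp$validation)), seq_along(labels))
  expect_equal(sum(labels[sp$train] == "positive"), 24L)
  expect_equal(sum(labels[sp$train] == "negative"), 36L)
})

test_that("all five classifiers train and report full metric rows", {
  sp <- stratified_split(.lab$labels, seed = 7L)
  rep <- fit_classifiers(.lab$descriptors, .lab$labels, sp, seed = 7L)
  expect_equal(nrow(rep), 10L)   # 5 methods x train/validation
  expect_setequal(unique(rep$method), c("svm", "knn", "gnb", "rf", "lr"))
  val <- rep[rep$split == "validation", ]
  expect_true(all(val$acc >= 0 & val$acc <= 1))
  expect_true(all(val$auc >= 0 & val$auc <= 1, na.rm = TRUE))
  expect_true(all(val$random_acc > 0 & val$random_acc < 1))
  # clearly separable data: everything should beat chance
  expect_true(all(val$acc > val$random_acc))
})

test_that("training split with a single class errors", {
  labels <- factor(rep("positive", 10), levels = c("negative", "positive"))
  X <- .lab$descriptors[1:10, ]
  expect_error(
    fit_classifiers(X, labels, list(train = 1:6, validation = 7:10)),
    "single class")
})

test_that("repeat_classifiers aggregates mean and sd over repeats", {
  res <- repeat_classifiers(.lab$descriptors, .lab$labels,
                            methods = c("gnb", "lr"), n_repeats = 3L,
                            seed = 11L)
  expect_equal(nrow(res$runs), 3L * 2L * 2L)
  expect_true(all(c("acc_mean", "acc_sd", "mcc_mean") %in%
                    names(res$summary)))
})

test_that("cross_validate covers each sample exactly once per fold set", {
  res <- cross_validate(.lab$descriptors, .lab$labels, k = 4L,
                        methods = "gnb", seed = 5L)
  expect_equal(nrow(res$folds), 4L)
  expect_true(all(res$folds$acc >= 0 & res$folds$acc <= 1))
  expect_error(cross_validate(.lab$descriptors, .lab$labels, k = 1L),
               "k")
})

test_that("retrospective recall: identity matching and the gate", {
  gen <- c("CCO", "CCN", "CCC")
  held <- c("CCO", "CCS")
  expect_equal(retrospective_recall(gen, held), 0.5)
  expect_equal(retrospective_recall(gen, held,
                                    predicted_positive = c(FALSE, TRUE, TRUE)),
               0)
  expect_error(retrospective_recall(gen, character(0)), "empty")
})

test_that("recall is monotone over nested generated sets", {
  pool <- sprintf("C%sO", strrep("C", 1:20))
  held <- pool[c(3, 7, 15)]
  r <- vapply(c(5, 10, 15, 20), function(k)
    retrospective_recall(pool[seq_len(k)], held), numeric(1))
  expect_true(all(diff(r) >= 0))
})
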