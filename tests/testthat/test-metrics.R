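test_that("stratified splits preserve class shares", {
  labels <- rep(c("a", "b"), c(100, 40))
  sp <- stratified_split(labels, 0.2, seed = 1)
  expect_length(sp$test, 28)
  expect_equal(sum(labels[sp$test] == "a"), 20)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(stratified_split(c("a", "a", "b"), 0.2), "b")
})

test_that("the published design allocates 5 Shandong test samples", {
  rc <- load_region_counts()
  labels <- rep(rc$region, rc$n)
  sp <- stratified_split(labels, 0.2, seed = 3)
  expect_equal(sum(labels[sp$test] == "Shandong"), 5)   # round(24 * 0.2)
  expect_equal(length(sp$test), round(1717 * 0.2))
})

test_that("stratified k-fold spreads classes as evenly as possible", {
  labels <- rep(c("a", "b"), each = 25)
  folds <- stratified_kfold(labels, 5, seed = 2)
  expect_equal(lengths(folds), rep(10, 5))
  expect_setequal(unlist(folds), seq_along(labels))
  expect_equal(anyDuplicated(unlist(folds)), 0)
  labels2 <- rep(c("a", "b"), c(35, 7))
  folds2 <- stratified_kfold(labels2, 5, seed = 2)
  per_fold_b <- vapply(folds2, function(f) sum(labels2[f] == "b"), 0)
  expect_true(all(per_fold_b %in% c(1, 2)))
  expect_error(stratified_kfold(labels, 1), "at least 2")
  expect_warning(stratified_kfold(rep(c("a", "b"), c(20, 3)), 5), "b")
})

test_that("confusion matrices tally true rows against predicted columns", {
  cm <- confusion(c("a", "a", "b"), c("a", "a", "b"), c("a", "b"))
  expect_equal(cm, matrix(c(2L, 0L, 0L, 1L), 2,
                          dimnames = list(true = c("a", "b"),
                                          predicted = c("a", "b"))))
  cm2 <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(cm2["a", "b"], 1L)
  expect_equal(sum(diag(cm2)), 2)
  expect_error(confusion(c("a"), c("z"), c("a", "b")), "z")
  expect_error(confusion(c("a", "b"), c("a"), labels = c("a", "b")),
               "equal length")
})

test_that("a worked confusion row reproduces its published recall", {
  # one origin with 75 test samples: 72 correct, 2 and 1 confused with two
  # neighbouring provinces
  true <- rep("Yunnan", 75)
  pred <- c(rep("Yunnan", 72), rep("Sichuan", 2), "Guizhou")
  cm <- confusion(c(true, "Sichuan", "Guizhou"),
                  c(pred, "Sichuan", "Guizhou"),
                  c("Yunnan", "Sichuan", "Guizhou"))
  met <- classification_metrics(cm)
  expect_equal(met$per_class$recall[met$per_class$class == "Yunnan"], 0.96)
})

test_that("macro-F1 is the harmonic mean of the printed macro pairs", {
  expect_equal(round(macro_f1(0.9836, 0.9806), 4), 0.9821)
  expect_equal(round(macro_f1(0.9432, 0.9736), 4), 0.9582)
  expect_equal(round(macro_f1(0.917, 0.9448), 4), 0.9307)
})

test_that("metrics satisfy their structural identities", {
  cm <- diag(4L) * 5L
  dimnames(cm) <- list(letters[1:4], letters[1:4])
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 1)
  expect_equal(met$macro_f1, 1)
  set.seed(50)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 4) + diag(k) * 10, k,
                 dimnames = list(letters[1:k], letters[1:k]))
    met <- classification_metrics(cm)
    expect_equal(met$accuracy, sum(diag(cm)) / sum(cm))
    expect_equal(met$macro_f1,
                 2 * met$macro_recall * met$macro_precision /
                   (met$macro_recall + met$macro_precision))
    expect_true(all(met$per_class$recall >= 0 & met$per_class$recall <= 1))
  }
  empty_col <- matrix(c(3L, 1L, 0L, 0L), 2,
                      dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(met0 <- classification_metrics(empty_col), "precision")
  expect_equal(met0$per_class$precision[2], 0)
})

test_that("macro one-vs-rest AUC matches exhaustive pair counting", {
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  colnames(one_hot) <- c("a", "b", "c")
  expect_equal(macro_ovr_auc(one_hot, c("a", "b", "c", "a")), 1)
  # worked two-class example: positives outrank negatives on column A
  sc <- cbind(A = c(0.9, 0.8, 0.4, 0.6), B = c(0.1, 0.2, 0.6, 0.4))
  expect_equal(macro_ovr_auc(sc, c("A", "A", "B", "B")), 1)
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    classes <- c("a", "b", "c")
    truth <- sample(classes, n, replace = TRUE)
    while (length(unique(truth)) < 2) truth <- sample(classes, n, TRUE)
    scores <- matrix(sample(seq(0, 1, 0.1), n * 3, TRUE), n,
                     dimnames = list(NULL, classes))
    oracle <- mean(vapply(intersect(classes, unique(truth)), function(cl) {
      bf_auc(scores[, cl], truth == cl)
    }, 0), na.rm = TRUE)
    got <- suppressWarnings(macro_ovr_auc(scores, truth))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # labels independent of scores hover near 1/2
  set.seed(52)
  n <- 4000
  truth <- sample(c("a", "b"), n, TRUE)
  scores <- matrix(runif(2 * n), n, dimnames = list(NULL, c("a", "b")))
  expect_lt(abs(macro_ovr_auc(scores, truth) - 0.5), 0.03)
})
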