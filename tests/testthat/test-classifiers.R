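test_that("linear SVM separates well-separated blobs perfectly", {
  set.seed(20)
  tbl <- blob_table(25)
  m <- train_svm(tbl, kernel_spec("linear"))
  expect_equal(mean(predict(m, tbl) == tbl$region), 1)
  expect_equal(levels(predict(m, tbl)), c("A", "B", "C"))
})

test_that("a pure-linear hybrid model predicts like the linear model", {
  set.seed(21)
  tbl <- blob_table(20, sd = 1.6)
  te <- blob_table(15, sd = 1.6)
  lin <- train_svm(tbl, kernel_spec("linear"))
  hyb <- train_svm(tbl, kernel_spec("hybrid", c1 = 0.02, c2 = 1, c3 = 2,
                                    sigma2 = 10, m = 1, n = 0, q = 0))
  expect_identical(predict(lin, te), predict(hyb, te))
})

test_that("predictions fulfil the score contract", {
  set.seed(22)
  tbl <- blob_table(20)
  te <- blob_table(1)
  for (scheme in c("ovo", "ovr")) {
    m <- train_svm(tbl, kernel_spec("gaussian", sigma2 = 10),
                   multiclass = scheme)
    one <- te[1, , drop = FALSE]
    sc <- predict(m, one, type = "scores")
    expect_equal(dim(sc), c(1, 3))
    expect_true(all(is.finite(sc)))
    expect_length(predict(m, one), 1)
  }
  # one-vs-rest labels are the score argmax
  m <- train_svm(tbl, kernel_spec("linear"), multiclass = "ovr")
  sc <- predict(m, tbl, type = "scores")
  lab <- predict(m, tbl)
  expect_equal(as.character(lab),
               colnames(sc)[max.col(sc, ties.method = "first")])
})

test_that("one-vs-one and one-vs-rest agree on separable classes", {
  set.seed(23)
  tbl <- blob_table(20)
  te <- blob_table(20)
  ovo <- train_svm(tbl, kernel_spec("linear"), multiclass = "ovo")
  ovr <- train_svm(tbl, kernel_spec("linear"), multiclass = "ovr")
  expect_identical(predict(ovo, te), predict(ovr, te))
})

test_that("SVM predictions survive training-order permutation", {
  set.seed(24)
  tbl <- blob_table(20)
  te <- blob_table(10)
  m1 <- train_svm(tbl, kernel_spec("gaussian", sigma2 = 10))
  perm <- sample(nrow(tbl))
  m2 <- train_svm(as_chem_table(tbl[perm, ]),
                  kernel_spec("gaussian", sigma2 = 10))
  # label order may differ (it follows first appearance); the assigned
  # classes must not
  expect_identical(as.character(predict(m1, te)),
                   as.character(predict(m2, te)))
})

test_that("standardization makes predictions unit-invariant", {
  set.seed(25)
  tbl <- blob_table(20, sd = 1.3)
  te <- blob_table(10, sd = 1.3)
  m1 <- train_svm(tbl, kernel_spec("gaussian", sigma2 = 10),
                  standardize = TRUE)
  rescale <- function(x) {
    x$f2 <- 1000 * x$f2
    x$f3 <- x$f3 / 50
    as_chem_table(x)
  }
  m2 <- train_svm(rescale(tbl), kernel_spec("gaussian", sigma2 = 10),
                  standardize = TRUE)
  expect_identical(predict(m1, te), predict(m2, rescale(te)))
})

test_that("mismatched prediction columns are rejected", {
  set.seed(26)
  tbl <- blob_table(15)
  m <- train_svm(tbl, kernel_spec("linear"))
  bad <- tbl
  names(bad)[names(bad) == "f3"] <- "g3"
  expect_error(predict(m, bad), "f3")
  expect_error(train_svm(tbl, kernel_spec("linear"), C = -1), "C")
})

test_that("the BPNN learns an XOR-style pattern", {
  set.seed(27)
  n <- 60
  x1 <- c(rnorm(n, 0, 0.5), rnorm(n, 3, 0.5), rnorm(n, 0, 0.5),
          rnorm(n, 3, 0.5))
  x2 <- c(rnorm(n, 0, 0.5), rnorm(n, 3, 0.5), rnorm(n, 3, 0.5),
          rnorm(n, 0, 0.5))
  cls <- rep(c("P", "P", "Q", "Q"), each = n)
  tbl <- as_chem_table(data.frame(region = cls, country = "X",
                                  f1 = x1, f2 = x2))
  m <- train_bpnn(tbl, hidden_layers = 1, neurons_per_layer = 8,
                  learning_rate = 0.01, max_epochs = 400,
                  validation_fraction = 0, seed = 1)
  expect_gte(mean(predict(m, tbl) == tbl$region), 0.95)
})

test_that("BPNN training is deterministic under the seed and validated", {
  set.seed(28)
  tbl <- blob_table(15)
  m1 <- train_bpnn(tbl, 1, 6, 0.01, max_epochs = 50, seed = 9)
  m2 <- train_bpnn(tbl, 1, 6, 0.01, max_epochs = 50, seed = 9)
  expect_identical(predict(m1, tbl, type = "scores"),
                   predict(m2, tbl, type = "scores"))
  expect_error(train_bpnn(tbl, hidden_layers = 6), "1, 5")
  expect_error(train_bpnn(tbl, 2, neurons_per_layer = 41), "2, 40")
  expect_error(train_bpnn(tbl, 2, 10, learning_rate = 0.5), "0.001")
})

test_that("the random forest baseline behaves at both extremes", {
  set.seed(29)
  tbl <- blob_table(30)
  te <- blob_table(30)
  m <- train_rf(tbl, n_trees = 100, min_samples_leaf = 2, seed = 3)
  expect_gte(mean(predict(m, te) == te$region), 0.99)
  # pure-noise labels: held-out accuracy near the majority rate (1/2)
  noise <- as_chem_table(data.frame(
    region = rep(c("P", "Q"), each = 60), country = "X",
    f1 = rnorm(120), f2 = rnorm(120)))
  noise_te <- as_chem_table(data.frame(
    region = rep(c("P", "Q"), each = 40), country = "X",
    f1 = rnorm(80), f2 = rnorm(80)))
  mn <- train_rf(noise, n_trees = 100, min_samples_leaf = 5, seed = 4)
  acc <- mean(predict(mn, noise_te) == noise_te$region)
  expect_gt(acc, 0.3)
  expect_lt(acc, 0.7)
  expect_error(train_rf(tbl, n_trees = 49), "50, 200")
  expect_error(train_rf(tbl, n_trees = 100, min_samples_leaf = 1), "2, 10")
})

test_that("a high-separation 13-class synthetic table is near-separable", {
  counts <- load_region_counts()
  counts$n <- pmax(10L, as.integer(counts$n * 0.03))
  tbl <- generate_chem_table(region_counts = counts, separation_scale = 25,
                             seed = 31)
  m <- train_svm(tbl, kernel_spec("linear"), C = 100)
  expect_gte(mean(predict(m, tbl) == tbl$region), 0.99)
})
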