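#' Stratified train/test split
#'
#' Splits sample indices into a training and an independent test partition
#' while preserving each class's share. Per-class test counts are rounded
#' half-up; the largest class is then adjusted so the global test count
#' equals `round(length(labels) * test_fraction)`. Deterministic under
#' `seed`.
#'
#' @param labels Factor or character vector of class labels.
#' @param test_fraction Test share (default 0.2).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering).
#' @export
#' @examples
#' sp <- stratified_split(rep(c("a", "b"), c(80, 20)), 0.2, seed = 1)
#' length(sp$test)   # 20
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  y <- factor(labels)
  counts <- table(y)
  if (any(counts < 2)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("'test_fraction' must lie in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_test <- floor(counts * test_fraction + 0.5)     # round half up
  total_target <- round(length(y) * test_fraction)
  big <- names(counts)[which.max(counts)]
  n_test[big] <- n_test[big] + (total_target - sum(n_test))
  n_test <- pmin(pmax(n_test, 1), counts - 1)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    test <- c(test, sort(sample(idx, n_test[cl])))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

#' Stratified k-fold partition
#'
#' Partitions indices into `k` folds with each class spread across folds as
#' evenly as integers allow (shuffled within class, then dealt round-robin
#' from a rotating start). A class with fewer members than folds triggers a
#' warning: some training folds will then lack that class.
#'
#' @param labels Factor or character vector of class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors forming a partition.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  y <- factor(labels)
  counts <- table(y)
  small <- names(counts)[counts < k]
  if (length(small)) {
    warning("class(es) with fewer than k = ", k, " members: ",
            paste(small, collapse = ", "),
            "; they cannot appear in every fold", call. = FALSE)
  }
  set.seed(as.integer(seed))
  folds <- vector("list", k)
  start <- 0
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    assign_to <- ((seq_along(idx) - 1 + start) %% k) + 1
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    start <- (start + length(idx)) %% k
  }
  lapply(folds, sort)
}

#' Confusion matrix
#'
#' Tallies true-label rows against predicted-label columns over a fixed
#' label order. Predictions outside the label set are rejected.
#'
#' @param true,predicted Vectors of equal length.
#' @param labels Class order (defaults to the union of levels of `true`).
#' @return Square integer matrix with `labels` dimnames; the trace is the
#'   number of correct predictions.
#' @export
confusion <- function(true, predicted, labels = NULL) {
  if (length(true) != length(predicted)) {
    stop("'true' and 'predicted' must have equal length", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (is.factor(true)) levels(true) else sort(unique(true))
  }
  bad <- setdiff(unique(as.character(predicted)), labels)
  if (length(bad)) {
    stop("predicted label(s) outside the label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!as.character(true) %in% labels)) {
    stop("true label(s) outside the label set", call. = FALSE)
  }
  tt <- table(factor(as.character(true), levels = labels),
              factor(as.character(predicted), levels = labels))
  m <- matrix(as.integer(tt), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

#' Macro-averaged classification metrics from a confusion matrix
#'
#' Computes overall accuracy, per-class recall, precision and F1, and the
#' macro averages: macro-recall and macro-precision are arithmetic means of
#' the per-class values, while macro-F1 is the harmonic mean of macro-recall
#' and macro-precision (not the mean of per-class F1 scores). A class with
#' zero predicted (or true) positives gets precision (recall) 0 with a
#' warning.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Object of class `"metrics_report"`: list with `accuracy`,
#'   `per_class` (data.frame recall/precision/f1), `macro_recall`,
#'   `macro_precision`, `macro_f1`, `n_classes`.
#' @export
classification_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0) {
    stop("'cm' must be a non-empty square confusion matrix", call. = FALSE)
  }
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  if (any(tp + fp == 0)) {
    warning("class(es) with zero predicted positives; precision set to 0: ",
            paste(rownames(cm)[tp + fp == 0], collapse = ", "), call. = FALSE)
  }
  if (any(tp + fn == 0)) {
    warning("class(es) with zero true positives; recall set to 0: ",
            paste(rownames(cm)[tp + fn == 0], collapse = ", "), call. = FALSE)
  }
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  macro_r <- mean(rec)
  macro_p <- mean(prec)
  structure(list(accuracy = sum(tp) / sum(cm),
                 per_class = data.frame(class = rownames(cm), recall = rec,
                                        precision = prec, f1 = f1,
                                        row.names = NULL),
                 macro_recall = macro_r, macro_precision = macro_p,
                 macro_f1 = macro_f1(macro_r, macro_p),
                 n_classes = nrow(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Accuracy %.4f | macro-R %.4f | macro-P %.4f | macro-F1 %.4f (%d classes)\n",
    x$accuracy, x$macro_recall, x$macro_precision, x$macro_f1, x$n_classes))
  invisible(x)
}

#' Macro F1 score from macro recall and macro precision
#'
#' Harmonic mean `2 * R * P / (R + P)` of the macro-averaged recall and
#' precision.
#'
#' @param macro_recall,macro_precision Values in \[0, 1\].
#' @return The macro-F1 score.
#' @export
#' @examples
#' round(macro_f1(0.9836, 0.9806), 4)   # 0.9821
macro_f1 <- function(macro_recall, macro_precision) {
  if (macro_recall + macro_precision == 0) return(0)
  2 * macro_recall * macro_precision / (macro_recall + macro_precision)
}

#' Macro one-vs-rest AUC from per-class scores
#'
#' For each class, the one-vs-rest AUC of that class's score column is
#' computed with the rank-sum (Mann-Whitney) formulation, ties handled by
#' midranks; the macro AUC is the arithmetic mean over classes present in
#' the true labels (absent classes are skipped with a warning). This is the
#' performance measure underlying the `1 - AUC` permutation-importance
#' loss.
#'
#' @param scores Numeric matrix, one column per class (named).
#' @param true True labels; every label must match a score column.
#' @return Macro AUC in \[0, 1\].
#' @export
macro_ovr_auc <- function(scores, true) {
  true <- as.character(true)
  if (is.null(colnames(scores))) {
    stop("'scores' must have class names as column names", call. = FALSE)
  }
  if (any(!true %in% colnames(scores))) {
    stop("true label(s) without a score column", call. = FALSE)
  }
  classes <- colnames(scores)
  present <- intersect(classes, unique(true))
  if (length(present) < length(classes)) {
    warning("class(es) absent from true labels skipped: ",
            paste(setdiff(classes, present), collapse = ", "), call. = FALSE)
  }
  aucs <- vapply(present, function(cl) {
    pos <- true == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n0 == 0) return(NA_real_)
    r <- rank(scores[, cl], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Export a metrics report or confusion matrix
#'
#' @param x A `"metrics_report"` or confusion matrix.
#' @param path Output file; `.json` or `.csv` by extension.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (is.matrix(x)) {
    if (ext == "csv") {
      utils::write.csv(as.data.frame(x), path, fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(list(labels = rownames(x), counts = unname(x)),
                           path, digits = NA)
    }
  } else if (inherits(x, "metrics_report")) {
    if (ext == "csv") {
      utils::write.csv(x$per_class, path, row.names = FALSE,
                       fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
    }
  } else {
    stop("don't know how to write objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  invisible(path)
}
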