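#' Random forest classifier
#'
#' Origin discrimination with a random forest, delegated to
#' \pkg{randomForest}. The tunable ranges mirror the swarm search space:
#' 50-200 trees and a minimum leaf size of 2-10 samples; values outside
#' these ranges are rejected. Deterministic under `seed`.
#'
#' @param table Training chem table.
#' @param n_trees Number of trees (integer in \[50, 200\]).
#' @param min_samples_leaf Minimum samples per leaf node (integer in
#'   \[2, 10\]).
#' @param group_by Label column.
#' @param seed Integer seed.
#' @return Object of class `c("origin_rf", "origin_classifier")`.
#' @export
train_rf <- function(table, n_trees = 151, min_samples_leaf = 2,
                     group_by = c("region", "country"), seed = 1) {
  group_by <- match.arg(group_by)
  if (n_trees < 50 || n_trees > 200 || n_trees != round(n_trees)) {
    stop("'n_trees' must be an integer in [50, 200]", call. = FALSE)
  }
  if (min_samples_leaf < 2 || min_samples_leaf > 10 ||
      min_samples_leaf != round(min_samples_leaf)) {
    stop("'min_samples_leaf' must be an integer in [2, 10]", call. = FALSE)
  }
  table <- as_chem_table(table)
  y <- .training_labels(table, group_by)
  components <- chem_components(table)
  X <- .design_matrix(table, components)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                    nodesize = min_samples_leaf)
  structure(list(algorithm = "RF", fit = fit, n_trees = n_trees,
                 min_samples_leaf = min_samples_leaf,
                 components = components, levels = levels(y),
                 group_by = group_by, n_train = nrow(X),
                 class_support = as.vector(table(y)), seed = seed),
            class = c("origin_rf", "origin_classifier"))
}

#' Predict origins with a fitted random forest
#'
#' @param object Fitted model from [train_rf()].
#' @param newdata Chem table with the training components.
#' @param type `"class"` or `"scores"` (per-class vote fractions).
#' @param ... Unused.
#' @return Factor of labels or a vote-fraction matrix.
#' @export
predict.origin_rf <- function(object, newdata,
                              type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Xnew <- .design_matrix(newdata, object$components)
  if (type == "scores") {
    pr <- stats::predict(object$fit, Xnew, type = "prob")
    return(pr[, object$levels, drop = FALSE])
  }
  factor(as.character(stats::predict(object$fit, Xnew, type = "response")),
         levels = object$levels)
}
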