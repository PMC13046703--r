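# Shared plumbing for the three origin classifiers. Every fitted model
# carries: $levels (full label set), $components (training column order),
# $group_by, and a predict() method returning either hard labels or a
# finite per-class score matrix over the full label set.

.design_matrix <- function(table, components) {
  table <- as_chem_table(table)
  missing <- setdiff(components, chem_components(table))
  if (length(missing)) {
    stop("table is missing component column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(table[, components, drop = FALSE])
}

.fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

.training_labels <- function(table, group_by) {
  y <- factor(table[[group_by]], levels = unique(table[[group_by]]))
  if (nlevels(y) < 2) stop("need at least two classes", call. = FALSE)
  empty <- levels(y)[table(y) == 0]
  if (length(empty)) {
    stop("class absent from training data: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  y
}

#' @export
print.origin_classifier <- function(x, ...) {
  cat("Origin classifier (", x$algorithm, "): ", length(x$levels),
      " classes, ", length(x$components), " components, n = ",
      x$n_train, "\n", sep = "")
  invisible(x)
}

#' Multiclass SVM on a precomputed Gram matrix
#'
#' Trains a soft-margin support vector machine for origin discrimination on
#' the Gram matrix of a [kernel_spec()] — including the simplex-weighted
#' hybrid kernel. The multiclass scheme is either pairwise one-vs-one
#' voting (default) or one-vs-rest; each binary subproblem is solved by the
#' SMO solver in \pkg{kernlab} on the precomputed kernel.
#'
#' Features are z-scored on the training split by default: the components
#' span four orders of magnitude in units (% to ug/g) and the Gaussian
#' width range \[10, 50\] is only meaningful on standardized inputs.
#'
#' @param table Training chem table.
#' @param kernel A [kernel_spec()].
#' @param C Soft-margin cost (> 0).
#' @param multiclass `"ovo"` (pairwise voting) or `"ovr"`.
#' @param standardize Z-score features using training statistics.
#' @param group_by Label column, `"region"` or `"country"`.
#' @return Object of class `c("origin_svm", "origin_classifier")`.
#' @seealso [predict.origin_svm()]
#' @export
train_svm <- function(table, kernel = kernel_spec("linear"), C = 1,
                      multiclass = c("ovo", "ovr"), standardize = TRUE,
                      group_by = c("region", "country")) {
  multiclass <- match.arg(multiclass)
  group_by <- match.arg(group_by)
  if (!(C > 0)) stop("'C' must be > 0", call. = FALSE)
  table <- as_chem_table(table)
  kernel <- as_kernel_spec(kernel)
  y <- .training_labels(table, group_by)
  components <- chem_components(table)
  X <- .design_matrix(table, components)
  scaler <- if (standardize) .fit_scaler(X) else NULL
  X <- .apply_scaler(X, scaler)
  G <- gram(X, X, kernel)
  lev <- levels(y)

  fit_binary <- function(idx_pos, idx_neg) {
    idx <- c(idx_pos, idx_neg)
    # NB: keep default (alphabetical) factor levels -- ksvm mis-solves
    # precomputed-kernel problems when the level order is customized
    ybin <- factor(rep(c("pos", "neg"), c(length(idx_pos), length(idx_neg))))
    Gsub <- G[idx, idx, drop = FALSE]
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(Gsub), ybin,
                         type = "C-svc", C = C)
    sv <- kernlab::SVindex(fit)
    dtr <- as.vector(kernlab::predict(
      fit, kernlab::as.kernelMatrix(Gsub[, sv, drop = FALSE]),
      type = "decision"))
    s <- mean(dtr[ybin == "pos"]) - mean(dtr[ybin == "neg"])
    list(fit = fit, train_idx = idx, sv = sv,
         sign = if (s >= 0) 1 else -1)
  }

  machines <- list()
  if (multiclass == "ovo") {
    for (i in seq_len(length(lev) - 1)) {
      for (j in (i + 1):length(lev)) {
        m <- fit_binary(which(y == lev[i]), which(y == lev[j]))
        m$pair <- c(lev[i], lev[j])
        machines[[length(machines) + 1]] <- m
      }
    }
  } else {
    for (cl in lev) {
      m <- fit_binary(which(y == cl), which(y != cl))
      m$pair <- c(cl, NA)
      machines[[length(machines) + 1]] <- m
    }
  }

  structure(list(algorithm = paste0("SVM-", kernel$family),
                 kernel = kernel, C = C, multiclass = multiclass,
                 machines = machines, X = X, y = y,
                 scaler = scaler, components = components,
                 levels = lev, group_by = group_by, n_train = nrow(X),
                 class_support = as.vector(table(y))),
            class = c("origin_svm", "origin_classifier"))
}

.svm_scores <- function(object, Xnew) {
  lev <- object$levels
  scores <- matrix(0, nrow(Xnew), length(lev),
                   dimnames = list(NULL, lev))
  votes <- matrix(0, nrow(Xnew), length(lev),
                  dimnames = list(NULL, lev))
  Kfull <- gram(Xnew, object$X, object$kernel)
  for (m in object$machines) {
    Kt <- Kfull[, m$train_idx, drop = FALSE][, m$sv, drop = FALSE]
    d <- m$sign * as.vector(kernlab::predict(
      m$fit, kernlab::as.kernelMatrix(Kt), type = "decision"))
    a <- m$pair[1]; b <- m$pair[2]
    scores[, a] <- scores[, a] + d
    if (!is.na(b)) {
      scores[, b] <- scores[, b] - d
      votes[, a] <- votes[, a] + (d > 0)
      votes[, b] <- votes[, b] + (d <= 0)
    }
  }
  list(scores = scores, votes = votes)
}

#' Predict origins with a fitted SVM
#'
#' @param object Fitted model from [train_svm()].
#' @param newdata Chem table with the training components.
#' @param type `"class"` for hard labels or `"scores"` for the per-class
#'   decision-score matrix (one-vs-one: aggregated signed pairwise
#'   decisions; one-vs-rest: per-class decision values, whose row argmax is
#'   the emitted label).
#' @param ... Unused.
#' @return A factor over the training label set, or a numeric matrix.
#' @export
predict.origin_svm <- function(object, newdata,
                               type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Xnew <- .apply_scaler(.design_matrix(newdata, object$components),
                        object$scaler)
  sc <- .svm_scores(object, Xnew)
  if (type == "scores") return(sc$scores)
  if (object$multiclass == "ovr") {
    idx <- max.col(sc$scores, ties.method = "first")
  } else {
    # pairwise voting; ties broken by the aggregate decision score
    idx <- vapply(seq_len(nrow(sc$votes)), function(r) {
      v <- sc$votes[r, ]
      cand <- which(v == max(v))
      if (length(cand) > 1) cand <- cand[which.max(sc$scores[r, cand])]
      cand[1]
    }, 0L)
  }
  factor(object$levels[idx], levels = object$levels)
}

#' @export
summary.origin_svm <- function(object, ...) {
  print(object)
  print(object$kernel)
  cat("  C =", object$C, "; multiclass =", object$multiclass,
      "; standardize =", !is.null(object$scaler), "\n")
  cat("  support vectors per machine:",
      paste(vapply(object$machines, function(m) length(m$sv), 0L),
            collapse = ", "), "\n")
  invisible(object)
}
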