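#' Permutation feature importance under a 1 - AUC loss
#'
#' Model-agnostic importance of each component for a fitted origin
#' classifier: the baseline loss is `1 - macro_ovr_auc` on the unpermuted
#' evaluation split; for each component and repeat, that column is shuffled
#' within the evaluation split (the model is never refit), the loss is
#' recomputed, and the increase over baseline is recorded. Components are
#' ranked by the mean loss increase over repeats.
#'
#' The evaluation split should be the held-out test set of the interpreted
#' model, which avoids training-set optimism.
#'
#' @param model A fitted origin classifier (SVM, BPNN or RF).
#' @param table Evaluation chem table with the training components.
#' @param repeats Number of permutation repeats per component (>= 1).
#' @param seed Integer seed; the full record set is reproducible.
#' @return A data.frame of class `"importance_ranking"` with columns
#'   `component`, `mean_delta_loss`, `sd_delta_loss` and `rank` (rank 1 is
#'   the largest mean loss increase; ties broken by component name), sorted
#'   by rank, with the baseline loss as attribute `baseline_loss`.
#' @export
permutation_importance <- function(model, table, repeats = 10, seed = 1) {
  if (repeats < 1) stop("'repeats' must be >= 1", call. = FALSE)
  table <- as_chem_table(table)
  truth <- table[[model$group_by]]
  base_scores <- predict(model, table, type = "scores")
  baseline <- 1 - macro_ovr_auc(base_scores, truth)
  comps <- model$components
  set.seed(as.integer(seed))
  deltas <- matrix(NA_real_, nrow = length(comps), ncol = repeats,
                   dimnames = list(comps, NULL))
  n <- nrow(table)
  for (ci in seq_along(comps)) {
    for (r in seq_len(repeats)) {
      perm <- sample.int(n)
      shuffled <- table
      shuffled[[comps[ci]]] <- shuffled[[comps[ci]]][perm]
      sc <- predict(model, shuffled, type = "scores")
      deltas[ci, r] <- (1 - macro_ovr_auc(sc, truth)) - baseline
    }
  }
  mean_delta <- rowMeans(deltas)
  sd_delta <- apply(deltas, 1, stats::sd)
  ord <- order(-mean_delta, comps)
  out <- data.frame(component = comps[ord],
                    mean_delta_loss = mean_delta[ord],
                    sd_delta_loss = sd_delta[ord],
                    rank = seq_along(comps),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "baseline_loss") <- baseline
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Top-k most important components
#'
#' @param records An `"importance_ranking"` (or compatible data.frame with
#'   a `rank` column).
#' @param k Number of leading records to keep (default 20).
#' @return The first `k` rows by rank.
#' @export
top_k <- function(records, k = 20) {
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (k > nrow(records)) {
    stop("'k' exceeds the number of records", call. = FALSE)
  }
  records[order(records$rank)[seq_len(k)], , drop = FALSE]
}

#' Plot an importance ranking as a horizontal bar chart
#'
#' @param x An `"importance_ranking"`.
#' @param k Number of top components to show.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted subset.
#' @export
plot.importance_ranking <- function(x, k = min(20, nrow(x)), ...) {
  top <- top_k(x, k)
  top <- top[rev(seq_len(nrow(top))), ]
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(top$mean_delta_loss, names.arg = top$component,
                    horiz = TRUE, las = 1, cex.names = 0.7,
                    xlab = "mean increase in 1 - AUC", ...)
  invisible(top)
}

#' Write an importance ranking to CSV
#'
#' @param records An `"importance_ranking"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
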