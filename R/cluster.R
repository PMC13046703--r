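#' Mean chemical profiles per origin group
#'
#' Averages every component within each origin group, producing the
#' groups x components matrix that hierarchical clustering operates on.
#'
#' @param table A chem table.
#' @param group_by `"region"` or `"country"`.
#' @param scale_components Optionally z-score each component column across
#'   groups before returning (off by default; correlation distance is
#'   already location/scale invariant per profile pair).
#' @return Numeric matrix, one row per group in order of first appearance.
#' @export
mean_profiles <- function(table, group_by = c("region", "country"),
                          scale_components = FALSE) {
  group_by <- match.arg(group_by)
  table <- as_chem_table(table)
  g <- factor(table[[group_by]], levels = unique(table[[group_by]]))
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  comps <- chem_components(table)
  prof <- vapply(comps, function(cm) tapply(table[[cm]], g, mean),
                 numeric(nlevels(g)))
  prof <- matrix(prof, nrow = nlevels(g),
                 dimnames = list(levels(g), comps))
  if (scale_components) prof <- scale(prof)[, , drop = FALSE]
  prof
}

#' Pearson-correlation distance between profiles
#'
#' Distance `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of
#' two profile rows across components; values lie in \[0, 2\] with 0 on the
#' diagonal. A profile that is constant across components has no defined
#' correlation and is rejected.
#'
#' @param profiles Numeric matrix, rows = profiles (see [mean_profiles()]).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
pearson_distance <- function(profiles) {
  if (!is.matrix(profiles) || nrow(profiles) < 2) {
    stop("'profiles' must be a matrix with at least two rows", call. = FALSE)
  }
  v <- apply(profiles, 1, stats::var)
  if (any(v == 0)) {
    stop("constant profile(s): ",
         paste(rownames(profiles)[v == 0], collapse = ", "),
         "; correlation distance undefined", call. = FALSE)
  }
  d <- 1 - stats::cor(t(profiles))
  d[d < 0] <- 0                      # guard rounding below zero
  diag(d) <- 0
  d
}

#' Agglomerative clustering of profile distances
#'
#' Standard agglomerative merging of a precomputed distance matrix.
#' Average linkage (UPGMA) is the default, matching common practice for
#' correlation distances; single and complete linkage are available.
#' Merging is deterministic: ties are resolved by the smallest leaf index.
#'
#' @param distances Symmetric distance matrix (e.g. [pearson_distance()])
#'   or a [stats::dist] object.
#' @param linkage One of `"average"`, `"single"`, `"complete"`.
#' @return An object of class [stats::hclust].
#' @export
agglomerate <- function(distances, linkage = c("average", "single",
                                               "complete")) {
  linkage <- match.arg(linkage)
  if (is.matrix(distances)) {
    if (nrow(distances) != ncol(distances) ||
        !isTRUE(all.equal(distances, t(distances), tolerance = 1e-8))) {
      stop("'distances' must be a symmetric square matrix", call. = FALSE)
    }
    distances <- stats::as.dist(distances)
  } else if (!inherits(distances, "dist")) {
    stop("'distances' must be a matrix or a 'dist' object", call. = FALSE)
  }
  stats::hclust(distances, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' Converts an agglomerative clustering result to Newick text with branch
#' lengths derived from the merge heights (each node sits at half its merge
#' height, so two leaves merging at height h are each at distance h/2 from
#' their parent).
#'
#' @param dendrogram An [stats::hclust] object.
#' @param path Optional file to write the string to (`.nwk`).
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(dendrogram, path = NULL) {
  if (!inherits(dendrogram, "hclust")) {
    stop("'dendrogram' must be an hclust object", call. = FALSE)
  }
  phy <- ape::as.phylo(dendrogram)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Export the merge list of a dendrogram as JSON
#'
#' @param dendrogram An [stats::hclust] object.
#' @param path Optional JSON path.
#' @return A list with `leaves` and `merges` (left, right, height), written
#'   to `path` when given.
#' @export
merge_list <- function(dendrogram, path = NULL) {
  if (!inherits(dendrogram, "hclust")) {
    stop("'dendrogram' must be an hclust object", call. = FALSE)
  }
  merges <- lapply(seq_len(nrow(dendrogram$merge)), function(i) {
    list(left = dendrogram$merge[i, 1], right = dendrogram$merge[i, 2],
         height = dendrogram$height[i])
  })
  out <- list(leaves = dendrogram$labels, merges = merges)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
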