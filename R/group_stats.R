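#' One-way ANOVA for a single chemical component
#'
#' Classical fixed-effects one-way analysis of variance of one component
#' across origin groups, with the F statistic from the between/within mean
#' square ratio and the p-value from the F distribution. Post hoc Tukey HSD
#' letters at `alpha` are attached so that the result mirrors one row of a
#' published mean-comparison table.
#'
#' If the pooled within-group variance is exactly zero while group means
#' differ, the decomposition is degenerate: F is reported as `Inf`, p as 0,
#' and the result is flagged.
#'
#' @param table A chem table.
#' @param component Component column name.
#' @param group_by `"region"` or `"country"`.
#' @param alpha Significance level for the post hoc letters.
#' @return An object of class `"chem_anova"`: a list with `component`, `F`,
#'   `df_between`, `df_within`, `p`, `category` (see
#'   [significance_category()]), `group_means`, `group_n`, `group_letters`
#'   and `degenerate`.
#' @export
#' @examples
#' tbl <- as_chem_table(data.frame(
#'   region = rep(c("A", "B", "C"), each = 3), country = "X",
#'   x = c(1, 2, 3, 2, 3, 4, 3, 4, 5)))
#' one_way_anova(tbl, "x")$F   # 3
one_way_anova <- function(table, component,
                          group_by = c("region", "country"),
                          alpha = 0.05) {
  group_by <- match.arg(group_by)
  table <- as_chem_table(table)
  if (!component %in% chem_components(table)) {
    stop("unknown component '", component, "'", call. = FALSE)
  }
  y <- table[[component]]
  g <- factor(table[[group_by]], levels = unique(table[[group_by]]))
  .check_groups(g)

  fit <- stats::aov(y ~ g)
  tab <- suppressWarnings(stats::anova(fit))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  dfb <- tab$Df[1]; dfw <- tab$Df[2]
  degenerate <- ssw <= .Machine$double.eps * max(1, ssb)
  if (degenerate && ssb > 0) {
    f <- Inf; p <- 0
  } else if (degenerate) {            # all values identical
    f <- 0; p <- 1
  } else {
    f <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }

  hsd <- tukey_hsd(table, component, group_by, alpha = alpha)
  letters <- compact_letter_display(hsd$significant, levels(g))

  structure(list(component = component,
                 group_by = group_by,
                 F = f, df_between = dfb, df_within = dfw, p = p,
                 category = significance_category(p),
                 group_means = c(tapply(y, g, mean)),
                 group_n = as.vector(table(g)),
                 group_letters = letters,
                 degenerate = degenerate),
            class = "chem_anova")
}

#' @export
print.chem_anova <- function(x, ...) {
  cat("One-way ANOVA of '", x$component, "' by ", x$group_by, "\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g  [%s]%s\n", x$df_between,
              x$df_within, x$F, x$p, x$category,
              if (x$degenerate) "  (degenerate: zero within-group variance)"
              else ""))
  means <- sprintf("%.4g%s", x$group_means, x$group_letters)
  names(means) <- names(x$group_means)
  print(means, quote = FALSE)
  invisible(x)
}

.check_groups <- function(g) {
  counts <- table(g)
  if (length(counts) < 2) stop("need at least two groups", call. = FALSE)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
}

#' Tukey HSD pairwise comparisons for one component
#'
#' All-pairs post hoc comparison with the studentized range criterion,
#' using Tukey-Kramer standard errors for unbalanced groups (group sizes
#' here span 24 to 1269). When the within-group variance is exactly zero
#' the studentized range test is undefined; pairs are then declared
#' significant exactly when their means differ.
#'
#' @inheritParams one_way_anova
#' @param alpha Familywise significance level.
#' @return A list with `p` (symmetric matrix of adjusted p-values, `NA` on
#'   the diagonal) and `significant` (symmetric logical matrix, `FALSE`
#'   diagonal).
#' @export
tukey_hsd <- function(table, component, group_by = c("region", "country"),
                      alpha = 0.05) {
  group_by <- match.arg(group_by)
  table <- as_chem_table(table)
  y <- table[[component]]
  g <- factor(table[[group_by]], levels = unique(table[[group_by]]))
  .check_groups(g)
  lev <- levels(g)
  k <- length(lev)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  sig <- matrix(FALSE, k, k, dimnames = list(lev, lev))

  msw <- suppressWarnings(stats::anova(stats::aov(y ~ g)))$`Mean Sq`[2]
  if (msw <= .Machine$double.eps * max(1, stats::var(y))) {
    means <- tapply(y, g, mean)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      differ <- means[i] != means[j]
      pmat[i, j] <- pmat[j, i] <- if (differ) 0 else 1
      sig[i, j] <- sig[j, i] <- differ
    }
    return(list(p = pmat, significant = sig))
  }

  hsd <- stats::TukeyHSD(stats::aov(y ~ g), conf.level = 1 - alpha)$g
  # level names may themselves contain '-': parse by matching level prefixes
  for (r in seq_len(nrow(hsd))) {
    nm <- rownames(hsd)[r]
    hit <- NULL
    for (a in lev) {
      if (startsWith(nm, paste0(a, "-"))) {
        b <- substring(nm, nchar(a) + 2)
        if (b %in% lev) { hit <- c(a, b); break }
      }
    }
    if (is.null(hit)) stop("cannot parse comparison '", nm, "'", call. = FALSE)
    pv <- hsd[r, "p adj"]
    pmat[hit[1], hit[2]] <- pmat[hit[2], hit[1]] <- pv
    s <- isTRUE(pv < alpha)
    sig[hit[1], hit[2]] <- sig[hit[2], hit[1]] <- s
  }
  list(p = pmat, significant = sig)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb letter assignment: two groups share at least one letter
#' exactly when they are NOT significantly different. Letters are assigned
#' `a`, `b`, ... to the letter groups ordered by their earliest member in
#' `group_order`, so the output is deterministic.
#'
#' @param significant Symmetric logical matrix with `FALSE` diagonal; entry
#'   `[i, j]` is `TRUE` when groups i and j differ significantly.
#' @param group_order Character vector giving the display order of groups
#'   (defaults to the matrix rownames).
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' m <- matrix(c(FALSE, FALSE, TRUE,
#'               FALSE, FALSE, FALSE,
#'               TRUE,  FALSE, FALSE), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' compact_letter_display(m)   # A "a", B "ab", C "b"
compact_letter_display <- function(significant,
                                   group_order = rownames(significant)) {
  if (!is.matrix(significant) || nrow(significant) != ncol(significant)) {
    stop("'significant' must be a square matrix", call. = FALSE)
  }
  if (!isTRUE(all(significant == t(significant)))) {
    stop("'significant' must be symmetric", call. = FALSE)
  }
  if (any(diag(significant))) {
    stop("'significant' must have a FALSE diagonal", call. = FALSE)
  }
  groups <- group_order
  if (is.null(groups)) groups <- as.character(seq_len(nrow(significant)))
  rn <- rownames(significant)
  if (is.null(rn)) {
    rn <- groups
    dimnames(significant) <- list(rn, rn)
  }

  cols <- list(groups)                      # start: one letter for all
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in (i + 1):length(groups)) {
      if (!significant[groups[i], groups[j]]) next
      new_cols <- list()
      for (col in cols) {
        if (groups[i] %in% col && groups[j] %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, groups[i])),
                        list(setdiff(col, groups[j])))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column contained in another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a == b || !keep[a]) next
          contained <- all(new_cols[[a]] %in% new_cols[[b]])
          if (contained &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }

  first_idx <- vapply(cols, function(col) min(match(col, groups)), 0)
  cols <- cols[order(first_idx)]
  pool <- c(letters, as.vector(outer(letters, letters, paste0)))
  if (length(cols) > length(pool)) stop("too many letter groups", call. = FALSE)
  out <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    members <- cols[[ci]]
    out[members] <- paste0(out[members], pool[ci])
  }
  if (any(out == "")) stop("internal error: group without a letter", call. = FALSE)
  out
}

#' Significance category label for a p-value
#'
#' Maps a p-value to the categorical label used in mean-comparison tables:
#' `***` for p <= 0.001 (extremely significant), `**` for 0.001 < p <= 0.01,
#' `*` for 0.01 < p <= 0.05, and `ns` for p > 0.05. Bins are right-closed.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of labels.
#' @export
#' @examples
#' significance_category(c(0.0004, 0.03, 0.2))   # "***" "*" "ns"
significance_category <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("'p' must be in [0, 1]", call. = FALSE)
  }
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Screen every component with ANOVA and Tukey letters
#'
#' Runs [one_way_anova()] on every component column of a chem table and
#' assembles a mean-comparison summary in the layout of a published
#' per-component table: one row per component with units, the F test, the
#' significance category and per-group `"mean +/- sd letters"` strings.
#' No multiplicity correction is applied across components.
#'
#' @inheritParams one_way_anova
#' @param path Optional CSV path; when given the table is also written there.
#' @return A data.frame, invisibly written to `path` when requested.
#' @export
anova_screen <- function(table, group_by = c("region", "country"),
                         alpha = 0.05, path = NULL) {
  group_by <- match.arg(group_by)
  table <- as_chem_table(table)
  comps <- chem_components(table)
  reg <- tryCatch(component_registry(), error = function(e) NULL)
  g <- factor(table[[group_by]], levels = unique(table[[group_by]]))
  lev <- levels(g)

  rows <- lapply(comps, function(cm) {
    res <- one_way_anova(table, cm, group_by, alpha = alpha)
    sds <- tapply(table[[cm]], g, stats::sd)
    cells <- sprintf("%.2f ± %.2f%s", res$group_means, sds,
                     res$group_letters[lev])
    units <- if (!is.null(reg) && cm %in% reg$component) {
      reg$units[match(cm, reg$component)]
    } else ""
    c(component = cm, units = units,
      stats::setNames(cells, lev),
      F = sprintf("%.4f", res$F), p = format(res$p, digits = 4),
      category = res$category)
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  out
}
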