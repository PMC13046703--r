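# Independent oracles and small fixture builders shared across tests.

# Brute-force one-way ANOVA F from the raw sum-of-squares decomposition.
bf_anova_F <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Exhaustive pair-counting one-vs-rest AUC (ties count 1/2).
bf_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Brute-force average-linkage (UPGMA) agglomeration: returns sorted merge
# heights, where the height of a merge is the mean of all between-cluster
# leaf pair distances.
bf_average_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Check a compact letter display against the non-significance relation.
cld_consistent <- function(letters_vec, sig) {
  groups <- names(letters_vec)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i == j) next
      share <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                strsplit(letters_vec[j], "")[[1]])) > 0
      if (share == sig[groups[i], groups[j]]) return(FALSE)
    }
  }
  TRUE
}

# Random symmetric significance matrix on k groups.
random_sig_matrix <- function(k, p = 0.4) {
  m <- matrix(FALSE, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- stats::runif(1) < p
  }
  m
}

# Gaussian-blob chem table with well separated classes.
blob_table <- function(n_per_class = 30, centers = list(A = c(0, 0, 0),
                                                        B = c(8, 0, 4),
                                                        C = c(0, 8, -4)),
                       sd = 1, country = "X") {
  blocks <- lapply(names(centers), function(cl) {
    mu <- centers[[cl]]
    vals <- matrix(stats::rnorm(n_per_class * length(mu),
                                mean = rep(mu, each = n_per_class), sd = sd),
                   nrow = n_per_class)
    colnames(vals) <- paste0("f", seq_along(mu))
    data.frame(region = cl, country = country, vals,
               stringsAsFactors = FALSE)
  })
  as_chem_table(do.call(rbind, blocks))
}

# Tiny custom generator inputs: k classes as their own countries.
toy_profiles <- function(means, sds) {
  out <- lapply(names(means), function(cl) {
    structure(list(class_label = cl, n = 10,
                   mean = means[[cl]], sd = sds[[cl]],
                   letters = NULL), class = "class_profile")
  })
  names(out) <- names(means)
  out
}
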