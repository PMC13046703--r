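#' Default within-country region mean offsets
#'
#' Mean-shift vectors that differentiate the nine Chinese provinces from the
#' China-wide component means. Only a handful of province-level means are
#' published (total alkaloids, reducing sugar, total sugar and total
#' nitrogen for Hunan/Heilongjiang/Sichuan; Fru-Asn for Henan and Hunan;
#' succinic acid for Heilongjiang; rutin for Sichuan); offsets are the
#' difference between those printed province means and the China country
#' mean, and zero everywhere else. Regions that are countries themselves
#' carry zero offsets.
#'
#' @param profiles Country profiles, as from [load_country_profiles()].
#' @param region_counts Region table, as from [load_region_counts()].
#' @return A 13 x 70 numeric matrix (regions x components) of mean offsets,
#'   in registry units.
#' @export
default_region_offsets <- function(profiles = load_country_profiles(),
                                   region_counts = load_region_counts()) {
  comp <- names(profiles[[1]]$mean)
  off <- matrix(0, nrow = nrow(region_counts), ncol = length(comp),
                dimnames = list(region_counts$region, comp))
  china <- profiles[["China"]]$mean
  published <- list(
    # region, component, published province mean
    list("Hunan", "Total alkaloids", 3.10),
    list("Heilongjiang", "Total alkaloids", 1.19),
    list("Heilongjiang", "Reducing sugar", 28.50),
    list("Hunan", "Reducing sugar", 16.39),
    list("Heilongjiang", "Total sugar", 33.23),
    list("Hunan", "Total sugar", 17.45),
    list("Sichuan", "Total nitrogen", 2.39),
    list("Heilongjiang", "Total nitrogen", 1.52),
    list("Henan", "Fru-Asn", 4368.55),
    list("Hunan", "Fru-Asn", 2666.50),
    list("Heilongjiang", "Succinic acid", 0.22),
    list("Sichuan", "Rutin", 10.40)
  )
  for (p in published) {
    off[p[[1]], p[[2]]] <- p[[3]] - china[[p[[2]]]]
  }
  off
}

#' Generate a synthetic chemical composition table
#'
#' Draws a labeled samples x components table whose per-country marginal
#' distributions follow the packaged class profiles: each sample of a region
#' is drawn per component from a normal distribution with mean equal to the
#' country mean plus the (scaled) region offset, and the country standard
#' deviation. Components are drawn independently unless a correlation matrix
#' is supplied. Negative draws are truncated at zero when
#' `truncate_at_zero` is set, and pH is always clamped to (0, 14).
#' Label-independent standard-normal noise columns can be appended.
#'
#' @param profiles Named list of class profiles ([load_country_profiles()]).
#' @param region_counts Data.frame `region`, `country`, `n`
#'   ([load_region_counts()]); countries must all have a profile.
#' @param region_offsets Optional regions x components offset matrix
#'   ([default_region_offsets()]), or `NULL` for no within-country offsets.
#' @param separation_scale Non-negative multiplier applied to the region
#'   offsets; 0 collapses every region onto its country marginal.
#' @param n_noise_features Number of appended N(0, 1) noise columns
#'   (`noise_01`, ...), independent of all labels.
#' @param truncate_at_zero Truncate negative concentrations to zero.
#' @param correlation Optional positive-definite components x components
#'   correlation matrix imposed on the within-class draws (defaults to the
#'   identity, i.e. independent marginals).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A chem table with `sum(region_counts$n)` rows and
#'   `length(profiles[[1]]$mean) + n_noise_features` component columns.
#' @export
#' @examples
#' tbl <- generate_chem_table(seed = 1)
#' dim(tbl)   # 1717 x 72
generate_chem_table <- function(profiles = load_country_profiles(),
                                region_counts = load_region_counts(),
                                region_offsets = default_region_offsets(
                                  profiles, region_counts),
                                separation_scale = 1,
                                n_noise_features = 0,
                                truncate_at_zero = TRUE,
                                correlation = NULL,
                                seed = 1) {
  comp <- names(profiles[[1]]$mean)
  p <- length(comp)
  if (separation_scale < 0) stop("'separation_scale' must be >= 0", call. = FALSE)
  if (n_noise_features < 0) stop("'n_noise_features' must be >= 0", call. = FALSE)
  for (prof in profiles) {
    if (length(prof$mean) != p || length(prof$sd) != p) {
      stop("profile '", prof$class_label, "' does not match the registry size",
           call. = FALSE)
    }
    if (any(prof$sd < 0)) {
      stop("profile '", prof$class_label, "' has negative standard deviations",
           call. = FALSE)
    }
  }
  missing_prof <- setdiff(unique(region_counts$country), names(profiles))
  if (length(missing_prof)) {
    stop("no profile for country: ", paste(missing_prof, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(region_offsets)) {
    if (ncol(region_offsets) != p) {
      stop("'region_offsets' must have one column per component (", p, ")",
           call. = FALSE)
    }
    extra <- setdiff(rownames(region_offsets), region_counts$region)
    if (length(extra)) {
      stop("'region_offsets' has unknown regions: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  chol_fac <- NULL
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) || nrow(correlation) != p ||
        ncol(correlation) != p) {
      stop("'correlation' must be a ", p, " x ", p, " matrix", call. = FALSE)
    }
    chol_fac <- chol(correlation)
  }

  set.seed(as.integer(seed))
  blocks <- vector("list", nrow(region_counts))
  for (i in seq_len(nrow(region_counts))) {
    region <- region_counts$region[i]
    country <- region_counts$country[i]
    n <- region_counts$n[i]
    prof <- profiles[[country]]
    mu <- prof$mean
    if (!is.null(region_offsets) && region %in% rownames(region_offsets)) {
      mu <- mu + separation_scale * region_offsets[region, ]
    }
    z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    if (!is.null(chol_fac)) z <- z %*% chol_fac
    vals <- sweep(sweep(z, 2, prof$sd, "*"), 2, mu, "+")
    colnames(vals) <- comp
    blocks[[i]] <- data.frame(region = rep(region, n),
                              country = rep(country, n),
                              vals, check.names = FALSE,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  if (truncate_at_zero) {
    for (col in comp) out[[col]] <- pmax(out[[col]], 0)
  }
  if ("pH" %in% comp) {
    out[["pH"]] <- pmin(pmax(out[["pH"]], .Machine$double.eps), 14)
  }
  if (n_noise_features > 0) {
    noise <- matrix(stats::rnorm(nrow(out) * n_noise_features), nrow(out))
    colnames(noise) <- sprintf("noise_%02d", seq_len(n_noise_features))
    out <- cbind(out, as.data.frame(noise))
  }
  as_chem_table(out)
}
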