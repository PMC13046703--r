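#' Component registry of the 70 measured chemical components
#'
#' Returns the packaged registry of the 70 chemical components measured on
#' every tobacco leaf sample, with the compound category and the reporting
#' unit for each ("%", "mg/g", "ug/g"; pH is unitless). The registry fixes
#' the canonical component order used by every table in the package.
#'
#' @return A data.frame with columns `component`, `category`, `units` and
#'   `significance` (the five-country ANOVA significance label), one row per
#'   component, in canonical order.
#' @export
#' @examples
#' reg <- component_registry()
#' nrow(reg)          # 70
#' table(reg$category)
component_registry <- function() {
  prof <- .load_profile_fixture()
  reg <- unique(prof[, c("component", "category", "units", "significance")])
  rownames(reg) <- NULL
  reg
}

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "tobtrace")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged fixture '", file, "' not found", call. = FALSE)
  }
  path
}

.load_profile_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    prof <- utils::read.csv(.fixture_path("country_profiles.csv"),
                            stringsAsFactors = FALSE, encoding = "UTF-8")
    need <- c("component", "category", "units", "country", "mean", "sd",
              "letters", "significance")
    if (!all(need %in% names(prof))) {
      stop("fixture 'country_profiles.csv' is corrupt: missing columns ",
           paste(setdiff(need, names(prof)), collapse = ", "), call. = FALSE)
    }
    if (nrow(prof) != 350 || anyNA(prof$mean) || anyNA(prof$sd)) {
      stop("fixture 'country_profiles.csv' is corrupt", call. = FALSE)
    }
    cache <<- prof
    cache
  }
})

#' Per-country statistical profiles of the 70 components
#'
#' Loads the packaged per-country class profiles: for each of the five
#' producing countries (China, United States, Brazil, Zimbabwe, Zambia) the
#' mean and standard deviation of every component, together with the planned
#' sample count of that country. These marginal statistics parameterize the
#' synthetic table generator ([generate_chem_table()]).
#'
#' @return A named list of five `"class_profile"` objects. Each has elements
#'   `class_label`, `n`, `mean` (named numeric vector of length 70), `sd`
#'   (same shape, non-negative) and `letters` (the published post hoc letter
#'   codes, kept for reference).
#' @export
#' @examples
#' prof <- load_country_profiles()
#' prof$China$mean[["Total alkaloids"]]   # 2.50
load_country_profiles <- function() {
  prof <- .load_profile_fixture()
  counts <- load_region_counts()
  country_n <- tapply(counts$n, counts$country, sum)
  comp_order <- component_registry()$component
  out <- lapply(unique(prof$country), function(ct) {
    sub <- prof[prof$country == ct, ]
    sub <- sub[match(comp_order, sub$component), ]
    if (anyNA(sub$mean) || any(sub$sd < 0)) {
      stop("fixture profile for ", ct, " is corrupt", call. = FALSE)
    }
    structure(
      list(class_label = ct,
           n = unname(country_n[[ct]]),
           mean = stats::setNames(sub$mean, sub$component),
           sd = stats::setNames(sub$sd, sub$component),
           letters = stats::setNames(sub$letters, sub$component)),
      class = "class_profile")
  })
  names(out) <- unique(prof$country)
  out
}

#' @export
print.class_profile <- function(x, ...) {
  cat("Class profile:", x$class_label, " (n =", x$n, ")\n")
  cat(" ", length(x$mean), "components; first means:\n")
  print(utils::head(round(x$mean, 3)))
  invisible(x)
}

#' Region sample counts and region-to-country mapping
#'
#' Loads the packaged overview of the 13 origin classes: the nine Chinese
#' provinces plus the four other producing countries, each with its planned
#' sample count. The counts sum to 1717.
#'
#' @return A data.frame with columns `region`, `country` and `n` (13 rows).
#' @export
#' @examples
#' rc <- load_region_counts()
#' sum(rc$n)   # 1717
load_region_counts <- function() {
  counts <- utils::read.csv(.fixture_path("region_counts.csv"),
                            stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("region", "country", "n")
  if (!all(need %in% names(counts)) || nrow(counts) != 13) {
    stop("fixture 'region_counts.csv' is corrupt", call. = FALSE)
  }
  counts
}
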