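#' Chemical composition tables
#'
#' A chem table is a plain data.frame carrying one row per tobacco leaf
#' sample: a `region` label (one of the 13 origin classes), the `country` it
#' belongs to, and one numeric column per chemical component. The region to
#' country mapping must be a function (every region lies in exactly one
#' country). `as_chem_table()` validates a data.frame and stamps the
#' `"chem_table"` class on it.
#'
#' @param x A data.frame with character/factor columns `region` and
#'   `country` and at least one numeric component column.
#' @return `x` with class `c("chem_table", "data.frame")`.
#' @export
#' @examples
#' tbl <- as_chem_table(data.frame(region = c("A", "B"), country = "X",
#'                                 comp1 = c(1, 2)))
#' chem_components(tbl)
as_chem_table <- function(x) {
  if (!is.data.frame(x)) stop("'x' must be a data.frame", call. = FALSE)
  for (col in c("region", "country")) {
    if (!col %in% names(x)) {
      stop("chem table is missing required column '", col, "'", call. = FALSE)
    }
  }
  comp <- setdiff(names(x), c("region", "country"))
  if (length(comp) == 0L) stop("chem table has no component columns", call. = FALSE)
  for (col in comp) {
    if (!is.numeric(x[[col]])) {
      stop("component column '", col, "' is not numeric", call. = FALSE)
    }
    if (anyNA(x[[col]])) {
      stop("component column '", col, "' contains missing values", call. = FALSE)
    }
  }
  map <- unique(x[, c("region", "country")])
  if (anyDuplicated(map$region)) {
    stop("region to country mapping is not a function: ",
         paste(map$region[duplicated(map$region)], collapse = ", "),
         call. = FALSE)
  }
  class(x) <- unique(c("chem_table", class(x)))
  x
}

#' @rdname as_chem_table
#' @export
chem_components <- function(x) setdiff(names(x), c("region", "country"))

#' @export
print.chem_table <- function(x, ...) {
  cat("Chemical composition table: ", nrow(x), " samples, ",
      length(chem_components(x)), " components, ",
      length(unique(x$region)), " regions in ",
      length(unique(x$country)), " countries\n", sep = "")
  NextMethod()
}

#' Read and write chemical composition tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with a header row: `region`, `country`,
#' then one column per component ('.' decimal separator). Values round-trip
#' at full double precision.
#'
#' @param path File path.
#' @param table A chem table (see [as_chem_table()]).
#' @return `read_chem_table()` returns a validated chem table;
#'   `write_chem_table()` returns `path` invisibly.
#' @export
read_chem_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         encoding = "UTF-8")
  for (col in c("region", "country")) {
    if (!col %in% names(raw)) {
      stop("file '", path, "' is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  comp <- setdiff(names(raw), c("region", "country"))
  for (col in comp) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(raw[[col]])))))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "', row ", bad[1], " of '",
           path, "'", call. = FALSE)
    }
    raw[[col]] <- as.numeric(raw[[col]])
  }
  as_chem_table(raw)
}

#' @rdname read_chem_table
#' @export
write_chem_table <- function(table, path) {
  table <- as_chem_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
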