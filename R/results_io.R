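#' Write a results table
#'
#' @param table `data.frame` of named numeric/string fields (all rows share
#'   the schema by construction).  A list of identically-named lists is
#'   accepted and bound into a data frame; mixed schemas are an error.
#' @param path Output path.
#' @param dialect `"csv"` (RFC-4180 quoting) or `"json"` (array of
#'   objects; lossless round trip).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!is.data.frame(table)) {
    if (!is.list(table)) stop("table must be a data frame or list of rows")
    if (length(table) > 0L) {
      schemas <- lapply(table, names)
      if (!all(vapply(schemas, identical, TRUE, schemas[[1]])))
        stop("rows do not share a schema")
      table <- do.call(rbind, lapply(table, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      table <- data.frame()
    }
  }
  if (dialect == "csv") {
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Input path.
#' @param dialect `"csv"` or `"json"`.
#' @return `data.frame`.
#' @export
read_results <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}
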