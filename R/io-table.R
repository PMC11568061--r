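#' Read a tab-separated table with a required schema
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @param schema Character vector of required column names; an error names
#'   any that are missing.
#' @return A data frame with character columns (no factor conversion).
#' @export
read_table <- function(path, schema = character(0)) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ",
         paste(sQuote(missing), collapse = ", "), " in '", path, "'")
  df
}

#' Write a data frame as a tab-separated table
#'
#' Round-trips with [read_table()] on character/numeric data.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
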