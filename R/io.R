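# Table reading/writing with schema validation. Tables are tidy/long with
# units encoded in column names (time_h, time_s, conc_M, ...).

#' Read a measurement table with schema validation
#'
#' Reads a TSV or CSV table (delimiter sniffed from the header line unless
#' given) and validates it against a simple schema: required column names and
#' the columns that must parse as numeric.
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @param numeric_cols Columns that must be numeric; rows with unparseable
#'   values raise an error naming the row.
#' @param sep Field delimiter; `NULL` sniffs `\t` vs `,` from the header.
#' @return A data frame.
#' @export
read_measurements <- function(path, required = character(),
                              numeric_cols = character(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in intersect(union(numeric_cols, required), names(df))) {
    if (col %in% numeric_cols) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]) & df[[col]] != "NA")
      if (length(bad))
        stop("unparseable numeric in column '", col, "' at row ", bad[1])
      df[[col]] <- num
    }
  }
  # columns not declared numeric: keep numbers numeric where they parse cleanly
  for (col in setdiff(names(df), numeric_cols)) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (!anyNA(num[!is.na(df[[col]])])) df[[col]] <- num
  }
  df
}

#' Write a measurement table
#'
#' Plain TSV (or CSV by extension), no quoting, no row names — the inverse of
#' [read_measurements()].
#'
#' @param df Data frame.
#' @param path Destination; `.csv` extension selects comma delimiting.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records parameters, seed, package version and input checksums beside an
#' analysis output so the run can be reproduced.
#'
#' @param path Destination JSON path.
#' @param params Named list of parameters.
#' @param seed Integer seed used.
#' @param inputs Character vector of input file paths to checksum (md5 of
#'   contents via [tools::md5sum()]).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, params = list(), seed = NA, inputs = character()) {
  manifest <- list(
    package = "weaklink",
    version = as.character(utils::packageVersion("weaklink")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    params = params,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
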