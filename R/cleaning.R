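# Intake data-cleaning workflow: raw intake exports -> standardized numeric
# table with the ethanol-stability label as the leading column. Rows with
# nulls or cells that stay non-numeric after stripping are removed; the
# categorical positive/negative encodings are mapped to 1/0.

binary_columns <- c("ES", "AD1", "AD2")

# Parse one cell of a continuous indicator: trim, allow a trailing unit
# suffix (letters, %, degree signs, slashes), and require the remainder to be
# a syntactically valid number. Returns NA_real_ when unparseable.
parse_numeric_cell <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  m <- regexpr("^[-+]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][-+]?[0-9]+)?", x)
  ml <- attr(m, "match.length")
  num <- rep(NA_real_, length(x))
  hit <- !is.na(x) & m > 0
  if (any(hit)) {
    head_txt <- substr(x[hit], 1L, ml[hit])
    tail_txt <- substring(x[hit], ml[hit] + 1L)
    # a unit suffix must be separated from the number by whitespace or start
    # with a clearly non-numeric character ("g/100g", "°C", "%", "°T", ...)
    ok <- tail_txt == "" | grepl("^[\t %°A-Za-z/]", tail_txt)
    num[hit][ok] <- as.numeric(head_txt[ok])
  }
  num
}

# Parse a binary (label / contaminant-flag) cell: numeric 0/1 or the strings
# "positive"/"negative" in any case. Anything else becomes NA.
parse_binary_cell <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[x %in% c("1", "1.0", "positive")] <- 1
  out[x %in% c("0", "0.0", "negative")] <- 0
  out
}

#' Clean a raw milk-intake table
#'
#' Implements the intake cleaning workflow: verify that the label and the
#' fifteen indicator columns are present, map `"positive"`/`"negative"` to
#' 1/0 in the label and contaminant-flag columns, strip whitespace and unit
#' suffixes from numeric cells, drop every row that contains a null or a cell
#' that is still non-numeric after stripping, and reorder the columns so the
#' ethanol-stability label leads, followed by the indicators in their
#' original ordering. The operation is idempotent and each removed row is
#' removed for a reason (null or unparseable cell), so
#' `rows_out == rows_in - rows_dropped`.
#'
#' @param raw A data frame with the 15 indicator columns plus the `ES` label
#'   (any column order, numeric or character cells).
#' @return A `clean_table` data frame: all cells numeric, no missing values,
#'   `ES` first. The number of dropped rows is attached as attribute
#'   `n_dropped`.
#' @export
clean_table <- function(raw) {
  raw <- as.data.frame(raw)
  missing_cols <- setdiff(milk_columns(), names(raw))
  if (length(missing_cols)) {
    stopf("schema error: missing required column%s: %s",
          if (length(missing_cols) > 1) "s" else "", paste(missing_cols, collapse = ", "))
  }
  out <- raw[, milk_columns(), drop = FALSE]
  for (cl in milk_columns()) {
    out[[cl]] <- if (cl %in% binary_columns) parse_binary_cell(out[[cl]]) else parse_numeric_cell(out[[cl]])
  }
  keep <- stats::complete.cases(out) & apply(is.finite(as.matrix(out)), 1L, all)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clean_table", "data.frame")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write / load a cleaned table as CSV
#'
#' Comma-separated UTF-8 with a header row, `"."` decimal separator, and full
#' double precision so that `load_clean_csv(write_clean_csv(x))` reproduces
#' `x` cell for cell.
#'
#' @param clean A `clean_table` (or any all-numeric data frame with the
#'   standard columns).
#' @param path File path.
#' @return `write_clean_csv` returns `path` invisibly; `load_clean_csv`
#'   returns a `clean_table`.
#' @export
write_clean_csv <- function(clean, path) {
  df <- as.data.frame(clean)
  out <- as.data.frame(lapply(df, function(v) sprintf("%.17g", as.numeric(v))),
                       check.names = FALSE, optional = TRUE)
  names(out) <- names(df)
  if (nrow(df) == 0L) out <- df
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_clean_csv
#' @export
load_clean_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!identical(names(df), milk_columns())) {
    stopf("parse error: expected %d columns (%s...), found %d",
          length(milk_columns()), paste(utils::head(milk_columns(), 3), collapse = ", "),
          ncol(df))
  }
  for (cl in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) && nrow(df)) {
      stopf("parse error: non-numeric value in column '%s' at data row %d",
            cl, which(is.na(v))[1L])
    }
    df[[cl]] <- v
  }
  class(df) <- c("clean_table", "data.frame")
  df
}
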