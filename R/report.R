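report_rows <- function(scores) {
  rows <- tidy(scores)
  rows$status[is.na(rows$status)] <- "insufficient valid frames"
  rows
}

#' Write or read a session score report
#'
#' Serializes a [score_session()] result to CSV or JSON, one row per
#' (request, face part): `request`, `time_s`, `expression`, `part`
#' (`"uf"`/`"lf"`), `score`, `ability`, `valid_fraction` and `status`.
#' Undefined scores are written as explicit empty/`null` values with their
#' status (e.g. `"insufficient valid frames"`) preserved. The JSON form
#' mirrors the CSV content; both round-trip through `read_report()` with
#' numeric values preserved to better than 1e-9.
#'
#' @param scores A [score_session()] result.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the long report tibble.
#' @export
write_report <- function(scores, path, format = NULL) {
  format <- report_format(path, format)
  rows <- report_rows(scores)
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(rows, path, na = "")
    } else {
      jsonlite::write_json(rows, path, dataframe = "rows", na = "null",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("could not write report to ", path, ": ", conditionMessage(ok)),
          class = "facexpr_io_error")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = NULL) {
  format <- report_format(path, format)
  if (format == "csv") {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             request = "i", time_s = "d", expression = "c",
                             part = "c", score = "d", ability = "c",
                             valid_fraction = "d", status = "c"
                           ))
  } else {
    df <- jsonlite::fromJSON(path)
    out <- tibble::as_tibble(df)
    for (col in c("time_s", "score", "valid_fraction")) {
      out[[col]] <- as.numeric(out[[col]])
    }
    out$request <- as.integer(out$request)
  }
  out
}

report_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else "csv"
}
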