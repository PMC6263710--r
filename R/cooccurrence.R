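#' Estimate the AU co-occurrence matrix
#'
#' The regularization rule weighs each pair of action units by how often they
#' are active together. Given a binary occurrence table (one row per sample
#' or frame, one column per canonical AU), the weight for a pair is the
#' empirical joint activation probability: the fraction of samples in which
#' both AUs are active. The diagonal is forced to zero (an AU does not
#' regularize itself) and the matrix is symmetric by construction.
#'
#' @param occurrence A data frame or matrix with the 14 canonical AU columns
#'   (`"AU01"`..`"AU26"`, any order; unnamed 14-column input is assumed
#'   canonical), entries 0/1.
#' @return A 14 x 14 matrix of class `"cooccurrence"` with AU dimnames.
#' @examples
#' occ <- matrix(rbinom(14 * 50, 1, 0.3), 50, 14,
#'   dimnames = list(NULL, au_columns())
#' )
#' p <- estimate_cooccurrence(occ)
#' p["AU01", "AU02"]
#' @export
estimate_cooccurrence <- function(occurrence) {
  m <- as.matrix(occurrence)
  if (nrow(m) == 0) abort_data("cannot estimate co-occurrence from an empty table")
  if (is.null(colnames(m))) {
    if (ncol(m) != length(AU_COLS)) {
      abort_format("unnamed occurrence table must have exactly 14 AU columns")
    }
    colnames(m) <- AU_COLS
  }
  missing_cols <- setdiff(AU_COLS, colnames(m))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "occurrence table is missing AU column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  m <- m[, AU_COLS, drop = FALSE]
  storage.mode(m) <- "numeric"
  if (any(!m %in% c(0, 1))) abort_data("occurrence entries must be 0 or 1")
  p <- crossprod(m) / nrow(m)
  diag(p) <- 0
  dimnames(p) <- list(AU_COLS, AU_COLS)
  new_cooccurrence(p)
}

new_cooccurrence <- function(p) {
  structure(p, class = c("cooccurrence", class(matrix())))
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("<cooccurrence: 14 x 14 joint AU activation probabilities>\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' @method tidy cooccurrence
#' @export
tidy.cooccurrence <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(unclass(x), responseName = "p",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("au_i", "au_j", "p"))
}

#' Binarize AU intensities into an occurrence table
#'
#' Convenience for learning a co-occurrence matrix from intensity data when
#' no annotated occurrence table is available: an AU counts as active in a
#' frame when its intensity exceeds `threshold` on the 0-5 scale. Only valid
#' frames contribute.
#'
#' @param stream An [as_au_stream()] tibble.
#' @param threshold Activation threshold (default 1 intensity unit).
#' @return A tibble of 0/1 occurrence indicators, one row per valid frame.
#' @export
au_occurrence <- function(stream, threshold = 1) {
  ints <- au_intensities(stream)[stream$valid, , drop = FALSE]
  tibble::as_tibble(1 * (ints > threshold))
}

#' Co-occurrence matrix implied by the expression AU sets
#'
#' A reference weighting derived from the four basic expressions alone:
#' treating each expression's AU set (see [expression_aus()]) as one
#' occurrence sample, the pairwise weight is the fraction of the four
#' expressions in which both AUs take part. This is also the generating
#' structure of the built-in simulator's request-locked events.
#'
#' @return A `"cooccurrence"` matrix.
#' @examples
#' p <- expression_cooccurrence()
#' p["AU06", "AU12"] # jointly active in happiness only: 1/4
#' @export
expression_cooccurrence <- function() {
  occ <- matrix(0, length(EXPRESSION_AUS), length(AU_COLS),
                dimnames = list(names(EXPRESSION_AUS), AU_COLS))
  for (x in names(EXPRESSION_AUS)) {
    occ[x, sprintf("AU%02d", EXPRESSION_AUS[[x]])] <- 1
  }
  estimate_cooccurrence(occ)
}

#' Read or write a co-occurrence matrix as CSV
#'
#' The on-disk form is a 14 x 14 table with an `au` header column and one
#' column per canonical AU.
#'
#' @param x A `"cooccurrence"` matrix.
#' @param path File path.
#' @return `read_cooccurrence()` returns a `"cooccurrence"` matrix;
#'   `write_cooccurrence()` returns `path` invisibly.
#' @export
write_cooccurrence <- function(x, path) {
  df <- tibble::as_tibble(unclass(x))
  df <- dplyr::bind_cols(tibble::tibble(au = rownames(x)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_cooccurrence
#' @export
read_cooccurrence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"au" %in% names(df) || !all(AU_COLS %in% names(df))) {
    abort_format("co-occurrence CSV must have an 'au' column plus the 14 AU columns")
  }
  p <- as.matrix(df[AU_COLS])
  rownames(p) <- df$au
  p <- p[AU_COLS, AU_COLS]
  validate_cooccurrence(new_cooccurrence(p))
}

validate_cooccurrence <- function(p) {
  if (!all(dim(p) == c(14, 14))) abort_config("co-occurrence matrix must be 14 x 14")
  if (any(p < 0) || any(p > 1)) abort_config("co-occurrence entries must lie in [0, 1]")
  if (max(abs(p - t(p))) > 1e-9) abort_config("co-occurrence matrix must be symmetric")
  if (any(diag(p) != 0)) abort_config("co-occurrence diagonal must be zero")
  p
}

## The regularization field: R[t, i] = sum_j p_ij (A[t,i] - A[t,j]) / n.
## For symmetric p the paired terms cancel, so rowSums(R) == 0.
regularization_field <- function(A, p) {
  n <- ncol(p)
  s <- rowSums(p)
  R <- (A * matrix(s, nrow(A), n, byrow = TRUE) - A %*% t(p)) / n
  dimnames(R) <- dimnames(A)
  R
}

#' Regularize AU intensities by their co-occurrence structure
#'
#' Independent per-frame AU estimates ignore the spatial dependencies between
#' facial muscles. This step adjusts each AU intensity by a correction term
#' built from its co-occurring peers:
#' \deqn{\bar{AU}_i(t) = AU_i(t) + R_i(t), \qquad
#'       R_i(t) = \frac{\sum_{j \ne i} p_{ij}\,(AU_i(t) - AU_j(t))}{n}}
#' with \eqn{p_{ij}} the pairwise co-occurrence weights and \eqn{n = 14} the
#' number of considered AUs. An AU above its correlated peers is pushed
#' further up and one below is pushed down, sharpening co-activated patterns;
#' note this amplifies rather than shrinks discrepancies with correlated
#' peers, a property users should keep in mind when interpreting single-AU
#' excursions. For a symmetric weight matrix the corrections cancel across
#' AUs frame by frame, so the total intensity mass is conserved before the
#' final clipping of negative values at 0.
#'
#' Only valid frames are adjusted; gated frames pass through unchanged.
#'
#' @param stream An [as_au_stream()] tibble (typically smoothed first).
#' @param cooccurrence A [estimate_cooccurrence()] matrix.
#' @return The stream with regularized intensities.
#' @export
regularize <- function(stream, cooccurrence) {
  p <- validate_cooccurrence(cooccurrence)
  if (!identical(colnames(p), AU_COLS)) {
    abort_config("co-occurrence AU order must match the canonical AU list")
  }
  if (nrow(stream) == 0) return(stream)
  ints <- au_intensities(stream)
  v <- stream$valid
  if (any(v)) {
    A <- ints[v, , drop = FALSE]
    out <- A + regularization_field(A, unclass(p))
    out[out < 0] <- 0
    ints[v, ] <- out
  }
  set_au_intensities(stream, ints)
}
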