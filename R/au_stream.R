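#' Build an AU stream from a data frame
#'
#' An AU stream is the package's universal carrier: a tibble with one row per
#' video frame holding the 14 canonical action-unit intensities (0-5 scale),
#' head pose angles in degrees relative to the frontal view, and a per-frame
#' validity mask. All pipeline stages (`gate_by_pose()`, `smooth_stream()`,
#' `regularize()`, `variation_series()`, `score_session()`, `score_clip()`)
#' take and return this shape.
#'
#' @param data A data frame with columns `frame` (0-based integer), `time_s`
#'   (strictly increasing seconds), `pitch`, `yaw`, `roll` (degrees),
#'   `valid` (logical) and the 14 AU intensity columns `"AU01"`..`"AU26"`
#'   (see [au_columns()]). AU columns may appear in any order; they are
#'   reordered canonically.
#' @param fps Frames per second. If `NULL`, derived as the reciprocal of the
#'   median timestamp increment.
#'
#' @return A tibble of class `"au_stream"` with canonical column order and an
#'   `fps` attribute.
#' @examples
#' df <- data.frame(
#'   frame = 0:2, time_s = (0:2) / 25,
#'   pitch = 0, yaw = 0, roll = 0, valid = TRUE
#' )
#' df[au_columns()] <- 0.5
#' as_au_stream(df)
#' @export
as_au_stream <- function(data, fps = NULL) {
  data <- tibble::as_tibble(data)
  meta <- c("frame", "time_s", "pitch", "yaw", "roll", "valid")
  missing_cols <- setdiff(c(meta, AU_COLS), names(data))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "AU stream is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- data[c(meta, AU_COLS)]
  n <- nrow(data)
  if (n > 1 && any(diff(data$time_s) <= 0)) {
    abort_data("timestamps must be strictly increasing")
  }
  ints <- as.matrix(data[AU_COLS])
  if (n > 0 && (any(!is.finite(ints)) || any(ints < 0))) {
    abort_data("AU intensities must be finite and non-negative")
  }
  data$frame <- as.integer(data$frame)
  data$valid <- as.logical(data$valid)
  if (is.null(fps)) {
    fps <- if (n > 1) 1 / median(diff(data$time_s)) else NA_real_
  }
  structure(data,
    fps = fps,
    class = c("au_stream", class(tibble::tibble()))
  )
}

#' @export
print.au_stream <- function(x, ...) {
  cat(sprintf(
    "<au_stream: %d frames, %.4g fps, %.1f%% valid>\n",
    nrow(x), attr(x, "fps"), if (nrow(x)) 100 * mean(x$valid) else NA_real_
  ))
  NextMethod()
}

au_fps <- function(stream) attr(stream, "fps")

au_intensities <- function(stream) as.matrix(stream[AU_COLS])

set_au_intensities <- function(stream, m) {
  stream[AU_COLS] <- as.data.frame(m)
  stream
}

#' Column-mapping dialect for AU tracker CSV files
#'
#' Describes how the columns of a tracker export map onto the AU-stream
#' fields. The default follows the OpenFace 2 regression output: AU columns
#' `AU01_r`..`AU26_r`, pose columns `pose_Rx`/`pose_Ry`/`pose_Rz` in radians
#' and a `success` flag.
#'
#' @param frame,time,success Column names of the frame index, timestamp
#'   (seconds) and tracker success flag.
#' @param pose Character vector of three column names giving pitch, yaw and
#'   roll, in that order.
#' @param pose_unit `"radians"` or `"degrees"`; radian poses are converted to
#'   degrees on read.
#' @param au Named character vector mapping each canonical AU column
#'   (`"AU01"`..`"AU26"`) to its file column.
#' @param yaml Optional path to a YAML file whose keys (`frame`, `time`,
#'   `success`, `pose`, `pose_unit`, `au`) override the defaults.
#'
#' @return A list of class `"au_dialect"`.
#' @examples
#' au_dialect()
#' @export
au_dialect <- function(frame = "frame",
                       time = "timestamp",
                       success = "success",
                       pose = c("pose_Rx", "pose_Ry", "pose_Rz"),
                       pose_unit = c("radians", "degrees"),
                       au = NULL,
                       yaml = NULL) {
  pose_unit <- match.arg(pose_unit)
  if (is.null(au)) {
    au <- stats::setNames(paste0(AU_COLS, "_r"), AU_COLS)
  }
  d <- list(frame = frame, time = time, success = success,
            pose = pose, pose_unit = pose_unit, au = au)
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    for (key in intersect(names(ov), c("frame", "time", "success", "pose_unit"))) {
      d[[key]] <- ov[[key]]
    }
    if (!is.null(ov[["pose"]])) d$pose <- unlist(ov[["pose"]])
    if (!is.null(ov[["au"]])) {
      au_ov <- unlist(ov[["au"]])
      d$au[names(au_ov)] <- au_ov
    }
  }
  if (length(d$pose) != 3) abort_config("dialect must map exactly 3 pose columns")
  if (!setequal(names(d$au), AU_COLS)) {
    abort_config("dialect AU map must cover exactly the canonical AU columns")
  }
  if (!d$pose_unit %in% c("radians", "degrees")) {
    abort_config("pose_unit must be 'radians' or 'degrees'")
  }
  structure(d, class = "au_dialect")
}

#' Read an AU intensity stream from a tracker CSV
#'
#' Reads a per-frame AU intensity export (OpenFace-style by default, see
#' [au_dialect()]) into an [as_au_stream()] tibble. Frames whose tracker
#' success flag is 0 are marked invalid; radian pose angles are converted to
#' degrees; negative intensity estimates are clipped to 0. The 14 canonical
#' AU columns must all be present.
#'
#' @param path Path to the CSV file.
#' @param dialect An [au_dialect()] describing the column mapping.
#' @return An `au_stream` tibble.
#' @export
read_au_stream <- function(path, dialect = au_dialect()) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- trimws(names(raw))
  needed <- c(dialect$frame, dialect$time, dialect$success, dialect$pose,
              unname(dialect$au))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "input is missing mapped column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  pose <- as.matrix(raw[dialect$pose])
  if (dialect$pose_unit == "radians") pose <- pose * 180 / pi
  ints <- as.matrix(raw[unname(dialect$au)])
  ints[!is.finite(ints)] <- 0
  ints[ints < 0] <- 0
  colnames(ints) <- AU_COLS
  out <- tibble::tibble(
    frame = as.integer(raw[[dialect$frame]]),
    time_s = as.numeric(raw[[dialect$time]]),
    pitch = pose[, 1], yaw = pose[, 2], roll = pose[, 3],
    valid = as.numeric(raw[[dialect$success]]) != 0
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(ints))
  as_au_stream(out)
}

#' Read a session request list
#'
#' Reads the two-column CSV listing when the subject was asked to produce
#' each expression: `time_s` (seconds into the stream) and `expression`
#' (one of `H`, `S`, `F`, `A`). Session protocols space requests by at least
#' a few seconds; requests closer than `min_spacing_s` raise a warning, not
#' an error, since real sessions may violate the protocol.
#'
#' @param path Path to the CSV file.
#' @param min_spacing_s Minimum expected spacing between consecutive
#'   requests, seconds (default 4).
#' @return A tibble with columns `time_s` and `expression`, of class
#'   `"request_list"`.
#' @export
read_requests <- function(path, min_spacing_s = 4) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "expression") %in% names(raw))) {
    abort_format("request file must have columns time_s and expression")
  }
  as_request_list(raw, min_spacing_s = min_spacing_s)
}

#' @param data A data frame with columns `time_s` and `expression`.
#' @rdname read_requests
#' @export
as_request_list <- function(data, min_spacing_s = 4) {
  out <- tibble::tibble(
    time_s = as.numeric(data$time_s),
    expression = as.character(data$expression)
  )
  bad <- setdiff(unique(out$expression), EXPRESSION_CODES)
  if (length(bad) > 0) {
    abort_format(paste0(
      "unknown expression code(s): ", paste(bad, collapse = ", "),
      " (expected H, S, F or A)"
    ))
  }
  if (nrow(out) > 1 && any(diff(out$time_s) < 0)) {
    abort_data("request times must be non-decreasing")
  }
  if (nrow(out) > 1 && any(diff(out$time_s) < min_spacing_s)) {
    warn(sprintf(
      "%d consecutive request(s) closer than %.3g s",
      sum(diff(out$time_s) < min_spacing_s), min_spacing_s
    ))
  }
  class(out) <- c("request_list", class(out))
  out
}
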