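#' Gate frames by head pose
#'
#' AU intensity estimates degrade sharply once the head turns away from the
#' camera, so frames whose head pose deviates from the frontal view by more
#' than `max_angle_deg` on any of the three reference angles (pitch, yaw,
#' roll) are marked unreliable. The new mask is AND-combined with the
#' incoming one; intensities are left untouched (unreliable frames are
#' excluded downstream, never interpolated).
#'
#' The inequality is strict: a frame at exactly the limit is kept.
#'
#' @param stream An [as_au_stream()] tibble.
#' @param max_angle_deg Gate limit in degrees (default 30).
#' @return The stream with an updated `valid` mask.
#' @examples
#' s <- simulate_session(sim_config(duration_s = 2, seed = 1))$stream
#' gate_by_pose(s)
#' @export
gate_by_pose <- function(stream, max_angle_deg = 30) {
  if (!is.numeric(max_angle_deg) || max_angle_deg <= 0) {
    abort_config("max_angle_deg must be a positive number")
  }
  if (nrow(stream) == 0) return(stream)
  off_frontal <- abs(stream$pitch) > max_angle_deg |
    abs(stream$yaw) > max_angle_deg |
    abs(stream$roll) > max_angle_deg
  stream$valid <- stream$valid & !off_frontal
  stream
}

## Least-squares hat matrices for a centered window of length w, one per
## candidate polynomial degree.
sg_hat_matrices <- function(w, degrees) {
  pos <- seq_len(w) - (w + 1) / 2
  lapply(degrees, function(d) {
    X <- outer(pos, 0:d, "^")
    X %*% solve(crossprod(X), t(X))
  })
}

## Smooth one contiguous series y (length >= w) by per-window polynomial
## fits with adaptive degree. Returns the smoothed series.
smooth_run <- function(y, w, degrees, hats) {
  len <- length(y)
  half <- (w - 1) / 2
  nwin <- len - w + 1
  idx <- outer(seq_len(nwin) - 1L, seq_len(w), "+")
  M <- matrix(y[idx], nwin, w)
  nd <- length(degrees)
  crit <- matrix(NA_real_, nwin, nd)
  fits <- vector("list", nd)
  for (k in seq_len(nd)) {
    Fk <- M %*% t(hats[[k]])
    rss <- rowSums((M - Fk)^2)
    ## corrected residual: RSS per residual degree of freedom penalizes
    ## higher-degree fits that chase noise
    crit[, k] <- rss / (w - (degrees[k] + 1))
    fits[[k]] <- Fk
  }
  pick <- max.col(-crit, ties.method = "first")
  out <- y
  centers <- vapply(seq_len(nwin), function(i) fits[[pick[i]]][i, half + 1],
                    numeric(1))
  out[(half + 1):(len - half)] <- centers
  ## edge samples: evaluated from the nearest full window's chosen fit
  out[seq_len(half)] <- fits[[pick[1]]][1, seq_len(half)]
  out[(len - half + 1):len] <- fits[[pick[nwin]]][nwin, (half + 2):w]
  out
}

#' Temporally smooth AU intensities with adaptive-degree polynomial filters
#'
#' Each AU series is denoised by sliding least-squares polynomial fits
#' (Savitzky-Golay family): every output sample is the center value of a
#' polynomial fitted over a short window around it, with the polynomial
#' degree chosen per window from `degrees` by the smallest residual sum of
#' squares per residual degree of freedom. Low degrees win on plateaus
#' (stronger denoising); higher degrees win across rapid onsets (less
#' distortion of expression dynamics).
#'
#' Smoothing runs independently per AU and only across contiguous runs of
#' valid frames: pose-gated or tracking-failure gaps are never bridged. Runs
#' shorter than the window pass through unchanged. Output intensities are
#' clipped at 0.
#'
#' @param stream An [as_au_stream()] tibble.
#' @param window_s Window length in seconds (default 0.5). The realized
#'   window is an odd number of samples at the stream's frame rate, at least
#'   `max(degrees) + 2`.
#' @param degrees Candidate polynomial degrees (default `2:4`).
#' @return The stream with smoothed AU intensities.
#' @export
smooth_stream <- function(stream, window_s = 0.5, degrees = 2:4) {
  fps <- au_fps(stream)
  if (is.null(fps) || is.na(fps) || fps <= 0) {
    abort_config("stream has a degenerate frame rate (fps <= 0)")
  }
  degrees <- sort(unique(as.integer(degrees)))
  w <- round(window_s * fps)
  if (w %% 2 == 0) w <- w + 1
  while (w < max(degrees) + 2) w <- w + 2
  if (nrow(stream) == 0) return(stream)
  hats <- sg_hat_matrices(w, degrees)
  ints <- au_intensities(stream)
  runs <- rle(stream$valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in which(runs$values & runs$lengths >= w)) {
    rows <- starts[r]:ends[r]
    for (j in seq_along(AU_COLS)) {
      ints[rows, j] <- smooth_run(ints[rows, j], w, degrees, hats)
    }
  }
  ints[ints < 0] <- 0
  set_au_intensities(stream, ints)
}
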