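#' Score a whole short clip against its own opening segment
#'
#' For short pre-segmented videos (a single expression performed once, as in
#' posed-expression corpora where clips run from a neutral face to the apex),
#' the request-response windowing does not apply. Clip mode instead fits one
#' baseline mixture per AU on the first `model_fraction` of the clip's valid
#' frames -- the near-neutral opening -- and scores the maximal AU value over
#' the remainder, yielding one V per AU and a single set of
#' [expression_scores()] for the clip.
#'
#' Clips too short for the opening segment to hold at least `k` valid
#' samples (or with an empty remainder) get undefined scores: the
#' statistical baseline is unreliable on such material.
#'
#' @inheritParams score_session
#' @param model_fraction Fraction of valid frames used for the baseline
#'   (default 0.25, i.e., the first quarter).
#' @return A tibble of class `"clip_scores"`: `expression`, `part`, `score`,
#'   `ability`, with the per-AU V values in attribute `"v"`.
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 12, requests = NULL,
#'   events = data.frame(time_s = 8, expression = "H"), seed = 1))
#' score_clip(sim$stream, seed = 1)
#' @export
score_clip <- function(stream, model_fraction = 0.25, cooccurrence = NULL,
                       k = 3, variance_floor = 1e-4,
                       low_bound = 100, high_bound = 500,
                       max_angle_deg = 30, window_s = 0.5, degrees = 2:4,
                       preprocess = TRUE, seed = NULL) {
  if (model_fraction <= 0 || model_fraction >= 1) {
    abort_config("model_fraction must lie in (0, 1)")
  }
  if (preprocess && nrow(stream) > 0) {
    stream <- gate_by_pose(stream, max_angle_deg)
    stream <- smooth_stream(stream, window_s = window_s, degrees = degrees)
    if (!is.null(cooccurrence)) stream <- regularize(stream, cooccurrence)
  }
  v <- stats::setNames(rep(NA_real_, length(AU_COLS)), AU_COLS)
  rows <- which(stream$valid)
  nm <- floor(model_fraction * length(rows))
  if (nm >= k && length(rows) > nm) {
    model_rows <- rows[seq_len(nm)]
    obs_rows <- rows[(nm + 1):length(rows)]
    with_seed(seed, {
      for (col in AU_COLS) {
        xm <- stream[[col]][model_rows]
        model <- em_mixture(xm, k, variance_floor, 100, 1e-6)
        v[col] <- neg_log_pdf(model, max(stream[[col]][obs_rows]))
      }
    })
  }
  out <- expression_scores(v)
  out$ability <- classify_ability(out$score, low_bound, high_bound)
  structure(out, class = c("clip_scores", class(tibble::tibble())), v = v)
}
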