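#' Window configuration for the short-term baseline
#'
#' The variation score at an instant `t` contrasts two windows: a modeling
#' window \eqn{W_m(t-\Delta_m; t-1)} just before `t`, on which the baseline
#' mixture of the non-emotional face is fitted, and an observation window
#' \eqn{W_o(t+1; t+\Delta_o)} just after, from which the maximal AU
#' intensity is scored against that baseline. Session protocols use a 2 s
#' modeling window and a 4 s observation window by default, matching a
#' request-response paradigm where expressions are expected within 4 s.
#'
#' @param delta_m Modeling-window length, seconds (default 2).
#' @param delta_o Observation-window length, seconds (default 4).
#' @param refit_stride Frames between mixture refits in [variation_series()]
#'   (default 1, i.e., refit at every frame); between refits the last model
#'   is reused.
#' @param min_valid_fraction Minimum fraction of valid frames each window
#'   must retain for the score to be defined (default 0.5).
#' @return A list of class `"window_config"`.
#' @export
window_config <- function(delta_m = 2, delta_o = 4, refit_stride = 1,
                          min_valid_fraction = 0.5) {
  if (delta_m <= 0 || delta_o <= 0) abort_config("window lengths must be positive")
  if (refit_stride < 1) abort_config("refit_stride must be >= 1")
  if (min_valid_fraction <= 0 || min_valid_fraction > 1) {
    abort_config("min_valid_fraction must lie in (0, 1]")
  }
  structure(
    list(delta_m = delta_m, delta_o = delta_o,
         refit_stride = as.integer(refit_stride),
         min_valid_fraction = min_valid_fraction),
    class = "window_config"
  )
}

window_frames <- function(wc, fps) {
  list(dm = max(1L, as.integer(round(wc$delta_m * fps))),
       do = max(1L, as.integer(round(wc$delta_o * fps))))
}

au_col <- function(au) {
  if (is.numeric(au)) {
    if (!au %in% AU_NUMBERS) abort_config(paste0("AU", au, " is not in the canonical AU set"))
    sprintf("AU%02d", au)
  } else {
    if (!au %in% AU_COLS) abort_config(paste0(au, " is not in the canonical AU set"))
    au
  }
}

## -log(mixture density), the variation measure. Guard against a zero
## density from underflow far in the tails by evaluating the best
## component's log-density directly.
neg_log_pdf <- function(model, x) {
  p <- mixture_pdf(model, x)
  out <- -log(p)
  bad <- !is.finite(out)
  if (any(bad)) {
    lp <- vapply(seq_len(model$k), function(j) {
      log(model$weights[j]) +
        dnorm(x[bad], model$means[j], sqrt(model$variances[j]), log = TRUE)
    }, numeric(sum(bad)))
    lp <- matrix(lp, sum(bad), model$k)
    out[bad] <- -apply(lp, 1, max)
  }
  out
}

#' Variation score of one AU at one instant
#'
#' Fits the baseline mixture on the modeling window before frame `t`, takes
#' the largest valid value of the AU in the observation window after `t`,
#' and returns its negative log-density under the baseline:
#' \deqn{V_{AU_i}(t) = -\log\big(PDF(\max(AU_i(t') : t' \in W_o))\big)}
#' High values flag muscle configurations the recent non-emotional face does
#' not explain -- including subtle but novel voluntary movements -- while
#' recurring stereotyped activations, being part of the modeling window, are
#' absorbed into the baseline and score low.
#'
#' The score is undefined (`NA`) when either window extends beyond the
#' stream, retains fewer valid frames than `min_valid_fraction`, or the
#' modeling window has fewer valid samples than the mixture needs.
#'
#' @param stream An [as_au_stream()] tibble (gated, smoothed and
#'   regularized upstream).
#' @param au AU number (e.g. `12`) or column name (`"AU12"`).
#' @param t Frame row index (1-based position in the stream).
#' @param wc A [window_config()].
#' @param k,variance_floor Mixture parameters, see [fit_mixture()].
#' @param seed Optional seed for the mixture fit.
#' @return A single numeric V value, or `NA` when undefined.
#' @export
variation_score <- function(stream, au, t, wc = window_config(), k = 3,
                            variance_floor = 1e-4, seed = NULL) {
  fps <- au_fps(stream)
  if (is.null(fps) || is.na(fps) || fps <= 0) abort_config("stream fps must be positive")
  wf <- window_frames(wc, fps)
  col <- au_col(au)
  n <- nrow(stream)
  if (t - wf$dm < 1 || t + wf$do > n) return(NA_real_)
  wm <- (t - wf$dm):(t - 1)
  wo <- (t + 1):(t + wf$do)
  vm <- stream$valid[wm]
  vo <- stream$valid[wo]
  if (mean(vm) < wc$min_valid_fraction || mean(vo) < wc$min_valid_fraction) {
    return(NA_real_)
  }
  xm <- stream[[col]][wm][vm]
  if (length(xm) < k) return(NA_real_)
  model <- fit_mixture(xm, k = k, seed = seed, variance_floor = variance_floor)
  x_star <- max(stream[[col]][wo][vo])
  neg_log_pdf(model, x_star)
}

#' Variation series for all 14 AUs
#'
#' Evaluates [variation_score()] at every frame of the stream, for every
#' canonical AU, refitting the baseline mixture every `refit_stride` frames
#' and reusing the last model in between. Frames whose windows do not fit or
#' fail the validity requirements are masked (`NA`).
#'
#' @inheritParams variation_score
#' @return A long tibble of class `"variation_series"` with columns `frame`,
#'   `time_s`, `au`, `v`.
#' @export
variation_series <- function(stream, wc = window_config(), k = 3,
                             variance_floor = 1e-4, seed = NULL) {
  fps <- au_fps(stream)
  if (is.null(fps) || is.na(fps) || fps <= 0) abort_config("stream fps must be positive")
  wf <- window_frames(wc, fps)
  n <- nrow(stream)
  ts <- seq_len(n)
  eligible <- ts - wf$dm >= 1 & ts + wf$do <= n
  out_v <- matrix(NA_real_, n, length(AU_COLS))

  if (any(eligible)) {
    valid <- stream$valid
    cv <- cumsum(c(0, valid))
    frac_m <- (cv[ts] - cv[pmax(ts - wf$dm, 1)]) / wf$dm        # valid in [t-dm, t-1]
    frac_o <- (cv[pmin(ts + wf$do, n) + 1] - cv[pmin(ts + 1, n)]) / wf$do
    defined <- eligible & frac_m >= wc$min_valid_fraction &
      frac_o >= wc$min_valid_fraction

    with_seed(seed, {
      for (j in seq_along(AU_COLS)) {
        x <- stream[[AU_COLS[j]]]
        xneg <- ifelse(valid, x, -Inf)
        ## sliding max over the observation window [t+1, t+do]
        emb <- stats::embed(c(xneg[-1], rep(-Inf, wf$do)), wf$do)
        wo_max <- do.call(pmax, as.data.frame(emb[, rev(seq_len(wf$do)), drop = FALSE]))
        model <- NULL
        anchor <- -1L
        for (t in ts[defined]) {
          if (is.null(model) || t - anchor >= wc$refit_stride) {
            wm <- (t - wf$dm):(t - 1)
            xm <- x[wm][valid[wm]]
            if (length(xm) < k) { model <- NULL; next }
            model <- em_mixture(xm, k, variance_floor, 100, 1e-6)
            anchor <- t
          }
          if (is.finite(wo_max[t])) {
            out_v[t, j] <- neg_log_pdf(model, wo_max[t])
          }
        }
      }
    })
  }

  res <- tibble::tibble(
    frame = rep(stream$frame, length(AU_COLS)),
    time_s = rep(stream$time_s, length(AU_COLS)),
    au = rep(AU_COLS, each = n),
    v = as.vector(out_v)
  )
  structure(res, class = c("variation_series", class(tibble::tibble())))
}
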