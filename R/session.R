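## Score one request: mixture per needed AU anchored on the modeling window
## just before the request frame; evaluation points slide through the
## response window, each scoring the maximal remaining AU value, and the
## per-part score is the maximum over evaluation points. This keeps every
## input inside [t_r - delta_m, t_r + delta_o].
score_request <- function(stream, r, expr, wf, wc, k, variance_floor) {
  n <- nrow(stream)
  if (r - wf$dm < 1 || r + wf$do > n) {
    return(list(m_uf = NA_real_, m_lf = NA_real_, valid_fraction = NA_real_,
                status = "outside stream"))
  }
  wm <- (r - wf$dm):(r - 1)
  resp <- r:(r + wf$do)
  vm <- stream$valid[wm]
  vr <- stream$valid[resp]
  valid_fraction <- mean(vr)
  if (mean(vm) < wc$min_valid_fraction || valid_fraction < wc$min_valid_fraction) {
    return(list(m_uf = NA_real_, m_lf = NA_real_, valid_fraction = valid_fraction,
                status = "insufficient valid frames"))
  }
  aus <- sprintf("AU%02d", EXPRESSION_AUS[[expr]])
  ## evaluation points: r, r + stride, ... while an observation window remains
  ev <- seq(r, r + wf$do - 1, by = wc$refit_stride)
  vmat <- matrix(NA_real_, length(ev), length(AU_COLS),
                 dimnames = list(NULL, AU_COLS))
  for (col in aus) {
    xm <- stream[[col]][wm][vm]
    if (length(xm) < k) {
      return(list(m_uf = NA_real_, m_lf = NA_real_, valid_fraction = valid_fraction,
                  status = "insufficient valid frames"))
    }
    model <- em_mixture(xm, k, variance_floor, 100, 1e-6)
    xo <- stream[[col]][resp]
    xo[!vr] <- -Inf
    rcm <- rev(cummax(rev(xo)))              # rcm[i] = max over resp[i..end]
    x_star <- rcm[ev - r + 2]                # max over (e, r + do]
    ok <- is.finite(x_star)
    vmat[ok, col] <- neg_log_pdf(model, x_star[ok])
  }
  m_uf_e <- vapply(seq_along(ev), function(i) score_uf(vmat[i, ], expr), numeric(1))
  m_lf_e <- vapply(seq_along(ev), function(i) score_lf(vmat[i, ], expr), numeric(1))
  pick_max <- function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
  list(m_uf = pick_max(m_uf_e), m_lf = pick_max(m_lf_e),
       valid_fraction = valid_fraction, status = "ok")
}

#' Score a request-response session end to end
#'
#' Runs the full assessment pipeline on a session recording: head-pose
#' gating, adaptive polynomial smoothing, co-occurrence regularization (when
#' a matrix is supplied), then for each expression request a personalized
#' baseline mixture is fitted per involved AU on the 2 s modeling window
#' before the request, and the production scores for the upper and lower
#' face are the maxima of the [expression_scores()] compositions over
#' evaluation points sliding through the 4 s response window. Ability
#' labels follow [classify_ability()], and per-expression means over the
#' repetitions summarize the session (see [session_summary()]).
#'
#' A request whose windows extend beyond the stream, or whose windows keep
#' too few valid frames, gets `NA` scores with an explanatory `status`.
#'
#' @param stream An [as_au_stream()] tibble (raw; preprocessing is applied
#'   internally unless `preprocess = FALSE`).
#' @param requests A [read_requests()] tibble (`time_s`, `expression`).
#' @param cooccurrence Optional [estimate_cooccurrence()] matrix; when
#'   `NULL` the regularization step is skipped.
#' @param wc A [window_config()].
#' @param k,variance_floor Baseline mixture parameters ([fit_mixture()]).
#' @param low_bound,high_bound Ability band edges ([classify_ability()]).
#' @param max_angle_deg Pose gate limit ([gate_by_pose()]).
#' @param window_s,degrees Smoother parameters ([smooth_stream()]).
#' @param preprocess If `FALSE`, the stream is assumed already gated,
#'   smoothed and regularized.
#' @param seed Optional integer seed; the whole session is then
#'   reproducible bit for bit.
#' @return A tibble of class `"session_scores"`, one row per request:
#'   `request`, `time_s`, `expression`, `m_uf`, `m_lf`, `ability_uf`,
#'   `ability_lf`, `valid_fraction`, `status`.
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 40,
#'   requests = standard_requests(n_repetitions = 1), seed = 1))
#' score_session(sim$stream, sim$requests, seed = 1)
#' @export
score_session <- function(stream, requests, cooccurrence = NULL,
                          wc = window_config(), k = 3, variance_floor = 1e-4,
                          low_bound = 100, high_bound = 500,
                          max_angle_deg = 30, window_s = 0.5, degrees = 2:4,
                          preprocess = TRUE, seed = NULL) {
  fps <- au_fps(stream)
  if (is.null(fps) || is.na(fps) || fps <= 0) abort_config("stream fps must be positive")
  if (preprocess) {
    stream <- gate_by_pose(stream, max_angle_deg)
    stream <- smooth_stream(stream, window_s = window_s, degrees = degrees)
    if (!is.null(cooccurrence)) stream <- regularize(stream, cooccurrence)
  }
  wf <- window_frames(wc, fps)
  nreq <- nrow(requests)
  out <- tibble::tibble(
    request = seq_len(nreq),
    time_s = as.numeric(requests$time_s),
    expression = as.character(requests$expression),
    m_uf = NA_real_, m_lf = NA_real_,
    ability_uf = NA_character_, ability_lf = NA_character_,
    valid_fraction = NA_real_, status = NA_character_
  )
  if (nreq > 0) {
    in_range <- out$time_s >= stream$time_s[1] & out$time_s <= stream$time_s[nrow(stream)]
    if (any(!in_range)) {
      warn(sprintf("%d request(s) fall outside the stream's time range", sum(!in_range)))
    }
    with_seed(seed, {
      for (i in seq_len(nreq)) {
        if (!in_range[i]) {
          out$status[i] <- "outside stream"
          next
        }
        r <- findInterval(out$time_s[i], stream$time_s)
        sc <- score_request(stream, r, out$expression[i], wf, wc, k, variance_floor)
        out$m_uf[i] <- sc$m_uf
        out$m_lf[i] <- sc$m_lf
        out$valid_fraction[i] <- sc$valid_fraction
        out$status[i] <- sc$status
      }
    })
    out$ability_uf <- classify_ability(out$m_uf, low_bound, high_bound)
    out$ability_lf <- classify_ability(out$m_lf, low_bound, high_bound)
  }
  structure(out, class = c("session_scores", class(tibble::tibble())),
            low_bound = low_bound, high_bound = high_bound)
}

#' Per-expression session summary
#'
#' Means of the per-request production scores over the repetitions of each
#' expression, the session-level view used to compare face parts and
#' expressions across subjects. Means are taken only over requests whose
#' scores are defined.
#'
#' @param scores A [score_session()] result.
#' @return A tibble with one row per expression: `expression`, `n_requests`,
#'   `n_scored`, `mean_m_uf`, `mean_m_lf`.
#' @export
session_summary <- function(scores) {
  scores |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$expression) |>
    dplyr::summarise(
      n_requests = dplyr::n(),
      n_scored = sum(!is.na(.data$m_uf) & !is.na(.data$m_lf)),
      mean_m_uf = mean(.data$m_uf, na.rm = TRUE),
      mean_m_lf = mean(.data$m_lf, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$expression, EXPRESSION_CODES))
}

#' @method tidy session_scores
#' @export
tidy.session_scores <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("m_uf", "m_lf"),
      names_to = "part", names_prefix = "m_", values_to = "score"
    ) |>
    dplyr::mutate(
      ability = ifelse(.data$part == "uf", .data$ability_uf, .data$ability_lf)
    ) |>
    dplyr::select("request", "time_s", "expression", "part", "score",
                  "ability", "valid_fraction", "status")
}

#' @method glance session_scores
#' @export
glance.session_scores <- function(x, ...) {
  tibble::tibble(
    n_requests = nrow(x),
    n_scored = sum(x$status == "ok", na.rm = TRUE),
    mean_valid_fraction = mean(x$valid_fraction, na.rm = TRUE),
    mean_m_uf = mean(x$m_uf, na.rm = TRUE),
    mean_m_lf = mean(x$m_lf, na.rm = TRUE)
  )
}
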