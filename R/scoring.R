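## Production-score compositions per expression and face part, evaluated on
## a named vector of per-AU V values ("AU01".."AU26"). NA propagates: a
## score is undefined whenever any referenced V is undefined.
score_uf <- function(v, x) {
  switch(x,
    H = v[["AU06"]],
    S = max(v[["AU01"]], v[["AU04"]]),
    F = min(max(v[["AU01"]], v[["AU02"]]), v[["AU04"]], v[["AU05"]]),
    A = max(v[["AU04"]], v[["AU05"]], v[["AU07"]])
  )
}

score_lf <- function(v, x) {
  switch(x,
    H = v[["AU12"]],
    S = v[["AU15"]],
    F = max(v[["AU20"]], v[["AU26"]]),
    A = max(max(v[["AU09"]], v[["AU23"]]), min(v[["AU17"]], v[["AU25"]]))
  )
}

#' Per-expression production scores from per-AU variation values
#'
#' Composes the per-AU variation scores V at one evaluation point into a
#' production-ability measure for the upper face (uf: brows and lids) and
#' lower face (lf: cheeks, mouth, jaw) of each basic expression:
#'
#' * Happiness: `M_uf = V(AU6)`, `M_lf = V(AU12)`
#' * Sadness: `M_uf = max(V(AU1), V(AU4))`, `M_lf = V(AU15)`
#' * Fear: `M_uf = min(max(V(AU1), V(AU2)), V(AU4), V(AU5))`,
#'   `M_lf = max(V(AU20), V(AU26))`
#' * Anger: `M_uf = max(V(AU4), V(AU5), V(AU7))`,
#'   `M_lf = max(max(V(AU9), V(AU23)), min(V(AU17), V(AU25)))`
#'
#' `max` rewards any sufficient route to the expression; `min` encodes AU
#' combinations that must all move (e.g. fear requires raised plus lowered
#' brows together with a raised upper lid). Every composition is monotone:
#' increasing any V never decreases any score.
#'
#' @param v Per-AU V values: a named numeric vector (names `"AU01"`..
#'   `"AU26"`) or a long data frame with columns `au` and `v`. Missing or
#'   `NA` values yield `NA` scores for the expressions that reference them.
#' @return A tibble with columns `expression`, `part` (`"uf"`/`"lf"`) and
#'   `score`, 8 rows.
#' @examples
#' v <- setNames(rep(10, 14), au_columns())
#' expression_scores(v)
#' @export
expression_scores <- function(v) {
  if (is.data.frame(v)) {
    if (!all(c("au", "v") %in% names(v))) {
      abort_format("data-frame input needs columns 'au' and 'v'")
    }
    v <- stats::setNames(as.numeric(v$v), v$au)
  }
  full <- stats::setNames(rep(NA_real_, length(AU_COLS)), AU_COLS)
  full[intersect(names(v), AU_COLS)] <- v[intersect(names(v), AU_COLS)]
  tibble::tibble(
    expression = rep(EXPRESSION_CODES, each = 2),
    part = rep(c("uf", "lf"), times = 4),
    score = as.numeric(rbind(
      vapply(EXPRESSION_CODES, function(x) score_uf(full, x), numeric(1)),
      vapply(EXPRESSION_CODES, function(x) score_lf(full, x), numeric(1))
    ))
  )
}

#' Classify production ability from a score
#'
#' Calibrated score bands: below `low_bound` the face part produced no
#' detectable expression ("no" ability); between the bounds (inclusive) the
#' expression was subtle ("moderate"); strictly above `high_bound` it was
#' strong. The defaults 100 and 500 come from calibrating the score scale on
#' neutral versus expressive reference sequences.
#'
#' @param score Numeric scores (vectorized); `NA` yields `NA`.
#' @param low_bound,high_bound Band edges (defaults 100 and 500).
#' @return Character vector in `"no"`, `"moderate"`, `"strong"`.
#' @examples
#' classify_ability(c(66.1724, 100, 501))
#' @export
classify_ability <- function(score, low_bound = 100, high_bound = 500) {
  if (low_bound <= 0 || high_bound <= low_bound) {
    abort_config("bounds must satisfy 0 < low_bound < high_bound")
  }
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score < low_bound ~ "no",
    score <= high_bound ~ "moderate",
    TRUE ~ "strong"
  )
}

#' Detect which expression (if any) a score set shows
#'
#' Threshold-based detection over the eight production scores of one
#' evaluation (clip or request): an expression counts as present only when
#' *both* its upper- and lower-face scores exceed `high_bound`; if none is
#' present the result is `"N"` (neutral); if several are, the one with the
#' larger mean of its two scores prevails (ties broken in the fixed order
#' H, S, F, A).
#'
#' @param scores An 8-row tibble as returned by [expression_scores()], or a
#'   4-row wide data frame with columns `expression`, `m_uf`, `m_lf`.
#' @param high_bound Detection threshold (default 500).
#' @return One of `"N"`, `"H"`, `"S"`, `"F"`, `"A"`, or `NA` if any score is
#'   undefined.
#' @examples
#' v <- setNames(rep(10, 14), au_columns())
#' v[c("AU06", "AU12")] <- 1000
#' detect_expression(expression_scores(v))
#' @export
detect_expression <- function(scores, high_bound = 500) {
  if (all(c("expression", "part", "score") %in% names(scores))) {
    wide <- tidyr::pivot_wider(scores,
      id_cols = "expression", names_from = "part",
      values_from = "score", names_prefix = "m_"
    )
  } else if (all(c("expression", "m_uf", "m_lf") %in% names(scores))) {
    wide <- scores
  } else {
    abort_format("scores must be long (expression, part, score) or wide (expression, m_uf, m_lf)")
  }
  wide <- wide[match(EXPRESSION_CODES, wide$expression), ]
  if (anyNA(wide$m_uf) || anyNA(wide$m_lf)) return(NA_character_)
  present <- wide$m_uf > high_bound & wide$m_lf > high_bound
  if (!any(present)) return("N")
  means <- (wide$m_uf + wide$m_lf) / 2
  means[!present] <- -Inf
  EXPRESSION_CODES[which.max(means)]
}
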