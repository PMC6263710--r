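#' Standard session request schedule
#'
#' The assessment protocol asks for the four basic expressions in the fixed
#' order happiness-sadness-fear-anger, repeated `n_repetitions` times
#' (5 by default, i.e., 20 requests), with requests at least 4 s apart.
#' The default spacing of 7 s with a 10 s lead-in yields a session of about
#' two and a half minutes, in the range of real recordings.
#'
#' @param n_repetitions Repetitions of the H,S,F,A block (default 5).
#' @param start_s Time of the first request, seconds (default 10).
#' @param spacing_s Spacing between consecutive requests, seconds (default 7).
#' @return A `request_list` tibble (`time_s`, `expression`).
#' @examples
#' standard_requests()
#' @export
standard_requests <- function(n_repetitions = 5, start_s = 10, spacing_s = 7) {
  n <- 4 * n_repetitions
  as_request_list(tibble::tibble(
    time_s = start_s + spacing_s * (seq_len(n) - 1),
    expression = rep(EXPRESSION_CODES, n_repetitions)
  ))
}

#' Simulation configuration
#'
#' Parameters of the synthetic AU-stream generator (see
#' [simulate_session()]). Defaults emulate the statistical structure the
#' assessment method assumes: slowly drifting per-AU resting levels,
#' frame-level estimation noise, short unsolicited stereotyped bursts, and
#' request-locked trapezoidal (onset-apex-offset) expression events on the
#' AU sets of [expression_aus()].
#'
#' @param duration_s Stream length, seconds (default 160, enough for the
#'   [standard_requests()] schedule).
#' @param fps Frame rate (default 25, the usual off-the-shelf camera rate).
#' @param baseline_mean Named per-AU resting intensities on the 0-5 scale;
#'   default spreads the 14 AUs over 0.2-0.8.
#' @param drift_amplitude,drift_period_s Slow sinusoidal baseline drift
#'   (default 0.1 intensity units over ~60 s), emulating changing
#'   engagement or fatigue.
#' @param noise_sd Frame-level Gaussian noise, intensity units (default 0.1).
#' @param requests A request schedule ([standard_requests()] by default) or
#'   `NULL` for a request-free stream.
#' @param compliance Probability that a request is answered with an injected
#'   expression event (default 1).
#' @param response_delay_s Delay from request to event onset (default 0.5).
#' @param event_amplitude Apex amplitude of injected events (default 2).
#' @param onset_s,apex_s,offset_s Trapezoid phase durations (defaults
#'   0.5 / 1 / 0.5 s).
#' @param events Optional explicit event table (`time_s`, `expression`,
#'   and optionally `amplitude`, `onset_s`, `apex_s`, `offset_s`); when
#'   given, request-locked event generation is skipped.
#' @param stereotypy_rate_per_min Rate of unsolicited bursts (default 2).
#' @param stereotypy_aus AU columns affected by stereotypies (default
#'   `"AU05"`, mimicking a continuously re-activated upper lid).
#' @param stereotypy_amplitude Burst amplitude (default 1.5).
#' @param stereotypy_duration_s Burst duration range, seconds (default
#'   0.2-1).
#' @param pose_excursions Optional table of head-pose excursions (`time_s`,
#'   `duration_s`, `axis` in `"pitch"`/`"yaw"`/`"roll"`, `angle_deg`)
#'   inserted into the pose channels, e.g. beyond the 30 degree gate limit.
#' @param seed Integer seed; the simulation is fully deterministic given
#'   the seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(duration_s = 160,
                       fps = 25,
                       baseline_mean = NULL,
                       drift_amplitude = 0.1,
                       drift_period_s = 60,
                       noise_sd = 0.1,
                       requests = standard_requests(),
                       compliance = 1,
                       response_delay_s = 0.5,
                       event_amplitude = 2,
                       onset_s = 0.5, apex_s = 1, offset_s = 0.5,
                       events = NULL,
                       stereotypy_rate_per_min = 2,
                       stereotypy_aus = "AU05",
                       stereotypy_amplitude = 1.5,
                       stereotypy_duration_s = c(0.2, 1),
                       pose_excursions = NULL,
                       seed = 1) {
  if (duration_s <= 0 || fps <= 0) abort_config("duration_s and fps must be positive")
  if (noise_sd < 0 || event_amplitude < 0 || stereotypy_amplitude < 0) {
    abort_config("noise and amplitudes must be non-negative")
  }
  if (any(c(onset_s, apex_s, offset_s) <= 0)) {
    abort_config("onset, apex and offset durations must be positive")
  }
  if (compliance < 0 || compliance > 1) abort_config("compliance must lie in [0, 1]")
  if (is.null(baseline_mean)) {
    baseline_mean <- stats::setNames(
      seq(0.2, 0.8, length.out = length(AU_COLS)), AU_COLS
    )
  }
  if (!all(AU_COLS %in% names(baseline_mean))) {
    abort_config("baseline_mean must name all 14 canonical AU columns")
  }
  structure(
    list(
      duration_s = duration_s, fps = fps,
      baseline_mean = baseline_mean[AU_COLS],
      drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
      noise_sd = noise_sd,
      requests = requests, compliance = compliance,
      response_delay_s = response_delay_s,
      event_amplitude = event_amplitude,
      onset_s = onset_s, apex_s = apex_s, offset_s = offset_s,
      events = events,
      stereotypy_rate_per_min = stereotypy_rate_per_min,
      stereotypy_aus = stereotypy_aus,
      stereotypy_amplitude = stereotypy_amplitude,
      stereotypy_duration_s = stereotypy_duration_s,
      pose_excursions = pose_excursions,
      seed = seed
    ),
    class = "sim_config"
  )
}

trapezoid <- function(t, t0, onset, apex, offset, amplitude) {
  ## piecewise-linear onset-apex-offset profile starting at t0
  u <- t - t0
  amplitude * pmax(0, pmin(1, pmin(u / onset, (onset + apex + offset - u) / offset)))
}

#' Simulate a session with ground truth
#'
#' Generates a synthetic AU stream with the structure the assessment method
#' assumes: per-AU baselines with slow drift and Gaussian noise, short
#' unsolicited stereotyped bursts, trapezoidal request-locked expression
#' events added to each expression's AU set, and optional head-pose
#' excursions. Intensities are clipped to the 0-5 scale. The returned
#' ground truth records every event's frames and affected AUs, so each
#' pipeline stage can be validated without any recorded dataset.
#'
#' Two events touching the same AU may not overlap (that would make the
#' ground truth ambiguous); such configurations raise an error.
#' Stereotypies, being unsolicited background activity that the baseline
#' model is supposed to absorb, are reported separately and may overlap
#' events.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `"simulated_session"`:
#'   * `stream` -- the [as_au_stream()] tibble,
#'   * `requests` -- the request schedule (possibly `NULL`),
#'   * `events` -- ground-truth event table (`event`, `request`, `time_s`,
#'     `expression`, `amplitude`, `t_start_s`, `t_end_s`, `frame_start`,
#'     `frame_end`, `aus` semicolon-separated),
#'   * `stereotypies` -- burst table (`time_s`, `duration_s`, `amplitude`,
#'     `aus`).
#' @examples
#' sim <- simulate_session(sim_config(duration_s = 30,
#'   requests = standard_requests(n_repetitions = 1), seed = 7))
#' sim$events
#' @export
simulate_session <- function(config, seed = NULL) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) abort_config("config must be a sim_config()")
  seed <- if (is.null(seed)) cfg$seed else seed
  with_seed(seed, {
    nT <- as.integer(round(cfg$duration_s * cfg$fps))
    time_s <- (seq_len(nT) - 1) / cfg$fps
    naus <- length(AU_COLS)

    ## baseline: resting level + slow sinusoidal drift + white noise
    phase <- runif(naus, 0, 2 * pi)
    ints <- matrix(0, nT, naus, dimnames = list(NULL, AU_COLS))
    for (j in seq_len(naus)) {
      ints[, j] <- cfg$baseline_mean[j] +
        cfg$drift_amplitude * sin(2 * pi * time_s / cfg$drift_period_s + phase[j]) +
        if (cfg$noise_sd > 0) rnorm(nT, 0, cfg$noise_sd) else 0
    }

    ## request-locked (or explicit) expression events
    events <- build_events(cfg)
    if (nrow(events) > 0) {
      check_event_overlap(events)
      for (i in seq_len(nrow(events))) {
        cols <- strsplit(events$aus[i], ";")[[1]]
        prof <- trapezoid(time_s, events$t_start_s[i], events$onset_s[i],
                          events$apex_s[i], events$offset_s[i], events$amplitude[i])
        ints[, cols] <- ints[, cols] + prof
      }
      events$frame_start <- findInterval(events$t_start_s, time_s)
      events$frame_end <- pmin(nT, findInterval(events$t_end_s, time_s) + 1L)
    }

    ## stereotyped unsolicited bursts: half-sine pulses on a fixed AU subset
    n_st <- if (cfg$stereotypy_rate_per_min > 0) {
      rpois(1, cfg$stereotypy_rate_per_min * cfg$duration_s / 60)
    } else 0L
    stereotypies <- tibble::tibble(
      time_s = numeric(0), duration_s = numeric(0),
      amplitude = numeric(0), aus = character(0)
    )
    if (n_st > 0) {
      st_t <- sort(runif(n_st, 0, cfg$duration_s))
      st_d <- runif(n_st, cfg$stereotypy_duration_s[1], cfg$stereotypy_duration_s[2])
      for (i in seq_len(n_st)) {
        inside <- time_s >= st_t[i] & time_s <= st_t[i] + st_d[i]
        pulse <- cfg$stereotypy_amplitude *
          sin(pi * (time_s[inside] - st_t[i]) / st_d[i])
        ints[inside, cfg$stereotypy_aus] <-
          ints[inside, cfg$stereotypy_aus] + pulse
      }
      stereotypies <- tibble::tibble(
        time_s = st_t, duration_s = st_d,
        amplitude = cfg$stereotypy_amplitude,
        aus = paste(cfg$stereotypy_aus, collapse = ";")
      )
    }

    ints[ints < 0] <- 0
    ints[ints > 5] <- 5

    pose <- matrix(0, nT, 3, dimnames = list(NULL, c("pitch", "yaw", "roll")))
    if (!is.null(cfg$pose_excursions) && nrow(cfg$pose_excursions) > 0) {
      pe <- cfg$pose_excursions
      for (i in seq_len(nrow(pe))) {
        inside <- time_s >= pe$time_s[i] & time_s <= pe$time_s[i] + pe$duration_s[i]
        pose[inside, pe$axis[i]] <- pose[inside, pe$axis[i]] + pe$angle_deg[i]
      }
    }

    stream <- as_au_stream(dplyr::bind_cols(
      tibble::tibble(
        frame = seq_len(nT) - 1L, time_s = time_s,
        pitch = pose[, 1], yaw = pose[, 2], roll = pose[, 3],
        valid = TRUE
      ),
      tibble::as_tibble(ints)
    ), fps = cfg$fps)

    structure(
      list(stream = stream, requests = cfg$requests,
           events = events, stereotypies = stereotypies),
      class = "simulated_session"
    )
  })
}

build_events <- function(cfg) {
  empty <- tibble::tibble(
    event = integer(0), request = integer(0), time_s = numeric(0),
    expression = character(0), amplitude = numeric(0),
    onset_s = numeric(0), apex_s = numeric(0), offset_s = numeric(0),
    t_start_s = numeric(0), t_end_s = numeric(0),
    frame_start = integer(0), frame_end = integer(0), aus = character(0)
  )
  if (!is.null(cfg$events)) {
    ev <- tibble::as_tibble(cfg$events)
    bad <- setdiff(unique(ev$expression), EXPRESSION_CODES)
    if (length(bad) > 0) abort_config(paste0("unknown event expression: ", bad[1]))
    ev$event <- seq_len(nrow(ev))
    ev$request <- if ("request" %in% names(ev)) ev$request else NA_integer_
    for (fld in c("amplitude", "onset_s", "apex_s", "offset_s")) {
      if (!fld %in% names(ev)) {
        ev[[fld]] <- cfg[[sub("amplitude", "event_amplitude", fld)]]
      }
    }
    ev$t_start_s <- ev$time_s
  } else if (!is.null(cfg$requests) && nrow(cfg$requests) > 0) {
    comply <- rbinom(nrow(cfg$requests), 1, cfg$compliance) == 1
    if (!any(comply)) return(empty)
    ev <- tibble::tibble(
      event = seq_len(sum(comply)),
      request = which(comply),
      time_s = cfg$requests$time_s[comply],
      expression = cfg$requests$expression[comply],
      amplitude = cfg$event_amplitude,
      onset_s = cfg$onset_s, apex_s = cfg$apex_s, offset_s = cfg$offset_s
    )
    ev$t_start_s <- ev$time_s + cfg$response_delay_s
  } else {
    return(empty)
  }
  ev$t_end_s <- ev$t_start_s + ev$onset_s + ev$apex_s + ev$offset_s
  ev$frame_start <- NA_integer_
  ev$frame_end <- NA_integer_
  ev$aus <- vapply(ev$expression, function(x) {
    paste(sprintf("AU%02d", EXPRESSION_AUS[[x]]), collapse = ";")
  }, character(1))
  ev[c("event", "request", "time_s", "expression", "amplitude",
       "onset_s", "apex_s", "offset_s", "t_start_s", "t_end_s",
       "frame_start", "frame_end", "aus")]
}

check_event_overlap <- function(events) {
  n <- nrow(events)
  if (n < 2) return(invisible())
  au_sets <- strsplit(events$aus, ";")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(au_sets[[i]], au_sets[[j]])) > 0
      overlap <- events$t_start_s[i] < events$t_end_s[j] &&
        events$t_start_s[j] < events$t_end_s[i]
      if (shared && overlap) {
        abort_config(sprintf(
          "events %d and %d overlap on shared AU(s); ground truth would be ambiguous",
          events$event[i], events$event[j]
        ))
      }
    }
  }
  invisible()
}

#' Write a simulated session to disk
#'
#' Writes the AU stream (in the default [au_dialect()] CSV form, radian
#' poses), the request list, and the ground-truth event table into a
#' directory, so simulated material can be fed back through
#' [read_au_stream()] / [read_requests()] or external tools.
#'
#' @param sim A [simulate_session()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly. Files: `au_stream.csv`,
#'   `requests.csv` (when the session has requests), `events.csv`,
#'   `stereotypies.csv`.
#' @export
write_session <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- sim$stream
  d <- au_dialect()
  out <- tibble::tibble(
    frame = s$frame, timestamp = s$time_s,
    success = as.integer(s$valid)
  )
  out[d$pose] <- list(s$pitch * pi / 180, s$yaw * pi / 180, s$roll * pi / 180)
  out[unname(d$au)] <- as.data.frame(au_intensities(s))
  readr::write_csv(out, file.path(dir, "au_stream.csv"))
  if (!is.null(sim$requests)) {
    readr::write_csv(tibble::as_tibble(sim$requests), file.path(dir, "requests.csv"))
  }
  readr::write_csv(sim$events, file.path(dir, "events.csv"))
  readr::write_csv(sim$stereotypies, file.path(dir, "stereotypies.csv"))
  invisible(dir)
}
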