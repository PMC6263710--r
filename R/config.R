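#' Pipeline configuration
#'
#' Collects every tunable of the assessment pipeline in one list, with the
#' session-protocol defaults: a 30 degree pose gate, a 0.5 s smoother window
#' with candidate degrees 2-4, a 3-component baseline mixture with a 1e-4
#' variance floor, 2 s / 4 s modeling and observation windows, and the
#' 100 / 500 ability bounds. `read_pipeline_config()` loads the same
#' settings from a YAML file with nested keys `pose.max_angle_deg`,
#' `smooth.window_s`, `smooth.degrees`, `model.k`, `model.variance_floor`,
#' `windows.delta_m`, `windows.delta_o`, `windows.refit_stride`,
#' `windows.min_valid_fraction`, `scoring.low_bound`, `scoring.high_bound`
#' and `seed`; unset keys keep their defaults.
#'
#' @param max_angle_deg,window_s,degrees,k,variance_floor Pipeline tunables
#'   (see [gate_by_pose()], [smooth_stream()], [fit_mixture()]).
#' @param delta_m,delta_o,refit_stride,min_valid_fraction Window settings
#'   (see [window_config()]).
#' @param low_bound,high_bound Ability bounds (see [classify_ability()]).
#' @param seed Optional integer seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(max_angle_deg = 30, window_s = 0.5, degrees = 2:4,
                            k = 3, variance_floor = 1e-4,
                            delta_m = 2, delta_o = 4, refit_stride = 1,
                            min_valid_fraction = 0.5,
                            low_bound = 100, high_bound = 500, seed = NULL) {
  structure(
    list(
      max_angle_deg = max_angle_deg, window_s = window_s, degrees = degrees,
      k = k, variance_floor = variance_floor,
      wc = window_config(delta_m, delta_o, refit_stride, min_valid_fraction),
      low_bound = low_bound, high_bound = high_bound, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' @param path Path to a YAML configuration file.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(section, key, default) {
    v <- y[[section]][[key]]
    if (is.null(v)) default else v
  }
  pipeline_config(
    max_angle_deg = pick("pose", "max_angle_deg", 30),
    window_s = pick("smooth", "window_s", 0.5),
    degrees = unlist(pick("smooth", "degrees", 2:4)),
    k = pick("model", "k", 3),
    variance_floor = pick("model", "variance_floor", 1e-4),
    delta_m = pick("windows", "delta_m", 2),
    delta_o = pick("windows", "delta_o", 4),
    refit_stride = pick("windows", "refit_stride", 1),
    min_valid_fraction = pick("windows", "min_valid_fraction", 0.5),
    low_bound = pick("scoring", "low_bound", 100),
    high_bound = pick("scoring", "high_bound", 500),
    seed = y$seed
  )
}
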