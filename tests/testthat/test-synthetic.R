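test_that("a noiseless, event-free simulation is a constant-baseline stream", {
  cfg <- sim_config(duration_s = 10, requests = NULL, noise_sd = 0,
                    drift_amplitude = 0, stereotypy_rate_per_min = 0, seed = 1)
  sim <- simulate_session(cfg)
  m <- facexpr:::au_intensities(sim$stream)
  expect_equal(nrow(sim$events), 0)
  for (j in 1:14) expect_lt(diff(range(m[, j])), 1e-12)
  expect_equal(unname(m[1, ]), unname(cfg$baseline_mean), ignore_attr = TRUE)
})

test_that("a happiness event touches exactly AU6 and AU12 at the apex", {
  cfg <- sim_config(duration_s = 20, requests = NULL, noise_sd = 0,
                    drift_amplitude = 0, stereotypy_rate_per_min = 0,
                    events = data.frame(time_s = 10, expression = "H",
                                        amplitude = 2),
                    seed = 2)
  sim <- simulate_session(cfg)
  m <- facexpr:::au_intensities(sim$stream)
  apex <- sim$stream$time_s > 10.6 & sim$stream$time_s < 11.4
  base <- matrix(cfg$baseline_mean, sum(apex), 14, byrow = TRUE)
  over <- m[apex, ] > base + 1
  touched <- colnames(m)[colSums(over) > 0]
  expect_setequal(touched, c("AU06", "AU12"))
  expect_true(all(over[, c("AU06", "AU12")]))
})

test_that("event support in the stream matches the ground-truth table", {
  cfg <- sim_config(duration_s = 120, noise_sd = 0, drift_amplitude = 0,
                    stereotypy_rate_per_min = 0,
                    requests = standard_requests(n_repetitions = 3), seed = 3)
  sim <- simulate_session(cfg)
  m <- facexpr:::au_intensities(sim$stream)
  base <- matrix(cfg$baseline_mean, nrow(m), 14, byrow = TRUE)
  raised <- abs(m - base) > 1e-12
  expect_equal(nrow(sim$events), 12)
  for (j in seq_along(au_columns())) {
    col <- au_columns()[j]
    ev <- sim$events[grepl(col, sim$events$aus), ]
    in_support <- rep(FALSE, nrow(m))
    for (i in seq_len(nrow(ev))) {
      in_support <- in_support |
        (sim$stream$time_s > ev$t_start_s[i] & sim$stream$time_s < ev$t_end_s[i])
    }
    expect_true(all(which(raised[, j]) %in% which(in_support)),
                info = paste("AU support exceeds ground truth for", col))
  }
})

test_that("simulations are bit-identical under the same seed and bounded in [0,5]", {
  cfg <- sim_config(duration_s = 30, event_amplitude = 4, noise_sd = 0.3,
                    requests = standard_requests(n_repetitions = 1,
                                                 start_s = 5, spacing_s = 6),
                    seed = 17)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(as.data.frame(a$stream), as.data.frame(b$stream))
  expect_identical(a$events, b$events)
  m <- facexpr:::au_intensities(a$stream)
  expect_true(all(m >= 0 & m <= 5))
})

test_that("overlapping events on a shared AU are rejected", {
  cfg <- sim_config(duration_s = 20, requests = NULL,
                    events = data.frame(time_s = c(5, 5.5),
                                        expression = c("H", "H")),
                    seed = 1)
  expect_error(simulate_session(cfg), class = "facexpr_config_error")
  # fear and anger share AU4/AU5: also an overlap
  cfg$events <- data.frame(time_s = c(5, 5.5), expression = c("F", "A"))
  expect_error(simulate_session(cfg), class = "facexpr_config_error")
  # happiness and sadness share no AU: allowed
  cfg$events <- data.frame(time_s = c(5, 5.5), expression = c("H", "S"))
  expect_silent(simulate_session(cfg))
})

test_that("stereotypy bursts hit only the configured AU set", {
  cfg <- sim_config(duration_s = 60, requests = NULL, noise_sd = 0,
                    drift_amplitude = 0, stereotypy_rate_per_min = 6,
                    stereotypy_aus = "AU05", seed = 23)
  sim <- simulate_session(cfg)
  expect_gt(nrow(sim$stereotypies), 0)
  m <- facexpr:::au_intensities(sim$stream)
  base <- matrix(cfg$baseline_mean, nrow(m), 14, byrow = TRUE)
  changed <- colSums(abs(m - base) > 1e-9) > 0
  expect_identical(names(changed)[changed], "AU05")
})

test_that("pose excursions land in the pose channels and trip the gate", {
  cfg <- sim_config(duration_s = 10, requests = NULL, noise_sd = 0,
                    pose_excursions = data.frame(time_s = 4, duration_s = 2,
                                                 axis = "yaw", angle_deg = 45),
                    seed = 5)
  sim <- simulate_session(cfg)
  g <- gate_by_pose(sim$stream, 30)
  inside <- sim$stream$time_s >= 4 & sim$stream$time_s <= 6
  expect_true(all(!g$valid[inside]))
  expect_true(all(g$valid[!inside]))
})

test_that("simulated sessions survive the disk round trip", {
  dir <- withr::local_tempdir()
  sim <- simulate_session(sim_config(duration_s = 8,
    requests = standard_requests(n_repetitions = 1, start_s = 1, spacing_s = 4),
    seed = 31))
  suppressWarnings(write_session(sim, dir))
  s2 <- read_au_stream(file.path(dir, "au_stream.csv"))
  expect_equal(facexpr:::au_intensities(s2),
               facexpr:::au_intensities(sim$stream), tolerance = 1e-9)
  expect_equal(s2$pitch, sim$stream$pitch, tolerance = 1e-6)
  req <- suppressWarnings(read_requests(file.path(dir, "requests.csv")))
  expect_equal(req$time_s, sim$requests$time_s)
})
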