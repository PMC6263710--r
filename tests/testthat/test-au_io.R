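test_that("tracker CSV is read with success flags mapped to the valid mask", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_dialect_csv(path, n = 3, success = c(1, 1, 0))
  s <- read_au_stream(path)
  expect_s3_class(s, "au_stream")
  expect_identical(s$valid, c(TRUE, TRUE, FALSE))
  expect_identical(names(s)[7:20], au_columns())
})

test_that("radian poses are converted to degrees", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_dialect_csv(path, n = 2, pose_rad = 0.5236)
  s <- read_au_stream(path)
  expect_equal(s$pitch[1], 30.0, tolerance = 1e-3)
  expect_equal(s$yaw[1], 30.0, tolerance = 1e-3)
})

test_that("a missing AU column is a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_dialect_csv(path, drop_au = "AU26")
  expect_error(read_au_stream(path), "AU26", class = "facexpr_format_error")
})

test_that("canonical AU ordering is independent of input column order", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  au_vals <- seq(0.1, 1.4, by = 0.1)
  d <- au_dialect()
  df <- data.frame(frame = 0:1, timestamp = c(0, 0.04), success = 1)
  df[d$pose] <- 0
  for (i in seq_along(d$au)) df[[unname(d$au)[i]]] <- au_vals[i]
  utils::write.csv(df, p1, row.names = FALSE)
  set.seed(42)
  utils::write.csv(df[, sample(ncol(df))], p2, row.names = FALSE)
  expect_equal(
    as.data.frame(read_au_stream(p1)),
    as.data.frame(read_au_stream(p2))
  )
})

test_that("non-monotone timestamps are a data error", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- au_dialect()
  df <- data.frame(frame = 0:2, timestamp = c(0, 0.08, 0.04), success = 1)
  df[d$pose] <- 0
  for (col in unname(d$au)) df[[col]] <- 0.5
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_au_stream(path), class = "facexpr_data_error")
})

test_that("request lists parse, warn on tight spacing and reject bad codes", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = c(10, 15), expression = c("H", "S")),
                   path, row.names = FALSE)
  req <- read_requests(path)
  expect_equal(nrow(req), 2)
  expect_identical(req$expression, c("H", "S"))

  utils::write.csv(data.frame(time_s = c(10, 12), expression = c("H", "S")),
                   path, row.names = FALSE)
  expect_warning(read_requests(path, min_spacing_s = 4), "closer than")

  utils::write.csv(data.frame(time_s = 10, expression = "X"),
                   path, row.names = FALSE)
  expect_error(read_requests(path), "X", class = "facexpr_format_error")
})

test_that("session reports round-trip through CSV and JSON to 1e-9", {
  sim <- simulate_session(sim_config(duration_s = 160, seed = 3))
  scores <- score_session(sim$stream, sim$requests, seed = 3)
  expect_equal(nrow(scores), 20)

  long <- tidy(scores)
  expect_equal(nrow(long), 40) # one row per request and face part

  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_report(scores, path)
    back <- read_report(path)
    expect_equal(nrow(back), 40)
    expect_identical(back$expression, long$expression)
    expect_equal(back$score, long$score, tolerance = 1e-9)
    expect_equal(back$time_s, long$time_s, tolerance = 1e-9)
    expect_equal(back$valid_fraction, long$valid_fraction, tolerance = 1e-9)
  }
})

test_that("a fully gated response window yields a flagged null score row", {
  s <- make_stream(20 * 25, intensities = 0.5)
  # gate out every frame after the first request instant
  s$valid[s$time_s >= 10] <- FALSE
  req <- as_request_list(data.frame(time_s = 10, expression = "H"))
  scores <- score_session(s, req, seed = 1)
  expect_true(is.na(scores$m_uf[1]))
  expect_identical(scores$status[1], "insufficient valid frames")

  path <- withr::local_tempfile(fileext = ".json")
  write_report(scores, path)
  back <- read_report(path)
  expect_true(all(is.na(back$score)))
  expect_true(all(back$status == "insufficient valid frames"))
})

test_that("a YAML column map overrides the default dialect", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "time: t_sec",
    "pose_unit: degrees",
    "au:",
    "  AU01: blink_a"
  ), yml)
  d <- au_dialect(yaml = yml)
  expect_identical(d$time, "t_sec")
  expect_identical(d$pose_unit, "degrees")
  expect_identical(unname(d$au["AU01"]), "blink_a")
  expect_identical(unname(d$au["AU02"]), "AU02_r")
})

test_that("an unwritable report path raises an I/O error", {
  sim <- simulate_session(sim_config(duration_s = 20,
    requests = standard_requests(n_repetitions = 1, start_s = 3, spacing_s = 4),
    seed = 2))
  scores <- suppressWarnings(score_session(sim$stream, sim$requests, seed = 2))
  expect_error(write_report(scores, "/nonexistent-dir/report.csv"),
               class = "facexpr_io_error")
})
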