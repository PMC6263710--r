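test_that("co-occurrence estimation matches brute-force joint counts", {
  # 4 toy samples: AU1 and AU2 jointly active in rows 1 and 2 only
  occ <- matrix(0, 4, 14, dimnames = list(NULL, au_columns()))
  occ[1, c("AU01", "AU02")] <- 1
  occ[2, c("AU01", "AU02")] <- 1
  occ[3, "AU01"] <- 1
  occ[4, "AU04"] <- 1
  p <- estimate_cooccurrence(occ)
  expect_equal(p["AU01", "AU02"], 0.5)
  expect_equal(p["AU01", "AU04"], 0)

  both <- matrix(0, 5, 14, dimnames = list(NULL, au_columns()))
  both[, c("AU01", "AU02")] <- 1
  expect_equal(estimate_cooccurrence(both)["AU01", "AU02"], 1)

  never <- matrix(0, 5, 14, dimnames = list(NULL, au_columns()))
  never[1:3, "AU01"] <- 1
  never[4:5, "AU02"] <- 1
  expect_equal(estimate_cooccurrence(never)["AU01", "AU02"], 0)
})

test_that("co-occurrence matrices are symmetric with zero diagonal in [0,1]", {
  set.seed(21)
  occ <- matrix(rbinom(14 * 200, 1, 0.4), 200, 14,
                dimnames = list(NULL, au_columns()))
  p <- estimate_cooccurrence(occ)
  expect_equal(unclass(p), t(unclass(p)))
  expect_true(all(diag(p) == 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("empty or non-binary occurrence tables are rejected", {
  empty <- matrix(numeric(0), 0, 14, dimnames = list(NULL, au_columns()))
  expect_error(estimate_cooccurrence(empty), class = "facexpr_data_error")
  bad <- matrix(0.5, 3, 14, dimnames = list(NULL, au_columns()))
  expect_error(estimate_cooccurrence(bad), class = "facexpr_data_error")
})

test_that("regularization is the identity on degenerate inputs", {
  # all AUs equal at a frame: differences vanish
  s <- make_stream(5, intensities = 1.7)
  set.seed(3)
  p <- random_symmetric_p()
  out <- regularize(s, p)
  expect_equal(as.data.frame(out[au_columns()]),
               as.data.frame(s[au_columns()]), tolerance = 1e-12)

  # null weights: no adjustment
  s2 <- make_stream(5, intensities = seq(0.1, 1.4, by = 0.1))
  p0 <- facexpr:::new_cooccurrence(
    matrix(0, 14, 14, dimnames = list(au_columns(), au_columns()))
  )
  expect_equal(as.data.frame(regularize(s2, p0)[au_columns()]),
               as.data.frame(s2[au_columns()]))
})

test_that("the regularization rule matches its hand-evaluated reduced form", {
  # 2-AU instance: AU = (2, 1), p12 = 0.5, n = 2
  # R1 = 0.5 * (2 - 1) / 2 = +0.25, R2 = -0.25
  A <- matrix(c(2, 1), 1, 2)
  p <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  R <- facexpr:::regularization_field(A, p)
  expect_equal(as.numeric(A + R), c(2.25, 0.75))
})

test_that("vectorized regularization matches a naive double loop to 1e-12", {
  naive_field <- function(A, p) {
    n <- ncol(p)
    R <- matrix(0, nrow(A), n)
    for (t in seq_len(nrow(A))) {
      for (i in seq_len(n)) {
        acc <- 0
        for (j in seq_len(n)) {
          if (j != i) acc <- acc + p[i, j] * (A[t, i] - A[t, j])
        }
        R[t, i] <- acc / n
      }
    }
    R
  }
  set.seed(8)
  for (rep in 1:3) {
    A <- matrix(runif(40 * 14, 0, 5), 40, 14)
    p <- unclass(random_symmetric_p())
    expect_equal(facexpr:::regularization_field(A, p), naive_field(A, p),
                 tolerance = 1e-12)
  }
})

test_that("symmetric weights conserve total intensity before clipping", {
  set.seed(13)
  A <- matrix(runif(100 * 14, 0, 5), 100, 14)
  p <- unclass(random_symmetric_p())
  R <- facexpr:::regularization_field(A, p)
  expect_true(all(abs(rowSums(R)) < 1e-9))
})

test_that("invalid frames pass through regularization unchanged", {
  set.seed(17)
  m <- matrix(runif(10 * 14, 0, 5), 10, 14)
  s <- make_stream(10, intensities = m, valid = rep(c(TRUE, FALSE), 5))
  p <- random_symmetric_p()
  out <- regularize(s, p)
  bad <- !s$valid
  expect_equal(as.matrix(out[bad, au_columns()]), m[bad, ],
               ignore_attr = TRUE)
})

test_that("malformed co-occurrence matrices are config errors", {
  s <- make_stream(3)
  expect_error(regularize(s, matrix(0, 5, 5)), class = "facexpr_config_error")
  asym <- unclass(random_symmetric_p())
  asym[1, 2] <- asym[1, 2] + 0.2
  expect_error(regularize(s, facexpr:::new_cooccurrence(asym)),
               class = "facexpr_config_error")
})

test_that("co-occurrence CSV round-trips", {
  set.seed(31)
  p <- estimate_cooccurrence(
    matrix(rbinom(14 * 50, 1, 0.3), 50, 14, dimnames = list(NULL, au_columns()))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cooccurrence(p, path)
  expect_equal(unclass(read_cooccurrence(path)), unclass(p), tolerance = 1e-9)
})
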