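test_that("MI hits its closed-form anchors", {
  expect_equal(mutual_information(rep(0:7, 125), rep(0:7, 125)), log(8))
  expect_equal(mutual_information(rep(3.3, 100), rnorm(100)), 0)  # constant x
  expect_error(mutual_information(c(1, NA, 3, 4, 5, 6, 7, 8), 1:8), "finite")
  expect_error(mutual_information(1:10, 1:9), "equal length")
})

test_that("MI matches the naive double-loop oracle to 1e-12", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(200); y <- 0.5 * x + rnorm(200)
    expect_equal(mutual_information(x, y), naive_mi(x, y), tolerance = 1e-12)
  }
})

test_that("MI is symmetric, non-negative, bounded by ln(8), shift-invariant", {
  set.seed(22)
  for (i in 1:25) {
    x <- rnorm(300); y <- rnorm(300) + (i %% 3) * x
    m <- mutual_information(x, y)
    expect_gte(m, 0)
    expect_lte(m, log(8) + 1e-12)
    expect_equal(m, mutual_information(y, x), tolerance = 1e-14)
    expect_equal(m, mutual_information(x + 17.3, y - 4.2), tolerance = 1e-12)
  }
})

test_that("Gaussian MI tracks the analytic value up to quantization loss", {
  set.seed(23)
  gauss_mean <- function(rho, reps = 25) {
    mean(replicate(reps, {
      x <- rnorm(1000)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(1000)
      mutual_information(x, y)
    }))
  }
  # weak dependence: only the small plug-in bias separates estimate and truth
  expect_equal(gauss_mean(0), 0, tolerance = 0.04)
  expect_equal(gauss_mean(0.5), -0.5 * log(1 - 0.25), tolerance = 0.05)
  # strong dependence: 8-level equal-width quantization loses information,
  # so the estimate sits below the continuous-variable MI, but not by more
  # than the quantization loss (~0.17 nats at rho = 0.9)
  m9 <- gauss_mean(0.9)
  analytic <- -0.5 * log(1 - 0.81)
  expect_lt(m9, analytic)
  expect_gt(m9, analytic - 0.25)
})

test_that("sliding_mi equals the naive loop reimplementation everywhere", {
  rec <- toy_recording(n_m1 = 2, n_dlpfc = 1, dur = 3, fs = 100, seed = 31)
  s <- sliding_mi(rec, network_definition(rec, "DLPFC_M1"),
                  mi_config(window_s = 1, step_s = 0.25))
  idx <- cbind(match(s$pairs[, 1], rec$channel_ids),
               match(s$pairs[, 2], rec$channel_ids))
  ref <- naive_sliding_mi(rec$samples, idx, 100, 1, 0.25)
  expect_equal(unname(s$mi), ref, tolerance = 1e-12)
  expect_equal(s$window_centers, 0.5 + 0.25 * (0:8))
})

test_that("window arithmetic matches the closed form", {
  expect_identical(n_sliding_windows(300, 1, 0.1, 1000), 2991L)
  expect_identical(n_sliding_windows(5, 1, 0.1, 1000), 41L)
  rec <- toy_recording(n_m1 = 2, n_dlpfc = 1, dur = 5, fs = 200, seed = 32)
  s <- sliding_mi(rec, network_definition(rec, "M1"))
  expect_equal(nrow(s$mi), n_sliding_windows(5, 1, 0.1, 200))
  expect_error(sliding_mi(rec, cbind("M1_1", "nope")), "not in recording")
})

test_that("session normalization is per-pair min-max and refuses re-entry", {
  s <- toy_series(cbind(c(1, 2, 3), c(4, 4, 4)))
  n <- normalize_session(s)
  expect_equal(unname(n$mi[, 1]), c(0, 0.5, 1))
  expect_equal(unname(n$mi[, 2]), c(0, 0, 0))   # constant pair -> zeros
  expect_true(n$normalized)
  expect_error(normalize_session(n), "already normalized")
})

test_that("strong-edge selection is a strict descending filter", {
  s <- toy_series(matrix(c(0.9, 0.5, 0.81), 1, 3), normalized = TRUE)
  e <- select_strong_edges(s, 1, 0.8)
  expect_equal(e$mi, c(0.9, 0.81))
  expect_equal(nrow(select_strong_edges(s, 1, 1.0)), 0L)  # strict inequality
  expect_error(select_strong_edges(toy_series(matrix(1, 1, 1)), 1), "normalized")
})

test_that("more strong edges appear at an event midpoint than at rest", {
  r <- session_results()[[1]]
  norm <- normalize_session(r$gamma_series)
  centers <- norm$window_centers
  ev <- r$truth
  mids <- (ev$onset_s + ev$offset_s) / 2
  gaps <- (ev$onset_s[-1] + ev$offset_s[-nrow(ev)]) / 2
  n_at <- function(t) nrow(select_strong_edges(norm,
                                               which.min(abs(centers - t))))
  expect_gt(mean(vapply(mids, n_at, 1)), mean(vapply(gaps, n_at, 1)))
})
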