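test_that("the band table matches the canonical edges", {
  expect_equal(unlist(band_spec("theta")[2:3]), c(low_hz = 4, high_hz = 7))
  expect_equal(unlist(band_spec("alpha")[2:3]), c(low_hz = 8, high_hz = 13))
  expect_equal(unlist(band_spec("beta")[2:3]), c(low_hz = 13, high_hz = 30))
  expect_equal(unlist(band_spec("gamma")[2:3]), c(low_hz = 30, high_hz = 50))
})

test_that("CAR removes the channel mean exactly", {
  rec <- recording(rbind(c(1, 1, 1), c(3, 3, 3)), 100, c("a", "b"))
  out <- common_average_reference(rec)
  expect_equal(unname(out$samples), rbind(c(-1, -1, -1), c(1, 1, 1)))

  set.seed(1)
  rec <- toy_recording(dur = 1)
  out <- common_average_reference(rec)
  expect_lt(max(abs(colSums(out$samples))), 1e-10)

  same <- recording(matrix(5, 3, 20) + rep(rnorm(20), each = 3), 100,
                    c("a", "b", "c"))
  expect_lt(max(abs(common_average_reference(same)$samples)), 1e-10)

  expect_error(common_average_reference(recording(matrix(0, 1, 10), 100, "a")),
               "single channel")
})

test_that("broadband and gamma filters meet the pass/stop specifications", {
  bb <- function(r) bandpass_fir(r, 1, 300)
  gm <- function(r) band_filter(r, "gamma")
  expect_equal(sine_gain(bb, 100), 1, tolerance = 0.01)    # pass preserved
  expect_equal(sine_gain(gm, 40), 1, tolerance = 0.01)
  expect_lt(sine_gain(gm, 2), 10^(-40 / 20))               # >= 40 dB stop
  expect_lt(sine_gain(gm, 10), 10^(-40 / 20))
  expect_error(bandpass_fir(toy_recording(), 10, 2000), "band edges")
})

test_that("the 60 Hz notch kills line noise but spares neighbours", {
  nf <- function(r) notch_filter(r)
  expect_lt(sine_gain(nf, 60), 0.03)
  expect_equal(sine_gain(nf, 10), 1, tolerance = 0.03)
  expect_gt(sine_gain(nf, 55), 10^(-3 / 20))               # < 3 dB loss
  expect_gt(sine_gain(nf, 65), 10^(-3 / 20))
  # zero in, zero out
  z <- recording(matrix(0, 2, 2000), 1000, c("a", "b"))
  expect_equal(max(abs(notch_filter(z)$samples)), 0)
  expect_error(notch_filter(toy_recording(fs = 100)), "fs/2")
})

test_that("all filters are zero-phase (impulse symmetry) and linear", {
  fs <- 1000; n <- 4000; k <- 2000
  imp <- matrix(0, 2, n); imp[, k] <- 1
  rec <- recording(imp, fs, c("a", "b"))
  for (f in list(function(r) band_filter(r, "gamma"),
                 function(r) notch_filter(r))) {
    y <- f(rec)$samples[1, ]
    m <- 300
    expect_equal(y[(k - m):(k - 1)], rev(y[(k + 1):(k + m)]), tolerance = 1e-8)
    expect_equal(which.max(abs(y)), k)
  }

  set.seed(3)
  x <- rnorm(3000); y2 <- rnorm(3000)
  mk <- function(v) recording(rbind(v, v), fs, c("a", "b"))
  g <- function(v) band_filter(mk(v), "gamma")$samples[1, ]
  expect_equal(g(2 * x + 3 * y2), 2 * g(x) + 3 * g(y2), tolerance = 1e-8)
})

test_that("the conditioning chain subsets to analysis channels after CAR", {
  set.seed(8)
  ids <- c("M1_1", "M1_2", "DLPFC_1", "OTHER_1")
  sig <- matrix(rnorm(4 * 3000), 4)
  rec <- recording(sig, 1000, ids,
                   stats::setNames(c("M1", "M1", "DLPFC", "OTHER"), ids))
  out <- preprocess_recording(rec, analysis_channels = ids[1:3])
  expect_equal(rownames(out$samples), ids[1:3])
  # the OTHER channel still contributed to the reference:
  ref <- colMeans(sig)
  car_sub <- recording(sweep(sig[1:3, , drop = FALSE], 2, ref), 1000, ids[1:3])
  manual <- notch_filter(bandpass_fir(car_sub, 1, 300))
  expect_equal(unname(out$samples), unname(manual$samples), tolerance = 1e-10)
})
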