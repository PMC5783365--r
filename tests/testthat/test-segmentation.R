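test_that("the activity threshold is mu + 3 sigma of the baseline envelope", {
  set.seed(1)
  fs <- 1000
  emg <- rnorm(5 * fs)
  thr <- emg_threshold(emg, fs, c(1, 2))
  env <- emg_envelope(emg, fs)
  seg <- env[(fs + 1):(2 * fs)]
  expect_equal(thr$threshold, mean(seg) + 3 * sd(seg))
  expect_equal(thr$baseline_mu, mean(seg))

  expect_error(emg_threshold(emg, fs, c(1, 2.5)), "1 s")
  expect_error(emg_threshold(rep(2, 5 * fs), fs, c(1, 2)), "degenerate")
})

test_that("a rectangular burst is detected with tight boundaries", {
  set.seed(4)
  fs <- 1000
  emg <- 0.05 * rnorm(20 * fs)
  emg[(10 * fs):(12 * fs)] <- emg[(10 * fs):(12 * fs)] + 3
  ev <- detect_events(emg, fs, threshold = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 10, tolerance = 0.06)
  expect_equal(ev$offset_s, 12, tolerance = 0.06)

  expect_warning(out <- detect_events(0.05 * rnorm(5 * fs), fs, threshold = 10),
                 "never exceeds")
  expect_equal(nrow(out), 0)
})

test_that("window labels follow the centre rule with strict exclusion", {
  s <- toy_series(matrix(0, 60, 1))               # centres 0.5 .. 6.4 s
  ev <- event_table(2.0, 4.0, "ground_truth")
  lab <- label_windows(s, ev, "strict")
  centre <- s$window_centers
  lab_at <- function(l, t) as.character(l$labels[which.min(abs(centre - t))])
  expect_equal(lab_at(lab, 3.0), "AS")            # mid-event
  expect_equal(lab_at(lab, 0.5), "IS")            # clear gap
  expect_equal(lab_at(lab, 1.8), "EXCLUDED")      # extent straddles the onset
  expect_equal(lab_at(lab, 2.3), "EXCLUDED")
  # partition: every window exactly one label, counts add up
  expect_equal(lab$n_as + lab$n_is + sum(lab$labels == "EXCLUDED"), 60L)

  lab2 <- label_windows(s, ev, "center")
  expect_equal(sum(lab2$labels == "EXCLUDED"), 0L)
  expect_equal(lab_at(lab2, 1.8), "IS")
})

test_that("raising the threshold never increases total active duration", {
  set.seed(6)
  fs <- 500
  emg <- abs(rnorm(30 * fs)) + 2 * sin(2 * pi * (1:(30 * fs)) / (10 * fs))^2
  dur <- function(thr) {
    ev <- suppressWarnings(detect_events(emg, fs, thr))
    if (nrow(ev) == 0) 0 else sum(ev$offset_s - ev$onset_s)
  }
  ds <- vapply(seq(0.5, 3, by = 0.25), dur, 1)
  expect_true(all(diff(ds) <= 1e-9))
})

test_that("onset epochs hold 26 frames and drop boundary events", {
  s <- toy_series(matrix(rexp(100 * 2), 100, 2))  # centres 0.5 .. 10.4 s
  ev <- event_table(c(1.0, 5.0), c(1.5, 6.0), "ground_truth")
  expect_message(ep <- extract_epochs(s, ev, "onset"), "dropping event 1")
  expect_equal(dim(ep$epochs), c(1, 26, 2))
  expect_equal(ep$frame_times_s[1], -2)
  expect_equal(ep$frame_times_s[26], 0.5)
  expect_equal(ep$kept, 2L)

  off <- extract_epochs(s, event_table(3, 5, "ground_truth"), "offset")
  expect_equal(dim(off$epochs)[2], 26)
  expect_equal(off$frame_times_s[c(1, 26)], c(-0.5, 2))

  const <- toy_series(matrix(0.7, 100, 1))
  ca <- extract_epochs(const, event_table(5, 6, "ground_truth"), "onset")
  expect_true(all(ca$average == 0.7))

  expect_error(extract_epochs(s, event_table(0.2, 0.4, "ground_truth"), "onset"),
               "no event")
})
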