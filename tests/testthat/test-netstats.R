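test_that("state means split windows by label and ignore exclusions", {
  s <- toy_series(matrix(c(1, 2, 3, 4), 4, 1))
  sm <- state_mean_mi(s, toy_labels(c("AS", "AS", "IS", "IS")))
  expect_equal(unname(sm$as_mean), 1.5)
  expect_equal(unname(sm$is_mean), 3.5)
  expect_equal(c(sm$n_as, sm$n_is), c(2, 2))

  expect_error(state_mean_mi(s, toy_labels(rep("AS", 4))), "at least one")

  s6 <- toy_series(matrix(c(1, 9, 2, 9, 3, 4), 6, 1))
  sm6 <- state_mean_mi(s6, toy_labels(c("AS", "EXCLUDED", "AS", "EXCLUDED",
                                        "IS", "IS")))
  expect_equal(unname(sm6$as_mean), 1.5)      # as if excluded rows deleted
  expect_equal(unname(sm6$is_mean), 3.5)
})

test_that("MIR follows its defining formula and invariances", {
  s <- toy_series(matrix(c(1.2, 1.2, 1.0, 1.0), 4, 1))
  lab <- toy_labels(c("AS", "AS", "IS", "IS"))
  expect_equal(mir(s, lab)$mir_percent, 20)

  # two pairs with per-pair ratios +10% and +30% average to +20%
  s2 <- toy_series(cbind(c(1.1, 1.1, 1, 1), c(2.6, 2.6, 2, 2)))
  expect_equal(mir(s2, lab)$mir_percent, 20)

  # scale invariance and exact zero
  s3 <- toy_series(7 * s2$mi)
  expect_equal(mir(s3, lab)$mir_percent, 20)
  s0 <- toy_series(matrix(2, 4, 3))
  expect_equal(mir(s0, lab)$mir_percent, 0)

  # sign law: all pairs up => MIR > 0
  expect_gt(mir(s2, lab)$mir_percent, 0)

  szero <- toy_series(matrix(c(1, 1, 0, 0), 4, 1))
  expect_error(mir(szero, lab), "zero idle-state")
})

test_that("the two-group rank test reproduces hand-computed values", {
  r <- rank_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 3.857, tolerance = 1e-3)
  expect_equal(r$p_value, 0.0495, tolerance = 1e-2)

  tie <- rank_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(tie$p_value, 0.9)

  expect_error(rank_test(1, c(1, 2)), "at least 2")

  set.seed(41)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = runif(1))
    expect_equal(rank_test(a, b)$statistic, naive_kw_h(a, b), tolerance = 1e-10)
  }
})

test_that("permuting state labels centres MIR at zero", {
  set.seed(42)
  mi <- matrix(rexp(400 * 5, rate = 10) + 0.05, 400, 5)
  s <- toy_series(mi)
  true_lab <- c(rep("AS", 80), rep("IS", 320))
  perm <- replicate(200, {
    mir(s, toy_labels(sample(true_lab)))$mir_percent
  })
  expect_lt(abs(mean(perm)), 4 * sd(perm) / sqrt(200) + 0.05)
})

test_that("state-independent coupling yields a near-zero MIR", {
  cfg <- synth_config(duration_s = 60, n_trials = 6, n_other = 10,
                      coupling_strength = 0.05, idle_coupling = 0.05, seed = 1)
  ses <- generate_session(cfg)
  rec <- preprocess_recording(ses$recording,
    analysis_channels =
      ses$recording$channel_ids[ses$recording$region_map != "OTHER"])
  g <- sliding_mi(band_filter(rec, "gamma"), network_definition(rec, "M1"),
                  band = "gamma")
  lab <- label_windows(g, ses$truth$events, "strict")
  expect_lt(abs(mir(g, lab)$mir_percent), 4)   # estimator noise only
})

test_that("the synthetic contrast shows the expected network ordering", {
  r <- session_results()[[1]]
  expect_gt(r$mir_gamma[["M1"]], 0)
  expect_gt(r$mir_gamma[["M1"]], r$mir_gamma[["DLPFC"]])
  expect_gt(r$mir_gamma[["DLPFC_M1"]], r$mir_gamma[["DLPFC"]])
  expect_lt(r$p_gamma[["M1"]], 0.01)
  expect_lt(r$p_gamma[["DLPFC_M1"]], 0.01)
  expect_gt(r$p_gamma[["DLPFC"]], 0.01)
})
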