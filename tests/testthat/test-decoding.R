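test_that("feature building concatenates pairs and drops exclusions", {
  set.seed(50)
  mi1 <- matrix(rexp(25 * 2), 25, 2); mi2 <- matrix(rexp(25 * 3), 25, 3)
  s1 <- toy_series(mi1); s2 <- toy_series(mi2)
  lab <- toy_labels(c(rep("AS", 10), rep("IS", 10), rep("EXCLUDED", 5)))
  f <- build_features(list(s1, s2), lab)
  expect_equal(dim(f$x), c(20, 5))
  expect_equal(nrow(f$column_pairs), 5)
  expect_equal(levels(f$y), c("AS", "IS"))

  short <- toy_series(matrix(0, 10, 1))
  expect_error(build_features(list(s1, short), lab), "window grid")
})

test_that("LDA separates well-separated clouds and knows its closed form", {
  f <- sep_features()
  fit <- lda_fit(f$x, f$y)
  expect_equal(mean(predict(fit, f$x) == f$y), 1)

  # 2-D hand case: means (0,0)/(2,0), spherical scatter => boundary x1 = 1
  xa <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  xb <- sweep(xa, 2, c(2, 0), "+")
  fit2 <- lda_fit(rbind(xa, xb), rep(c("A", "B"), each = 4), gamma = 0)
  expect_equal(as.character(predict(fit2, rbind(c(0.95, 5), c(1.05, -5)))),
               c("A", "B"))

  expect_error(lda_fit(f$x, rep("AS", nrow(f$x))), "two classes")
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(52)
  x <- rbind(matrix(rnorm(200 * 3), ncol = 3),
             matrix(rnorm(160 * 3, mean = 0.8), ncol = 3))
  y <- factor(rep(c("AS", "IS"), c(200, 160)))
  ours <- predict(lda_fit(x, y, gamma = 0), x)
  ref <- predict(MASS::lda(x, y), x)$class
  expect_gt(mean(ours == ref), 0.99)
})

test_that("indistinguishable classes decode at the majority prior", {
  set.seed(53)
  acc <- replicate(50, {
    x <- matrix(rnorm(200 * 3), ncol = 3)
    y <- factor(rep(c("AS", "IS"), each = 100))
    f <- list(x = x, y = y)
    cross_validate(f, k = 5, repeats = 1, seed = 1)$mean_accuracy
  })
  expect_equal(mean(acc), 0.5, tolerance = 0.05)
})

test_that("cross-validation is deterministic, exhaustive and near-equal-sized", {
  f <- sep_features(n = 103)
  r1 <- cross_validate(f, seed = 7)
  r2 <- cross_validate(f, seed = 7)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_equal(r1$mean_accuracy, 1)
  expect_equal(length(r1$fold_accuracies), 100)
  expect_equal(r1$mean_accuracy, mean(r1$fold_accuracies))
  # confusion over the first repeat covers every row exactly once
  expect_equal(sum(r1$confusion), 103)

  expect_error(cross_validate(f, k = 500), "k must not")
})

test_that("blocked CV is no more optimistic than permuted CV under leakage", {
  set.seed(54)
  n <- 600
  drift <- stats::filter(rnorm(n), rep(1, 25), circular = TRUE) / 5
  x <- cbind(drift + rnorm(n, sd = 0.3), rnorm(n))
  y <- factor(ifelse(drift > 0, "AS", "IS"))
  f <- list(x = x, y = y)
  perm <- cross_validate(f, seed = 2)$mean_accuracy
  blocked <- cross_validate(f, seed = 2, cv = "blocked")$mean_accuracy
  expect_lte(blocked, perm + 0.02)
})

test_that("class balancing equalises the groups deterministically", {
  f <- list(x = matrix(rnorm(60), 30, 2),
            y = factor(rep(c("AS", "IS"), c(10, 20))),
            column_pairs = NULL)
  b <- balance_classes(f, seed = 3)
  expect_equal(as.vector(table(b$y)), c(10, 10))
  expect_identical(balance_classes(f, seed = 3)$x, b$x)
})

test_that("network comparison reports both accuracies and their gap", {
  r <- session_results()[[1]]
  dec <- compare_networks(lapply(r$networks, function(nw)
    subset_pairs(r$gamma_series, nw)), r$labels, seed = 1, repeats = 2)
  expect_equal(dec$accuracy_gain,
               dec$combined$mean_accuracy - dec$m1_only$mean_accuracy)
  expect_gt(dec$m1_only$mean_accuracy, 0.8)
  expect_gte(dec$combined$mean_accuracy + 0.02, dec$m1_only$mean_accuracy)
})
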