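#' Build the per-window connectivity feature matrix
#'
#' Horizontally concatenates the pair columns of one or more connectivity
#' series sharing a window grid; rows labeled `EXCLUDED` are dropped. On the
#' default channel layout the M1-only set has 45 columns and the
#' M1 + DLPFC + DLPFC-M1 set has 45 + 36 + 90 = 171.
#'
#' @param series_list a [connectivity_series()] or list of them (one per
#'   network), all on the same window grid.
#' @param labels a [label_windows()] result on that grid.
#' @return object of class `feature_matrix`: list with `x` (rows = retained
#'   windows, columns = pairs), `y` (factor `AS`/`IS`), `column_pairs`.
#' @export
build_features <- function(series_list, labels) {
  if (inherits(series_list, "connectivity_series")) series_list <- list(series_list)
  grids <- lapply(series_list, `[[`, "window_centers")
  for (g in grids[-1])
    if (length(g) != length(grids[[1]]) || any(abs(g - grids[[1]]) > 1e-9))
      stop("all series must share the same window grid")
  if (length(labels$labels) != length(grids[[1]]))
    stop("labels do not align with the series windows")
  x <- do.call(cbind, lapply(series_list, `[[`, "mi"))
  pairs <- do.call(rbind, lapply(series_list, `[[`, "pairs"))
  keep <- labels$labels != "EXCLUDED"
  structure(list(x = x[keep, , drop = FALSE],
                 y = droplevels(labels$labels[keep]),
                 column_pairs = pairs),
            class = "feature_matrix")
}

#' Two-class regularized linear discriminant
#'
#' Classic LDA: class means, pooled within-class covariance (with a small
#' shrink toward its diagonal, needed when the feature count approaches the
#' row count), linear decision rule with class priors estimated from the
#' training frequencies.
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y two-level factor (or vector coercible to one).
#' @param gamma shrinkage weight toward `diag(S)` (default `1e-4`).
#' @return object of class `lda_model` with `w` (weights), `b` (intercept:
#'   classify as the second level when `x %*% w + b > 0`), `means`,
#'   `levels`, `priors`.
#' @export
lda_fit <- function(x, y, gamma = 1e-4) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("lda_fit needs exactly two classes in the training set")
  if (nrow(x) <= 2) stop("need more than 2 training rows")
  lv <- levels(y)
  i1 <- y == lv[1]; i2 <- y == lv[2]
  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[i2, , drop = FALSE])
  c1 <- crossprod(sweep(x[i1, , drop = FALSE], 2, m1))
  c2 <- crossprod(sweep(x[i2, , drop = FALSE], 2, m2))
  sp <- (c1 + c2) / (nrow(x) - 2)
  sp <- (1 - gamma) * sp + gamma * diag(diag(sp), ncol(x))
  w <- solve(sp, m2 - m1)
  pri <- c(mean(i1), mean(i2))
  b <- -sum(w * (m1 + m2)) / 2 + log(pri[2] / pri[1])
  structure(list(w = w, b = b, means = rbind(m1, m2), levels = lv,
                 priors = pri, gamma = gamma),
            class = "lda_model")
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  s <- as.matrix(newdata) %*% object$w + object$b
  factor(object$levels[ifelse(s > 0, 2, 1)], levels = object$levels)
}

#' Permuted k-fold cross-validated decoding accuracy
#'
#' Rows are permuted by a seeded RNG and partitioned into `k` near-equal
#' blocks; each block is tested once per repeat against a classifier trained
#' on the rest. `cv = "blocked"` keeps rows in temporal order (contiguous
#' blocks, no permutation), which avoids the optimism that overlapping
#' windows cause under permuted CV.
#'
#' @param features a [build_features()] result (or list with `x`, `y`).
#' @param k folds (default 10).
#' @param repeats repetitions of the whole procedure (default 10; 1 for
#'   blocked CV since it is deterministic).
#' @param seed RNG seed for the permutations.
#' @param cv `"permuted"` (default) or `"blocked"`.
#' @return object of class `decoding_result`: `fold_accuracies` (one per
#'   fold per repeat), `mean_accuracy`, `sd_accuracy`, `confusion`
#'   (2x2 counts, truth in rows, aggregated over folds of the first repeat),
#'   `cv`, `k`, `repeats`.
#' @export
cross_validate <- function(features, k = 10, repeats = 10, seed = 1,
                           cv = c("permuted", "blocked")) {
  cv <- match.arg(cv)
  x <- as.matrix(features$x)
  y <- droplevels(as.factor(features$y))
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of rows")
  if (cv == "blocked") repeats <- 1L
  set.seed(as.integer(seed))
  fold_acc <- numeric(0)
  confusion <- matrix(0L, 2, 2, dimnames = list(truth = levels(y),
                                                predicted = levels(y)))
  sizes <- rep(n %/% k, k)                     # fold sizes differ by <= 1
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  for (r in seq_len(repeats)) {
    ord <- if (cv == "permuted") sample.int(n) else seq_len(n)
    folds <- unname(split(ord, rep(seq_len(k), times = sizes)))
    for (f in seq_len(k)) {
      test <- folds[[f]]
      train <- setdiff(ord, test)
      fit <- lda_fit(x[train, , drop = FALSE], y[train])
      pred <- predict(fit, x[test, , drop = FALSE])
      fold_acc <- c(fold_acc, mean(pred == y[test]))
      if (r == 1L)
        confusion <- confusion + table(truth = y[test], predicted = pred)
    }
  }
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 sd_accuracy = sd(fold_acc),
                 confusion = confusion, cv = cv, k = k, repeats = repeats),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result (%s %d-fold x %d): accuracy %.1f +/- %.1f%%>\n",
              x$cv, x$k, x$repeats, 100 * x$mean_accuracy, 100 * x$sd_accuracy))
  invisible(x)
}

#' Compare M1-only and DLPFC+M1 feature sets
#'
#' Runs the same cross-validation on the intra-M1 feature set and on the
#' combined M1 + DLPFC + DLPFC-M1 set, and reports both results plus the
#' accuracy difference.
#'
#' @param series_by_network named list of [connectivity_series()] with
#'   elements `M1`, `DLPFC`, `DLPFC_M1` on a common window grid.
#' @param labels a [label_windows()] result.
#' @param seed RNG seed forwarded to [cross_validate()].
#' @param ... further arguments to [cross_validate()].
#' @return list with `m1_only`, `combined` (both `decoding_result`) and
#'   `accuracy_gain` (combined minus M1-only, proportion).
#' @export
compare_networks <- function(series_by_network, labels, seed = 1, ...) {
  stopifnot(all(c("M1", "DLPFC", "DLPFC_M1") %in% names(series_by_network)))
  f_m1 <- build_features(series_by_network[["M1"]], labels)
  f_all <- build_features(series_by_network[c("M1", "DLPFC", "DLPFC_M1")], labels)
  r_m1 <- cross_validate(f_m1, seed = seed, ...)
  r_all <- cross_validate(f_all, seed = seed, ...)
  list(m1_only = r_m1, combined = r_all,
       accuracy_gain = r_all$mean_accuracy - r_m1$mean_accuracy)
}

#' Subsample the majority class to balance a feature matrix
#'
#' Idle windows typically outnumber active ones; chance level under a
#' prior-sensitive accuracy then exceeds 50%. This helper subsamples the
#' majority class (seeded) to equalise the classes for chance-level checks.
#'
#' @param features a [build_features()] result.
#' @param seed RNG seed.
#' @return a balanced `feature_matrix`.
#' @export
balance_classes <- function(features, seed = 1) {
  y <- features$y
  tab <- table(y)
  nmin <- min(tab)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(levels(y), function(lv) {
    idx <- which(y == lv)
    if (length(idx) > nmin) sample(idx, nmin) else idx
  }))
  keep <- sort(keep)
  structure(list(x = features$x[keep, , drop = FALSE], y = droplevels(y[keep]),
                 column_pairs = features$column_pairs),
            class = "feature_matrix")
}
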