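#' Per-pair state-mean MI
#'
#' For each pair, the mean MI over the K active-state windows and over the L
#' idle-state windows; `EXCLUDED` windows are ignored.
#'
#' @param series a [connectivity_series()].
#' @param labels a [label_windows()] result aligned with the series.
#' @return list with `as_mean`, `is_mean` (named numeric, one value per
#'   pair), `n_as` (K), `n_is` (L).
#' @export
state_mean_mi <- function(series, labels) {
  stopifnot(inherits(series, "connectivity_series"),
            inherits(labels, "state_labels"))
  if (length(labels$labels) != nrow(series$mi))
    stop("labels do not align with the series windows")
  as_idx <- labels$labels == "AS"
  is_idx <- labels$labels == "IS"
  if (!any(as_idx) || !any(is_idx))
    stop("need at least one AS and one IS window (K >= 1, L >= 1)")
  list(as_mean = colMeans(series$mi[as_idx, , drop = FALSE]),
       is_mean = colMeans(series$mi[is_idx, , drop = FALSE]),
       n_as = sum(as_idx), n_is = sum(is_idx))
}

#' Mutual information ratio (MIR) of a network
#'
#' The per-network percentage increase of active-state over idle-state
#' connectivity:
#' `MIR = (100 / N) * sum_p (as_mean(p) - is_mean(p)) / is_mean(p)`,
#' averaging the per-pair relative change over the N pairs of the network.
#'
#' @param series a [connectivity_series()] restricted to the network's pairs
#'   (see [subset_pairs()]).
#' @param labels a [label_windows()] result.
#' @param network optional [network_definition()]; when given, the series is
#'   subset to its pairs and the network name is recorded.
#' @return object of class `mir_result`: list with `network`, `band`,
#'   `mir_percent`, `per_pair_as_mean`, `per_pair_is_mean`, `n_pairs`,
#'   `n_as`, `n_is`.
#' @export
mir <- function(series, labels, network = NULL) {
  if (!is.null(network)) series <- subset_pairs(series, network)
  sm <- state_mean_mi(series, labels)
  if (any(sm$is_mean == 0))
    stop("degenerate input: a pair has zero idle-state mean MI")
  ratio <- (sm$as_mean - sm$is_mean) / sm$is_mean
  structure(list(network = if (is.null(network)) NA_character_ else network$name,
                 band = series$band,
                 mir_percent = 100 * mean(ratio),
                 per_pair_as_mean = sm$as_mean,
                 per_pair_is_mean = sm$is_mean,
                 n_pairs = ncol(series$mi), n_as = sm$n_as, n_is = sm$n_is),
            class = "mir_result")
}

#' @export
print.mir_result <- function(x, ...) {
  cat(sprintf("<mir_result: %s network, %s band>  MIR = %.2f%%  (N = %d pairs, K = %d AS, L = %d IS windows)\n",
              x$network, x$band, x$mir_percent, x$n_pairs, x$n_as, x$n_is))
  invisible(x)
}

#' Two-sample Kruskal-Wallis rank test
#'
#' Rank-based two-group comparison (tie-corrected H, chi-square p-value with
#' 1 degree of freedom). The default analysis unit is the pair: one value per
#' pair per state, namely that pair's state-mean MI.
#'
#' @param as_values,is_values numeric vectors (each of length at least 2).
#' @return object of class `kw_test_result`: list with `statistic`,
#'   `p_value`, `n_group_a`, `n_group_b`.
#' @export
rank_test <- function(as_values, is_values) {
  if (length(as_values) < 2 || length(is_values) < 2)
    stop("each group needs at least 2 values")
  kt <- kruskal.test(list(as.numeric(as_values), as.numeric(is_values)))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n_group_a = length(as_values), n_group_b = length(is_values)),
            class = "kw_test_result")
}

#' @export
print.kw_test_result <- function(x, ...) {
  cat(sprintf("<kw_test: H = %.4f, p = %.4g (n = %d vs %d)>\n",
              x$statistic, x$p_value, x$n_group_a, x$n_group_b))
  invisible(x)
}

#' Network-level AS/IS contrast test
#'
#' Convenience wrapper: per-pair state means from [state_mean_mi()], then
#' [rank_test()] on the two groups of per-pair means (group sizes = N pairs,
#' matching the N reported for intra/inter networks).
#'
#' @inheritParams mir
#' @return a `kw_test_result`.
#' @export
network_rank_test <- function(series, labels, network = NULL) {
  if (!is.null(network)) series <- subset_pairs(series, network)
  sm <- state_mean_mi(series, labels)
  rank_test(sm$as_mean, sm$is_mean)
}
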