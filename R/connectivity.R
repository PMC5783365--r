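#' Sliding-window MI configuration
#'
#' @param window_s analysis window length, seconds (default 1.0).
#' @param step_s window step, seconds (default 0.1).
#' @param n_bins histogram bins per signal (default 8).
#' @param miller_madow apply the Miller-Madow bias correction
#'   (default `FALSE`: plain plug-in estimator).
#' @return list of class `mi_config`.
#' @export
mi_config <- function(window_s = 1.0, step_s = 0.1, n_bins = 8,
                      miller_madow = FALSE) {
  if (window_s <= 0 || step_s <= 0) stop("window_s and step_s must be positive")
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(window_s = window_s, step_s = step_s, n_bins = as.integer(n_bins),
                 miller_madow = isTRUE(miller_madow)), class = "mi_config")
}

#' Histogram-binned mutual information of two signal windows
#'
#' The plug-in estimator: each signal is partitioned into `n_bins`
#' equal-width bins spanning its own per-window `[min, max]`; MI is
#' `sum p(x, y) * ln(p(x, y) / (p(x) p(y)))` over non-empty joint cells, in
#' nats. A constant input occupies a single bin, making the MI exactly 0.
#'
#' @param x,y equal-length numeric vectors (length at least `n_bins`), finite.
#' @param n_bins number of bins per marginal (default 8).
#' @param miller_madow subtract the Miller-Madow bias estimate
#'   `(Kxy - Kx - Ky + 1) / (2n)` (occupied-cell counts); default `FALSE`.
#' @return MI in nats, `>= 0` (the corrected value may be negative).
#' @export
mutual_information <- function(x, y, n_bins = 8, miller_madow = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < n_bins) stop("need at least n_bins samples")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  .mi_pair_cpp(as.numeric(x), as.numeric(y), as.integer(n_bins),
               isTRUE(miller_madow))
}

#' Sliding-window MI over a network's channel pairs
#'
#' For every 1 s window (stepped every 100 ms by default) and every channel
#' pair of the network, computes [mutual_information()] on the two channels'
#' window samples. Window centers sit at `window_s / 2 + k * step_s`; an
#' incomplete trailing window is dropped.
#'
#' @param rec a band-filtered [recording()].
#' @param network a [network_definition()], or a 2-column character matrix of
#'   channel pairs.
#' @param cfg an [mi_config()].
#' @param band band name recorded in the output (metadata only).
#' @return a [connectivity_series()] (windows x pairs, nats).
#' @export
sliding_mi <- function(rec, network, cfg = mi_config(), band = "broadband") {
  stopifnot(inherits(rec, "recording"))
  pairs <- if (inherits(network, "network_definition")) network$pairs else as.matrix(network)
  missing_ch <- setdiff(unique(c(pairs)), rec$channel_ids)
  if (length(missing_ch))
    stop("channels not in recording: ", paste(missing_ch, collapse = ", "))
  win <- round(cfg$window_s * rec$fs)
  step <- round(cfg$step_s * rec$fs)
  nsamp <- ncol(rec$samples)
  if (nsamp < win) stop("recording shorter than one analysis window")
  ia <- match(pairs[, 1], rec$channel_ids) - 1L
  ib <- match(pairs[, 2], rec$channel_ids) - 1L
  mi <- .sliding_mi_cpp(t(rec$samples), cbind(ia, ib), win, step,
                        cfg$n_bins, cfg$miller_madow)
  nwin <- nrow(mi)
  centers <- cfg$window_s / 2 + (seq_len(nwin) - 1) * cfg$step_s
  connectivity_series(mi, centers, pairs, band = band,
                      window_s = cfg$window_s, step_s = cfg$step_s,
                      bias_corrected = cfg$miller_madow)
}

#' Expected sliding-window count
#'
#' `floor((duration - window) / step) + 1`, computed in integer sample
#' arithmetic (a 300 s session at 1 s / 0.1 s gives 2991).
#'
#' @param duration_s,window_s,step_s seconds.
#' @param fs sampling rate, Hz.
#' @return integer window count.
#' @export
n_sliding_windows <- function(duration_s, window_s = 1.0, step_s = 0.1, fs = 1000) {
  nsamp <- round(duration_s * fs)
  win <- round(window_s * fs)
  step <- round(step_s * fs)
  as.integer((nsamp - win) %/% step + 1L)
}

#' Session-wide min-max normalization
#'
#' Rescales each pair's MI trace to `[0, 1]` using that pair's minimum and
#' maximum over all windows of the session (`scope = "pair"`), or the global
#' session extremes (`scope = "global"`). A constant pair maps to all zeros.
#'
#' @param series an unnormalized [connectivity_series()].
#' @param scope `"pair"` (default) or `"global"`.
#' @return the normalized [connectivity_series()].
#' @export
normalize_session <- function(series, scope = c("pair", "global")) {
  stopifnot(inherits(series, "connectivity_series"))
  scope <- match.arg(scope)
  if (series$normalized) stop("series is already normalized")
  mi <- series$mi
  if (scope == "global") {
    rng <- range(mi)
    mi <- if (diff(rng) > 0) (mi - rng[1]) / diff(rng) else mi * 0
  } else {
    lo <- apply(mi, 2, min)
    hi <- apply(mi, 2, max)
    span <- hi - lo
    flat <- span <= 0
    span[flat] <- 1
    mi <- sweep(sweep(mi, 2, lo), 2, span, "/")
    mi[, flat] <- 0
  }
  connectivity_series(mi, series$window_centers, series$pairs, series$band,
                      series$window_s, series$step_s, normalized = TRUE)
}

#' Strong edges at one window
#'
#' Pairs whose normalized MI at the given window strictly exceeds the
#' threshold, sorted by descending MI.
#'
#' @param series a normalized [connectivity_series()].
#' @param window_index window row index.
#' @param threshold normalized-MI cut-off (default 0.8).
#' @return data.frame with columns `channel_a`, `channel_b`, `mi`.
#' @export
select_strong_edges <- function(series, window_index, threshold = 0.8) {
  stopifnot(inherits(series, "connectivity_series"))
  if (!series$normalized) stop("select_strong_edges needs a normalized series")
  v <- series$mi[window_index, ]
  keep <- which(v > threshold)
  keep <- keep[order(v[keep], decreasing = TRUE)]
  data.frame(channel_a = series$pairs[keep, 1],
             channel_b = series$pairs[keep, 2],
             mi = unname(v[keep]))
}
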