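#' Canonical analysis bands
#'
#' Fixed band table: theta 4-7, alpha 8-13, beta 13-30, gamma 30-50 Hz.
#'
#' @param name one of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return list with `name`, `low_hz`, `high_hz`.
#' @export
band_spec <- function(name = c("theta", "alpha", "beta", "gamma")) {
  name <- match.arg(name)
  edges <- list(theta = c(4, 7), alpha = c(8, 13), beta = c(13, 30),
                gamma = c(30, 50))[[name]]
  list(name = name, low_hz = edges[1], high_hz = edges[2])
}

#' @rdname band_spec
#' @export
band_names <- function() c("theta", "alpha", "beta", "gamma")

#' Common average reference
#'
#' Subtracts the instantaneous mean across all recorded channels from each
#' channel, removing globally shared background activity. The EMG trace is
#' untouched.
#'
#' @param rec a [recording()] with at least two channels.
#' @return the re-referenced [recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 2)
    stop("CAR is undefined for a single channel")
  car <- colMeans(rec$samples)
  rec$samples <- sweep(rec$samples, 2, car)
  rec
}

# Weighted least-squares linear-phase (type I) FIR design.
# bands: matrix with columns (f1, f2, desired, weight), f in Hz. Transition
# regions are simply absent from the band list ("don't care"). Returns the
# odd-length symmetric impulse response.
design_firls <- function(n_taps, fs, bands) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  M <- (n_taps - 1) / 2
  w <- bands[, 1:2, drop = FALSE] * 2 * pi / fs   # rad/sample edges
  # I_n(band) = integral of cos(n w) over band
  In <- function(nn, b) {
    if (nn == 0) w[b, 2] - w[b, 1]
    else (sin(nn * w[b, 2]) - sin(nn * w[b, 1])) / nn
  }
  K <- M + 1
  Q <- matrix(0, K, K)
  bvec <- numeric(K)
  for (b in seq_len(nrow(bands))) {
    wt <- bands[b, 4]; d <- bands[b, 3]
    for (k in 0:M) {
      bvec[k + 1] <- bvec[k + 1] + wt * d * In(k, b)
      for (m in k:M) {
        q <- wt * 0.5 * (In(k - m, b) + In(k + m, b))
        Q[k + 1, m + 1] <- Q[k + 1, m + 1] + q
        if (m != k) Q[m + 1, k + 1] <- Q[m + 1, k + 1] + q
      }
    }
  }
  # wide don't-care regions make Q rank-deficient for long filters (cosine
  # polynomials can concentrate inside the gap); a tiny ridge picks one of
  # the near-equivalent least-squares optima without altering the response
  ridge <- 1e-9 * mean(diag(Q))
  a <- solve(Q + ridge * diag(K), bvec)
  h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  h
}

# cache of designed filters, keyed by parameters
.filter_cache <- new.env(parent = emptyenv())

# Least-squares band-pass design with don't-care transition bands (15% of
# each edge). Length combines the classic three-cycles-of-the-low-edge rule
# with a narrow-band floor (six cycles of the bandwidth, at least 1 s of
# taps) so that even the 3 Hz-wide theta band keeps pass-band ripple well
# under 1%.
bandpass_taps <- function(fs, low, high) {
  key <- sprintf("bp_%g_%g_%g", fs, low, high)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  n_taps <- ceiling(max(3 * fs / low, 6 * fs / (high - low), fs))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  nyq <- fs / 2
  stop_lo <- 0.85 * low
  stop_hi <- min(1.15 * high, nyq)
  bands <- rbind(c(0, stop_lo, 0, 1),
                 c(low, high, 1, 1))
  if (stop_hi < nyq - 1e-9)
    bands <- rbind(bands, c(stop_hi, nyq, 0, 1))
  h <- design_firls(n_taps, fs, bands)
  .filter_cache[[key]] <- h
  h
}

# Zero-phase FIR filtering of one trace: odd-reflection padding of
# 3 filter lengths at each edge, then multiplication of the spectrum by
# |H(f)|^2 — exactly a forward pass followed by a backward pass with the
# same symmetric FIR.
zero_phase_fir <- function(x, h) {
  n <- length(x)
  L <- length(h)
  p <- min(3 * L, n - 1)
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  xp <- c(left, x, right)
  nfft <- stats::nextn(length(xp) + 2 * L, c(2, 3, 5))
  H <- fft(c(h, rep(0, nfft - L)))
  y <- Re(fft(fft(c(xp, rep(0, nfft - length(xp)))) * (Mod(H)^2),
              inverse = TRUE)) / nfft
  y[(p + 1):(p + n)]
}

apply_to_channels <- function(rec, fun) {
  for (i in seq_len(nrow(rec$samples)))
    rec$samples[i, ] <- fun(rec$samples[i, ])
  rec
}

#' Two-way least-squares FIR band-pass filter
#'
#' Applies a linear-phase least-squares FIR band-pass forward and backward
#' (zero net phase). Filter length is
#' `max(3 * fs / low_hz, 6 * fs / bandwidth, fs)` rounded up to odd; edge
#' transients are absorbed by odd-reflection padding of three filter
#' lengths.
#'
#' @param rec a [recording()].
#' @param low_hz,high_hz pass-band edges, `0 < low < high < fs/2`.
#' @return the filtered [recording()]; EMG untouched.
#' @export
bandpass_fir <- function(rec, low_hz, high_hz) {
  stopifnot(inherits(rec, "recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  h <- bandpass_taps(rec$fs, low_hz, high_hz)
  apply_to_channels(rec, function(x) zero_phase_fir(x, h))
}

#' 60 Hz notch filter
#'
#' Second-order IIR notch (about 3 Hz wide at -3 dB) applied forward and
#' backward for zero phase.
#'
#' @param rec a [recording()].
#' @param freq_hz notch centre frequency, Hz (default 60).
#' @return the filtered [recording()].
#' @export
notch_filter <- function(rec, freq_hz = 60) {
  stopifnot(inherits(rec, "recording"))
  if (freq_hz <= 0 || freq_hz >= rec$fs / 2)
    stop("notch frequency must lie in (0, fs/2)")
  w0 <- 2 * pi * freq_hz / rec$fs
  bw <- 2 * pi * 3 / rec$fs                    # -3 dB bandwidth 3 Hz
  r <- 1 - bw / 2
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b)                     # unit gain at DC
  apply_to_channels(rec, function(x) filtfilt_iir(b, a, x))
}

# forward-backward IIR with odd-reflection padding
filtfilt_iir <- function(b, a, x) {
  n <- length(x)
  p <- min(1000, n - 1)                        # ~10 pole time constants
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Band filter with the canonical band table
#'
#' @param rec a [recording()].
#' @param band a band name or a [band_spec()].
#' @return the band-filtered [recording()].
#' @export
band_filter <- function(rec, band) {
  if (is.character(band)) band <- band_spec(band)
  bandpass_fir(rec, band$low_hz, band$high_hz)
}

#' Standard signal-conditioning chain
#'
#' Applies, in this fixed order: common average reference, 1-300 Hz two-way
#' least-squares FIR band-pass, 60 Hz notch. Per-band filtering
#' ([band_filter()]) follows downstream.
#'
#' @param rec a [recording()].
#' @param broadband length-2 numeric, broadband pass edges (default
#'   `c(1, 300)`).
#' @param notch_hz notch frequency (default 60); `NA` skips the notch.
#' @param analysis_channels optional channel subset kept after the CAR: the
#'   reference is computed over all recorded channels, while the filtering
#'   (and everything downstream) runs on the analysis montage only.
#' @return the conditioned [recording()].
#' @export
preprocess_recording <- function(rec, broadband = c(1, 300), notch_hz = 60,
                                 analysis_channels = NULL) {
  rec <- common_average_reference(rec)
  if (!is.null(analysis_channels)) rec <- subset_channels(rec, analysis_channels)
  rec <- bandpass_fir(rec, broadband[1], min(broadband[2], rec$fs / 2 - 1))
  if (!is.na(notch_hz)) rec <- notch_filter(rec, notch_hz)
  rec
}
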