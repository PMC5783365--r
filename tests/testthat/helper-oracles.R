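# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain R loops and closed-form formulas.

# naive plug-in MI: equal-width bins over [min, max], explicit double loop
naive_mi <- function(x, y, n_bins = 8) {
  bin <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(rep(1L, length(v)))
    b <- floor((v - r[1]) / diff(r) * n_bins) + 1L
    pmin(b, n_bins)
  }
  bx <- bin(x); by <- bin(y)
  n <- length(x)
  mi <- 0
  for (i in seq_len(n_bins)) {
    for (j in seq_len(n_bins)) {
      nij <- sum(bx == i & by == j)
      if (nij == 0) next
      pxy <- nij / n
      px <- sum(bx == i) / n
      py <- sum(by == j) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  mi
}

# naive sliding MI: explicit window loop, no shared code with the package
naive_sliding_mi <- function(sig, pairs_idx, fs, window_s = 1, step_s = 0.1,
                             n_bins = 8) {
  win <- round(window_s * fs); step <- round(step_s * fs)
  nwin <- (ncol(sig) - win) %/% step + 1
  out <- matrix(NA_real_, nwin, nrow(pairs_idx))
  for (w in seq_len(nwin)) {
    s0 <- (w - 1) * step + 1
    idx <- s0:(s0 + win - 1)
    for (p in seq_len(nrow(pairs_idx)))
      out[w, p] <- naive_mi(sig[pairs_idx[p, 1], idx], sig[pairs_idx[p, 2], idx],
                            n_bins)
  }
  out
}

# hand Kruskal-Wallis H with tie correction, two groups
naive_kw_h <- function(a, b) {
  v <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  r <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# steady-state amplitude of a sinusoid after filtering (ignore edges)
sine_gain <- function(filter_fun, freq, fs = 1000, dur = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  rec <- recording(rbind(x, x), fs, c("a", "b"))
  y <- filter_fun(rec)$samples[1, ]
  core <- seq(round(0.25 * length(y)), round(0.75 * length(y)))
  sqrt(2) * sd(y[core])   # RMS amplitude: robust to stroboscopic sampling
}

# small recording with an M1/DLPFC montage
toy_recording <- function(n_m1 = 3, n_dlpfc = 2, dur = 2, fs = 100, seed = 42) {
  set.seed(seed)
  ids <- c(sprintf("M1_%d", seq_len(n_m1)), sprintf("DLPFC_%d", seq_len(n_dlpfc)))
  sig <- matrix(rnorm((n_m1 + n_dlpfc) * dur * fs), n_m1 + n_dlpfc)
  recording(sig, fs, ids,
            stats::setNames(rep(c("M1", "DLPFC"), c(n_m1, n_dlpfc)), ids))
}

# a connectivity series built directly from a matrix (bypasses sliding_mi)
toy_series <- function(mi, step_s = 0.1, window_s = 1, band = "gamma",
                       normalized = FALSE) {
  mi <- as.matrix(mi)
  np <- ncol(mi)
  pairs <- cbind(sprintf("A%d", seq_len(np)), sprintf("B%d", seq_len(np)))
  colnames(pairs) <- c("channel_a", "channel_b")
  connectivity_series(mi, window_s / 2 + (seq_len(nrow(mi)) - 1) * step_s,
                      pairs, band, window_s, step_s, normalized)
}

# two well-separated Gaussian clouds as a decoding feature set
sep_features <- function(n = 120, d = 4, delta = 6, seed = 51) {
  set.seed(seed)
  n1 <- n %/% 2; n2 <- n - n1
  x <- rbind(matrix(rnorm(n1 * d), ncol = d),
             matrix(rnorm(n2 * d, mean = delta), ncol = d))
  list(x = x, y = factor(rep(c("AS", "IS"), c(n1, n2))))
}

# state labels aligned with a toy series
toy_labels <- function(labs) {
  structure(list(labels = factor(labs, levels = c("AS", "IS", "EXCLUDED")),
                 n_as = sum(labs == "AS"), n_is = sum(labs == "IS"),
                 policy = "strict", threshold = NA_real_,
                 baseline_mu = NA_real_, baseline_sigma = NA_real_),
            class = "state_labels")
}
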