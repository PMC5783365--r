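#' EMG envelope
#'
#' Full-wave rectification followed by a centred 100 ms moving average, the
#' standard EMG-onset envelope.
#'
#' @param emg numeric EMG trace.
#' @param fs sampling rate, Hz.
#' @param smooth_s moving-average length, seconds (default 0.1).
#' @return numeric envelope, same length.
#' @export
emg_envelope <- function(emg, fs, smooth_s = 0.1) {
  w <- max(1L, round(smooth_s * fs))
  env <- as.numeric(stats::filter(abs(emg), rep(1 / w, w), sides = 2))
  # fill the half-window edges with the nearest computed value
  idx <- which(!is.na(env))
  if (length(idx) && idx[1] > 1) env[seq_len(idx[1] - 1)] <- env[idx[1]]
  last <- idx[length(idx)]
  if (length(idx) && last < length(env))
    env[(last + 1):length(env)] <- env[last]
  env
}

#' Resting-baseline EMG threshold
#'
#' Computes the mean and SD of the EMG envelope over a 1 s resting window and
#' returns the activity threshold `mu + 3 sigma`.
#'
#' @param emg raw EMG trace.
#' @param fs sampling rate, Hz.
#' @param baseline length-2 numeric `(start_s, end_s)` of a 1 s rest window.
#' @return list with `threshold`, `baseline_mu`, `baseline_sigma`,
#'   `baseline` (the window used).
#' @export
emg_threshold <- function(emg, fs, baseline) {
  if (length(baseline) != 2) stop("baseline must be (start_s, end_s)")
  n <- round((baseline[2] - baseline[1]) * fs)
  if (abs(n - round(fs)) > 1)
    stop("baseline window must be 1 s long (within one sample)")
  env <- emg_envelope(emg, fs)
  i0 <- round(baseline[1] * fs) + 1
  i1 <- i0 + n - 1
  if (i0 < 1 || i1 > length(emg)) stop("baseline window outside the session")
  seg <- env[i0:i1]
  mu <- mean(seg); sigma <- sd(seg)
  if (sigma == 0) stop("degenerate baseline: constant EMG (sigma = 0)")
  list(threshold = mu + 3 * sigma, baseline_mu = mu, baseline_sigma = sigma,
       baseline = baseline)
}

#' Pick a resting baseline window automatically
#'
#' Two-pass default: a provisional threshold from low-percentile session
#' statistics flags candidate bursts; the first 1 s interval at least 1 s
#' away from any candidate burst becomes the baseline.
#'
#' @param emg raw EMG trace.
#' @param fs sampling rate, Hz.
#' @return length-2 numeric `(start_s, end_s)`.
#' @export
find_rest_baseline <- function(emg, fs) {
  env <- emg_envelope(emg, fs)
  q <- quantile(env, c(0.25, 0.75))
  prov <- q[2] + 3 * (q[2] - q[1])             # provisional upper fence
  busy <- env > prov
  # dilate busy regions by 1 s each side
  w <- round(fs)
  busy <- as.logical(stats::filter(as.numeric(busy), rep(1, 2 * w + 1),
                                   sides = 2, circular = FALSE) > 0)
  busy[is.na(busy)] <- TRUE
  free <- !busy
  run <- rle(free)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  ok <- which(run$values & run$lengths >= w)
  if (!length(ok)) stop("no 1 s rest interval found for the baseline")
  s <- starts[ok[1]]
  c((s - 1) / fs, (s - 1) / fs + 1)
}

#' Detect movement events from the EMG
#'
#' Active intervals are maximal runs where the EMG envelope exceeds the
#' threshold, after debouncing: gaps shorter than 200 ms are bridged, then
#' runs shorter than 200 ms are dropped.
#'
#' @param emg raw EMG trace.
#' @param fs sampling rate, Hz.
#' @param threshold activity threshold from [emg_threshold()].
#' @param debounce_s minimum run/gap duration, seconds (default 0.2).
#' @return an [event_table()] with `source = "emg_detected"`; empty (with a
#'   warning) if the envelope never crosses the threshold.
#' @export
detect_events <- function(emg, fs, threshold, debounce_s = 0.2) {
  env <- emg_envelope(emg, fs)
  active <- env > threshold
  if (!any(active)) {
    warning("EMG envelope never exceeds the threshold; empty event table")
    return(event_table(numeric(0), numeric(0), "emg_detected"))
  }
  nmin <- round(debounce_s * fs)
  runs <- rle(active)
  # drop short active runs (threshold chatter), ...
  short <- runs$values & runs$lengths < nmin
  runs$values[short] <- FALSE
  runs <- rle(inverse.rle(runs))
  # ... then bridge short inactive gaps (not at the edges)
  if (length(runs$lengths) > 2) {
    inner <- seq(2, length(runs$lengths) - 1)
    bridge <- inner[!runs$values[inner] & runs$lengths[inner] < nmin]
    runs$values[bridge] <- TRUE
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  on <- (starts[runs$values] - 1) / fs
  off <- ends[runs$values] / fs
  if (!length(on)) {
    warning("no event survives debouncing; empty event table")
    return(event_table(numeric(0), numeric(0), "emg_detected"))
  }
  event_table(on, off, "emg_detected")
}

#' Label connectivity windows as active / idle
#'
#' A window is `AS` when its centre lies inside any event and `IS` otherwise.
#' Under `policy = "strict"` a window whose 1 s extent straddles an event
#' onset or offset is `EXCLUDED`; `policy = "center"` keeps every window.
#'
#' @param series a [connectivity_series()] (defines the window grid).
#' @param events an [event_table()].
#' @param policy `"strict"` (default) or `"center"`.
#' @param threshold_info optional list from [emg_threshold()], stored in the
#'   result.
#' @return object of class `state_labels`: list with `labels` (factor
#'   `AS`/`IS`/`EXCLUDED` per window), `n_as`, `n_is`, `policy`, and the
#'   threshold fields.
#' @export
label_windows <- function(series, events, policy = c("strict", "center"),
                          threshold_info = NULL) {
  stopifnot(inherits(series, "connectivity_series"))
  policy <- match.arg(policy)
  centers <- series$window_centers
  half <- series$window_s / 2
  lab <- rep("IS", length(centers))
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]; off <- events$offset_s[i]
    lab[centers >= on & centers <= off] <- "AS"
    if (policy == "strict") {
      straddle_on <- centers - half < on & centers + half > on
      straddle_off <- centers - half < off & centers + half > off
      lab[straddle_on | straddle_off] <- "EXCLUDED"
    }
  }
  lab <- factor(lab, levels = c("AS", "IS", "EXCLUDED"))
  structure(list(labels = lab, n_as = sum(lab == "AS"), n_is = sum(lab == "IS"),
                 policy = policy,
                 threshold = threshold_info$threshold,
                 baseline_mu = threshold_info$baseline_mu,
                 baseline_sigma = threshold_info$baseline_sigma),
            class = "state_labels")
}

#' @export
print.state_labels <- function(x, ...) {
  cat(sprintf("<state_labels: AS = %d, IS = %d, EXCLUDED = %d (policy %s)>\n",
              x$n_as, x$n_is, sum(x$labels == "EXCLUDED"), x$policy))
  invisible(x)
}

#' Event-locked connectivity epochs
#'
#' Extracts, for each event, the stack of connectivity windows around the
#' movement onset (`[-2000, +500]` ms) or offset (`[-500, +2000]` ms): 26
#' frames at the default 100 ms step. Events whose epoch span falls outside
#' the session are dropped.
#'
#' @param series a [connectivity_series()].
#' @param events an [event_table()].
#' @param lock `"onset"` or `"offset"`.
#' @return list with `epochs` (array trials x frames x pairs), `average`
#'   (frames x pairs trial average), `frame_times_s` (relative to the lock),
#'   `kept` (indices of retained events).
#' @export
extract_epochs <- function(series, events, lock = c("onset", "offset")) {
  stopifnot(inherits(series, "connectivity_series"))
  lock <- match.arg(lock)
  span <- if (lock == "onset") c(-2.0, 0.5) else c(-0.5, 2.0)
  step <- series$step_s
  nframe <- as.integer(round(diff(span) / step)) + 1L
  centers <- series$window_centers
  tlock <- if (lock == "onset") events$onset_s else events$offset_s
  kept <- integer(0)
  stacks <- list()
  for (i in seq_along(tlock)) {
    i0 <- which.min(abs(centers - (tlock[i] + span[1])))
    idx <- i0 + seq_len(nframe) - 1L
    if (abs(centers[i0] - (tlock[i] + span[1])) > step / 2 + 1e-9 ||
        idx[nframe] > length(centers)) {
      message("dropping event ", i, ": epoch span outside the session")
      next
    }
    kept <- c(kept, i)
    stacks[[length(stacks) + 1]] <- series$mi[idx, , drop = FALSE]
  }
  if (!length(kept)) stop("no event has full epoch coverage")
  epochs <- array(NA_real_, c(length(kept), nframe, ncol(series$mi)))
  for (j in seq_along(stacks)) epochs[j, , ] <- stacks[[j]]
  avg <- apply(epochs, c(2, 3), mean)
  list(epochs = epochs, average = avg,
       frame_times_s = span[1] + (seq_len(nframe) - 1) * step, kept = kept)
}
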