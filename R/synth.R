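#' Synthetic session configuration
#'
#' Defaults mirror the study protocol this pipeline targets: a 5-minute
#' session at 1000 Hz, 25-39 self-paced grasps with at least 5 s between
#' consecutive onsets, about 10 M1 and 9 DLPFC channels, and a gamma-band
#' (30-50 Hz) cross-channel coupling that ramps up from ~600 ms before
#' movement onset, plateaus during the grasp and decays after offset.
#'
#' @param duration_s session length, seconds.
#' @param fs sampling rate, Hz.
#' @param n_m1,n_dlpfc channel counts for the two simulated regions.
#' @param n_other additional non-analysis background channels (a real grid
#'   carries 64-72 electrodes of which only the M1/DLPFC subset is
#'   analysed); they take part in the common average reference only.
#' @param n_trials number of grasp events (protocol range 25-39).
#' @param min_inter_onset_s minimum onset-to-onset interval, seconds.
#' @param grasp_duration_s length-2 range the per-trial grasp duration is
#'   drawn from, seconds.
#' @param coupling_strength shared gamma-source mixing coefficient reached
#'   during movement, dimensionless in `[0, 1]` (units of the background
#'   gamma-band SD).
#' @param coupling_ramp_s pre-onset ramp / post-offset decay length, seconds.
#' @param idle_coupling baseline mixing coefficient at rest.
#' @param noise_sd broadband background SD per channel, microvolts.
#' @param emg_noise_sd EMG rest-noise SD (arbitrary EMG units).
#' @param emg_burst_gain multiplicative EMG burst amplitude relative to rest
#'   noise.
#' @param line_amp amplitude of an optional 60 Hz line-noise sinusoid
#'   (microvolts); 0 disables it. Used to exercise the notch filter.
#' @param seed integer RNG seed; the whole session is deterministic given the
#'   config.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(duration_s = 300, fs = 1000, n_m1 = 10, n_dlpfc = 9,
                         n_other = 45,
                         n_trials = 30, min_inter_onset_s = 5,
                         grasp_duration_s = c(1.0, 2.5),
                         coupling_strength = 0.8, coupling_ramp_s = 0.6,
                         idle_coupling = 0.05, noise_sd = 10,
                         emg_noise_sd = 1, emg_burst_gain = 6,
                         line_amp = 0, seed = 1L) {
  cfg <- list(duration_s = duration_s, fs = fs, n_m1 = n_m1, n_dlpfc = n_dlpfc,
              n_other = n_other,
              n_trials = n_trials, min_inter_onset_s = min_inter_onset_s,
              grasp_duration_s = sort(grasp_duration_s),
              coupling_strength = coupling_strength,
              coupling_ramp_s = coupling_ramp_s, idle_coupling = idle_coupling,
              noise_sd = noise_sd, emg_noise_sd = emg_noise_sd,
              emg_burst_gain = emg_burst_gain, line_amp = line_amp,
              seed = as.integer(seed))
  if (cfg$duration_s <= 0 || cfg$fs <= 0) stop("duration_s and fs must be positive")
  if (cfg$n_trials * cfg$min_inter_onset_s >= cfg$duration_s)
    stop("configuration error: n_trials x min_inter_onset_s must be < duration_s")
  if (cfg$idle_coupling < 0 || cfg$idle_coupling > cfg$coupling_strength ||
      cfg$coupling_strength > 1)
    stop("need 0 <= idle_coupling <= coupling_strength <= 1")
  structure(cfg, class = "synth_config")
}

#' Draw a protocol-conforming grasp event table
#'
#' Places `n_trials` non-overlapping grasp events inside
#' `[5, duration_s - 5]` seconds with all consecutive onset-to-onset gaps at
#' least `min_inter_onset_s`; slack time is spread randomly between trials.
#'
#' @param config a [synth_config()].
#' @return an [event_table()] with `source = "ground_truth"`.
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_trials
  if (n == 0)
    return(event_table(numeric(0), numeric(0), "ground_truth",
                       config$min_inter_onset_s))
  dmax <- config$grasp_duration_s[2]
  usable <- config$duration_s - 10            # 5 s guard at each session edge
  need <- (n - 1) * config$min_inter_onset_s + dmax
  if (need > usable)
    stop("configuration error: cannot pack ", n, " trials with ",
         config$min_inter_onset_s, " s spacing into ", config$duration_s, " s")
  set.seed(config$seed)
  durations <- runif(n, config$grasp_duration_s[1], config$grasp_duration_s[2])
  slack <- usable - (n - 1) * config$min_inter_onset_s - durations[n]
  extra <- runif(n)                            # n gaps: before trial 1..n
  extra <- extra / sum(extra) * slack
  onsets <- 5 + cumsum(extra) + (seq_len(n) - 1) * config$min_inter_onset_s
  event_table(onsets, onsets + durations, "ground_truth",
              config$min_inter_onset_s)
}

#' Per-sample coupling-coefficient trace
#'
#' Piecewise-linear profile: `idle_coupling` at rest, a linear ramp from
#' `idle_coupling` to `coupling_strength` over `[onset - ramp, onset]`, a
#' plateau until offset, and a linear decay back over
#' `[offset, offset + ramp]`. Overlapping bumps are resolved by the pointwise
#' maximum.
#'
#' @param events an [event_table()].
#' @param config a [synth_config()].
#' @return numeric vector of length `duration_s * fs`.
#' @export
coupling_profile <- function(events, config) {
  n <- round(config$duration_s * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  prof <- rep(config$idle_coupling, n)
  lo <- config$idle_coupling; hi <- config$coupling_strength
  ramp <- config$coupling_ramp_s
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]; off <- events$offset_s[i]
    bump <- rep(0, n)
    up <- t >= on - ramp & t < on
    bump[up] <- lo + (hi - lo) * (t[up] - (on - ramp)) / ramp
    bump[t >= on & t <= off] <- hi
    dn <- t > off & t <= off + ramp
    bump[dn] <- hi - (hi - lo) * (t[dn] - off) / ramp
    prof <- pmax(prof, bump)
  }
  pmin(prof, hi)
}

# Band-limited Gaussian noise via frequency-domain masking; unit SD.
band_noise <- function(n, fs, low, high) {
  freqs <- (0:(n - 1)) * fs / n
  f <- pmin(freqs, fs - freqs)                 # two-sided frequency axis
  spec <- fft(rnorm(n))
  spec[f < low | f > high] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

# 1/f-shaped broadband background plus mild alpha/beta oscillatory bumps.
pink_background <- function(n, fs) {
  freqs <- (0:(n - 1)) * fs / n
  f <- pmin(freqs, fs - freqs)
  amp <- 1 / sqrt(pmax(f, 1))                  # flat below 1 Hz, 1/f above
  amp <- amp + 0.6 * exp(-(f - 10)^2 / (2 * 2^2)) + 0.3 * exp(-(f - 20)^2 / (2 * 3^2))
  amp[1] <- 0                                  # zero mean
  spec <- fft(rnorm(n)) * amp
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate a full synthetic session
#'
#' Each channel is 1/f-shaped broadband noise with alpha/beta oscillatory
#' bumps. During coupled periods, gamma-band (30-50 Hz) sources are mixed in
#' scaled by the coupling profile: every DLPFC channel drives its own gamma
#' source, every M1 channel mixes all the DLPFC sources (inter-regional
#' transmission) plus one gamma source shared among the M1 channels
#' (intra-M1 synchrony). This makes the active-state MI contrast strong
#' within M1, intermediate for DLPFC-M1 pairs and absent within DLPFC —
#' distinct DLPFC channels share no source — which is the ordering the
#' analysis is designed to detect. Source polarity varies per electrode
#' (dipole orientation), keeping the sources out of the common average.
#' The EMG trace is rest noise with a slow tone modulation plus burst noise
#' spanning each grasp.
#'
#' @param config a [synth_config()].
#' @return list with elements `recording` (a [recording()]; channels
#'   `M1_01..`, `DLPFC_01..` with matching region map and EMG attached) and
#'   `truth` (list: `events`, `coupling_profile`, `gains`, `seed`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  events <- generate_events(config)            # seeds the RNG with config$seed
  prof <- coupling_profile(events, config)
  n <- round(config$duration_s * config$fs)
  fs <- config$fs
  n_ch <- config$n_m1 + config$n_dlpfc + config$n_other
  ids <- c(sprintf("M1_%02d", seq_len(config$n_m1)),
           sprintf("DLPFC_%02d", seq_len(config$n_dlpfc)),
           sprintf("OTHER_%02d", seq_len(config$n_other)))
  regions <- stats::setNames(
    rep(c("M1", "DLPFC", "OTHER"),
        c(config$n_m1, config$n_dlpfc, config$n_other)), ids)

  # gamma sources (unit SD, 30-50 Hz): one per DLPFC channel plus one shared
  # within M1
  u_dlpfc <- lapply(seq_len(config$n_dlpfc), function(i) band_noise(n, fs, 30, 50))
  s_m1 <- band_noise(n, fs, 30, 50)

  # background, and its gamma-band SD used to scale the sources so the
  # coupling coefficients are in units of background gamma power
  bg <- matrix(0, n_ch, n)
  for (c in seq_len(n_ch)) bg[c, ] <- pink_background(n, fs) * config$noise_sd
  gref <- band_noise_sd_gamma(bg[1, ], fs)

  # per-channel source gains; the sign models electrode-dependent dipole
  # polarity (MI is sign-blind, and signed gains keep the sources out of the
  # common average)
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  g_m1 <- runif(config$n_m1, 0.6, 1.0) * sgn(config$n_m1)
  g_dlpfc <- runif(config$n_dlpfc, 0.5, 0.9) * sgn(config$n_dlpfc)
  w_inter <- matrix(runif(config$n_m1 * config$n_dlpfc, 0.15, 0.35) *
                      sgn(config$n_m1 * config$n_dlpfc),
                    config$n_m1, config$n_dlpfc)

  sig <- bg
  for (j in seq_len(config$n_m1)) {
    mix <- g_m1[j] * s_m1
    for (i in seq_len(config$n_dlpfc)) mix <- mix + w_inter[j, i] * u_dlpfc[[i]]
    sig[j, ] <- sig[j, ] + prof * gref * mix
  }
  for (i in seq_len(config$n_dlpfc)) {
    c <- config$n_m1 + i
    sig[c, ] <- sig[c, ] + prof * g_dlpfc[i] * gref * u_dlpfc[[i]]
  }
  if (config$line_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    sig <- sig + matrix(config$line_amp * sin(2 * pi * 60 * t), n_ch, n,
                        byrow = TRUE)
  }

  # EMG: rest noise + burst noise with 20 ms cosine ramps at event edges
  burst_env <- rep(0, n)
  t <- (seq_len(n) - 1) / fs
  rampn <- round(0.02 * fs)
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$onset_s[i] * fs) + 1
    i1 <- min(round(events$offset_s[i] * fs) + 1, n)
    burst_env[i0:i1] <- 1
    up <- i0:min(i0 + rampn - 1, n)
    burst_env[up] <- pmax(burst_env[up] * (1 - cos(pi * seq_along(up) / rampn)) / 2, 0)
    dn <- i1:min(i1 + rampn - 1, n)
    burst_env[dn] <- pmax((1 + cos(pi * (seq_along(dn) - 1) / rampn)) / 2, 0)
  }
  # rest noise carries a slow amplitude-modulated muscle tone (~2.2 Hz),
  # which dominates the resting envelope SD and so sets the mu + 3 sigma
  # threshold well clear of instantaneous noise excursions
  tone <- 1 + 0.6 * sin(2 * pi * 2.2 * t + runif(1) * 2 * pi)
  emg <- config$emg_noise_sd * rnorm(n) * tone +
    burst_env * config$emg_burst_gain * config$emg_noise_sd * rnorm(n)

  rec <- recording(sig, fs, ids, regions, emg = emg,
                   session_id = sprintf("synthetic-seed%d", config$seed))
  list(recording = rec,
       truth = list(events = events, coupling_profile = prof,
                    gains = list(m1 = g_m1, dlpfc = g_dlpfc,
                                 inter = w_inter),
                    seed = config$seed))
}

# gamma-band (30-50 Hz) SD of a trace, by frequency-domain masking
band_noise_sd_gamma <- function(x, fs) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  f <- pmin(freqs, fs - freqs)
  spec <- fft(x)
  spec[f < 30 | f > 50] <- 0
  sd(Re(fft(spec, inverse = TRUE)) / n)
}
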