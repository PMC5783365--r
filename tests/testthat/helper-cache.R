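# Heavy multi-seed pipeline results, computed once per test run and shared
# between test files. Default generator settings throughout; 20 seeds.

.session_cache <- new.env(parent = emptyenv())

# run the full analysis for one seed; keep summaries only
analyse_session <- function(seed, keep_series = FALSE) {
  cfg <- synth_config(seed = seed)
  ses <- generate_session(cfg)
  rec <- ses$recording
  analysis <- rec$channel_ids[rec$region_map[rec$channel_ids] != "OTHER"]
  rec <- preprocess_recording(rec, analysis_channels = analysis)

  thr <- emg_threshold(rec$emg, rec$fs, find_rest_baseline(rec$emg, rec$fs))
  events <- detect_events(rec$emg, rec$fs, thr$threshold)
  truth <- ses$truth$events
  recovery <- list(
    n_detected = nrow(events), n_true = nrow(truth),
    max_err = if (nrow(events) == nrow(truth))
      max(abs(events$onset_s - truth$onset_s),
          abs(events$offset_s - truth$offset_s)) else Inf)

  nets <- list(M1 = network_definition(rec, "M1"),
               DLPFC = network_definition(rec, "DLPFC"),
               DLPFC_M1 = network_definition(rec, "DLPFC_M1"))
  all_pairs <- rbind(nets$M1$pairs, nets$DLPFC$pairs, nets$DLPFC_M1$pairs)

  gseries <- sliding_mi(band_filter(rec, "gamma"), all_pairs, band = "gamma")
  labels <- label_windows(gseries, events, "strict", threshold_info = thr)

  mir_gamma <- sapply(nets, function(nw) mir(gseries, labels, nw)$mir_percent)
  p_gamma <- sapply(nets, function(nw) network_rank_test(gseries, labels, nw)$p_value)

  # other bands: M1 network only (band-selectivity comparison)
  mir_m1_band <- c(gamma = unname(mir_gamma["M1"]))
  for (b in c("theta", "alpha", "beta")) {
    s <- sliding_mi(band_filter(rec, b), nets$M1, band = b)
    mir_m1_band[b] <- mir(s, labels)$mir_percent
  }

  series_by_net <- lapply(nets, function(nw) subset_pairs(gseries, nw))
  dec <- compare_networks(series_by_net, labels, seed = seed)

  out <- list(seed = seed, recovery = recovery, mir_gamma = mir_gamma,
              p_gamma = p_gamma, mir_m1_band = mir_m1_band,
              acc_m1 = dec$m1_only$mean_accuracy,
              acc_all = dec$combined$mean_accuracy,
              events = events, truth = truth)
  if (keep_series) {
    out$gamma_series <- gseries
    out$labels <- labels
    out$networks <- nets
  }
  out
}

session_results <- function(seeds = 1:20) {
  key <- paste0("seeds_", paste(range(seeds), collapse = "_"))
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- lapply(seeds, function(s)
      analyse_session(s, keep_series = (s == seeds[1])))
  }
  .session_cache[[key]]
}
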