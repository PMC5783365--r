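#' intentconn: movement-intention decoding from intracranial connectivity
#'
#' Pipeline stages: synthetic session generation ([generate_session()]),
#' preprocessing ([preprocess_recording()]), EMG state segmentation
#' ([emg_threshold()], [detect_events()], [label_windows()]), sliding-window
#' binned mutual information ([sliding_mi()]), the MIR network statistic
#' ([mir()]) with a rank test ([rank_test()]), and LDA intention decoding
#' ([cross_validate()], [compare_networks()]). [run_intention_pipeline()]
#' chains everything.
#'
#' @useDynLib intentconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor fft kruskal.test median predict quantile rnorm runif sd var
#' @importFrom utils head modifyList read.table tail write.table
#' @name intentconn-package
"_PACKAGE"

REGION_TAGS <- c("M1", "DLPFC", "OTHER")

#' Multichannel recording container
#'
#' Bundles a channels-by-time signal matrix (microvolts), its sampling rate,
#' ordered channel labels, a channel-to-region map over `{M1, DLPFC, OTHER}`
#' and an optional simultaneous surface-EMG trace of the same length.
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param fs sampling rate in Hz (1000 in the study design this mirrors).
#' @param channel_ids character vector of unique channel labels, one per row.
#' @param region_map named character vector mapping channel labels to a region
#'   tag in `{M1, DLPFC, OTHER}`; unmapped channels default to `OTHER`.
#' @param emg optional numeric EMG trace, same number of samples as `samples`
#'   columns, same sampling rate.
#' @param session_id free-text identifier.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, fs, channel_ids, region_map = NULL,
                      emg = NULL, session_id = "session") {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(samples))
    stop("channel-count mismatch: ", nrow(samples), " signal rows vs ",
         length(channel_ids), " channel labels")
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique")
  if (is.null(region_map)) region_map <- character(0)
  region_map <- vapply(region_map, as.character, "")
  if (length(region_map) && is.null(names(region_map)))
    stop("region_map must be named by channel label")
  if (!all(names(region_map) %in% channel_ids))
    stop("region_map keys must be a subset of channel_ids; unknown: ",
         paste(setdiff(names(region_map), channel_ids), collapse = ", "))
  bad <- setdiff(unique(region_map), REGION_TAGS)
  if (length(bad))
    stop("region tag outside {DLPFC, M1, OTHER}: ", paste(bad, collapse = ", "))
  full_map <- stats::setNames(rep("OTHER", length(channel_ids)), channel_ids)
  full_map[names(region_map)] <- region_map
  if (!is.null(emg)) {
    emg <- as.numeric(emg)
    if (length(emg) != ncol(samples))
      stop("emg length (", length(emg), ") must equal the number of time samples (",
           ncol(samples), ")")
  }
  rownames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 region_map = full_map, emg = emg, session_id = session_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$fs
  counts <- table(factor(x$region_map, levels = REGION_TAGS))
  cat(sprintf("<recording '%s'>  %d channels x %.1f s @ %g Hz\n",
              x$session_id, nrow(x$samples), dur, x$fs))
  cat(sprintf("  regions: M1 = %d, DLPFC = %d, OTHER = %d;  EMG: %s\n",
              counts[["M1"]], counts[["DLPFC"]], counts[["OTHER"]],
              if (is.null(x$emg)) "absent" else "present"))
  invisible(x)
}

#' Channel labels belonging to one region
#' @param rec a [recording()].
#' @param region one of `"M1"`, `"DLPFC"`, `"OTHER"`.
#' @return character vector of channel labels, in recording order.
#' @export
region_channels <- function(rec, region) {
  region <- match.arg(region, REGION_TAGS)
  rec$channel_ids[rec$region_map[rec$channel_ids] == region]
}

#' Keep a subset of channels
#'
#' @param rec a [recording()].
#' @param channels channel labels to keep (recording order preserved).
#' @return the reduced [recording()]; EMG and metadata untouched.
#' @export
subset_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "recording"))
  missing_ch <- setdiff(channels, rec$channel_ids)
  if (length(missing_ch))
    stop("unknown channels: ", paste(missing_ch, collapse = ", "))
  keep <- rec$channel_ids[rec$channel_ids %in% channels]
  recording(rec$samples[keep, , drop = FALSE], rec$fs, keep,
            rec$region_map[keep], emg = rec$emg, session_id = rec$session_id)
}

#' Movement event table
#'
#' Onset/offset times (seconds from session start) of grasp events, either
#' simulator ground truth or detected from the EMG.
#'
#' @param onsets,offsets numeric vectors, seconds; `onsets < offsets`,
#'   sorted, non-overlapping.
#' @param source `"ground_truth"` or `"emg_detected"`.
#' @param min_inter_onset_s minimum inter-grasp (onset-to-onset) interval the
#'   protocol enforces; checked when `source = "ground_truth"`.
#' @return an object of class `event_table` (a data.frame with columns
#'   `onset_s`, `offset_s` and attributes `source`).
#' @export
event_table <- function(onsets, offsets, source = c("ground_truth", "emg_detected"),
                        min_inter_onset_s = NULL) {
  source <- match.arg(source)
  onsets <- as.numeric(onsets); offsets <- as.numeric(offsets)
  if (length(onsets) != length(offsets))
    stop("onsets and offsets must have equal length")
  if (length(onsets)) {
    if (any(onsets >= offsets)) stop("every onset must precede its offset")
    if (is.unsorted(onsets, strictly = TRUE)) stop("events must be sorted by onset")
    if (length(onsets) > 1 && any(onsets[-1] < offsets[-length(offsets)]))
      stop("events must not overlap")
    if (source == "ground_truth" && !is.null(min_inter_onset_s) &&
        length(onsets) > 1 && any(diff(onsets) < min_inter_onset_s - 1e-9))
      stop("consecutive onsets violate the minimum inter-grasp interval of ",
           min_inter_onset_s, " s")
  }
  structure(data.frame(onset_s = onsets, offset_s = offsets),
            source = source, class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table, %d events, source = %s>\n", nrow(x),
              attr(x, "source")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Connectivity network definition
#'
#' An intra-regional network is the set of all C(n,2) unordered channel pairs
#' within one region; an inter-regional network is the full n x m cross
#' product of two regions.
#'
#' @param rec a [recording()].
#' @param name `"M1"`, `"DLPFC"` (intra) or `"DLPFC_M1"` (inter).
#' @return object of class `network_definition` with `name`, `mode`,
#'   `regions`, and `pairs` (2-column character matrix of channel labels;
#'   inter pairs are region-ordered DLPFC then M1).
#' @export
network_definition <- function(rec, name = c("M1", "DLPFC", "DLPFC_M1")) {
  name <- match.arg(name)
  if (name %in% c("M1", "DLPFC")) {
    ch <- region_channels(rec, name)
    if (length(ch) < 2) stop("region ", name, " needs >= 2 channels")
    idx <- utils::combn(ch, 2)
    pairs <- cbind(idx[1, ], idx[2, ])
    mode <- "intra"; regions <- name
  } else {
    a <- region_channels(rec, "DLPFC"); b <- region_channels(rec, "M1")
    if (!length(a) || !length(b)) stop("DLPFC_M1 network needs channels in both regions")
    pairs <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
    mode <- "inter"; regions <- c("DLPFC", "M1")
  }
  colnames(pairs) <- c("channel_a", "channel_b")
  structure(list(name = name, mode = mode, regions = regions, pairs = pairs),
            class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat(sprintf("<network '%s' (%s), %d pairs>\n", x$name, x$mode, nrow(x$pairs)))
  invisible(x)
}

#' Sliding-window connectivity series
#'
#' Windows x pairs matrix of mutual-information values (nats) for one
#' frequency band and one pair set, with window-center timestamps.
#'
#' @param mi numeric matrix, windows x pairs, MI in nats (or in `[0, 1]` when
#'   normalized).
#' @param window_centers window-center times in seconds, strictly increasing
#'   on a constant step.
#' @param pairs 2-column character matrix of channel pairs.
#' @param band band name (`theta`/`alpha`/`beta`/`gamma`) or `"broadband"`.
#' @param window_s,step_s analysis window length and step, seconds.
#' @param normalized logical; `TRUE` after [normalize_session()].
#' @param bias_corrected logical; `TRUE` when the MI values carry a
#'   Miller-Madow correction, which may legitimately be negative.
#' @return object of class `connectivity_series`.
#' @export
connectivity_series <- function(mi, window_centers, pairs, band,
                                window_s, step_s, normalized = FALSE,
                                bias_corrected = FALSE) {
  mi <- as.matrix(mi)
  if (nrow(mi) != length(window_centers))
    stop("mi rows must match window_centers length")
  if (ncol(mi) != nrow(pairs)) stop("mi columns must match pair count")
  if (length(window_centers) > 1) {
    d <- diff(window_centers)
    if (any(d <= 0)) stop("window_centers must be strictly increasing")
    if (max(d) - min(d) > 1e-6) stop("window_centers must have a constant step")
  }
  if (!normalized && !bias_corrected && any(mi < -1e-12))
    stop("unnormalized MI must be >= 0")
  if (normalized && (any(mi < -1e-12) || any(mi > 1 + 1e-12)))
    stop("normalized MI must lie in [0, 1]")
  colnames(mi) <- paste(pairs[, 1], pairs[, 2], sep = "~")
  structure(list(mi = mi, window_centers = as.numeric(window_centers),
                 pairs = pairs, band = band, window_s = window_s,
                 step_s = step_s, normalized = normalized,
                 bias_corrected = bias_corrected),
            class = "connectivity_series")
}

#' @export
print.connectivity_series <- function(x, ...) {
  cat(sprintf("<connectivity_series: %s band, %d windows x %d pairs%s>\n",
              x$band, nrow(x$mi), ncol(x$mi),
              if (x$normalized) ", normalized" else ""))
  cat(sprintf("  window %g s / step %g s, centers %.2f..%.2f s\n",
              x$window_s, x$step_s, min(x$window_centers), max(x$window_centers)))
  invisible(x)
}

#' Restrict a connectivity series to a network's pairs
#'
#' @param series a [connectivity_series()] whose pairs are a superset of the
#'   network's pairs.
#' @param network a [network_definition()].
#' @return a [connectivity_series()] holding exactly the network's pairs, in
#'   network order.
#' @export
subset_pairs <- function(series, network) {
  key <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]), sep = "~")
  have <- key(series$pairs)
  want <- key(network$pairs)
  idx <- match(want, have)
  if (anyNA(idx))
    stop("series is missing pairs required by network ", network$name)
  connectivity_series(series$mi[, idx, drop = FALSE], series$window_centers,
                      network$pairs, series$band, series$window_s,
                      series$step_s, series$normalized,
                      isTRUE(series$bias_corrected))
}
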