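#' Write a recording to the native container
#'
#' The native format is a directory holding `meta.json` (sampling rate,
#' channel order, region map, session id) and `signals.feather`, an Arrow
#' Feather table with one float64 column per channel (plus `.emg` when an
#' EMG trace is attached). Feather preserves full double precision, so the
#' round trip is lossless.
#'
#' @param rec a [recording()].
#' @param path directory path (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(fs = rec$fs, channel_ids = rec$channel_ids,
               region_map = as.list(rec$region_map),
               session_id = rec$session_id, has_emg = !is.null(rec$emg))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channel_ids
  if (!is.null(rec$emg)) df[[".emg"]] <- rec$emg
  arrow::write_feather(df, file.path(path, "signals.feather"))
  invisible(path)
}

read_native <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  df <- as.data.frame(arrow::read_feather(file.path(path, "signals.feather")))
  emg <- if (isTRUE(meta$has_emg)) df[[".emg"]] else NULL
  sig <- t(as.matrix(df[, meta$channel_ids, drop = FALSE]))
  recording(sig, as.numeric(meta$fs), meta$channel_ids, unlist(meta$region_map),
            emg = emg, session_id = meta$session_id)
}

#' Read a channel-to-region map
#'
#' Accepts JSON (an object mapping channel label to region tag) or a
#' two-column TSV (`channel`, `region`, no header required). Tags must be in
#' `{DLPFC, M1, OTHER}`.
#'
#' @param path file path ending in `.json` or `.tsv`/`.txt`.
#' @return named character vector (channel -> region).
#' @export
read_region_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    map <- stats::setNames(as.character(unlist(m)), names(m))
  } else if (ext %in% c("tsv", "txt")) {
    d <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("channel", "region"),
                    colClasses = "character")
    if (tolower(d$channel[1]) == "channel") d <- d[-1, , drop = FALSE]
    map <- stats::setNames(d$region, d$channel)
  } else stop("format error: region map must be .json or .tsv, got .", ext)
  bad <- setdiff(unique(map), REGION_TAGS)
  if (length(bad))
    stop("region tag outside {DLPFC, M1, OTHER}: ", paste(bad, collapse = ", "))
  map
}

#' Read a recording from EDF or the native container
#'
#' @param path an `.edf` file or a native container directory (see
#'   [write_recording()]).
#' @param region_map_path optional JSON/TSV region map
#'   ([read_region_map()]); channels absent from the map default to `OTHER`.
#'   For the native container the stored map is used when this is `NULL`.
#' @param emg_channel for EDF input, the label of the channel holding the
#'   EMG trace (removed from the signal matrix and attached as `emg`).
#' @return a [recording()].
#' @export
read_recording <- function(path, region_map_path = NULL, emg_channel = NULL) {
  if (dir.exists(path)) {
    rec <- read_native(path)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext != "edf")
      stop("format error: unknown extension .", ext,
           " (expected .edf or a native container directory)")
    rec <- read_edf(path, emg_channel = emg_channel)
  }
  if (!is.null(region_map_path)) {
    map <- read_region_map(region_map_path)
    map <- map[intersect(names(map), rec$channel_ids)]
    rec <- recording(rec$samples, rec$fs, rec$channel_ids, map,
                     emg = rec$emg, session_id = rec$session_id)
  }
  rec
}

# ---- minimal EDF reader/writer -------------------------------------------
# Continuous EDF with a common sampling rate across channels; samples are
# int16 scaled over each channel's physical range (EDF's 16-bit quantization
# is inherent to the format; the native container is float-exact).

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording as EDF
#'
#' @param rec a [recording()]; the EMG trace, when present, becomes a channel
#'   labeled `EMG`.
#' @param path output `.edf` path.
#' @param record_s data-record length, seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  sig <- rec$samples
  labels <- rec$channel_ids
  if (!is.null(rec$emg)) {
    sig <- rbind(sig, rec$emg)
    labels <- c(labels, "EMG")
  }
  ns <- nrow(sig)
  spr <- round(record_s * rec$fs)              # samples per record per channel
  n_rec <- floor(ncol(sig) / spr)
  sig <- sig[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad(rec$session_id, 80),
                edf_pad("recording", 80),
                edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
                edf_pad(as.character(256 * (ns + 1)), 8), edf_pad("", 44),
                edf_pad(as.character(n_rec), 8),
                edf_pad(format(record_s), 8), edf_pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)
  field(format(pmin_, digits = 7), 8)
  field(format(pmax_, digits = 7), 8)
  field(rep(as.character(dmin), ns), 8)
  field(rep(as.character(dmax), ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(as.character(spr), ns), 8)
  field(rep("", ns), 32)                       # reserved
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (c in seq_len(ns)) {
      dig <- round((sig[c, cols] - pmin_[c]) * scale[c] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path `.edf` file.
#' @param emg_channel optional channel label to detach as the EMG trace.
#' @return a [recording()] (all regions `OTHER` until a map is supplied).
#' @export
read_edf <- function(path, emg_channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                        # version
  session_id <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("structural error: differing per-channel sampling rates")
  fs <- spr[1] / record_s
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (c in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[1], size = 2, endian = "little")
      sig[c, cols] <- (dig - dmin[c]) / (dmax[c] - dmin[c]) *
        (pmax_[c] - pmin_[c]) + pmin_[c]
    }
  }
  emg <- NULL
  if (!is.null(emg_channel) && emg_channel %in% labels) {
    emg <- sig[labels == emg_channel, ]
    keep <- labels != emg_channel
    sig <- sig[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  recording(sig, fs, labels, emg = emg, session_id = session_id)
}

# ---- connectivity TSV -----------------------------------------------------

#' Write a connectivity series as long-format TSV
#'
#' One data row per (window, pair) with columns `window_center_s`,
#' `channel_a`, `channel_b`, `band`, `mi`, `normalized`; a commented header
#' carries band, window length and step. Values are printed at full double
#' precision so the round trip is bitwise exact.
#'
#' @param series a [connectivity_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(series, path) {
  stopifnot(inherits(series, "connectivity_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band=%s window_s=%.17g step_s=%.17g normalized=%s",
                     series$band, series$window_s, series$step_s,
                     series$normalized), con)
  writeLines("window_center_s\tchannel_a\tchannel_b\tband\tmi\tnormalized", con)
  if (ncol(series$mi) == 0) {
    warning("empty pair list: writing a header-only connectivity file")
    return(invisible(path))
  }
  nw <- nrow(series$mi); np <- ncol(series$mi)
  rows <- sprintf("%.17g\t%s\t%s\t%s\t%.17g\t%s",
                  rep(series$window_centers, np),
                  rep(series$pairs[, 1], each = nw),
                  rep(series$pairs[, 2], each = nw),
                  series$band, as.vector(series$mi), series$normalized)
  writeLines(rows, con)
  invisible(path)
}

#' Read a connectivity TSV written by [write_connectivity()]
#'
#' @param path TSV path.
#' @return a [connectivity_series()].
#' @export
read_connectivity <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  d <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  colClasses = c("numeric", "character", "character",
                                 "character", "numeric", "logical"))
  key <- paste(d$channel_a, d$channel_b, sep = "\r")
  pair_keys <- unique(key)
  centers <- unique(d$window_center_s)
  mi <- matrix(d$mi, nrow = length(centers), ncol = length(pair_keys))
  pairs <- do.call(rbind, strsplit(pair_keys, "\r", fixed = TRUE))
  colnames(pairs) <- c("channel_a", "channel_b")
  connectivity_series(mi, centers, pairs, band = meta[["band"]],
                      window_s = as.numeric(meta[["window_s"]]),
                      step_s = as.numeric(meta[["step_s"]]),
                      normalized = as.logical(meta[["normalized"]]))
}

#' Serialize pipeline results as JSON
#'
#' Works for `mir_result`, `kw_test_result`, `decoding_result`,
#' `event_table`, `state_labels` and plain lists.
#'
#' @param x result object.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.factor(x)) as.character(x)
  else if (is.table(x)) as.matrix(x)
  else x
}
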