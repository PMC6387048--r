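# Minimal EDF (European Data Format) support: 16-bit continuous signals, one
# common sampling rate, 1-s data records.  Covers the polysomnography use case
# (read a multichannel recording, write synthetic ones); EDF+ annotation
# channels are skipped on read.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits with per-channel symmetric physical
#' ranges; data records last 1 s, so the sampling rate must be an integer and
#' any trailing partial second is dropped (with a warning).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) {
    rps_error("EDF writer requires an integer sampling rate", "rps_usage_error")
  }
  n <- nrow(rec$signals)
  n_rec <- floor(ncol(rec$signals) / fs)
  if (n_rec < 1) rps_error("recording shorter than one data record",
                           "rps_usage_error")
  if (n_rec * fs < ncol(rec$signals)) {
    warning("trailing partial second dropped when writing EDF")
  }
  X <- rec$signals[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- pmax(apply(abs(X), 1, max), 1e-6)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (n + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(n, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_names, pad_field, "", width = 16),
    rep(pad_field("", 80), n),
    rep(pad_field("uV", 8), n),
    vapply(sprintf("%.6g", -pmax_), pad_field, "", width = 8),
    vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
    rep(pad_field("-32767", 8), n),
    rep(pad_field("32767", 8), n),
    rep(pad_field("", 80), n),
    rep(pad_field(fs, 8), n),
    rep(pad_field("", 32), n))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  dig <- round(X / pmax_ * 32767)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- t(dig[, cols, drop = FALSE])  # per signal contiguous
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_header_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read an EDF file
#'
#' @param path EDF/EDF+ file path.
#' @param channels Optional character vector of channel labels to keep (in the
#'   requested order); an unknown label is a format error.
#' @return An `eeg_recording` (signals in physical units).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path) || file.size(path) < 256) {
    rps_error("not a readable EDF file (missing or truncated header)",
              "rps_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                      # version
  readChar(con, 160, useBytes = TRUE)                    # patient + recording
  readChar(con, 16, useBytes = TRUE)                     # date + time
  hdr_bytes <- suppressWarnings(as.integer(read_header_field(con, 8)))
  readChar(con, 44, useBytes = TRUE)
  n_rec <- suppressWarnings(as.integer(read_header_field(con, 8)))
  rec_dur <- suppressWarnings(as.numeric(read_header_field(con, 8)))
  ns <- suppressWarnings(as.integer(read_header_field(con, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    rps_error("unreadable EDF header", "rps_format_error")
  }
  if (file.size(path) < 256 * (ns + 1)) {
    rps_error("truncated EDF signal headers", "rps_format_error")
  }
  labels <- vapply(seq_len(ns), function(i) read_header_field(con, 16), "")
  readChar(con, 80 * ns, useBytes = TRUE)                # transducer
  readChar(con, 8 * ns, useBytes = TRUE)                 # physical dimension
  phys_min <- vapply(seq_len(ns), function(i)
    as.numeric(read_header_field(con, 8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i)
    as.numeric(read_header_field(con, 8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i)
    as.numeric(read_header_field(con, 8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i)
    as.numeric(read_header_field(con, 8)), numeric(1))
  readChar(con, 80 * ns, useBytes = TRUE)                # prefiltering
  spr <- vapply(seq_len(ns), function(i)
    as.integer(read_header_field(con, 8)), integer(1))
  readChar(con, 32 * ns, useBytes = TRUE)

  keep <- which(labels != "EDF Annotations")
  if (length(keep) == 0) rps_error("EDF file contains no signals",
                                   "rps_format_error")
  fs_all <- spr[keep] / rec_dur
  if (length(unique(fs_all)) != 1) {
    rps_error("channels have differing sampling rates", "rps_format_error")
  }
  fs <- fs_all[1]

  total_per_rec <- sum(spr)
  sig <- matrix(0, length(keep), n_rec * spr[keep[1]])
  raw <- readBin(con, "integer", n = n_rec * total_per_rec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * total_per_rec) {
    rps_error("truncated EDF data records", "rps_format_error")
  }
  offs <- c(0, cumsum(spr))
  for (r in seq_len(n_rec)) {
    base <- (r - 1) * total_per_rec
    for (ii in seq_along(keep)) {
      s <- keep[ii]
      vals <- raw[(base + offs[s] + 1):(base + offs[s] + spr[s])]
      cols <- ((r - 1) * spr[s] + 1):(r * spr[s])
      sig[ii, cols] <- vals
    }
  }
  scale <- (phys_max[keep] - phys_min[keep]) / (dig_max[keep] - dig_min[keep])
  sig <- (sig - dig_min[keep]) * scale + phys_min[keep]
  labels <- labels[keep]
  rec <- new_recording(sig, fs, labels)
  if (!is.null(channels)) {
    miss <- setdiff(channels, labels)
    if (length(miss)) {
      rps_error(sprintf("channel(s) not present in EDF: %s",
                        paste(miss, collapse = ", ")),
                "rps_format_error")
    }
    idx <- match(channels, labels)
    rec <- new_recording(rec$signals[idx, , drop = FALSE], fs, channels)
  }
  rec
}

#' Read expert artifact annotations from a CSV interval list
#'
#' Expects columns `start_s`, `end_s` and optionally `score`; intervals are
#' validated (`end > start`, non-negative), sorted, and overlapping rows are
#' merged with a warning.
#'
#' @param path CSV file path.
#' @return Tibble with `start_s`, `end_s`, optional `score`, `source`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) rps_error("annotation file not found",
                                    "rps_format_error")
  df <- tryCatch(read.csv(path), error = function(e)
    rps_error(paste("malformed annotation CSV:", conditionMessage(e)),
              "rps_format_error"))
  if (!all(c("start_s", "end_s") %in% names(df))) {
    rps_error("annotation CSV must have columns start_s,end_s",
              "rps_format_error")
  }
  bad <- which(!is.finite(df$start_s) | !is.finite(df$end_s) |
                 df$start_s < 0 | df$end_s <= df$start_s)
  if (length(bad)) {
    rps_error(sprintf("invalid interval at line %d (need 0 <= start_s < end_s)",
                      bad[1] + 1L),
              "rps_format_error")
  }
  o <- order(df$start_s)
  df <- df[o, , drop = FALSE]
  # merge overlaps
  if (nrow(df) > 1) {
    merged <- df[1, , drop = FALSE]
    overlap <- FALSE
    for (i in 2:nrow(df)) {
      last <- nrow(merged)
      if (df$start_s[i] < merged$end_s[last]) {
        overlap <- TRUE
        merged$end_s[last] <- max(merged$end_s[last], df$end_s[i])
      } else {
        merged <- rbind(merged, df[i, , drop = FALSE])
      }
    }
    if (overlap) warning("overlapping annotation intervals merged")
    df <- merged
  }
  out <- tibble::as_tibble(df)
  out$source <- "expert"
  out
}

#' Write artifact segments to a CSV interval list
#'
#' @param segments Tibble with `start_s`, `end_s` and optionally `peak_score`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segments, path) {
  cols <- intersect(c("start_s", "end_s", "peak_score", "score"),
                    names(segments))
  write.csv(as.data.frame(segments)[, cols, drop = FALSE], path,
            row.names = FALSE)
  invisible(path)
}

#' Write a score trace to CSV
#'
#' @param trace An `rp_trace`.
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "rp_trace"))
  write.csv(data.frame(sample = seq_along(trace$p_outlier),
                       p_outlier = trace$p_outlier),
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Stores the cluster count, centroids (row-major), per-cluster distance
#' statistics, channel names, sampling rate, seed and a configuration echo, so
#' a fitted model can score new recordings later.
#'
#' @param model An `rp_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "rp_model"))
  obj <- list(
    k = model$k,
    n_channels = model$n_channels,
    centroids = lapply(model$centroids, function(m) as.vector(t(m))),
    mu = vapply(model$stats, function(s) s$mu, numeric(1)),
    sigma = vapply(model$stats, function(s) s$sigma, numeric(1)),
    count = vapply(model$stats, function(s) s$count, numeric(1)),
    combined_p = model$combined_p,
    cluster_p = model$cluster_p,
    channel_names = model$channel_names,
    fs = model$fs,
    seed = model$seed,
    config = model$config[!vapply(model$config, is.null, logical(1))])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model from JSON
#'
#' @param path JSON path written by [write_model()].
#' @return An `rp_model` (without training labels, which are not serialized).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) rps_error("model file not found", "rps_format_error")
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    rps_error("unreadable model JSON", "rps_format_error"))
  n <- obj$n_channels
  # simplifyVector collapses the list of row-major centroid vectors to a
  # k x n^2 matrix; normalise both shapes
  cent_list <- if (is.matrix(obj$centroids)) {
    lapply(seq_len(nrow(obj$centroids)), function(i) obj$centroids[i, ])
  } else if (is.list(obj$centroids)) {
    obj$centroids
  } else {
    list(obj$centroids)
  }
  centroids <- lapply(cent_list, function(v) matrix(unlist(v), n, n, byrow = TRUE))
  stats <- lapply(seq_len(obj$k), function(j) {
    structure(list(mu = obj$mu[j], sigma = obj$sigma[j],
                   count = as.integer(obj$count[j])),
              class = "distance_stats")
  })
  cfg <- NULL
  if (!is.null(obj$config)) {
    cfg <- do.call(rp_config, obj$config[names(obj$config) %in%
                                           names(formals(rp_config))])
  }
  structure(list(centroids = centroids, stats = stats, labels = NULL,
                 k = obj$k, combined_p = obj$combined_p,
                 cluster_p = obj$cluster_p, member_distances = NULL,
                 inertia = NULL, n_channels = n,
                 rejected_epochs = integer(0), config = cfg,
                 channel_names = obj$channel_names, fs = obj$fs,
                 seed = obj$seed),
            class = "rp_model")
}
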