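#' Construct a multichannel EEG recording
#'
#' Lightweight container for a sampled multichannel time series: a named
#' list of equal-length numeric channels (amplitudes in microvolts), a
#' sampling rate and channel labels.
#'
#' @param data Named list of numeric vectors (one per channel), or a single
#'   numeric vector.
#' @param fs Sampling rate, Hz.
#' @param labels Channel names; defaults to the names of `data` or
#'   `"ch1", "ch2", ...`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL) {
  if (is.numeric(data)) data <- list(data)
  if (fs <= 0) abort("fs must be positive.")
  lens <- lengths(data)
  if (length(unique(lens)) != 1) {
    abort("All channels must have equal length.")
  }
  if (is.null(labels)) {
    labels <- names(data)
    if (is.null(labels) || any(labels == "")) {
      labels <- paste0("ch", seq_along(data))
    }
  }
  names(data) <- labels
  structure(list(data = data, fs = fs, labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              length(x$data), length(x$data[[1]]), x$fs,
              length(x$data[[1]]) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.eeg_recording <- function(x, ...) {
  n <- length(x$data[[1]])
  purrr::imap(x$data, function(v, nm) {
    tibble(channel = nm, time_s = (seq_len(n) - 1) / x$fs, value = v)
  }) |> dplyr::bind_rows()
}

# ---- EDF (European Data Format) ----------------------------------------
# 16-bit integer format with a fixed-layout ASCII header; widely used for
# polysomnography. Reader/writer cover plain continuous EDF: equal-rate
# channels, no annotations.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  hdr(8)                                   # version
  hdr(80); hdr(80); hdr(8); hdr(8)         # patient, recording, date, time
  hdr(8)                                   # header length
  hdr(44)                                  # reserved
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  per <- function(nc) vapply(seq_len(ns), function(i) hdr(nc), character(1))
  labels <- per(16)
  per(80); per(8)                          # transducer, physical dimension
  phys_min <- as.numeric(per(8))
  phys_max <- as.numeric(per(8))
  dig_min <- as.numeric(per(8))
  dig_max <- as.numeric(per(8))
  per(80)                                  # prefiltering
  spr <- as.integer(per(8))                # samples per record
  per(32)                                  # reserved
  raw <- lapply(seq_len(ns), function(i) vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2,
                               signed = TRUE, endian = "little")
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- lapply(seq_len(ns), function(i) {
    d <- unlist(raw[[i]])
    phys_min[i] + gain[i] * (d - dig_min[i])
  })
  names(data) <- labels
  fs <- spr[1] / rec_dur
  if (length(unique(spr)) != 1) {
    abort("Channels with differing sampling rates are not supported.")
  }
  eeg_recording(data, fs = fs, labels = labels)
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort("EDF writer needs an integer fs.")
  ns <- length(rec$data)
  n <- length(rec$data[[1]])
  n_rec <- floor(n / fs)
  if (n_rec * fs != n) {
    warn("Recording truncated to a whole number of 1 s data records.")
  }
  phys_min <- vapply(rec$data, min, numeric(1))
  phys_max <- vapply(rec$data, max, numeric(1))
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) {
    writeBin(charToRaw(pad_field(x, width)), con)
  }
  put("0", 8)
  put("X", 80); put("X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 + ns * 256, 8)
  put("", 44)
  put(n_rec, 8)
  put("1", 8)
  put(ns, 4)
  for (l in rec$labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (v in phys_min) put(formatC(v, format = "g", digits = 7), 8)
  for (v in phys_max) put(formatC(v, format = "g", digits = 7), 8)
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(round(fs), 8)
  for (i in seq_len(ns)) put("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      d <- round((rec$data[[i]][idx] - phys_min[i]) / gain[i] + dig_min)
      writeBin(as.integer(pmin(pmax(d, dig_min), dig_max)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a recording from EDF or delimited text
#'
#' EDF files carry their own sampling rate and channel labels. Text input
#' is one column per channel (comma or whitespace delimited, optional
#' header row of channel names) and requires `fs_override`.
#'
#' @param path File path. Extension `.edf` (case-insensitive) selects the
#'   EDF reader; anything else is parsed as delimited text.
#' @param fs_override Sampling rate in Hz for text input (ignored for EDF).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, fs_override = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    return(read_edf(path))
  }
  if (is.null(fs_override)) {
    abort("Text input carries no sampling rate; supply fs_override.")
  }
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- !all(grepl("^[-+.0-9eE]+$",
                           strsplit(trimws(first),
                                    if (sep == ",") "," else "[[:space:]]+")[[1]]))
  df <- utils::read.table(path, header = has_header, sep = sep)
  eeg_recording(as.list(df), fs = fs_override,
                labels = if (has_header) colnames(df) else NULL)
}

#' Write a recording to EDF or delimited text
#'
#' @param rec An [eeg_recording()].
#' @param path Destination; `.edf` selects EDF, anything else CSV with a
#'   header row of channel names.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    return(write_edf(rec, path))
  }
  df <- as.data.frame(rec$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cut one channel into fixed-length non-overlapping windows
#'
#' Consecutive windows of `window_s` seconds; a trailing partial window is
#' dropped since every downstream operator assumes full windows.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel name or index (default: first channel).
#' @param window_s Window length in seconds (default 10, the segment length
#'   used for artifact classification).
#' @return Tibble with one row per segment: `segment` (1-based index),
#'   `channel`, `start_index` (0-based sample offset, half-open windows
#'   `[start, start + len)`), `fs` and the `samples` list-column. Zero rows
#'   (with a warning) when the recording is shorter than one window.
#' @export
segment_signal <- function(rec, channel = 1, window_s = 10) {
  if (window_s <= 0) abort("window_s must be positive.")
  x <- get_channel(rec, channel)
  len <- round(window_s * rec$fs)
  n_seg <- floor(length(x) / len)
  if (n_seg == 0) {
    warn("Recording shorter than one window; no segments produced.")
  }
  ch_name <- if (is.character(channel)) channel else rec$labels[channel]
  tibble(
    segment = seq_len(n_seg),
    channel = rep(ch_name, n_seg),
    start_index = (seq_len(n_seg) - 1) * len,
    fs = rep(rec$fs, n_seg),
    samples = purrr::map(seq_len(n_seg), function(i) {
      x[((i - 1) * len + 1):(i * len)]
    })
  )
}

get_channel <- function(rec, channel) {
  if (is.character(channel)) {
    if (!channel %in% rec$labels) {
      abort(paste0("No channel named '", channel, "'."))
    }
    rec$data[[channel]]
  } else {
    if (channel < 1 || channel > length(rec$data)) abort("Channel out of range.")
    rec$data[[channel]]
  }
}

#' Splice cleaned windows back into a recording
#'
#' Replaces the samples of the listed windows and leaves everything else
#' bit-identical; with an empty `cleaned` table the output equals the
#' input. Replacement windows must lie inside the channel and must not
#' overlap.
#'
#' @param rec An [eeg_recording()].
#' @param channel Channel name or index.
#' @param cleaned Tibble with `start_index` and `samples` columns (the
#'   shape returned by [segment_signal()]), holding the windows to write
#'   back.
#' @return A new [eeg_recording()].
#' @export
splice_segments <- function(rec, channel = 1, cleaned) {
  x <- get_channel(rec, channel)
  if (nrow(cleaned) > 0) {
    starts <- cleaned$start_index
    lens <- lengths(cleaned$samples)
    ends <- starts + lens
    if (any(starts < 0) || any(ends > length(x))) {
      abort("Replacement window outside the channel.")
    }
    ord <- order(starts)
    if (any(starts[ord][-1] < ends[ord][-length(ord)])) {
      abort("Replacement windows overlap.")
    }
    for (i in seq_len(nrow(cleaned))) {
      x[(starts[i] + 1):ends[i]] <- cleaned$samples[[i]]
    }
  }
  ch_idx <- if (is.character(channel)) match(channel, rec$labels) else channel
  rec$data[[ch_idx]] <- x
  rec
}
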