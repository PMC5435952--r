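#' Read a recording from CSV
#'
#' Reads a wide CSV of microvolt samples — a header row with channel names,
#' one column per channel, optionally a leading `time` column (ignored except
#' for validation) — into the long recording format.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz.
#' @param subject_id,state Metadata to attach (see [eeg_recording()]).
#' @return A recording tibble.
#' @export
read_eeg_csv <- function(path, fs = 1000, subject_id = "S01",
                         state = c("normal", "fatigue")) {
  state <- match.arg(state)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (tolower(names(df)[1]) %in% c("time", "t")) df <- df[-1]
  eeg_recording(as.matrix(df), fs = fs, subject_id = subject_id, state = state)
}

#' Write a recording to CSV
#'
#' One file per (subject, state) session, wide format with one column per
#' channel. The inverse of [read_eeg_csv()] for a single session.
#'
#' @param rec A recording tibble containing exactly one subject and state.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  check_recording(rec)
  if (dplyr::n_distinct(rec$subject_id) != 1 ||
      dplyr::n_distinct(rec$state) != 1) {
    abort("write_eeg_csv() writes one (subject, state) session per file")
  }
  wide <- rec |>
    dplyr::arrange(.data$sample) |>
    tidyr::pivot_wider(id_cols = "sample", names_from = "channel",
                       values_from = "value") |>
    dplyr::select(-"sample")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

## ---- EDF (European Data Format) ------------------------------------------
## Minimal classic-EDF support: fixed 256-byte header + 256 bytes per signal,
## 16-bit little-endian samples, 1-second data records. Subject and session
## labels are carried in the local patient / recording identification fields.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording session to an EDF file
#'
#' Writes one (subject, state) session as a classic European Data Format
#' file: 16-bit samples, one-second data records, physical range set from the
#' data. Trailing samples short of a whole second are dropped (EDF stores
#' fixed-length records).
#'
#' @inheritParams write_eeg_csv
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  check_recording(rec)
  if (dplyr::n_distinct(rec$subject_id) != 1 ||
      dplyr::n_distinct(rec$state) != 1) {
    abort("write_edf() writes one (subject, state) session per file")
  }
  fs <- rec$fs[1]
  if (fs != as.integer(fs)) abort("EDF writer requires an integer sampling rate")
  wide <- rec |>
    dplyr::arrange(.data$sample) |>
    tidyr::pivot_wider(id_cols = "sample", names_from = "channel",
                       values_from = "value") |>
    dplyr::select(-"sample")
  ns <- ncol(wide)
  n_rec <- floor(nrow(wide) / fs)
  if (n_rec < 1) abort("session shorter than one EDF data record (1 s)")
  X <- as.matrix(wide)[seq_len(n_rec * fs), , drop = FALSE]

  pmin_ <- floor(apply(X, 2, min)); pmax_ <- ceiling(apply(X, 2, max))
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id[1], 80),
    edf_pad(rec$state[1], 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),      # record duration, seconds
    edf_pad(ns, 4),
    paste0(vapply(colnames(X), edf_pad, "", width = 16), collapse = ""),
    paste0(rep(edf_pad("EEG", 80), ns), collapse = ""),
    paste0(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste0(vapply(pmin_, edf_pad, "", width = 8), collapse = ""),
    paste0(vapply(pmax_, edf_pad, "", width = 8), collapse = ""),
    paste0(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste0(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste0(rep(edf_pad("", 80), ns), collapse = ""),
    paste0(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste0(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((X[rows, ch] - pmin_[ch]) / scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording tibble
#'
#' Reads a classic European Data Format file (16-bit samples) and converts
#' digital values back to physical units. Subject and state metadata are
#' taken from the patient / recording identification fields when present
#' (as written by [write_edf()]) unless overridden.
#'
#' @param path EDF file path.
#' @param subject_id,state Optional overrides for the embedded metadata.
#' @return A recording tibble.
#' @export
read_edf <- function(path, subject_id = NULL, state = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  pat <- rd(80); rid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # units
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)           # reserved

  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
      out[[ch]][((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  X <- do.call(cbind, out)
  colnames(X) <- labels
  st <- state %||% (if (rid %in% c("normal", "fatigue")) rid else "normal")
  eeg_recording(X, fs = spr[1] / rec_dur,
                subject_id = subject_id %||% (if (nzchar(pat)) pat else "S01"),
                state = st)
}

#' Write / read a feature table
#'
#' CSV round-trip for the feature representation: one row per epoch, one
#' fuzzy-entropy column per channel (`fuzzyen_<channel>`), a `label` column
#' (0 = normal, 1 = fatigue) and identifying columns.
#'
#' @param features A feature table from [extract_features()].
#' @param path CSV path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("subject_id", "epoch_index", "label") %in% names(df))) {
    abort("feature CSV must contain subject_id, epoch_index and label columns")
  }
  tibble::as_tibble(df)
}
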