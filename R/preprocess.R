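#' Build an EEG recording tibble
#'
#' Converts a samples-by-channels matrix (or wide data frame with one column
#' per channel) into the long, tidy recording format used throughout the
#' package: one row per sample per channel, with subject, session-state and
#' sampling-rate metadata carried as columns.
#'
#' @param data Numeric matrix or data frame, samples in rows, one column per
#'   channel; column names become channel names (default `FP1`, `FP2`, ...
#'   if unnamed).
#' @param fs Sampling rate in Hz (default 1000).
#' @param subject_id Subject identifier (default `"S01"`).
#' @param state Session label, `"normal"` or `"fatigue"`.
#' @return A tibble with columns `subject_id`, `state`, `channel`, `fs`,
#'   `sample` (1-based index) and `value` (microvolts).
#' @examples
#' eeg_recording(cbind(FP1 = rnorm(100), FP2 = rnorm(100)), fs = 1000,
#'               subject_id = "S01", state = "normal")
#' @export
eeg_recording <- function(data, fs = 1000, subject_id = "S01",
                          state = c("normal", "fatigue")) {
  state <- match.arg(state)
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("recording data must be numeric")
  if (any(!is.finite(data))) abort("recording contains non-finite samples")
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) abort("`fs` must be > 0")
  chn <- colnames(data)
  if (is.null(chn)) chn <- paste0("FP", seq_len(ncol(data)))
  tibble::tibble(
    subject_id = subject_id,
    state = state,
    channel = rep(chn, each = nrow(data)),
    fs = fs,
    sample = rep(seq_len(nrow(data)), times = ncol(data)),
    value = as.numeric(data)
  )
}

check_recording <- function(rec) {
  need <- c("subject_id", "state", "channel", "fs", "sample", "value")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    abort(paste0("recording is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(rec$value))) abort("recording contains non-finite samples")
  invisible(rec)
}

#' Filter specification for the acquisition band
#'
#' Cutoffs of the preprocessing chain: a zero-phase Butterworth band-pass
#' (high-pass and low-pass applied in cascade) and a mains notch. Defaults
#' match a typical frontal-EEG acquisition band: 0.05-200 Hz with a 50 Hz
#' notch.
#'
#' @param highpass_hz High-pass cutoff in Hz (default 0.05).
#' @param lowpass_hz Low-pass cutoff in Hz (default 200).
#' @param notch_hz Notch center frequency in Hz (default 50).
#' @param notch_q Notch quality factor, center / bandwidth (default 30).
#' @param order Butterworth order for each of the high- and low-pass stages
#'   (default 4; must be even, realized as second-order sections).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.05, lowpass_hz = 200, notch_hz = 50,
                        notch_q = 30, order = 4) {
  if (!(highpass_hz > 0 && highpass_hz < notch_hz && notch_hz < lowpass_hz)) {
    abort("need 0 < highpass_hz < notch_hz < lowpass_hz")
  }
  if (order < 2 || order %% 2 != 0) abort("`order` must be a positive even integer")
  if (notch_q <= 0) abort("`notch_q` must be > 0")
  structure(
    list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
         notch_hz = notch_hz, notch_q = notch_q, order = as.integer(order)),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "<filter_spec> band %g-%g Hz (order %d), notch %g Hz (Q = %g)\n",
    x$highpass_hz, x$lowpass_hz, x$order, x$notch_hz, x$notch_q))
  invisible(x)
}

check_spec_fs <- function(spec, fs) {
  if (spec$lowpass_hz >= fs / 2) {
    abort(sprintf("low-pass cutoff %g Hz is not below Nyquist (%g Hz)",
                  spec$lowpass_hz, fs / 2))
  }
  if (spec$notch_hz >= fs / 2) {
    abort(sprintf("notch frequency %g Hz is not below Nyquist (%g Hz)",
                  spec$notch_hz, fs / 2))
  }
  invisible(spec)
}

# Butterworth biquads via analytic analog prototype + bilinear transform.
# The transfer-function (b, a) form of a high-order filter with cutoff near
# 0 (e.g. 0.05 Hz at fs = 1000) is numerically ill-conditioned; cascaded
# second-order sections are not.
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  K <- 2 * fs
  wc <- K * tan(pi * cutoff_hz / fs)  # prewarped analog cutoff
  n <- order
  sections <- vector("list", n / 2)
  for (s in seq_len(n / 2)) {
    # conjugate prototype pole pair (unit analog Butterworth circle)
    theta <- pi * (2 * s - 1) / (2 * n) + pi / 2
    re <- cos(theta); im <- sin(theta)
    # analog section: LP  wc^2 / (s^2 - 2 re wc s + wc^2)
    #                 HP  s^2  / (s^2 - 2 re wc s + wc^2)   (poles wc / p)
    A1 <- -2 * re * wc
    A0 <- wc^2
    if (type == "low") { B2 <- 0; B1 <- 0; B0 <- wc^2 }
    else { B2 <- 1; B1 <- 0; B0 <- 0 }
    a0 <- K^2 + A1 * K + A0
    sections[[s]] <- list(
      b = c(B2 * K^2 + B1 * K + B0, 2 * (B0 - B2 * K^2),
            B2 * K^2 - B1 * K + B0) / a0,
      a = c(1, 2 * (A0 - K^2) / a0, (K^2 - A1 * K + A0) / a0)
    )
  }
  sections
}

# one forward pass with step-matched initial state: filtering x - x[1] from
# rest and adding back DCgain * x[1] reproduces the steady-state response,
# eliminating the startup transient a zero initial state would inject
filt_step_matched <- function(b, a, x) {
  g0 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x - x[1])) + g0 * x[1]
}

# zero-phase forward-backward filtering through a cascade of (b, a)
# sections, with odd-reflection padding at both ends
zp_filtfilt <- function(sections, x, npad = 250) {
  L <- length(x)
  np <- min(L - 1, npad)
  xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
          2 * x[L] - rev(x[(L - np):(L - 1)]))
  for (sec in sections) {
    xp <- filt_step_matched(sec$b, sec$a, xp)
    xp <- rev(filt_step_matched(sec$b, sec$a, rev(xp)))
  }
  xp[(np + 1):(np + L)]
}

filter_rec <- function(rec, fun) {
  check_recording(rec)
  rec |>
    dplyr::group_by(.data$subject_id, .data$state, .data$channel) |>
    dplyr::arrange(.data$sample, .by_group = TRUE) |>
    dplyr::mutate(value = fun(.data$value, .data$fs[1])) |>
    dplyr::ungroup()
}

#' Zero-phase band-pass filtering
#'
#' Applies the high-pass and low-pass Butterworth stages of `spec` to every
#' channel of every session in the recording, forward and backward for zero
#' phase (no group delay in the features). The DC component and slow baseline
#' drift are removed by the high-pass stage.
#'
#' @param rec A recording tibble (see [eeg_recording()]).
#' @param spec A [filter_spec()].
#' @return The recording with `value` replaced by the filtered signal; same
#'   shape and ordering by (subject, state, channel, sample).
#' @export
band_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  filter_rec(rec, function(x, fs) {
    check_spec_fs(spec, fs)
    sos <- c(butter_sos(spec$order, spec$highpass_hz, fs, "high"),
             butter_sos(spec$order, spec$lowpass_hz, fs, "low"))
    zp_filtfilt(sos, x)
  })
}

#' Zero-phase mains notch filtering
#'
#' Removes narrow-band mains interference (50 Hz by default) with an order-2
#' Butterworth band-stop of bandwidth `notch_hz / notch_q`, applied forward
#' and backward. In-band EEG rhythms (e.g. the 10 Hz alpha band) pass
#' essentially unattenuated.
#'
#' @inheritParams band_filter
#' @return The recording with the notch applied.
#' @export
notch_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  filter_rec(rec, function(x, fs) {
    check_spec_fs(spec, fs)
    bw <- spec$notch_hz / spec$notch_q
    flt <- signal::butter(2, c(spec$notch_hz - bw / 2, spec$notch_hz + bw / 2) /
                            (fs / 2), type = "stop")
    zp_filtfilt(list(list(b = flt$b, a = flt$a)), x)
  })
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts each channel of each session into consecutive windows of
#' `epoch_seconds`, optionally overlapping, dropping any trailing partial
#' window. Epochs are the unit of feature extraction and classification.
#'
#' @inheritParams band_filter
#' @param epoch_seconds Epoch duration in seconds (default 1).
#' @param overlap Fractional overlap between consecutive epochs, in `[0, 1)`
#'   (default 0).
#' @return A tibble with one row per epoch: `subject_id`, `state`, `channel`,
#'   `fs`, `epoch_index` and a `samples` list-column of numeric vectors of
#'   length `round(epoch_seconds * fs)`.
#' @examples
#' rec <- eeg_recording(cbind(FP1 = rnorm(5000)), fs = 1000)
#' segment_epochs(rec, epoch_seconds = 1)          # 5 epochs
#' segment_epochs(rec, epoch_seconds = 1, overlap = 0.5)  # 9 epochs
#' @export
segment_epochs <- function(rec, epoch_seconds = 1, overlap = 0) {
  check_recording(rec)
  if (epoch_seconds <= 0) abort("`epoch_seconds` must be > 0")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  out <- rec |>
    dplyr::group_by(.data$subject_id, .data$state, .data$channel, .data$fs) |>
    dplyr::arrange(.data$sample, .by_group = TRUE) |>
    dplyr::summarise(samples = list(.data$value), .groups = "drop") |>
    dplyr::mutate(epochs = purrr::map2(.data$samples, .data$fs, function(v, fs) {
      W <- round(epoch_seconds * fs)
      step <- max(1L, round(W * (1 - overlap)))
      L <- length(v)
      if (L < W) return(list())
      starts <- seq(1L, L - W + 1L, by = step)
      lapply(starts, function(s) v[s:(s + W - 1L)])
    })) |>
    dplyr::select(-"samples") |>
    dplyr::mutate(epoch_index = purrr::map(.data$epochs, seq_along)) |>
    tidyr::unnest(c("epochs", "epoch_index")) |>
    dplyr::rename(samples = "epochs") |>
    dplyr::relocate("subject_id", "state", "channel", "fs", "epoch_index",
                    "samples")
  if (nrow(out) == 0) {
    warn("recording shorter than one epoch: no epochs produced")
  }
  out
}

#' Reject epochs containing amplitude artifacts
#'
#' Drops every epoch in which any sample exceeds `threshold_uv` in absolute
#' value — a deterministic peak-amplitude criterion suited to frontal
#' channels, where eye blinks dominate the artifact budget. Sample values are
#' never modified; epochs are only kept or dropped.
#'
#' @param epochs An epoch tibble from [segment_epochs()].
#' @param threshold_uv Rejection threshold in microvolts (default 100). Use
#'   `Inf` to keep everything.
#' @return The kept epochs, with the number of rejected epochs reported in a
#'   message and attached as attribute `n_rejected`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100) {
  if (threshold_uv <= 0) abort("`threshold_uv` must be > 0")
  if (nrow(epochs) == 0) {
    return(structure(epochs, n_rejected = 0L))
  }
  keep <- purrr::map_lgl(epochs$samples, ~ all(abs(.x) <= threshold_uv))
  n_rej <- sum(!keep)
  if (n_rej > 0) {
    inform(sprintf("rejected %d of %d epochs exceeding +/-%g uV",
                   n_rej, length(keep), threshold_uv))
  }
  structure(epochs[keep, , drop = FALSE], n_rejected = n_rej)
}
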