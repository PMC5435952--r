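# shared fixtures, built in code at test time

fft_amplitude <- function(x, freq_hz, fs) {
  n <- length(x)
  f <- Mod(stats::fft(x)) * 2 / n
  bin <- round(freq_hz * n / fs) + 1
  f[bin]
}

sine_at <- function(freq_hz, fs = 1000, seconds = 10, amp = 1) {
  t <- seq_len(round(seconds * fs)) / fs
  amp * sin(2 * pi * freq_hz * t)
}

# two cleanly separated 1-D feature clusters (gap >> width)
separable_features <- function(n_per_class = 100, gap = 10, seed = 1,
                               subject_id = "S01") {
  set.seed(seed)
  tibble::tibble(
    subject_id = subject_id,
    epoch_index = rep(seq_len(n_per_class), 2),
    fuzzyen_FP1 = c(rnorm(n_per_class, 0, 0.1),
                    rnorm(n_per_class, gap, 0.1)),
    fuzzyen_FP2 = c(rnorm(n_per_class, 0, 0.1),
                    rnorm(n_per_class, gap, 0.1)),
    label = rep(c(0L, 1L), each = n_per_class)
  )
}

# small two-subject cohort run through the entropy front end, computed once
# and reused across test files
local({
  cache <- new.env(parent = emptyenv())
  small_cohort_features <<- function() {
    if (is.null(cache$feats)) {
      cohort <- simulate_cohort(
        synth_config(n_subjects = 2, session_seconds = 16, seed = 11))
      cache$feats <- suppressMessages(
        cohort |>
          segment_epochs() |>
          reject_artifacts() |>
          extract_features())
    }
    cache$feats
  }
})
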