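test_that("recording constructor validates input and produces the long format", {
  rec <- eeg_recording(cbind(FP1 = rnorm(100), FP2 = rnorm(100)),
                       fs = 500, subject_id = "S03", state = "fatigue")
  expect_s3_class(rec, "tbl_df")
  expect_equal(nrow(rec), 200)
  expect_setequal(unique(rec$channel), c("FP1", "FP2"))
  expect_equal(unique(rec$fs), 500)
  expect_error(eeg_recording(cbind(FP1 = c(1, NA)), fs = 1000), "non-finite")
  expect_error(eeg_recording(cbind(FP1 = 1:10), fs = -1), "fs")
})

test_that("filter spec enforces cutoff ordering and Nyquist validity", {
  expect_error(filter_spec(highpass_hz = 300, lowpass_hz = 200), "highpass")
  expect_error(filter_spec(order = 3), "even")
  rec <- eeg_recording(cbind(FP1 = rnorm(1000)), fs = 300)
  expect_error(band_filter(rec, filter_spec(lowpass_hz = 200)), "Nyquist")
})

test_that("band-pass removes DC, preserves in-band tones, rejects out-of-band", {
  fs <- 1000
  spec <- filter_spec()
  offset <- 40
  rec_dc <- eeg_recording(cbind(FP1 = rep(offset, 10 * fs)), fs = fs)
  out_dc <- band_filter(rec_dc, spec)
  expect_lt(mean(abs(out_dc$value)), 1e-3 * offset)

  s10 <- sine_at(10, fs)
  out10 <- band_filter(eeg_recording(cbind(FP1 = s10), fs = fs), spec)
  amp <- fft_amplitude(out10$value, 10, fs)
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)

  s400 <- sine_at(400, fs)
  out400 <- band_filter(eeg_recording(cbind(FP1 = s400), fs = fs), spec)
  expect_lt(fft_amplitude(out400$value, 400, fs), 10^(-20 / 20))
})

test_that("notch attenuates mains >= 30 dB and leaves alpha band intact", {
  fs <- 1000
  spec <- filter_spec()
  out50 <- notch_filter(eeg_recording(cbind(FP1 = sine_at(50, fs)), fs = fs),
                        spec)
  expect_lt(fft_amplitude(out50$value, 50, fs), 10^(-30 / 20))

  out10 <- notch_filter(eeg_recording(cbind(FP1 = sine_at(10, fs)), fs = fs),
                        spec)
  expect_gt(fft_amplitude(out10$value, 10, fs), 10^(-1 / 20))

  zero <- notch_filter(eeg_recording(cbind(FP1 = rep(0, 2000)), fs = fs), spec)
  expect_equal(zero$value, rep(0, 2000))
})

test_that("filtering is linear and zero-phase", {
  fs <- 1000
  spec <- filter_spec()
  set.seed(13)
  x <- rnorm(5 * fs)
  rec1 <- eeg_recording(cbind(FP1 = x), fs = fs)
  rec3 <- eeg_recording(cbind(FP1 = 3 * x), fs = fs)
  y1 <- band_filter(rec1, spec)$value
  y3 <- band_filter(rec3, spec)$value
  expect_lt(max(abs(y3 - 3 * y1)), 1e-9 * max(abs(y3)))

  s10 <- sine_at(10, fs)
  y10 <- band_filter(eeg_recording(cbind(FP1 = s10), fs = fs), spec)$value
  cc <- stats::ccf(y10, s10, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("epoch segmentation counts follow length, rate and overlap", {
  fs <- 1000
  rec <- eeg_recording(cbind(FP1 = rnorm(10 * fs), FP2 = rnorm(10 * fs)),
                       fs = fs)
  ep <- segment_epochs(rec, epoch_seconds = 1)
  expect_equal(nrow(ep), 20)  # 10 per channel
  expect_true(all(lengths(ep$samples) == 1000))

  rec2 <- eeg_recording(cbind(FP1 = rnorm(10.5 * fs)), fs = fs)
  expect_equal(nrow(segment_epochs(rec2, 1)), 10)  # remainder dropped

  ep_ov <- segment_epochs(rec, epoch_seconds = 1, overlap = 0.5)
  expect_equal(nrow(ep_ov), 38)  # 19 per channel

  short <- eeg_recording(cbind(FP1 = rnorm(100)), fs = fs)
  expect_warning(empty <- segment_epochs(short, 1), "shorter")
  expect_equal(nrow(empty), 0)
})

test_that("concatenating non-overlapping epochs reproduces the source samples", {
  fs <- 1000
  x <- rnorm(4321)
  rec <- eeg_recording(cbind(FP1 = x), fs = fs)
  ep <- segment_epochs(rec, epoch_seconds = 1)
  expect_identical(unlist(ep$samples), x[1:4000])
})

test_that("artifact rejection drops exactly the epochs that cross the threshold", {
  fs <- 1000
  x <- matrix(rnorm(5 * fs, sd = 10), ncol = 1)
  colnames(x) <- "FP1"
  x[2 * fs + 17, 1] <- 500  # spike inside the third epoch
  ep <- segment_epochs(eeg_recording(x, fs = fs), 1)
  expect_message(kept <- reject_artifacts(ep, 100), "rejected 1 of 5")
  expect_equal(nrow(kept), 4)
  expect_equal(attr(kept, "n_rejected"), 1L)
  expect_false(3 %in% kept$epoch_index)
  # sample values are never modified
  expect_identical(kept$samples, ep$samples[ep$epoch_index != 3])

  all_kept <- reject_artifacts(ep, Inf)
  expect_equal(nrow(all_kept), nrow(ep))
  expect_equal(attr(all_kept, "n_rejected"), 0L)
  expect_error(reject_artifacts(ep, -5), "> 0")
})
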