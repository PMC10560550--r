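test_that("compensation is the identity at the reference distance and restores a mic dip", {
  cfg <- pipeline_config(); fs <- 500e3; w <- std_weather()
  x <- synthesize_call(call_spec(), fs)
  flat <- flat_mic_calibration(1)
  em <- compensate_to_source(x, 0.1, w, flat, fs, full_scale_pa = 1,
                             config = cfg)
  expect_equal(em$waveform, x, tolerance = 1e-10)
  expect_equal(em$clamped_bins, 0)

  # forward-apply a -6 dB dip at 70 kHz, compensate with the true response:
  # a 70 kHz tone level is restored within 0.2 dB
  dip <- default_mic_calibration(dip = TRUE, full_scale_pa = 1)
  n <- 5000; tt <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 70e3 * tt) *
    echotrack:::envelope_shape("flat-with-ramps", n, fs)
  X <- stats::fft(tone)
  f <- abs(echotrack:::fft_frequencies(n, fs))
  tone_dipped <- Re(stats::fft(X * 10^(mic_response_db(dip, f) / 20),
                               inverse = TRUE)) / n
  em2 <- compensate_to_source(tone_dipped, 0.1, w, dip, fs,
                              full_scale_pa = 1, config = cfg)
  core <- seq(round(n * 0.2), round(n * 0.8))
  loss <- 20 * log10(sqrt(mean(em2$waveform[core]^2)) /
                       sqrt(mean(tone[core]^2)))
  expect_lt(abs(loss), 0.2)
})

test_that("compensation round-trips the renderer and is linear in level", {
  geom <- std_geometry(); w <- std_weather(); cfg <- pipeline_config()
  pos <- c(0, 0.5, 3)
  ev <- list(list(id = "c1", trajectory_id = 1L, time = 0.01, position = pos,
                  spec = call_spec(source_level_rms = 96)))
  sc <- scene_spec(ev, w, mic_cal = flat_mic_calibration(0.25),
                   noise_floor = -Inf)
  r <- render_scene(sc, geom, seed = 4)
  fs <- r$recording$sample_rate
  d <- sqrt(sum(pos^2))
  # raw central-channel window around the call (no bandpass: isolates the
  # compensator itself)
  i0 <- round((0.01 + d / speed_of_sound(w)) * fs) - 500
  win <- r$recording$samples[i0:(i0 + 3000), 1]
  em <- compensate_to_source(win, d, w, sc$mic_cal, fs,
                             full_scale_pa = 0.25, config = cfg)
  dur <- measure_duration(em, cfg)
  lv <- measure_levels(em, dur$window, cfg)
  expect_equal(lv$rms_spl, r$truth$rms_spl_true, tolerance = 0.1 / 96)
  # linearity: +12 dB input scales both levels by exactly +12 dB
  em_g <- compensate_to_source(win * 10^(12 / 20), d, w, sc$mic_cal, fs,
                               full_scale_pa = 0.25, config = cfg)
  lv_g <- measure_levels(em_g, measure_duration(em_g, cfg)$window, cfg)
  expect_equal(lv_g$rms_spl - lv$rms_spl, 12, tolerance = 1e-6)
  expect_equal(lv_g$pe_spl - lv$pe_spl, 12, tolerance = 1e-6)
  # silent padding does not change the levels
  em_pad <- em
  em_pad$waveform <- c(numeric(2000), em$waveform, numeric(2000))
  dur_p <- measure_duration(em_pad, cfg)
  lv_p <- measure_levels(em_pad, dur_p$window, cfg)
  expect_lt(abs(lv_p$rms_spl - lv$rms_spl), 0.01)
  expect_lt(abs(lv_p$pe_spl - lv$pe_spl), 0.01)
})

test_that("duration measurement matches analytic envelope widths", {
  cfg <- pipeline_config(); fs <- 500e3
  # flat envelope with near-instant ramps: duration ~ nominal, smoothing may
  # widen by up to the 0.2 ms moving average
  n <- round(2.5e-3 * fs); tt <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 40e3 * tt)
  x <- c(numeric(1000), x, numeric(1000))
  d <- measure_duration_wave(x, fs, cfg)
  expect_equal(d$duration_ms, 2.5, tolerance = 0.2 / 2.5)
  # Gaussian envelope of s.d. sigma: -12 dB full width = 2 sigma sqrt(2 ln 10^0.6)
  sigma <- 4e-4
  tt2 <- (seq_len(10000) - 1) / fs
  g <- exp(-((tt2 - 0.01)^2) / (2 * sigma^2)) * sin(2 * pi * 40e3 * tt2)
  dg <- measure_duration_wave(g, fs, cfg)
  width_ms <- 2 * sigma * sqrt(2 * log(10^0.6)) * 1000
  expect_equal(dg$duration_ms, width_ms, tolerance = 0.1)
  # an envelope that never drops 12 dB spans the whole window and is flagged
  const <- sin(2 * pi * 40e3 * tt)
  dc <- measure_duration_wave(const, fs, cfg)
  expect_true(dc$flagged)
  expect_equal(dc$duration_ms, n / fs * 1000)
  expect_error(measure_duration_wave(numeric(100), fs, cfg), "all-zero")
})

test_that("SPL definitions reproduce closed-form sine levels", {
  cfg <- pipeline_config(); fs <- 500e3
  n <- 5000
  tt <- (seq_len(n) - 1) / fs
  # sine of rms 1 Pa (amplitude sqrt 2): rms and pe SPL both 93.98 dB
  s <- sqrt(2) * sin(2 * pi * 40e3 * tt)
  lv <- measure_levels_wave(s, fs, c(1, n), cfg)
  expect_equal(lv$rms_spl, 20 * log10(1 / 20e-6), tolerance = 1e-4)
  expect_equal(lv$pe_spl, 20 * log10(1 / 20e-6), tolerance = 1e-3)
  # sine of peak 2 Pa: peSPL = 20 log10((2/sqrt 2)/20e-6) = 96.99 dB
  s2 <- 2 * sin(2 * pi * 40e3 * tt)
  lv2 <- measure_levels_wave(s2, fs, c(1, n), cfg)
  expect_equal(lv2$pe_spl, 96.99, tolerance = 1e-3)
  expect_error(measure_levels_wave(s, fs, c(10, 5), cfg), "empty")
})

test_that("spectral peak and lowest frequency follow the averaged spectrogram definition", {
  cfg <- pipeline_config(); fs <- 500e3
  n <- 5000; tt <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 38e3 * tt)
  fr <- measure_frequencies_wave(tone, fs, cfg)
  expect_lt(abs(fr$peak_frequency - 38e3), 250)
  # bin spacing is fs / fft_length
  expect_equal(diff(fr$spectrum$frequency[1:2]),
               fs / cfg$spectrogram_fft_length)
  # flat-envelope linear sweep 45 -> 25 kHz: lowest frequency at the sweep
  # edge, broadened downward by the 100-sample Hann window's spectral
  # leakage (main-lobe half-width ~2 kHz at 500 kHz)
  sweep <- synthesize_call(call_spec(2.5, 45e3, 25e3, "linear", 1, 0,
                                     "flat-with-ramps", 94), fs)
  fr2 <- measure_frequencies_wave(sweep, fs, cfg)
  expect_lt(fr2$lowest_frequency, 25e3)
  expect_gt(fr2$lowest_frequency, 25e3 - 2.5e3)
  # a -6 dB second harmonic does not displace the peak from the first
  two <- synthesize_call(call_spec(2.5, 40e3, 30e3, "linear", 2, c(0, -6),
                                   "raised-cosine", 94), fs)
  fr3 <- measure_frequencies_wave(two, fs, cfg)
  expect_lt(fr3$peak_frequency, 50e3)
  expect_error(measure_frequencies_wave(tone[1:50], fs, cfg), "shorter")
})
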