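#' Back-compensate a recorded call to the emitted waveform at 10 cm
#'
#' FFT-based spectral compensation: the recorded window (full-scale units) is
#' converted to pascals, its amplitude spectrum multiplied by the inverse
#' microphone response, by `10^(alpha(f) (d - ref) / 20)` (atmospheric
#' absorption over the travel path) and by the spherical-spreading gain
#' `d / ref`; the phase spectrum is untouched and the waveform recovered by
#' inverse FFT. The frequency-dependent part of the gain (microphone inverse
#' plus absorption) is capped at `max_comp_gain` dB per bin to guard against
#' noise blow-up; clamped bins are flagged. The flat spreading term is not
#' capped (it carries no frequency-selective noise amplification).
#'
#' @param waveform numeric window in full-scale units (central channel).
#' @param distance source distance used for compensation, m (> reference).
#' @param weather a [weather_record()].
#' @param mic_cal a [mic_calibration()].
#' @param sample_rate Hz.
#' @param full_scale_pa Pa at full scale (defaults to the calibration's).
#' @param config a [pipeline_config()].
#' @return object of class `emitted_call`: `waveform` (Pa at the reference
#'   distance), `sample_rate`, `distance`, `weather`, `clamped_bins`.
#' @export
compensate_to_source <- function(waveform, distance, weather, mic_cal,
                                 sample_rate,
                                 full_scale_pa = mic_cal$full_scale_pa,
                                 config = pipeline_config()) {
  if (distance < config$reference_distance)
    stop("compensation distance must be at least the reference distance")
  n <- length(waveform)
  x <- waveform * full_scale_pa
  X <- stats::fft(x)
  f <- abs(fft_frequencies(n, sample_rate))
  gain_db <- -mic_response_db(mic_cal, f) +
    absorption_coefficient(f, weather) * (distance - config$reference_distance)
  clamped <- gain_db > config$max_comp_gain
  gain_db[clamped] <- config$max_comp_gain
  gain_db <- gain_db + spreading_gain(distance, config$reference_distance)
  y <- Re(stats::fft(X * 10^(gain_db / 20), inverse = TRUE)) / n
  structure(list(waveform = y, sample_rate = sample_rate,
                 distance = distance, weather = weather,
                 clamped_bins = sum(clamped)),
            class = "emitted_call")
}

#' Call duration at -12 dB below the smoothed envelope peak
#'
#' Envelope = magnitude of the analytic signal smoothed with a 0.2 ms moving
#' average; duration = width from the first rise above peak - 12 dB to the
#' last fall below it. Flagged when the envelope never drops 12 dB inside
#' the window (duration then equals the window length).
#'
#' @param emitted an `emitted_call` (or numeric waveform via
#'   `measure_duration_wave`).
#' @param config a [pipeline_config()].
#' @return list: `duration_ms`, `window` (sample indices), `flagged`.
#' @export
measure_duration <- function(emitted, config = pipeline_config()) {
  stopifnot(inherits(emitted, "emitted_call"))
  measure_duration_wave(emitted$waveform, emitted$sample_rate, config)
}

#' @rdname measure_duration
#' @param waveform numeric waveform.
#' @param sample_rate Hz.
#' @export
measure_duration_wave <- function(waveform, sample_rate,
                                  config = pipeline_config()) {
  if (all(waveform == 0)) stop("all-zero waveform")
  env <- signal_envelope(waveform, sample_rate, config$envelope_smoothing)
  win <- envelope_window(env, config$duration_criterion)
  flagged <- win[1] == 1 && win[2] == length(waveform)
  list(duration_ms = (win[2] - win[1] + 1) / sample_rate * 1000,
       window = win, flagged = flagged)
}

#' Peak-equivalent and rms sound pressure level of a call
#'
#' `rmsSPL = 20 log10(rms(p within the duration window) / 20 uPa)`;
#' `peSPL` from the envelope peak within the window, by default referenced to
#' a sine of equal peak (peak / sqrt(2); convention configurable via
#' `pe_convention`), on the smoothed envelope by default (`pe_envelope`).
#'
#' @param emitted an `emitted_call`.
#' @param window sample-index window from [measure_duration()].
#' @param config a [pipeline_config()].
#' @return list: `pe_spl`, `rms_spl` (dB re. 20 uPa at the reference
#'   distance).
#' @export
measure_levels <- function(emitted, window, config = pipeline_config()) {
  stopifnot(inherits(emitted, "emitted_call"))
  measure_levels_wave(emitted$waveform, emitted$sample_rate, window, config)
}

#' @rdname measure_levels
#' @param waveform numeric waveform (Pa).
#' @param sample_rate Hz.
#' @export
measure_levels_wave <- function(waveform, sample_rate, window,
                                config = pipeline_config()) {
  if (window[2] < window[1]) stop("empty duration window")
  seg <- waveform[window[1]:window[2]]
  p_ref <- 20e-6
  rms_spl <- 20 * log10(sqrt(mean(seg^2)) / p_ref)
  smoothing <- if (config$pe_envelope == "smoothed") config$envelope_smoothing else 0
  env <- signal_envelope(waveform, sample_rate, smoothing)
  pk <- max(env[window[1]:window[2]])
  pe_peak <- if (config$pe_convention == "sine") pk / sqrt(2) else pk
  list(pe_spl = 20 * log10(pe_peak / p_ref), rms_spl = rms_spl)
}

#' Peak and lowest frequency from the time-averaged spectrogram
#'
#' Spectrogram of Hann windows (`spectrogram_window` samples, default 100)
#' zero-padded to `spectrogram_fft_length`-point FFTs (default 2000, i.e. a
#' 25-fold interpolated spectrum, 250 Hz bins at 500 kHz) at
#' `spectrogram_overlap` % overlap (default 95 %, hop 5 samples), magnitude
#' averaged over time. Peak frequency = argmax bin; lowest frequency = the
#' lowest bin still within `spectral_edge_criterion` dB of the peak reached
#' by walking downward from the peak (so noise below the call band cannot
#' fake a lower edge).
#'
#' @param emitted an `emitted_call`.
#' @param config a [pipeline_config()].
#' @return list: `peak_frequency`, `lowest_frequency` (Hz), `spectrum`
#'   (data.frame frequency/amplitude).
#' @export
measure_frequencies <- function(emitted, config = pipeline_config()) {
  stopifnot(inherits(emitted, "emitted_call"))
  measure_frequencies_wave(emitted$waveform, emitted$sample_rate, config)
}

#' @rdname measure_frequencies
#' @param waveform numeric waveform.
#' @param sample_rate Hz.
#' @export
measure_frequencies_wave <- function(waveform, sample_rate,
                                     config = pipeline_config()) {
  wlen <- config$spectrogram_window
  nfft <- config$spectrogram_fft_length
  hop <- max(1L, as.integer(round(wlen * (1 - config$spectrogram_overlap / 100))))
  n <- length(waveform)
  if (n < wlen) stop("call shorter than one spectrogram window")
  starts <- seq(1L, n - wlen + 1L, by = hop)
  win <- signal::hanning(wlen)
  frames <- vapply(starts, function(s) waveform[s:(s + wlen - 1)] * win,
                   numeric(wlen))
  frames <- rbind(frames, matrix(0, nfft - wlen, length(starts)))
  spec <- Mod(stats::mvfft(frames))[seq_len(nfft %/% 2 + 1), , drop = FALSE]
  avg <- rowMeans(spec)
  freqs <- (seq_len(nfft %/% 2 + 1) - 1) * sample_rate / nfft
  ipk <- which.max(avg)
  thr <- avg[ipk] * 10^(config$spectral_edge_criterion / 20)
  ilow <- ipk
  while (ilow > 1 && avg[ilow - 1] >= thr) ilow <- ilow - 1
  list(peak_frequency = freqs[ipk], lowest_frequency = freqs[ilow],
       spectrum = data.frame(frequency = freqs, amplitude = avg))
}

#' All acoustic parameters of an emitted call
#'
#' @param emitted an `emitted_call`.
#' @param config a [pipeline_config()].
#' @return one-row data.frame: `duration_ms`, `pe_spl_db`, `rms_spl_db`,
#'   `peak_khz`, `lowest_khz`, `duration_flagged`.
#' @export
call_parameters <- function(emitted, config = pipeline_config()) {
  dur <- measure_duration(emitted, config)
  lv <- measure_levels(emitted, dur$window, config)
  fr <- measure_frequencies(emitted, config)
  data.frame(duration_ms = dur$duration_ms, pe_spl_db = lv$pe_spl,
             rms_spl_db = lv$rms_spl, peak_khz = fr$peak_frequency / 1e3,
             lowest_khz = fr$lowest_frequency / 1e3,
             duration_flagged = dur$flagged)
}
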