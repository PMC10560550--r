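#' Pipeline configuration
#'
#' Collects every fixed threshold of the measurement chain with its default.
#' Defaults mirror a calibrated 500 kHz four-microphone field setup; every
#' value can be overridden per call site.
#'
#' @param band_low,band_high bandpass edges, Hz.
#' @param filter_order elliptic lowpass prototype order (bandpass has twice
#'   as many poles).
#' @param passband_ripple peak-to-peak passband ripple, dB.
#' @param stopband_attenuation minimum stopband attenuation, dB.
#' @param detection_threshold detection threshold on the smoothed envelope of
#'   the central channel, dB full scale.
#' @param min_duration,max_duration call-duration acceptance window, ms.
#' @param min_snr minimum signal-to-noise ratio, dB.
#' @param envelope_smoothing moving-average length for envelope smoothing, ms.
#' @param duration_criterion envelope criterion for call duration, dB below
#'   the envelope peak.
#' @param spectral_edge_criterion criterion for the lowest frequency, dB below
#'   the peak-frequency amplitude.
#' @param reference_distance source-level reference distance, m.
#' @param percentile percentile of apparent source levels used as the on-axis
#'   estimate, %.
#' @param rms_correction,pe_correction system bias corrections added to the
#'   rms / peak-equivalent estimates, dB.
#' @param spectrogram_window spectrogram analysis window length, samples.
#' @param spectrogram_fft_length FFT length the windows are zero-padded to,
#'   samples.
#' @param spectrogram_overlap window overlap, %.
#' @param merge_gap detections closer than this are merged, ms.
#' @param window_pad padding added to each side of a detection window, ms.
#' @param min_correlation cross-correlation peak coefficient below which a
#'   TDOA is flagged unreliable.
#' @param max_comp_gain cap on the frequency-dependent compensation gain
#'   (microphone inverse + absorption), dB; bins above it are clamped and
#'   flagged.
#' @param outlier_distance distance from the local trajectory fit beyond
#'   which a position is flagged as an outlier, m.
#' @param max_speed maximum plausible flight speed for trajectory linking,
#'   m/s.
#' @param max_link_gap maximum time gap within one trajectory, s.
#' @param pe_convention peak-equivalent SPL convention: `"sine"` (peak / sqrt 2,
#'   the SPL of a sine of equal peak) or `"peak"`.
#' @param pe_envelope envelope used for the peSPL peak: `"smoothed"` or `"raw"`.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(band_low = 20e3, band_high = 90e3,
                            filter_order = 4, passband_ripple = 0.1,
                            stopband_attenuation = 40,
                            detection_threshold = -35,
                            min_duration = 1, max_duration = 8,
                            min_snr = 15, envelope_smoothing = 0.2,
                            duration_criterion = -12,
                            spectral_edge_criterion = -12,
                            reference_distance = 0.1, percentile = 95,
                            rms_correction = 4, pe_correction = 1,
                            spectrogram_window = 100,
                            spectrogram_fft_length = 2000,
                            spectrogram_overlap = 95,
                            merge_gap = 2, window_pad = 5,
                            min_correlation = 0.2, max_comp_gain = 60,
                            outlier_distance = 1, max_speed = 15,
                            max_link_gap = 1,
                            pe_convention = c("sine", "peak"),
                            pe_envelope = c("smoothed", "raw")) {
  cfg <- list(band_low = band_low, band_high = band_high,
              filter_order = filter_order, passband_ripple = passband_ripple,
              stopband_attenuation = stopband_attenuation,
              detection_threshold = detection_threshold,
              min_duration = min_duration, max_duration = max_duration,
              min_snr = min_snr, envelope_smoothing = envelope_smoothing,
              duration_criterion = duration_criterion,
              spectral_edge_criterion = spectral_edge_criterion,
              reference_distance = reference_distance, percentile = percentile,
              rms_correction = rms_correction, pe_correction = pe_correction,
              spectrogram_window = spectrogram_window,
              spectrogram_fft_length = spectrogram_fft_length,
              spectrogram_overlap = spectrogram_overlap,
              merge_gap = merge_gap, window_pad = window_pad,
              min_correlation = min_correlation, max_comp_gain = max_comp_gain,
              outlier_distance = outlier_distance, max_speed = max_speed,
              max_link_gap = max_link_gap,
              pe_convention = match.arg(pe_convention),
              pe_envelope = match.arg(pe_envelope))
  stopifnot(cfg$band_low > 0, cfg$band_high > cfg$band_low,
            cfg$min_duration > 0, cfg$max_duration > cfg$min_duration,
            cfg$duration_criterion < 0, cfg$spectral_edge_criterion < 0,
            cfg$reference_distance > 0,
            cfg$percentile > 0, cfg$percentile <= 100,
            cfg$spectrogram_fft_length >= cfg$spectrogram_window,
            cfg$spectrogram_overlap >= 0, cfg$spectrogram_overlap < 100)
  structure(cfg, class = "pipeline_config")
}

#' Read / write geometry, weather and configuration as YAML
#'
#' @param x object to serialize.
#' @param path file path.
#' @name config_io
#' @export
write_geometry_yaml <- function(x, path) {
  stopifnot(inherits(x, "mic_array_geometry"))
  yaml::write_yaml(list(mic_positions = apply(x$mic_positions, 1, as.numeric,
                                              simplify = FALSE),
                        central_index = x$central_index), path,
                   precision = 12)
}

#' @rdname config_io
#' @export
read_geometry_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mic_array_geometry(mic_positions = do.call(rbind, y$mic_positions))
}

#' @rdname config_io
#' @export
write_weather_yaml <- function(x, path) {
  stopifnot(inherits(x, "weather_record"))
  yaml::write_yaml(unclass(x), path)
}

#' @rdname config_io
#' @export
read_weather_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  weather_record(y$temperature, y$relative_humidity, y$pressure,
                 if (is.null(y$timestamp)) 0 else y$timestamp)
}

#' @rdname config_io
#' @export
write_config_yaml <- function(x, path) {
  stopifnot(inherits(x, "pipeline_config"))
  yaml::write_yaml(unclass(x), path)
}

#' @rdname config_io
#' @export
read_config_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
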