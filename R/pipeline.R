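#' Run the full measurement chain on one recording
#'
#' Bandpass -> detect on the central channel -> SNR -> TDOA measurement ->
#' 3D localization -> spectral back-compensation at the measured distance ->
#' call parameters -> trajectory linking -> exclusion cascade.
#'
#' @param rec a [multichannel_recording()].
#' @param geometry a [mic_array_geometry()].
#' @param weather a [weather_record()].
#' @param mic_cal the [mic_calibration()] used for compensation.
#' @param config a [pipeline_config()].
#' @return list with `detections` (the raw detection table) and `calls`: one
#'   row per detection with emission time, position, distance, residual, SNR,
#'   duration, peSPL, rmsSPL, peak/lowest frequency, trajectory id,
#'   `included` flag and exclusion `reason`.
#' @export
analyze_recording <- function(rec, geometry = mic_array_geometry(),
                              weather = weather_record(15, 60),
                              mic_cal = default_mic_calibration(
                                full_scale_pa = rec$full_scale_pa),
                              config = pipeline_config()) {
  filtered <- bandpass(rec, config)
  dets <- detect_calls(filtered, geometry, config)
  if (nrow(dets) == 0)
    return(list(detections = dets, calls = data.frame()))
  snr <- vapply(seq_len(nrow(dets)), function(i)
    estimate_snr(filtered, dets[i, ], dets, geometry, config), numeric(1))
  fixes <- localize_detections(filtered, dets, geometry, weather, config)
  ch <- central_channel(filtered, geometry)
  params <- lapply(seq_len(nrow(dets)), function(i) {
    if (is.na(fixes$distance[i]) ||
        fixes$distance[i] < config$reference_distance)
      return(data.frame(duration_ms = NA_real_, pe_spl_db = NA_real_,
                        rms_spl_db = NA_real_, peak_khz = NA_real_,
                        lowest_khz = NA_real_, duration_flagged = NA))
    w <- filtered$samples[dets$start[i]:(dets$end[i] - 1), ch]
    em <- compensate_to_source(w, fixes$distance[i], weather, mic_cal,
                               filtered$sample_rate,
                               full_scale_pa = rec$full_scale_pa,
                               config = config)
    call_parameters(em, config)
  })
  calls <- cbind(fixes, snr_db = snr, do.call(rbind, params),
                 peak_time = dets$peak_time, peak_dbfs = dets$peak_dbfs)
  calls <- link_trajectories(calls, config)
  calls <- apply_exclusions(calls, config)
  list(detections = dets, calls = calls)
}
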