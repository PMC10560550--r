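#' Zero-phase elliptic bandpass filter
#'
#' Designs the elliptic bandpass (default 20-90 kHz, 4th-order lowpass
#' prototype, 0.1 dB peak-to-peak passband ripple, 40 dB minimum stopband
#' attenuation) and applies it forward-backward (`signal::filtfilt`) so call
#' timing is not biased by filter group delay. Zero-phase application doubles
#' the effective attenuation and squares the ripple.
#'
#' @param rec a [multichannel_recording()] (sample rate must exceed 180 kHz).
#' @param config a [pipeline_config()].
#' @return the filtered recording.
#' @export
bandpass <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (rec$sample_rate <= 180e3) stop("sample_rate must exceed 180 kHz")
  flt <- design_bandpass(config, rec$sample_rate)
  out <- rec
  for (ch in seq_len(ncol(rec$samples)))
    out$samples[, ch] <- signal::filtfilt(flt, rec$samples[, ch])
  out
}

#' @rdname bandpass
#' @param sample_rate Hz.
#' @return for `design_bandpass`: the `signal::Arma` filter coefficients.
#' @export
design_bandpass <- function(config, sample_rate) {
  flt <- signal::ellip(config$filter_order, config$passband_ripple,
                       config$stopband_attenuation,
                       c(config$band_low, config$band_high) / (sample_rate / 2),
                       type = "pass")
  if (any(abs(polyroot(rev(flt$a))) >= 1))
    stop("unstable bandpass design at this sample rate")
  flt
}

#' @rdname bandpass
#' @param f frequencies at which to evaluate, Hz.
#' @param flt filter from [design_bandpass()].
#' @return for `filter_response_db`: single-pass magnitude response, dB.
#' @export
filter_response_db <- function(flt, f, sample_rate) {
  # evaluate in zero-pole form: direct polynomial evaluation loses precision
  # deep in the stopband (zeros near z = 1 cancel catastrophically)
  zeros <- polyroot(rev(flt$b))
  poles <- polyroot(rev(flt$a))
  k <- flt$b[1] / flt$a[1]
  z <- exp(1i * 2 * pi * f / sample_rate)
  h <- vapply(z, function(zz) {
    abs(k) * exp(sum(log(abs(zz - zeros))) - sum(log(abs(zz - poles))))
  }, numeric(1))
  20 * log10(h)
}

#' Detect calls on the central channel
#'
#' Thresholding on the smoothed analytic envelope of the (already
#' band-passed) central channel: each contiguous supra-threshold event above
#' `detection_threshold` dBFS yields one detection; events closer than the
#' merge gap are merged; windows are padded on both sides for downstream TDOA
#' and spectral analysis and capped at 50 ms.
#'
#' @param rec a band-passed [multichannel_recording()].
#' @param geometry a [mic_array_geometry()] (identifies the central channel).
#' @param config a [pipeline_config()].
#' @return data.frame of class `call_detections`: `call_id`, `start`, `end`
#'   (half-open sample window, padded), `core_start`, `core_end`
#'   (supra-threshold run), `peak_sample`, `peak_time`, `peak_dbfs`.
#' @export
detect_calls <- function(rec, geometry = mic_array_geometry(),
                         config = pipeline_config()) {
  fs <- rec$sample_rate
  ch <- central_channel(rec, geometry)
  x <- rec$samples[, ch]
  env <- signal_envelope(x, fs, config$envelope_smoothing)
  thr <- 10^(config$detection_threshold / 20)
  above <- env >= thr
  if (!any(above)) return(empty_detections())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than the merge gap
  gap <- config$merge_gap / 1000 * fs
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    last <- merged[[length(merged)]]
    if (runs[i, 1] - last[2] <= gap) {
      merged[[length(merged)]] <- c(last[1], runs[i, 2])
    } else merged[[length(merged) + 1]] <- runs[i, ]
  }
  pad <- round(config$window_pad / 1000 * fs)
  max_len <- round(0.050 * fs)
  out <- lapply(seq_along(merged), function(i) {
    run <- merged[[i]]
    pk <- run[1] - 1 + which.max(env[run[1]:run[2]])
    s <- max(1, run[1] - pad)
    e <- min(length(x), run[2] + pad)
    if (e - s + 1 > max_len) { # cap, centred on the peak
      s <- max(1, pk - max_len %/% 2)
      e <- min(length(x), s + max_len - 1)
    }
    data.frame(call_id = i, start = s, end = e + 1L,  # half-open
               core_start = run[1], core_end = run[2],
               peak_sample = pk, peak_time = (pk - 1) / fs,
               peak_dbfs = 20 * log10(env[pk]))
  })
  structure(do.call(rbind, out), class = c("call_detections", "data.frame"))
}

empty_detections <- function() {
  structure(data.frame(call_id = integer(), start = integer(),
                       end = integer(), core_start = integer(),
                       core_end = integer(), peak_sample = integer(),
                       peak_time = numeric(), peak_dbfs = numeric()),
            class = c("call_detections", "data.frame"))
}

#' Signal-to-noise ratio of one detection
#'
#' `20 log10(rms_signal / rms_noise)`: signal rms over the -12 dB
#' smoothed-envelope window inside the detection; noise rms over a 10 ms
#' flanking window just before the padded detection window (falling back to
#' just after it), shrunk to avoid neighbouring detections. Returns `NA`
#' (flagged) when no clean flank of at least 2 ms exists.
#'
#' @param rec the band-passed recording.
#' @param detection one row of [detect_calls()] output.
#' @param detections all detections (to keep flanks clean).
#' @param geometry,config as elsewhere.
#' @return SNR in dB, or `NA`.
#' @export
estimate_snr <- function(rec, detection, detections = NULL,
                         geometry = mic_array_geometry(),
                         config = pipeline_config()) {
  fs <- rec$sample_rate
  x <- rec$samples[, central_channel(rec, geometry)]
  seg <- x[detection$start:(detection$end - 1)]
  env <- signal_envelope(seg, fs, config$envelope_smoothing)
  win <- envelope_window(env, config$duration_criterion)
  sig_rms <- sqrt(mean(seg[win[1]:win[2]]^2))
  flank_len <- round(0.010 * fs)
  min_len <- round(0.002 * fs)
  occupied <- function(lo, hi) {
    if (is.null(detections) || nrow(detections) == 0) return(c(lo, hi))
    for (j in seq_len(nrow(detections))) {
      ds <- detections$start[j]; de <- detections$end[j]
      if (ds < hi && de > lo) {            # overlap: shrink toward the call
        if (ds > lo) hi <- min(hi, ds) else lo <- max(lo, de)
      }
    }
    c(lo, hi)
  }
  # preferred flank: before the padded window
  lo <- max(1, detection$start - flank_len); hi <- detection$start
  w <- occupied(lo, hi)
  if (w[2] - w[1] < min_len) {             # fall back: after the window
    lo <- detection$end; hi <- min(length(x), detection$end + flank_len)
    w <- occupied(lo, hi)
  }
  if (w[2] - w[1] < min_len) return(NA_real_)
  noise_rms <- sqrt(mean(x[w[1]:(w[2] - 1)]^2))
  if (noise_rms == 0) return(Inf)
  20 * log10(sig_rms / noise_rms)
}
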