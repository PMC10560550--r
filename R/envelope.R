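# Shared envelope machinery: magnitude of the analytic signal, optionally
# smoothed by a centred moving average. Used by detection (threshold), the
# duration criterion and the peSPL peak.

#' Analytic-signal envelope
#'
#' Envelope = magnitude of the analytic signal (Hilbert construction via FFT),
#' optionally smoothed with a centred moving average. Edge samples use
#' partial-window averages.
#'
#' @param x numeric waveform.
#' @param sample_rate Hz (only needed when smoothing).
#' @param smoothing_ms moving-average length in ms; 0 disables smoothing.
#' @return numeric envelope, same length as `x`.
#' @export
signal_envelope <- function(x, sample_rate = NULL, smoothing_ms = 0) {
  n <- length(x)
  if (n == 0) stop("empty waveform")
  env <- Mod(analytic_signal(x))
  if (smoothing_ms > 0) {
    if (is.null(sample_rate)) stop("sample_rate required for smoothing")
    w <- max(1L, as.integer(round(smoothing_ms * sample_rate / 1000)))
    env <- moving_average(env, w)
  }
  env
}

# centred moving average with partial windows at the edges (cumsum based)
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# indices [first rise, last fall] where env >= peak * 10^(criterion_db/20);
# used by the duration criterion and the SNR signal window
envelope_window <- function(env, criterion_db) {
  pk <- max(env)
  if (pk <= 0) stop("degenerate (all-zero) envelope")
  idx <- which(env >= pk * 10^(criterion_db / 20))
  c(idx[1], idx[length(idx)])
}
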