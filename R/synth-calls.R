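#' Parametric echolocation-call specification
#'
#' Describes a downward-FM multi-harmonic call. Defaults emulate the calls of
#' a low-amplitude FM/FM-qCF gleaning bat: ~2.5 ms first-harmonic sweep from
#' ~52 to ~24 kHz with a weaker second harmonic, emitted around 94 dB SPL rms
#' re. 20 uPa at 10 cm.
#'
#' @param duration call duration, ms (> 0).
#' @param f_start,f_end first-harmonic start/end frequency, Hz (downward
#'   sweep: `f_start > f_end > 0`).
#' @param sweep_shape `"linear"` or `"hyperbolic"` instantaneous-frequency law.
#' @param n_harmonics number of harmonics rendered.
#' @param harmonic_levels levels of each harmonic relative to the first, dB
#'   (length `n_harmonics`, first element 0).
#' @param envelope `"raised-cosine"`, `"gaussian"` or `"flat-with-ramps"`.
#' @param source_level_rms source level, dB SPL re. 20 uPa at 0.1 m, rms
#'   within the -12 dB envelope window.
#' @return object of class `call_spec`.
#' @export
call_spec <- function(duration = 2.5, f_start = 52e3, f_end = 24e3,
                      sweep_shape = c("linear", "hyperbolic"),
                      n_harmonics = 2, harmonic_levels = c(0, -6),
                      envelope = c("raised-cosine", "gaussian",
                                   "flat-with-ramps"),
                      source_level_rms = 94) {
  if (duration <= 0) stop("duration must be positive")
  if (!(f_start > f_end && f_end > 0)) stop("need f_start > f_end > 0")
  if (length(harmonic_levels) != n_harmonics)
    stop("harmonic_levels must have length n_harmonics")
  structure(list(duration = duration, f_start = f_start, f_end = f_end,
                 sweep_shape = match.arg(sweep_shape),
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_levels = harmonic_levels,
                 envelope = match.arg(envelope),
                 source_level_rms = source_level_rms),
            class = "call_spec")
}

# instantaneous phase (radians) of the first harmonic at times t for a spec
sweep_phase <- function(spec, t) {
  T_s <- spec$duration / 1000
  f0 <- spec$f_start; f1 <- spec$f_end
  if (spec$sweep_shape == "linear") {
    2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * T_s))
  } else {
    a <- (f0 / f1 - 1) / T_s          # f(t) = f0 / (1 + a t)
    2 * pi * f0 * log1p(a * t) / a
  }
}

# instantaneous frequency (Hz) of the first harmonic
sweep_frequency <- function(spec, t) {
  T_s <- spec$duration / 1000
  if (spec$sweep_shape == "linear") {
    spec$f_start + (spec$f_end - spec$f_start) * t / T_s
  } else {
    a <- (spec$f_start / spec$f_end - 1) / T_s
    spec$f_start / (1 + a * t)
  }
}

envelope_shape <- function(kind, n, sample_rate, ramp_ms = 0.2) {
  t <- seq_len(n)
  switch(kind,
    "raised-cosine" = 0.5 * (1 - cos(2 * pi * (t - 0.5) / n)),
    "gaussian" = exp(-((t - (n + 1) / 2)^2) / (2 * (n / 6)^2)),
    "flat-with-ramps" = {
      r <- min(as.integer(round(ramp_ms * sample_rate / 1000)), n %/% 2)
      e <- rep(1, n)
      if (r > 0) {
        ramp <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
        e[seq_len(r)] <- ramp
        e[n + 1 - seq_len(r)] <- ramp
      }
      e
    },
    stop("unknown envelope kind: ", kind))
}

# scale a waveform so rms within its -12 dB smoothed-envelope window hits
# level_db (dB SPL re. 20 uPa)
calibrate_level <- function(x, sample_rate, level_db, config = pipeline_config()) {
  env <- signal_envelope(x, sample_rate, config$envelope_smoothing)
  win <- envelope_window(env, config$duration_criterion)
  r <- sqrt(mean(x[win[1]:win[2]]^2))
  x * (20e-6 * 10^(level_db / 20)) / r
}

#' Synthesize a call waveform in pascals at the reference distance
#'
#' Renders the multi-harmonic FM sweep of a [call_spec()] and calibrates it so
#' the rms pressure within the -12 dB smoothed-envelope window equals the
#' specified source level.
#'
#' @param spec a [call_spec()].
#' @param sample_rate Hz; must be at least `4 * f_start` and keep every
#'   harmonic below Nyquist.
#' @param config a [pipeline_config()] (envelope smoothing / duration
#'   criterion used for level calibration).
#' @return numeric waveform, Pa at 0.1 m.
#' @export
synthesize_call <- function(spec, sample_rate, config = pipeline_config()) {
  stopifnot(inherits(spec, "call_spec"))
  if (sample_rate < 4 * spec$f_start)
    stop("sample_rate must be at least 4 * f_start")
  if (spec$n_harmonics * spec$f_start >= sample_rate / 2)
    stop("harmonic above Nyquist frequency")
  n <- as.integer(round(spec$duration * sample_rate / 1000))
  t <- (seq_len(n) - 1) / sample_rate
  phi <- sweep_phase(spec, t)
  env <- envelope_shape(spec$envelope, n, sample_rate)
  x <- numeric(n)
  for (k in seq_len(spec$n_harmonics))
    x <- x + 10^(spec$harmonic_levels[k] / 20) * sin(k * phi)
  calibrate_level(env * x, sample_rate, spec$source_level_rms, config)
}

#' Calibration playback signal specification
#'
#' The six playback signal types of the in-silico calibration design: two
#' pure tones, a linear and a hyperbolic FM sweep, an FM-qCF composite and a
#' band-limited noise burst, spanning the FM / FM-qCF call-shape contrast.
#'
#' @param signal_type one of `"tone_35k"`, `"tone_60k"`, `"fm_linear"`,
#'   `"fm_hyperbolic"`, `"fm_qcf"`, `"noise_burst"`.
#' @param duration ms; defaults per type (10 ms tones/noise, 5 ms sweeps,
#'   7 ms FM-qCF).
#' @param level dB SPL rms re. 20 uPa at 0.1 m; the 96 dB default keeps the
#'   high-crest-factor noise burst below full scale at the nearest grid
#'   distance of the calibration design.
#' @return object of class `cal_signal_spec`.
#' @export
calibration_signal_spec <- function(signal_type = calibration_signal_types(),
                                    duration = NULL, level = 96) {
  signal_type <- match.arg(signal_type)
  if (is.null(duration))
    duration <- switch(signal_type, tone_35k = 10, tone_60k = 10,
                       fm_linear = 5, fm_hyperbolic = 5, fm_qcf = 7,
                       noise_burst = 10)
  if (duration <= 0) stop("duration must be positive")
  structure(list(signal_type = signal_type, duration = duration,
                 level = level),
            class = "cal_signal_spec")
}

#' @rdname calibration_signal_spec
#' @return for `calibration_signal_types`: the six type names.
#' @export
calibration_signal_types <- function() {
  c("tone_35k", "tone_60k", "fm_linear", "fm_hyperbolic", "fm_qcf",
    "noise_burst")
}

#' Synthesize a calibration playback signal
#'
#' @param spec a [calibration_signal_spec()].
#' @param sample_rate Hz.
#' @param seed integer; only the noise burst uses randomness.
#' @param config a [pipeline_config()].
#' @return numeric waveform, Pa at 0.1 m.
#' @export
synthesize_signal <- function(spec, sample_rate, seed = 1,
                              config = pipeline_config()) {
  if (inherits(spec, "call_spec")) return(synthesize_call(spec, sample_rate, config))
  stopifnot(inherits(spec, "cal_signal_spec"))
  n <- as.integer(round(spec$duration * sample_rate / 1000))
  t <- (seq_len(n) - 1) / sample_rate
  ramps <- envelope_shape("flat-with-ramps", n, sample_rate, ramp_ms = 0.3)
  x <- switch(spec$signal_type,
    tone_35k = ramps * sin(2 * pi * 35e3 * t),
    tone_60k = ramps * sin(2 * pi * 60e3 * t),
    fm_linear = {
      cs <- call_spec(spec$duration, 85e3, 25e3, "linear", 1, 0,
                      "flat-with-ramps", spec$level)
      return(synthesize_call(cs, sample_rate, config))
    },
    fm_hyperbolic = {
      cs <- call_spec(spec$duration, 85e3, 25e3, "hyperbolic", 1, 0,
                      "flat-with-ramps", spec$level)
      return(synthesize_call(cs, sample_rate, config))
    },
    fm_qcf = {
      # downward sweep 50 -> 28 kHz over the first 40%, then quasi-constant
      # 28 kHz tail; phase kept continuous
      n_fm <- as.integer(round(0.4 * n))
      finst <- c(seq(50e3, 28e3, length.out = n_fm), rep(28e3, n - n_fm))
      phi <- 2 * pi * cumsum(finst) / sample_rate
      ramps * sin(phi)
    },
    noise_burst = {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      set.seed(seed)
      w <- stats::rnorm(n)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      # band-limit to 20-90 kHz in the frequency domain (raised-cosine edges)
      W <- stats::fft(w)
      f <- fft_frequencies(n, sample_rate)
      g <- band_taper(abs(f), 20e3, 90e3, 2e3)
      ramps * Re(stats::fft(W * g, inverse = TRUE)) / n
    })
  calibrate_level(x, sample_rate, spec$level, config)
}

# frequencies of the length-n DFT (two-sided, Hz)
fft_frequencies <- function(n, sample_rate) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  k * sample_rate / n
}

# smooth 0/1 band mask with raised-cosine transitions of given width
band_taper <- function(f, lo, hi, width) {
  g <- numeric(length(f))
  g[f >= lo & f <= hi] <- 1
  rise <- f > lo - width & f < lo
  g[rise] <- 0.5 * (1 - cos(pi * (f[rise] - (lo - width)) / width))
  fall <- f > hi & f < hi + width
  g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / width))
  g
}
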