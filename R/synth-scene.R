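#' Microphone frequency-response calibration
#'
#' Relative frequency response on a grid (0 dB at the reference frequency)
#' plus the absolute full-scale mapping. The default synthetic response is
#' flat over 20-90 kHz except for a -6 dB sensitivity dip around 70 kHz, a
#' typical imperfectly-compensated artefact of small electret ultrasound
#' microphones; a perfectly flat response is available for oracle tests.
#'
#' @param frequency strictly increasing frequency grid, Hz.
#' @param response_db relative response at each grid frequency, dB.
#' @param valid_band two frequencies bounding the calibrated band, Hz.
#' @param full_scale_pa pressure (Pa) mapped to full-scale amplitude 1.0.
#' @return object of class `mic_calibration`.
#' @export
mic_calibration <- function(frequency, response_db,
                            valid_band = c(20e3, 90e3), full_scale_pa = 0.5) {
  stopifnot(length(frequency) == length(response_db),
            all(diff(frequency) > 0), all(is.finite(response_db)),
            length(valid_band) == 2, full_scale_pa > 0)
  structure(list(frequency = frequency, response_db = response_db,
                 valid_band = valid_band, full_scale_pa = full_scale_pa),
            class = "mic_calibration")
}

#' @rdname mic_calibration
#' @param dip include the -6 dB dip at 70 kHz.
#' @export
default_mic_calibration <- function(dip = TRUE, full_scale_pa = 0.5) {
  f <- seq(5e3, 120e3, by = 1e3)
  r <- if (dip) -6 * exp(-((f - 70e3)^2) / (2 * 4e3^2)) else rep(0, length(f))
  mic_calibration(f, r, full_scale_pa = full_scale_pa)
}

#' @rdname mic_calibration
#' @export
flat_mic_calibration <- function(full_scale_pa = 0.5) {
  default_mic_calibration(dip = FALSE, full_scale_pa = full_scale_pa)
}

#' @rdname mic_calibration
#' @param cal a `mic_calibration`.
#' @param f frequencies to evaluate, Hz (clamped to the grid ends).
#' @return for `mic_response_db`: interpolated relative response, dB.
#' @export
mic_response_db <- function(cal, f) {
  stats::approx(cal$frequency, cal$response_db, xout = f, rule = 2)$y
}

#' Flight-trajectory specification
#'
#' A piecewise-linear 3D path flown at constant speed, with calls emitted at
#' a jittered regular interval and per-call source-level jitter.
#'
#' @param waypoints matrix (>= 2 rows x 3 columns), metres, all z > 0.
#' @param speed flight speed, m/s, in (0, 15].
#' @param call_interval mean call interval, ms.
#' @param interval_jitter_pct uniform jitter half-width on the interval, %.
#' @param level_jitter_sd per-call source-level jitter, dB s.d.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(waypoints, speed = 5, call_interval = 80,
                            interval_jitter_pct = 10, level_jitter_sd = 1) {
  waypoints <- as.matrix(waypoints)
  stopifnot(ncol(waypoints) == 3, nrow(waypoints) >= 2)
  if (!(speed > 0 && speed <= 15)) stop("speed must be in (0, 15] m/s")
  if (any(waypoints[, 3] <= 0)) stop("path must stay in the front hemisphere (z > 0)")
  structure(list(waypoints = waypoints, speed = speed,
                 call_interval = call_interval,
                 interval_jitter_pct = interval_jitter_pct,
                 level_jitter_sd = level_jitter_sd),
            class = "trajectory_spec")
}

# position along the piecewise-linear path at arc length s (clamped)
path_position <- function(waypoints, s) {
  seg <- diff(waypoints)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(which(cum <= s + 1e-12)[sum(cum <= s + 1e-12)], 1)
  i <- min(i, nrow(waypoints) - 1)
  frac <- (s - cum[i]) / len[i]
  waypoints[i, ] + frac * seg[i, ]
}

path_length <- function(waypoints) sum(sqrt(rowSums(diff(waypoints)^2)))

#' Generate the timed call emissions of one flight
#'
#' Walks the path at constant speed and emits calls at the jittered interval;
#' deterministic under `seed`. Errors if any point of the path comes within
#' 0.5 m of a microphone.
#'
#' @param tspec a [trajectory_spec()].
#' @param cspec the [call_spec()] emitted along the flight (its
#'   `source_level_rms` is jittered per call by `level_jitter_sd`).
#' @param seed integer seed.
#' @param geometry a [mic_array_geometry()] (for the clearance check).
#' @param t0 emission time of the first call, s.
#' @return data.frame with columns `time`, `x`, `y`, `z`,
#'   `source_level_rms` (one row per call).
#' @export
generate_trajectory <- function(tspec, cspec, seed = 1,
                                geometry = mic_array_geometry(), t0 = 0.05) {
  stopifnot(inherits(tspec, "trajectory_spec"), inherits(cspec, "call_spec"))
  wp <- tspec$waypoints
  total <- path_length(wp)
  s_grid <- seq(0, total, by = 0.05)
  pts <- t(vapply(s_grid, function(s) path_position(wp, s), numeric(3)))
  for (m in seq_len(nrow(geometry$mic_positions))) {
    d <- sqrt(rowSums(sweep(pts, 2, geometry$mic_positions[m, ])^2))
    if (any(d < 0.5)) stop("path comes within 0.5 m of a microphone")
  }
  flight_time <- total / tspec$speed
  n_max <- ceiling(flight_time / (tspec$call_interval / 1000) *
                     (1 + tspec$interval_jitter_pct / 100)) + 2L
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  jit <- stats::runif(n_max, -1, 1) * tspec$interval_jitter_pct / 100
  lev <- stats::rnorm(n_max, 0, tspec$level_jitter_sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  intervals <- tspec$call_interval / 1000 * (1 + jit)
  times <- t0 + c(0, cumsum(intervals))[seq_len(n_max)]
  keep <- (times - t0) <= flight_time
  times <- times[keep]
  pos <- t(vapply(times, function(tt)
    path_position(wp, (tt - t0) * tspec$speed), numeric(3)))
  data.frame(time = times, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             source_level_rms = cspec$source_level_rms + lev[seq_along(times)])
}

#' Synthetic acoustic scene
#'
#' A scene is a list of timed emission events (each with a position and a
#' waveform specification), the weather, the microphone calibration and the
#' recording-chain parameters. Build scenes with [flight_scene()] or
#' [make_calibration_scene()].
#'
#' @param events list of events: each a list with `id`, `trajectory_id`,
#'   `time` (s), `position` (3-vector, m), `spec` ([call_spec()] or
#'   [calibration_signal_spec()]), optional `meta` (named list).
#' @param weather a [weather_record()].
#' @param mic_cal a [mic_calibration()].
#' @param noise_floor Gaussian background level, dBFS rms (`-Inf` = noiseless).
#' @param sample_rate Hz.
#' @param seed default seed used by [render_scene()].
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(events, weather, mic_cal = default_mic_calibration(),
                       noise_floor = -60, sample_rate = 500e3, seed = 1) {
  stopifnot(inherits(weather, "weather_record"),
            inherits(mic_cal, "mic_calibration"))
  structure(list(events = events, weather = weather, mic_cal = mic_cal,
                 noise_floor = noise_floor, sample_rate = sample_rate,
                 seed = seed),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @param sources list of `list(trajectory = trajectory_spec, call = call_spec)`.
#' @param geometry a [mic_array_geometry()].
#' @param t0 first-call time of each flight, s (recycled).
#' @param ... passed to [scene_spec()].
#' @export
flight_scene <- function(sources, weather,
                         geometry = mic_array_geometry(), t0 = 0.05,
                         seed = 1, ...) {
  t0 <- rep_len(t0, length(sources))
  events <- list()
  for (j in seq_along(sources)) {
    src <- sources[[j]]
    calls <- generate_trajectory(src$trajectory, src$call, seed = seed + j,
                                 geometry = geometry, t0 = t0[j])
    for (i in seq_len(nrow(calls))) {
      sp <- src$call
      sp$source_level_rms <- calls$source_level_rms[i]
      events[[length(events) + 1]] <- list(
        id = sprintf("t%d_c%03d", j, i), trajectory_id = j,
        time = calls$time[i],
        position = c(calls$x[i], calls$y[i], calls$z[i]), spec = sp)
    }
  }
  scene_spec(events, weather, seed = seed, ...)
}

#' Calibration playback scene: 3 azimuths x 3 elevations x 5 distances
#'
#' Reproduces a loudspeaker calibration design: six signal types broadcast
#' from each of 45 positions (3 azimuthal x 3 elevational directions x 5
#' distances from 3 to 10 m, uniformly spaced). Positions lie along
#' directions `(sin az cos el, sin el, cos az cos el)` in front of the array.
#'
#' @param weather a [weather_record()].
#' @param signals list of the six [calibration_signal_spec()]s.
#' @param azimuths_deg,elevations_deg,distances the grid (degrees, degrees,
#'   metres).
#' @param spacing_ms time between consecutive playback events, ms.
#' @param mic_cal,noise_floor,sample_rate,seed passed to [scene_spec()].
#' @return a [scene_spec()] whose events carry `meta` fields `azimuth`,
#'   `elevation`, `distance`, `signal_type`.
#' @export
make_calibration_scene <- function(weather = weather_record(15, 60),
                                   signals = lapply(calibration_signal_types(),
                                                    calibration_signal_spec),
                                   azimuths_deg = c(-30, 0, 30),
                                   elevations_deg = c(-20, 0, 20),
                                   distances = seq(3, 10, length.out = 5),
                                   spacing_ms = 50,
                                   mic_cal = default_mic_calibration(full_scale_pa = 0.125),
                                   noise_floor = -Inf, sample_rate = 500e3,
                                   seed = 1) {
  events <- list()
  k <- 0L
  for (az in azimuths_deg) for (el in elevations_deg) for (d in distances) {
    a <- az * pi / 180; e <- el * pi / 180
    u <- c(sin(a) * cos(e), sin(e), cos(a) * cos(e))
    for (s in seq_along(signals)) {
      k <- k + 1L
      events[[k]] <- list(
        id = sprintf("az%+d_el%+d_d%04.2f_%s", az, el, d,
                     signals[[s]]$signal_type),
        trajectory_id = NA_integer_,
        time = 0.02 + (s - 1) * spacing_ms / 1000,
        position = d * u, spec = signals[[s]],
        meta = list(azimuth = az, elevation = el, distance = d,
                    signal_type = signals[[s]]$signal_type,
                    position_id = sprintf("az%+d_el%+d_d%04.2f", az, el, d)))
    }
  }
  scene_spec(events, weather, mic_cal = mic_cal, noise_floor = noise_floor,
             sample_rate = sample_rate, seed = seed)
}

#' Canonical single-bat approach scene
#'
#' A zig-zag approach flight from ~12.4 m down to ~1 m in front of the
#' array, emitting a fixed number of calls at a jittered interval - the
#' standard ground-truthed scene for end-to-end recovery studies. Noiseless
#' and flat-microphone by default so that recovery errors isolate the
#' analysis chain.
#'
#' @param seed scene seed.
#' @param n_calls number of calls emitted along the flight.
#' @param level call source level, dB SPL rms at 0.1 m.
#' @param full_scale_pa recording full-scale mapping, Pa.
#' @param speed flight speed, m/s.
#' @param noise_floor dBFS rms (`-Inf` = noiseless).
#' @param weather a [weather_record()].
#' @return a [scene_spec()].
#' @export
example_flight_scene <- function(seed = 1, n_calls = 100, level = 94,
                                 full_scale_pa = 0.25, speed = 3,
                                 noise_floor = -Inf,
                                 weather = weather_record(15, 60)) {
  wp <- rbind(c(-3, 2, 12), c(1, 0.8, 7.5), c(-1.5, 1.5, 4), c(0.3, 0.3, 1))
  flight_time <- path_length(wp) / speed
  tspec <- trajectory_spec(wp, speed = speed,
                           call_interval = 1000 * flight_time / n_calls,
                           interval_jitter_pct = 5, level_jitter_sd = 1)
  flight_scene(list(list(trajectory = tspec,
                         call = call_spec(source_level_rms = level))),
               weather, mic_cal = flat_mic_calibration(full_scale_pa),
               noise_floor = noise_floor, seed = seed)
}

# windowed-sinc fractional-delay kernel (delay = frac samples, 0 <= frac < 1)
sinc_kernel <- function(frac, half_width = 40, beta = 8) {
  m <- -half_width:half_width
  x <- m - frac
  s <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  w <- signal::kaiser(2 * half_width + 1, beta)
  # shift the window centre to the delayed sample for symmetry
  s * stats::approx(m, w, xout = x, rule = 2)$y
}

#' Render a scene to a ground-truthed multichannel recording
#'
#' Physical forward model: each event's source waveform (Pa at 0.1 m) is, per
#' microphone, attenuated by spherical spreading, filtered by atmospheric
#' absorption (frequency domain) and the microphone response, delayed by the
#' exact travel time (integer shift + windowed-sinc fractional delay), summed
#' into the channel, converted to full-scale units, mixed with Gaussian noise
#' at the scene noise floor and quantized to 16 bits. Clipping never
#' truncates silently: affected events are flagged in the manifest.
#'
#' @param scene a [scene_spec()].
#' @param geometry a [mic_array_geometry()].
#' @param seed overrides the scene seed.
#' @param config a [pipeline_config()] (truth-parameter estimators).
#' @return list with `recording` (a [multichannel_recording()]) and `truth`
#'   (data.frame, one row per event: id, trajectory_id, emission time,
#'   position, distance to the central mic, true duration/levels/frequencies
#'   measured on the clean source waveform, clipping flag, and any grid
#'   metadata).
#' @export
render_scene <- function(scene, geometry = mic_array_geometry(),
                         seed = scene$seed, config = pipeline_config()) {
  stopifnot(inherits(scene, "scene_spec"))
  fs <- scene$sample_rate
  cs <- speed_of_sound(scene$weather)
  mics <- geometry$mic_positions
  n_mic <- nrow(mics)
  max_delay <- 0
  end_time <- 0.05
  durations <- vapply(scene$events, function(e) e$spec$duration, numeric(1))
  for (i in seq_along(scene$events)) {
    e <- scene$events[[i]]
    dmax <- max(sqrt(rowSums(sweep(mics, 2, e$position)^2)))
    end_time <- max(end_time, e$time + durations[i] / 1000 + dmax / cs)
    max_delay <- max(max_delay, dmax / cs)
  }
  n <- ceiling((end_time + 0.02) * fs)
  channels <- matrix(0, n, n_mic)
  half_w <- 40L
  truth <- vector("list", length(scene$events))
  for (i in seq_along(scene$events)) {
    e <- scene$events[[i]]
    w <- synthesize_signal(e$spec, fs,
                           seed = (seed + i * 7919L) %% 2147483647L,
                           config = config)
    # truth parameters from the clean source waveform
    dur <- measure_duration_wave(w, fs, config)
    lv <- measure_levels_wave(w, fs, dur$window, config)
    fr <- measure_frequencies_wave(w, fs, config)
    d_c <- sqrt(sum((e$position - mics[geometry$central_index, ])^2))
    L <- stats::nextn(length(w) + 512, 2)
    Wf <- stats::fft(c(w, numeric(L - length(w))))
    f2 <- fft_frequencies(L, fs)
    alpha <- absorption_coefficient(abs(f2), scene$weather)
    mic_db <- mic_response_db(scene$mic_cal, abs(f2))
    ev_clip <- FALSE
    for (m in seq_len(n_mic)) {
      d <- sqrt(sum((e$position - mics[m, ])^2))
      gain_db <- -alpha * (d - config$reference_distance) + mic_db
      y <- Re(stats::fft(Wf * 10^(gain_db / 20), inverse = TRUE)) / L
      y <- y * (config$reference_distance / d)
      s0 <- e$time * fs + d / cs * fs
      i0 <- floor(s0); frac <- s0 - i0
      h <- sinc_kernel(frac, half_w)
      yd <- stats::convolve(y, rev(h), type = "open")
      idx <- (i0 - half_w + 1):(i0 - half_w + length(yd))
      ok <- idx >= 1 & idx <= n
      channels[idx[ok], m] <- channels[idx[ok], m] + yd[ok]
    }
    truth[[i]] <- data.frame(
      id = e$id, trajectory_id = e$trajectory_id, time = e$time,
      x = e$position[1], y = e$position[2], z = e$position[3],
      distance = d_c,
      duration_true = dur$duration_ms,
      rms_spl_true = lv$rms_spl, pe_spl_true = lv$pe_spl,
      peak_khz_true = fr$peak_frequency / 1e3,
      lowest_khz_true = fr$lowest_frequency / 1e3,
      clipped = ev_clip, stringsAsFactors = FALSE)
    if (!is.null(e$meta))
      truth[[i]] <- cbind(truth[[i]],
                          as.data.frame(e$meta, stringsAsFactors = FALSE))
  }
  x <- channels / scene$mic_cal$full_scale_pa
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed((seed + 104729L) %% 2147483647L)
  if (is.finite(scene$noise_floor))
    x <- x + matrix(stats::rnorm(n * n_mic, 0, 10^(scene$noise_floor / 20)),
                    n, n_mic)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  truth <- do.call(rbind, truth)
  # clipping check per event on the central channel span
  clipped_samples <- which(abs(x) >= 1, arr.ind = TRUE)
  if (nrow(clipped_samples) > 0) {
    tclip <- clipped_samples[, 1] / fs
    for (i in seq_len(nrow(truth))) {
      t_lo <- truth$time[i]; t_hi <- truth$time[i] + durations[i] / 1000 + max_delay
      if (any(tclip >= t_lo & tclip <= t_hi)) truth$clipped[i] <- TRUE
    }
    warning(sprintf("%d samples clipped at full scale", nrow(clipped_samples)))
  }
  x[x > 1] <- 1; x[x < -1] <- -1
  x <- round(x * 32767) / 32767
  rec <- multichannel_recording(x, fs, seq_len(n_mic),
                                scene$mic_cal$full_scale_pa)
  list(recording = rec, truth = truth)
}

#' Read/write a truth manifest as CSV
#' @param truth data.frame from [render_scene()].
#' @param path file path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
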