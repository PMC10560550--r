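test_that("synthesized calls hit the requested level and sweep law", {
  fs <- 500e3
  # 94 dB SPL rms re. 20 uPa corresponds to ~1.002 Pa rms
  sp <- call_spec(duration = 2.5, f_start = 45e3, f_end = 25e3,
                  n_harmonics = 1, harmonic_levels = 0,
                  envelope = "flat-with-ramps", source_level_rms = 94)
  x <- synthesize_call(sp, fs)
  expect_equal(sqrt(mean(x^2)), 1.002, tolerance = 0.01)

  # instantaneous frequency from the unwrapped phase follows the linear law
  z <- echotrack:::analytic_signal(x)
  phi <- cumsum(c(0, Arg(Conj(z[-length(z)]) * z[-1])))  # unwrapped increments
  finst <- diff(phi) * fs / (2 * pi)
  n <- length(x)
  t <- (seq_len(n - 1) - 0.5) / fs
  f_law <- 45e3 + (25e3 - 45e3) * t / (2.5e-3)
  core <- seq(round(0.1 * n), round(0.9 * n))   # away from edge transients
  expect_lt(max(abs(finst[core] - f_law[core]) / f_law[core]), 0.01)

  # hyperbolic law as well
  sph <- call_spec(duration = 2.5, f_start = 45e3, f_end = 25e3,
                   sweep_shape = "hyperbolic", n_harmonics = 1,
                   harmonic_levels = 0, envelope = "flat-with-ramps")
  xh <- synthesize_call(sph, fs)
  zh <- echotrack:::analytic_signal(xh)
  phih <- cumsum(c(0, Arg(Conj(zh[-length(zh)]) * zh[-1])))
  finsth <- diff(phih) * fs / (2 * pi)
  a <- (45 / 25 - 1) / 2.5e-3
  f_lawh <- 45e3 / (1 + a * t)
  expect_lt(max(abs(finsth[core] - f_lawh[core]) / f_lawh[core]), 0.01)

  expect_error(call_spec(duration = 0), "positive")
  expect_error(synthesize_call(call_spec(n_harmonics = 6,
                                         harmonic_levels = rep(0, 6)), fs),
               "Nyquist")
})

test_that("all six calibration signal types synthesize at the requested level", {
  fs <- 500e3
  types <- calibration_signal_types()
  expect_length(types, 6)
  cfg <- pipeline_config()
  for (ty in types) {
    sp <- calibration_signal_spec(ty, level = 96)
    x <- synthesize_signal(sp, fs, seed = 5)
    env <- signal_envelope(x, fs, cfg$envelope_smoothing)
    win <- echotrack:::envelope_window(env, cfg$duration_criterion)
    spl <- 20 * log10(sqrt(mean(x[win[1]:win[2]]^2)) / 20e-6)
    expect_equal(spl, 96, tolerance = 0.1)
  }
  # tones sit at their nominal frequencies
  x35 <- synthesize_signal(calibration_signal_spec("tone_35k"), fs)
  fr <- measure_frequencies_wave(x35, fs)
  expect_equal(fr$peak_frequency, 35e3, tolerance = 300 / 35e3)
})

test_that("trajectory generation is deterministic and respects timing and clearance", {
  geom <- std_geometry()
  cs <- call_spec()
  straight <- trajectory_spec(rbind(c(0, 0, 10), c(0, 0, 2)), speed = 5,
                              call_interval = 100, interval_jitter_pct = 0,
                              level_jitter_sd = 0)
  calls <- generate_trajectory(straight, cs, seed = 1, geometry = geom)
  # 8 m at 5 m/s = 1.6 s flight, 100 ms interval -> 17 calls including t0
  expect_equal(nrow(calls), 17)
  expect_equal(diff(calls$time), rep(0.1, 16), tolerance = 1e-12)
  calls2 <- generate_trajectory(straight, cs, seed = 1, geometry = geom)
  expect_identical(calls, calls2)
  jittered <- trajectory_spec(rbind(c(0, 0, 10), c(0, 0, 2)), speed = 5,
                              call_interval = 100, interval_jitter_pct = 20)
  cj <- generate_trajectory(jittered, cs, seed = 3, geometry = geom)
  expect_gt(stats::sd(diff(cj$time)), 0)
  too_close <- trajectory_spec(rbind(c(0, 0, 5), c(0, 0, 0.2)), speed = 5)
  expect_error(generate_trajectory(too_close, cs, geometry = geom), "0.5 m")
})

test_that("rendered arrivals reproduce the forward TDOA model", {
  geom <- std_geometry(); w <- std_weather()
  ev <- list(list(id = "c1", trajectory_id = 1L, time = 0.01,
                  position = c(0.8, -0.5, 5), spec = call_spec()))
  sc <- scene_spec(ev, w, mic_cal = flat_mic_calibration(0.25),
                   noise_floor = -Inf)
  r <- render_scene(sc, geom, seed = 2)
  fs <- r$recording$sample_rate
  cs <- speed_of_sound(w)
  tau_exp <- expected_tdoas(c(0.8, -0.5, 5), geom, cs)
  # arrival time per channel from the envelope peak
  pk <- apply(r$recording$samples, 2, function(ch)
    which.max(signal_envelope(ch, fs, 0.2)))
  tau_meas <- (pk[2:4] - pk[1]) / fs
  expect_equal(tau_meas, tau_exp, tolerance = 1 / fs / max(abs(tau_exp)),
               ignore_attr = TRUE)
})

test_that("received amplitude follows spherical spreading plus absorption", {
  geom <- std_geometry(); w <- std_weather()
  mk <- function(d) {
    ev <- list(list(id = "c1", trajectory_id = 1L, time = 0.01,
                    position = c(0, 0, d),
                    spec = call_spec(n_harmonics = 1, harmonic_levels = 0)))
    sc <- scene_spec(ev, w, mic_cal = flat_mic_calibration(0.25),
                     noise_floor = -Inf)
    r <- render_scene(sc, geom, seed = 2)
    max(abs(r$recording$samples[, 1]))
  }
  p3 <- mk(3); p6 <- mk(6)
  # one doubling: -6.02 dB spreading, plus absorption over the extra 3 m at
  # the call's dominant frequency (~38 kHz)
  alpha <- absorption_coefficient(38e3, w)
  expect_equal(20 * log10(p6 / p3), -6.02 - alpha * 3, tolerance = 0.01)
})

test_that("empty scenes are pure noise at the floor and rendering is deterministic", {
  geom <- std_geometry(); w <- std_weather()
  sc <- scene_spec(list(), w, noise_floor = -60)
  r <- render_scene(sc, geom, seed = 9)
  lev <- 20 * log10(apply(r$recording$samples, 2, function(x) sqrt(mean(x^2))))
  expect_true(all(abs(lev - (-60)) < 0.5))
  r2 <- render_scene(sc, geom, seed = 9)
  expect_identical(r$recording$samples, r2$recording$samples)
  r3 <- render_scene(sc, geom, seed = 10)
  expect_false(identical(r$recording$samples, r3$recording$samples))
})

test_that("the calibration grid is 45 positions x 6 signals with uniform distances", {
  sc <- make_calibration_scene()
  expect_length(sc$events, 270)
  meta <- do.call(rbind, lapply(sc$events, function(e)
    data.frame(pos = e$meta$position_id, d = e$meta$distance)))
  expect_equal(length(unique(meta$pos)), 45)
  expect_equal(sort(unique(meta$d)), c(3, 4.75, 6.5, 8.25, 10))
})

test_that("WAV files round-trip through write and read", {
  geom <- std_geometry()
  sc <- scene_spec(list(), std_weather(), noise_floor = -40)
  r <- render_scene(sc, geom, seed = 1)
  path <- tempfile(fileext = ".wav")
  write_wav(r$recording, path)
  rec2 <- read_wav(path, full_scale_pa = r$recording$full_scale_pa)
  expect_equal(rec2$sample_rate, r$recording$sample_rate)
  expect_equal(dim(rec2$samples), dim(r$recording$samples))
  # rendering already quantizes to 16 bits, so IO is lossless here
  expect_equal(rec2$samples, r$recording$samples, tolerance = 1e-12)
})
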