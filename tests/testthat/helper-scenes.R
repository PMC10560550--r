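# shared fixture builders: everything is generated in code at test time

std_geometry <- function() mic_array_geometry()
std_weather <- function() weather_record(15, 60)

# a short single-bat flight approaching the array, noiseless and flat-mic so
# recovery errors isolate the analysis chain
noiseless_flight <- function(n_calls = 12, seed = 11,
                             waypoints = rbind(c(-2, 1, 9), c(0, 0.5, 5),
                                               c(1, 1, 2)),
                             speed = 5, level = 94, full_scale_pa = 0.25) {
  interval <- 1000 * path_total_time(waypoints, speed) / n_calls
  tspec <- trajectory_spec(waypoints, speed = speed, call_interval = interval,
                           interval_jitter_pct = 5, level_jitter_sd = 1)
  cspec <- call_spec(source_level_rms = level)
  flight_scene(list(list(trajectory = tspec, call = cspec)), std_weather(),
               mic_cal = flat_mic_calibration(full_scale_pa),
               noise_floor = -Inf, seed = seed)
}

path_total_time <- function(waypoints, speed) {
  sum(sqrt(rowSums(diff(waypoints)^2))) / speed
}

# config for noiseless synthetic scenes: same chain, lower detection
# threshold (no ambient noise to reject)
noiseless_config <- function(...) {
  pipeline_config(detection_threshold = -50, ...)
}

# deterministic pseudo-random source positions in the front hemisphere,
# 1-15 m range
random_front_sources <- function(n, seed, r_min = 1, r_max = 15) {
  set.seed(seed)
  r <- runif(n, r_min, r_max)
  az <- runif(n, -60, 60) * pi / 180
  el <- runif(n, -45, 45) * pi / 180
  cbind(r * sin(az) * cos(el), r * sin(el), r * cos(az) * cos(el))
}
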