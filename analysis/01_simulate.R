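#!/usr/bin/env Rscript
# Step 1: simulate a field session - five bats released one after another,
# each flying an approach path past the four-microphone star array while
# echolocating. Writes the multichannel recordings, the ground-truth
# manifests and the shared configuration under results/.

suppressPackageStartupMessages(library(echotrack))
set.seed(42)
dir.create("results/recordings", recursive = TRUE, showWarnings = FALSE)

geom <- mic_array_geometry()
weather <- weather_record(15, 60)           # mild late-summer night
write_geometry_yaml(geom, "results/array_geometry.yaml")
write_weather_yaml(weather, "results/weather.yaml")

# five individuals: slightly different flight styles and source levels
flights <- list(
  list(wp = rbind(c(-3, 2, 12), c(1, 0.8, 7.5), c(-1.5, 1.5, 4), c(0.3, 0.3, 1)),
       speed = 3.5, level = 92),
  list(wp = rbind(c(4, 1, 11), c(0, 1.5, 6), c(-2, 0.8, 2)),
       speed = 4.5, level = 95),
  list(wp = rbind(c(-4, 0.5, 10), c(0.5, 1.2, 5.5), c(2, 0.5, 1.5)),
       speed = 5, level = 90),
  list(wp = rbind(c(2, 2.5, 12), c(-0.5, 1, 7), c(0.8, 1.8, 2.5)),
       speed = 4, level = 94),
  list(wp = rbind(c(0, 3, 11), c(1.5, 1, 6.5), c(-1, 0.5, 2)),
       speed = 5.5, level = 97))

for (i in seq_along(flights)) {
  fl <- flights[[i]]
  tspec <- trajectory_spec(fl$wp, speed = fl$speed, call_interval = 85,
                           interval_jitter_pct = 15, level_jitter_sd = 1.5)
  cspec <- call_spec(source_level_rms = fl$level)
  sc <- flight_scene(list(list(trajectory = tspec, call = cspec)), weather,
                     mic_cal = default_mic_calibration(full_scale_pa = 0.25),
                     noise_floor = -55, seed = 100 + i)
  r <- render_scene(sc, geom)
  write_wav(r$recording, sprintf("results/recordings/bat%02d.wav", i))
  write_truth_csv(r$truth, sprintf("results/recordings/bat%02d_truth.csv", i))
  message(sprintf("bat %d: %d calls at %.0f dB SPL rms, %.1f s of audio",
                  i, nrow(r$truth), fl$level,
                  nrow(r$recording$samples) / r$recording$sample_rate))
}
message("wrote recordings, truth manifests and config under results/")
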