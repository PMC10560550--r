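test_that("speed of sound follows the stated closed form and is monotone", {
  expect_equal(speed_of_sound(weather_record(0, 50)), 331.3)
  expect_equal(speed_of_sound(weather_record(20, 50)),
               331.3 * sqrt(1 + 20 / 273.15))
  temps <- seq(-40, 60, by = 5)
  cs <- vapply(temps, function(T) speed_of_sound(weather_record(T, 50)),
               numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_error(weather_record(-60, 50), "temperature")
})

test_that("absorption matches an independent reference within 5% and behaves physically", {
  ref <- read.csv(system.file("extdata", "iso9613_reference_synthetic.csv",
                              package = "echotrack"))
  alpha <- mapply(function(f, T, rh, p)
    absorption_coefficient(f, weather_record(T, rh, p)),
    ref$frequency_hz, ref$temperature_c, ref$rh_pct, ref$pressure_kpa)
  rel <- abs(alpha - ref$alpha_db_per_m) / ref$alpha_db_per_m
  expect_lt(max(rel), 0.05)

  # limit f -> 0 gives alpha -> 0 (alpha ~ f^2)
  expect_lt(absorption_coefficient(1, weather_record(20, 50)), 1e-6)
  expect_lt(absorption_coefficient(0.01, weather_record(20, 50)),
            absorption_coefficient(1, weather_record(20, 50)) / 1e3)

  # non-decreasing in frequency over the analysis band, several conditions
  fgrid <- seq(20e3, 90e3, by = 1e3)
  for (w in list(weather_record(0, 30), weather_record(15, 60),
                 weather_record(30, 90))) {
    a <- absorption_coefficient(fgrid, w)
    expect_true(all(diff(a) > -1e-12))
    expect_true(all(a >= 0))
  }

  # components are non-negative and sum to the total
  comp <- absorption_components(c(30e3, 60e3), weather_record(10, 40))
  expect_true(all(comp >= 0))
  expect_equal(rowSums(comp),
               absorption_coefficient(c(30e3, 60e3), weather_record(10, 40)))

  expect_error(absorption_coefficient(300e3, weather_record(20, 50)),
               "validated band")
})

test_that("spreading gain is the free-field 1/r law and antisymmetric", {
  expect_equal(spreading_gain(0.1, 0.1), 0)
  expect_equal(spreading_gain(1, 0.1), 20)
  expect_equal(spreading_gain(10, 0.1), 40)
  set.seed(4)
  d <- runif(20, 0.05, 30); r <- runif(20, 0.05, 30)
  expect_equal(spreading_gain(d, r) + spreading_gain(r, d), rep(0, 20))
  expect_error(spreading_gain(-1, 0.1), "positive")
})

test_that("expected TDOAs match direct geometry and the far-field limit", {
  geom <- std_geometry()
  c_s <- 343
  # axial source: all three TDOAs equal and positive
  tau <- expected_tdoas(c(0, 0, 3), geom, c_s)
  expect_equal(tau, rep((sqrt(9 + 0.36) - 3) / c_s, 3))
  expect_true(all(tau > 0))
  # far field: tau_i -> -(u . p_i)/c for a distant source
  u <- c(0.3, -0.2, 0.933); u <- u / sqrt(sum(u^2))
  tau_far <- expected_tdoas(1e3 * u, geom, c_s)
  per <- geom$mic_positions[-1, ]
  plane <- -(per %*% u) / c_s
  expect_equal(tau_far, as.numeric(plane), tolerance = 1e-3)
  # bound |tau| <= baseline / c for arbitrary front-hemisphere sources
  src <- random_front_sources(50, seed = 2)
  for (i in seq_len(nrow(src)))
    expect_true(all(abs(expected_tdoas(src[i, ], geom, c_s)) <= 0.6 / c_s + 1e-12))
  expect_error(expected_tdoas(c(0, 0, 3), geom, -1), "positive")
  expect_error(expected_tdoas(c(0.6 * cos(pi / 2), 0.6 * sin(pi / 2), 0),
                              geom, c_s), "coincides")
})

test_that("star-array invariants are enforced and geometry round-trips via YAML", {
  geom <- std_geometry()
  r <- sqrt(rowSums(geom$mic_positions[-1, ]^2))
  expect_equal(r, rep(0.6, 3), tolerance = 1e-12)
  expect_error(mic_array_geometry(mic_positions = rbind(c(0, 0, 0),
    c(0.6, 0, 0), c(-0.3, sqrt(0.27), 0),
    c(-0.3, -sqrt(0.23), 0.2))), "coplanar")
  expect_error(mic_array_geometry(mic_positions = rbind(c(0, 0, 0),
    c(0.7, 0, 0), c(-0.3, 0.52, 0), c(-0.3, -0.52, 0))), "equidistant")
  path <- tempfile(fileext = ".yaml")
  write_geometry_yaml(geom, path)
  geom2 <- read_geometry_yaml(path)
  expect_equal(geom2$mic_positions, geom$mic_positions, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("weather validation, nearest-in-time lookup and config IO work", {
  expect_error(weather_record(20, 140), "humidity")
  expect_error(weather_record(20, 50, -1), "pressure")
  log <- data.frame(timestamp = c(0, 120, 240), temperature = c(14, 15, 16),
                    relative_humidity = c(60, 62, 64),
                    pressure = c(101, 101, 101))
  expect_equal(weather_at(log, 130)$temperature, 15)
  expect_equal(weather_at(log, 200)$temperature, 16)
  cfg <- pipeline_config(detection_threshold = -40)
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  expect_equal(read_config_yaml(path)$detection_threshold, -40)
})
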