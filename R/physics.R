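#' Four-microphone star-array geometry
#'
#' Builds the canonical planar star array: one central microphone at the
#' origin and three peripherals at equal radius and 120 degree angular
#' separation in the x-y plane. The array faces +z; all localization is done
#' in this frame (right-handed, sources assumed at z > 0).
#'
#' @param radius peripheral distance from the central microphone, metres.
#' @param azimuths_deg in-plane azimuths of the three peripherals, degrees
#'   measured counter-clockwise from +x.
#' @param mic_positions optional 4 x 3 matrix of positions (metres), row 1 =
#'   central microphone; overrides `radius`/`azimuths_deg`. Must satisfy the
#'   star-array invariants (coplanar, equal radius, 120 deg separation).
#' @return object of class `mic_array_geometry` with elements `mic_positions`
#'   (4 x 3 matrix, metres) and `central_index` (always 1).
#' @export
mic_array_geometry <- function(radius = 0.6, azimuths_deg = c(90, 210, 330),
                               mic_positions = NULL) {
  if (is.null(mic_positions)) {
    az <- azimuths_deg * pi / 180
    mic_positions <- rbind(c(0, 0, 0),
                           cbind(radius * cos(az), radius * sin(az), 0))
  }
  mic_positions <- as.matrix(mic_positions)
  if (!all(dim(mic_positions) == c(4, 3)))
    stop("geometry requires exactly 4 microphones with 3D positions")
  geom <- structure(list(mic_positions = mic_positions, central_index = 1L),
                    class = "mic_array_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  p <- geom$mic_positions
  ctr <- p[geom$central_index, ]
  per <- p[-geom$central_index, , drop = FALSE]
  rel <- sweep(per, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  if (any(abs(r - r[1]) > 1e-9))
    stop("peripheral microphones must be equidistant from the central microphone")
  # coplanarity: peripherals + central must lie in one plane
  n <- pracma_cross(rel[1, ], rel[2, ])
  if (abs(sum(n * rel[3, ])) > 1e-9 * r[1]^3)
    stop("microphones are not coplanar")
  ang <- function(a, b) acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  angs <- c(ang(rel[1, ], rel[2, ]), ang(rel[2, ], rel[3, ]), ang(rel[1, ], rel[3, ]))
  if (any(abs(angs - 2 * pi / 3) > 1e-6))
    stop("peripheral microphones must be separated by 120 degrees")
  invisible(geom)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' @export
print.mic_array_geometry <- function(x, ...) {
  cat("Star microphone array: central mic at origin, 3 peripherals, radius",
      format(sqrt(sum(x$mic_positions[2, ]^2)), digits = 3), "m\n")
  invisible(x)
}

#' Weather record for propagation modelling
#'
#' @param temperature air temperature, degrees Celsius (physical range -40..60).
#' @param relative_humidity relative humidity, percent (0..100).
#' @param pressure atmospheric pressure, kPa.
#' @param timestamp seconds (used for nearest-in-time lookup in weather logs).
#' @return object of class `weather_record`.
#' @export
weather_record <- function(temperature, relative_humidity,
                           pressure = 101.325, timestamp = 0) {
  if (!is.finite(temperature) || temperature < -40 || temperature > 60)
    stop("temperature outside physical range [-40, 60] degC")
  if (!is.finite(relative_humidity) || relative_humidity < 0 || relative_humidity > 100)
    stop("relative humidity must be in [0, 100] %")
  if (!is.finite(pressure) || pressure <= 0)
    stop("pressure must be positive (kPa)")
  structure(list(temperature = temperature,
                 relative_humidity = relative_humidity,
                 pressure = pressure, timestamp = timestamp),
            class = "weather_record")
}

#' Nearest-in-time weather lookup from a log
#'
#' Weather loggers typically sample every couple of minutes; each call is
#' assigned the nearest sample in time (no interpolation).
#'
#' @param log data.frame with columns `timestamp`, `temperature`,
#'   `relative_humidity`, `pressure` (e.g. from [read_weather_log()]).
#' @param time seconds.
#' @return a [weather_record()].
#' @export
weather_at <- function(log, time) {
  i <- which.min(abs(log$timestamp - time))
  weather_record(log$temperature[i], log$relative_humidity[i],
                 log$pressure[i], log$timestamp[i])
}

#' @rdname weather_at
#' @param path CSV file with the four weather-log columns.
#' @export
read_weather_log <- function(path) {
  log <- utils::read.csv(path)
  need <- c("timestamp", "temperature", "relative_humidity", "pressure")
  if (!all(need %in% names(log))) stop("weather log must have columns: ",
                                       paste(need, collapse = ", "))
  log
}

#' Speed of sound in air
#'
#' Temperature-only closed form `c(T) = 331.3 * sqrt(1 + T/273.15)` m/s.
#' Humidity and pressure corrections are below 0.5% over the conditions this
#' chain targets and are deliberately ignored.
#'
#' @param weather a [weather_record()].
#' @return speed of sound, m/s.
#' @export
speed_of_sound <- function(weather) {
  stopifnot(inherits(weather, "weather_record"))
  331.3 * sqrt(1 + weather$temperature / 273.15)
}

#' Atmospheric absorption of sound in humid air (pure-tone model)
#'
#' ISO 9613-1 analytic pure-tone attenuation coefficient: classical
#' (translational/rotational) absorption plus molecular relaxation of oxygen
#' and nitrogen, as a function of frequency, temperature, relative humidity
#' and pressure. Strong at ultrasonic frequencies (order 1 dB/m around
#' 40 kHz under temperate conditions), which is why the compensation chain
#' must apply it per frequency and distance.
#'
#' @param frequency frequency in Hz (vectorized); validated 0..250 kHz.
#' @param weather a [weather_record()].
#' @return attenuation coefficient alpha, dB per metre (same length as
#'   `frequency`).
#' @seealso [absorption_components()] for the separate terms.
#' @export
absorption_coefficient <- function(frequency, weather) {
  rowSums(as.matrix(absorption_components(frequency, weather)))
}

#' @rdname absorption_coefficient
#' @return for `absorption_components`: data.frame with columns `classical`,
#'   `oxygen`, `nitrogen` (dB/m), summing to the total coefficient.
#' @export
absorption_components <- function(frequency, weather) {
  stopifnot(inherits(weather, "weather_record"))
  if (any(!is.finite(frequency)) || any(frequency < 0) || any(frequency > 250e3))
    stop("frequency outside validated band [0, 250 kHz]")
  f <- frequency
  T_k <- weather$temperature + 273.15
  T0 <- 293.15       # reference temperature, K
  T01 <- 273.16      # triple point, K
  pr <- 101.325      # reference pressure, kPa
  pa <- weather$pressure
  # molar concentration of water vapour (%)
  psat <- pr * 10^(-6.8346 * (T01 / T_k)^1.261 + 4.6151)
  h <- weather$relative_humidity * psat / pa
  # relaxation frequencies of O2 and N2, Hz
  frO <- (pa / pr) * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  frN <- (pa / pr) * (T_k / T0)^(-0.5) *
    (9 + 280 * h * exp(-4.170 * ((T_k / T0)^(-1 / 3) - 1)))
  classical <- 8.686 * f^2 * 1.84e-11 * (pa / pr)^(-1) * (T_k / T0)^0.5
  oxygen <- 8.686 * f^2 * (T_k / T0)^(-2.5) *
    0.01275 * exp(-2239.1 / T_k) / (frO + f^2 / frO)
  nitrogen <- 8.686 * f^2 * (T_k / T0)^(-2.5) *
    0.1068 * exp(-3352.0 / T_k) / (frN + f^2 / frN)
  data.frame(classical = classical, oxygen = oxygen, nitrogen = nitrogen)
}

#' Spherical-spreading gain
#'
#' Free-field pressure falls as 1/r; this returns the gain in dB to ADD when
#' back-compensating a level measured at `distance` to `reference_distance`
#' (positive when `distance > reference_distance`; 6.02 dB per doubling).
#'
#' @param distance measurement distance, m (> 0).
#' @param reference_distance reference distance, m (> 0; 0.1 m is the
#'   standard source-level reference).
#' @return gain in dB: `20 * log10(distance / reference_distance)`.
#' @export
spreading_gain <- function(distance, reference_distance) {
  if (any(distance <= 0) || any(reference_distance <= 0))
    stop("distances must be positive")
  20 * log10(distance / reference_distance)
}

#' Expected time differences of arrival for a known source
#'
#' Forward geometric model: for each peripheral microphone i,
#' `tau_i = (|source - peripheral_i| - |source - central|) / c`
#' (peripheral arrival minus central arrival; positive when the peripheral is
#' farther from the source). This is the oracle the localizer inverts.
#'
#' @param source 3-vector, metres.
#' @param geometry a [mic_array_geometry()].
#' @param c speed of sound, m/s.
#' @return numeric length 3, seconds, in peripheral order.
#' @export
expected_tdoas <- function(source, geometry, c) {
  stopifnot(inherits(geometry, "mic_array_geometry"))
  if (c <= 0) stop("speed of sound must be positive")
  p <- geometry$mic_positions
  ctr <- p[geometry$central_index, ]
  per <- p[-geometry$central_index, , drop = FALSE]
  d_all <- sqrt(rowSums(sweep(p, 2, source)^2))
  if (any(d_all < 1e-12)) stop("source coincides with a microphone")
  dc <- sqrt(sum((source - ctr)^2))
  dp <- sqrt(rowSums(sweep(per, 2, source)^2))
  (dp - dc) / c
}
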