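#' Measure TDOAs of one detection by cross-correlation
#'
#' Cross-correlates each peripheral channel against the central channel over
#' the detection window, restricted to physically possible lags
#' (|tau| <= baseline/c plus one sample). The lag is picked on the magnitude
#' of the analytic-signal (complex) cross-correlation - the matched-filter
#' envelope, which is unimodal and immune to the carrier-cycle ambiguity
#' that affects narrowband signals (pure tones, quasi-CF components) when
#' the real correlation is sampled at integer lags. The estimate is then
#' refined to sub-sample precision by parabolic interpolation of the real
#' (carrier-phase) correlation around its local maximum within half a
#' carrier cycle of the envelope peak. TDOAs with a normalized peak
#' correlation below `min_correlation` are flagged unreliable.
#'
#' @param rec the band-passed [multichannel_recording()].
#' @param detection one row of [detect_calls()] output.
#' @param geometry a [mic_array_geometry()].
#' @param c speed of sound, m/s.
#' @param config a [pipeline_config()].
#' @return object of class `tdoa_set`: list with `tau` (3 TDOAs, s,
#'   peripheral minus central), `correlation` (3 peak coefficients),
#'   `reliable` (3 logicals).
#' @export
measure_tdoas <- function(rec, detection, geometry = mic_array_geometry(),
                          c = 343, config = pipeline_config()) {
  fs <- rec$sample_rate
  idx <- detection$start:(detection$end - 1)
  xc <- rec$samples[idx, central_channel(rec, geometry)]
  baseline <- max(sqrt(rowSums(sweep(
    geometry$mic_positions[-geometry$central_index, , drop = FALSE], 2,
    geometry$mic_positions[geometry$central_index, ])^2)))
  max_lag <- ceiling(baseline / c * fs) + 2L
  per_idx <- setdiff(seq_len(nrow(geometry$mic_positions)),
                     geometry$central_index)
  zc <- analytic_signal(xc)
  # half carrier cycle at the power-weighted spectral centroid bounds the
  # cycle-disambiguation search around the envelope peak
  f_cent <- spectral_centroid(xc, fs)
  half_cycle <- max(2L, as.integer(floor(fs / (2 * f_cent))) - 1L)
  tau <- cor_pk <- numeric(length(per_idx))
  for (i in seq_along(per_idx)) {
    ch <- which(rec$channel_map == per_idx[i])
    xp <- rec$samples[idx, ch]
    zp <- analytic_signal(xp)
    ca <- cross_correlate_cplx(zp, zc, max_lag)
    pk_env <- which.max(Mod(ca$r))
    cc <- list(lags = ca$lags, r = Re(cross_correlate_cplx(xp, xc, max_lag)$r))
    # local maximum of the real correlation within half a cycle
    lo <- max(1L, pk_env - half_cycle); hi <- min(length(cc$r), pk_env + half_cycle)
    pk <- lo - 1L + which.max(cc$r[lo:hi])
    lag <- cc$lags[pk]
    # parabolic refinement on the three points around the peak
    if (pk > 1 && pk < length(cc$r)) {
      y1 <- cc$r[pk - 1]; y2 <- cc$r[pk]; y3 <- cc$r[pk + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
    }
    tau[i] <- lag / fs
    norm <- sqrt(sum(Mod(zc)^2) * sum(Mod(zp)^2))
    cor_pk[i] <- if (norm > 0) Mod(ca$r[pk_env]) / norm else 0
  }
  structure(list(tau = tau, correlation = cor_pk,
                 reliable = cor_pk >= config$min_correlation),
            class = "tdoa_set")
}

# cross-correlation r[l] = sum_n a[n] conj(b[n - l]) for |l| <= max_lag
# (FFT based; works for real or complex inputs)
cross_correlate_cplx <- function(a, b, max_lag) {
  n <- length(a)
  L <- stats::nextn(2 * n, 2)
  A <- stats::fft(c(a, numeric(L - n)))
  B <- stats::fft(c(b, numeric(L - n)))
  r <- stats::fft(A * Conj(B), inverse = TRUE) / L
  lags <- -max_lag:max_lag
  # circular layout: lag l >= 0 at index l + 1, lag l < 0 at index L + l + 1
  r_l <- r[ifelse(lags >= 0, lags + 1, L + lags + 1)]
  list(lags = lags, r = r_l)
}

# analytic signal (one-sided spectrum) via FFT; computed on a zero-padded
# power-of-two length (mixed-radix FFTs degrade badly on awkward lengths)
# and truncated - the padding perturbs only the few edge samples
analytic_signal <- function(x) {
  n <- length(x)
  L <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(L - n)))
  h <- numeric(L)
  h[1] <- 1; h[L / 2 + 1] <- 1; h[2:(L / 2)] <- 2
  (stats::fft(X * h, inverse = TRUE) / L)[seq_len(n)]
}

# power-weighted mean frequency, Hz
spectral_centroid <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1)]^2
  f <- (seq_len(n %/% 2 + 1) - 1) * fs / n
  sum(f * P) / sum(P)
}

#' Solve the 3D source position from three TDOAs
#'
#' Nonlinear least squares on the TDOA residuals
#' `tau_i - expected_tdoas(position)_i`, initialized from the far-field
#' plane-wave direction combined with a coarse range grid, refined by
#' Levenberg-Marquardt. The planar array cannot distinguish a source from its
#' mirror image through the array plane (identical TDOAs), so the solution is
#' always returned in the front hemisphere (z > 0).
#'
#' @param tdoas a `tdoa_set` (or numeric length 3, seconds).
#' @param geometry a [mic_array_geometry()].
#' @param c speed of sound, m/s.
#' @return object of class `position_fix`: `position` (3-vector, m),
#'   `distance_to_central` (m), `residual` (rms TDOA residual, s),
#'   `converged` (logical).
#' @export
localize <- function(tdoas, geometry = mic_array_geometry(), c = 343) {
  tau <- if (inherits(tdoas, "tdoa_set")) tdoas$tau else as.numeric(tdoas)
  stopifnot(length(tau) == 3)
  p <- geometry$mic_positions
  ctr <- p[geometry$central_index, ]
  per <- sweep(p[-geometry$central_index, , drop = FALSE], 2, ctr)
  baseline <- max(sqrt(rowSums(per^2)))
  if (any(abs(tau) > baseline / c + 2e-6))
    stop("impossible geometry: |TDOA| exceeds baseline travel time")
  # far-field initialization: tau_i ~ -(u . p_i)/c constrains the in-plane
  # direction; z component from normalization, front hemisphere
  uxy <- tryCatch(qr.solve(per[, 1:2], -tau * c),
                  error = function(e) c(0, 0))
  nrm <- sum(uxy^2)
  u <- if (nrm < 1) c(uxy, sqrt(1 - nrm)) else c(uxy / sqrt(nrm), 0.05)
  u <- u / sqrt(sum(u^2))
  resid_fn <- function(pos) tau - expected_tdoas(pos + ctr, geometry, c)
  ranges <- c(0.5, 1, 2, 3, 5, 8, 12, 18)
  ssr <- vapply(ranges, function(r) sum(resid_fn(r * u)^2), numeric(1))
  start <- ranges[which.min(ssr)] * u
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 200))
  pos <- fit$par
  if (pos[3] < 0) pos[3] <- -pos[3]       # mirror ambiguity: front hemisphere
  pos <- pos + ctr
  res <- sqrt(mean((tau - expected_tdoas(pos, geometry, c))^2))
  structure(list(position = pos,
                 distance_to_central = sqrt(sum((pos - ctr)^2)),
                 residual = res,
                 converged = fit$info %in% 1:4),
            class = "position_fix")
}

#' Localize every detection of a recording
#'
#' Runs [measure_tdoas()] and [localize()] for each detection and anchors the
#' emission time as envelope-peak arrival time minus travel time to the
#' central microphone.
#'
#' @param rec band-passed recording.
#' @param detections output of [detect_calls()].
#' @param geometry a [mic_array_geometry()].
#' @param weather a [weather_record()].
#' @param config a [pipeline_config()].
#' @return data.frame: `call_id`, `emission_time`, `x`, `y`, `z`, `distance`,
#'   `residual`, `min_correlation`, `reliable`, `converged`.
#' @export
localize_detections <- function(rec, detections,
                                geometry = mic_array_geometry(),
                                weather = weather_record(15, 60),
                                config = pipeline_config()) {
  cs <- speed_of_sound(weather)
  rows <- lapply(seq_len(nrow(detections)), function(i) {
    det <- detections[i, ]
    td <- measure_tdoas(rec, det, geometry, cs, config)
    fix <- tryCatch(localize(td, geometry, cs), error = function(e) NULL)
    if (is.null(fix))
      return(data.frame(call_id = det$call_id, emission_time = NA_real_,
                        x = NA_real_, y = NA_real_, z = NA_real_,
                        distance = NA_real_, residual = NA_real_,
                        min_correlation = min(td$correlation),
                        reliable = FALSE, converged = FALSE))
    data.frame(call_id = det$call_id,
               emission_time = det$peak_time - fix$distance_to_central / cs,
               x = fix$position[1], y = fix$position[2], z = fix$position[3],
               distance = fix$distance_to_central, residual = fix$residual,
               min_correlation = min(td$correlation),
               reliable = all(td$reliable), converged = fix$converged)
  })
  do.call(rbind, rows)
}

#' Link position fixes into flight trajectories
#'
#' Greedy nearest-neighbour linking in time order: each fix joins the
#' trajectory whose last fix is nearest in space among those reachable with
#' implied speed <= `max_speed` and time gap <= `max_link_gap`; otherwise it
#' starts a new trajectory.
#'
#' @param fixes data.frame from [localize_detections()] (time-sorted or not;
#'   sorted internally by `emission_time`).
#' @param config a [pipeline_config()].
#' @return `fixes` with a `trajectory` integer column, sorted by emission
#'   time.
#' @export
link_trajectories <- function(fixes, config = pipeline_config()) {
  if (nrow(fixes) == 0) { fixes$trajectory <- integer(0); return(fixes) }
  fixes <- fixes[order(fixes$emission_time), , drop = FALSE]
  traj_of <- integer(nrow(fixes))
  last_idx <- integer(0)                    # index of last fix per trajectory
  for (i in seq_len(nrow(fixes))) {
    if (is.na(fixes$x[i])) { traj_of[i] <- NA_integer_; next }
    best <- NA_integer_; best_d <- Inf
    for (tr in seq_along(last_idx)) {
      j <- last_idx[tr]
      dt <- fixes$emission_time[i] - fixes$emission_time[j]
      if (dt <= 0 || dt > config$max_link_gap) next
      d <- sqrt((fixes$x[i] - fixes$x[j])^2 + (fixes$y[i] - fixes$y[j])^2 +
                  (fixes$z[i] - fixes$z[j])^2)
      if (d / dt <= config$max_speed && d < best_d) { best <- tr; best_d <- d }
    }
    if (is.na(best)) {
      last_idx <- c(last_idx, i)
      traj_of[i] <- length(last_idx)
    } else {
      traj_of[i] <- best
      last_idx[best] <- i
    }
  }
  fixes$trajectory <- traj_of
  fixes
}

#' Apply the exclusion cascade
#'
#' Flags (never deletes) positions: spatial outliers first (distance from the
#' 3-point running-median trajectory path beyond `outlier_distance`), then
#' implausible call durations (outside `[min_duration, max_duration]` ms),
#' then low SNR (below `min_snr` dB). Reason codes: `"outlier"`,
#' `"duration"`, `"snr"`, `"none"`. Idempotent.
#'
#' @param fixes data.frame with columns `trajectory`, `x`, `y`, `z`,
#'   `duration_ms`, `snr_db`.
#' @param config a [pipeline_config()].
#' @return `fixes` with logical `included` and character `reason` columns.
#' @export
apply_exclusions <- function(fixes, config = pipeline_config()) {
  n <- nrow(fixes)
  reason <- rep("none", n)
  for (tr in unique(stats::na.omit(fixes$trajectory))) {
    sel <- which(fixes$trajectory == tr & !is.na(fixes$x))
    if (length(sel) >= 3) {
      med <- sapply(c("x", "y", "z"), function(cc)
        stats::runmed(fixes[[cc]][sel], 3, endrule = "median"))
      d <- sqrt(rowSums((as.matrix(fixes[sel, c("x", "y", "z")]) - med)^2))
      reason[sel[d > config$outlier_distance]] <- "outlier"
    }
  }
  dur_bad <- !is.na(fixes$duration_ms) &
    (fixes$duration_ms < config$min_duration |
       fixes$duration_ms > config$max_duration)
  reason[reason == "none" & dur_bad] <- "duration"
  snr_bad <- !is.na(fixes$snr_db) & fixes$snr_db < config$min_snr
  reason[reason == "none" & snr_bad] <- "snr"
  fixes$included <- reason == "none"
  fixes$reason <- reason
  fixes
}

#' Exclusion-cascade bookkeeping
#'
#' Arithmetic of the sequential cascade: detections minus manually flagged
#' spatial outliers minus parameter-based exclusions (duration / SNR) gives
#' the calls remaining for analysis.
#'
#' @param n_detected total detected positions.
#' @param n_outlier positions excluded as spatial outliers.
#' @param n_parameter positions excluded by duration or SNR rules.
#' @return list with the three inputs and `remaining`.
#' @export
exclusion_cascade <- function(n_detected, n_outlier, n_parameter) {
  stopifnot(n_detected >= n_outlier + n_parameter)
  list(detected = n_detected, outlier = n_outlier, parameter = n_parameter,
       remaining = n_detected - n_outlier - n_parameter)
}
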