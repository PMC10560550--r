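# echotrack

Acoustic 3D tracking and source-level measurement for bat echolocation
calls recorded with a calibrated four-microphone star array, together with
a ground-truthed synthetic-scene generator that makes every stage of the
chain verifiable by parameter recovery.

**Who it is for:** bioacousticians measuring call amplitudes of free-flying
animals with ultrasonic microphone arrays (500 kHz multichannel recordings),
and anyone who needs a tested TDOA localization + spectral back-compensation
chain with a simulator to validate it against.

## The method

For each detected call, the time difference of arrival between the central
microphone (position *p₀*) and each peripheral *pᵢ* is measured by
cross-correlation and inverted for the source position *x* by nonlinear
least squares on

> τᵢ = ( ‖x − pᵢ‖ − ‖x − p₀‖ ) / c,  i = 1, 2, 3

with the front-hemisphere constraint z > 0 (a planar array cannot tell a
source from its mirror image). The recorded call is then back-compensated to
the emitted waveform at the 10 cm reference distance by multiplying its
amplitude spectrum with the inverse microphone response, the ISO 9613-1
atmospheric absorption over the travel path, and the spherical-spreading
gain 20 log₁₀(d / 0.1 m). From the reconstructed waveform the chain measures
duration (−12 dB below the smoothed envelope peak), rmsSPL and
peak-equivalent SPL (dB re. 20 µPa at 0.1 m), and peak / lowest frequency
from a time-averaged, 25× zero-padded spectrogram. Because a call's beam is
rarely aimed at the array, the per-trajectory **on-axis source level** is
estimated as the 95th percentile of the apparent source levels, plus an
additive system-bias correction (+4 dB rms / +1 dB pe by default).

The `synth` side renders the exact inverse: parametric FM/FM-qCF calls on
smooth flight paths, propagated (spreading, absorption, microphone response,
fractional-sample delays) onto a quantized 16-bit four-channel recording
with a truth manifest, plus a 45-position × 6-signal loudspeaker calibration
design analysed end-to-end by `calibration_harness()`.

## Worked example

```r
library(echotrack)
geom    <- mic_array_geometry()          # star array, 0.6 m radius
weather <- weather_record(15, 60)        # 15 degC, 60 % RH
scene   <- example_flight_scene(seed = 1, n_calls = 15)   # approach flight
r       <- render_scene(scene, geom)     # ground-truthed 4-channel audio
res     <- analyze_recording(r$recording, geom, weather, scene$mic_cal,
                             pipeline_config(detection_threshold = -50))
head(res$calls[, c("call_id", "distance", "duration_ms", "rms_spl_db",
                   "pe_spl_db", "peak_khz", "lowest_khz")], 4)
#>   call_id distance duration_ms rms_spl_db pe_spl_db peak_khz lowest_khz
#> 1       1    12.53       1.654      93.77     95.95       38         27
#> 2       2    11.72       1.654      94.32     96.50       38         27
#> 3       3    10.89       1.656      94.88     97.07       38         27
#> 4       4    10.09       1.654      93.51     95.69       38         27

source_level_estimates(res$calls, pipeline_config())[ , c("n_calls",
    "asl_rms_p", "sl_rms", "asl_pe_p", "sl_pe")]
#>   n_calls asl_rms_p sl_rms asl_pe_p sl_pe
#> 1      15      95.9   99.9    98.08 99.08
```

The bat flew from 12.5 m towards the array emitting ~94 dB SPL calls (±1 dB
per-call jitter); every call is localized (distances above), its waveform
reconstructed and measured, and the trajectory's 95th-percentile apparent
source level (95.9 dB rmsSPL — the truth manifest's own 95th percentile is
96.0 dB) is reported alongside the bias-corrected value. Peak (38 kHz) and
lowest frequency (27 kHz) match the synthesized call's first harmonic.

The `analysis/` scripts run the same chain as a study-style workflow:
`01_simulate.R` (five bats + config files), `02_track_calls.R` (per-call
table and exclusion cascade), `03_source_levels.R` (per-individual
percentiles, median of medians), `04_calibration.R` (noiseless and noisy
calibration harness). Outputs land in `results/`.

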