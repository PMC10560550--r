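---
title: "Calibrated microphone-array measurement of bat echolocation calls: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated microphone-array measurement of bat echolocation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotrack)
```

## The measurement problem

Estimating the source level of a free-flying echolocating bat requires
knowing, for every call, (i) where the bat was when it called and (ii) how
much the sound was attenuated between mouth and microphone. `echotrack`
implements the complete chain for a planar four-microphone star array (one
central microphone, three peripherals at 0.6 m radius and 120° separation):

1. **Detection** — zero-phase elliptic bandpass (20–90 kHz, 4th-order
   prototype, 0.1 dB passband ripple, 40 dB stopband), then thresholding of
   the smoothed analytic-signal envelope of the central channel at
   −35 dB full scale.
2. **Localization** — time differences of arrival (TDOA) between the central
   and each peripheral microphone by cross-correlation, then nonlinear least
   squares on the forward model
   $\tau_i = \left(\lVert x - p_i \rVert - \lVert x - p_0 \rVert\right) / c$.
3. **Waveform reconstruction** — FFT-based back-compensation of the recorded
   call for the microphone's frequency response, frequency- and
   distance-dependent atmospheric absorption (ISO 9613-1 pure-tone model)
   and spherical spreading, referencing the emitted waveform to 0.1 m in
   pascals.
4. **Call parameters** — duration at −12 dB below the smoothed envelope
   peak; rmsSPL within that window; peak-equivalent SPL from the envelope
   peak; peak and lowest frequency from the time-averaged spectrogram
   (100-sample Hann windows zero-padded to 2000-point FFTs, 95 % overlap).
5. **Source-level statistics** — the 95th percentile of the apparent source
   levels (aSL) of a trajectory as the on-axis estimate, plus additive
   system-bias corrections (+4 dB rms, +1 dB peak-equivalent by default).

Every stage is verifiable against ground truth because the package also
contains the *inverse* of the chain: a synthetic-scene renderer that places
parametric FM calls on flight paths and renders them through the same
physics onto a 16-bit four-channel recording.

## Physical model and assumptions

**Speed of sound.** $c(T) = 331.3\sqrt{1 + T/273.15}$ m/s, temperature only.
Humidity and pressure corrections are below 0.5 % under temperate field
conditions; for a 10 m range this is below the localization error budget,
so the simpler form is used and stated here.

**Atmospheric absorption.** The ISO 9613-1 pure-tone attenuation
coefficient (classical + O₂ and N₂ relaxation terms), implemented from the
standard's closed form and exposed term-by-term
(`absorption_components()`). The test suite pins the implementation to an
independently written reference tabulation to within 5 % (observed
agreement is ~0.0003 %, i.e. identical up to floating-point noise); the
tabulation itself was cross-checked against published values of the humid-air
absorption model (e.g. ~1.32 dB/m at 40 kHz, 20 °C, 50 % RH). Weather enters
per call by nearest-in-time lookup in the 2-minute weather log — no
interpolation, a deliberate choice given how slowly the relevant quantities
drift.

**Geometry and the mirror ambiguity.** A planar array cannot distinguish a
source from its reflection through the array plane: both produce identical
TDOAs. The solver therefore always returns the front-hemisphere solution
(z > 0), which matches the field situation of an array facing the animals.
The canonical frame puts the central microphone at the origin, peripherals
at azimuths 90°, 210°, 330° in the x–y plane, +z facing forward.

**What the renderer models, and what it does not.** Spherical spreading,
ISO 9613-1 absorption applied per frequency bin, the microphone's relative
frequency response (default: flat with a −6 dB dip at 70 kHz, a typical
imperfectly-compensated electret artefact; a perfectly flat response exists
for oracle tests), exact propagation delays (integer shift plus an 81-tap
Kaiser-windowed-sinc fractional delay), Gaussian ambient noise, and 16-bit
round-to-nearest quantization with a configurable pascal-per-full-scale
mapping. Deliberately absent: **call directionality** (sources are
omnidirectional, so in simulation aSL ≈ SL and the 95th-percentile estimator
plus bias correction *overestimates* the true level by design — in real data
directionality pushes aSL far below SL, which is exactly why the estimator
exists), Doppler (< 2 % at ≤ 10 m/s flight speed), wind, refraction, ground
and vegetation echoes, and microphone directionality. Passing recovery tests
therefore demonstrates correctness of the measurement chain, not robustness
to every field nuisance.

## Numerical choices

* **Envelope.** "Envelope" means magnitude of the analytic signal followed
  by a 0.2 ms moving average; the analytic signal is computed via FFT on a
  power-of-two padded copy (mixed-radix FFTs on awkward lengths are
  prohibitively slow) and truncated, which perturbs only edge samples.
* **TDOA estimator.** Plain argmax of the real cross-correlation fails for
  narrowband signals: sampled at integer lags, the correlation at the
  adjacent carrier cycle can exceed the sample nearest the true peak. The
  estimator therefore picks the peak of the *analytic-signal*
  cross-correlation magnitude (the matched-filter envelope, unimodal), then
  refines on the real correlation's local maximum within half a carrier
  cycle (at the spectral centroid) by parabolic interpolation. At 500 kHz
  one sample is ~0.7 mm of path difference; sub-sample refinement is what
  makes ~0.01 % distance errors possible in noiseless scenes.
* **Localizer.** Levenberg–Marquardt on the three TDOA residuals,
  initialized from the far-field plane-wave direction (linear solve on the
  in-plane components) plus a coarse range grid; mirrored into z > 0.
  Convergence tolerances are set to machine precision — the 3-equation,
  3-unknown problem is exactly determined and the oracle-inversion test
  demands sub-millimetre agreement.
* **Compensation cap.** The frequency-dependent part of the compensation
  gain (microphone inverse + absorption) is capped at +60 dB per bin to
  prevent noise blow-up where the call has no energy; the flat spreading
  term is not capped, since it amplifies all bins equally and capping it
  would corrupt every level measured beyond ~10 m.
* **Spectrogram convention.** "2000-point FFT of 100-sample windows" is
  read as zero-padding each 100-sample Hann window to 2000 points — a
  25-fold interpolated spectrum with 250 Hz bins at 500 kHz. The lowest
  frequency is found by walking *downward from the peak* until the averaged
  amplitude drops 12 dB, so a noise floor below the call band cannot fake a
  lower edge. The 100-sample window smears the spectral edge by ~2 kHz,
  which the tests account for.
* **peSPL convention.** Labs differ; default is the SPL of a sine with the
  same peak (envelope peak divided by √2), computed on the smoothed
  envelope. Both choices are configurable (`pe_convention`, `pe_envelope`).
* **Percentile.** Linear interpolation between closest order statistics
  (`stats::quantile` type 7), stated because percentile conventions differ
  and the estimate enters the headline result directly.
* **Filter contract.** The elliptic design's computed response has exactly
  0.1 dB peak-to-peak passband ripple; its equiripple stopbands sit at
  −40 dB below ~12 kHz and above ~135 kHz (the response is evaluated in
  zero-pole form — direct polynomial evaluation loses ~25 dB of apparent
  attenuation to cancellation deep in the stopband). Forward–backward
  application doubles attenuation and ripple and keeps call timing unbiased
  (a symmetric pulse's peak moves < 2 samples).

## Exclusion cascade and trajectory assembly

Positions are never deleted, only flagged with a reason code: `outlier`
(further than 1 m from the 3-point running-median path of the trajectory —
an automated stand-in for manual curation of positions that "do not align"),
`duration` (outside 1–8 ms, the band of plausible species call durations;
over-long durations are in practice measurement errors at low SNR), `snr`
(below 15 dB). Trajectory assembly is greedy nearest-neighbour linking with
a 15 m/s speed cap and 1 s maximum gap, replacing a manual GUI step. The
sequential bookkeeping (detections − outliers − parameter exclusions =
analysed calls) is exposed as `exclusion_cascade()`.

## Calibration harness

`make_calibration_scene()` reproduces a loudspeaker calibration design: six
signal types — 35 and 60 kHz pure tones, linear and hyperbolic FM sweeps
(85→25 kHz), an FM-qCF composite (50→28 kHz sweep with a quasi-constant
tail) and a 20–90 kHz noise burst, 96 dB SPL rms each (the level keeps the
high-crest-factor noise burst below full scale at the nearest grid
distance) — broadcast from 45 positions (azimuths ±30°/0°, elevations
±20°/0°, five uniformly spaced distances from 3 to 10 m).
`calibration_harness()` renders each position, runs the full analysis chain
and reports per-event distance and level errors against truth, overall and
by distance class and signal type; undetected events stay in the report as
missing rows. Noiseless runs characterize the chain itself; runs with
injected ambient noise show the physically expected growth of
localization-error spread with distance (the far events approach the SNR
floor).

Two systematic effects the harness surfaces are worth knowing about. The
zero-phase bandpass removes a small amount of in-band energy (squared
0.1 dB ripple), giving a slight, uniform *underestimation* of reconstructed
levels — the in-silico analog of the bias that the additive system
corrections exist to undo. And in noisy runs the level bias grows slightly
with distance because compensation amplifies in-band noise. The printed
field-hardware bias values themselves stem from real equipment and are not
recoverable from simulation; the harness verifies the *procedure*.

## Problem sizes and determinism

The standard verification scenes are a 100-call approach flight spanning
~12 m down to ~1 m (noiseless, flat microphone, detection threshold lowered
to −50 dBFS — without ambient noise the field threshold's noise-rejection
role is moot, and at the field gain a 94 dB call at 12 m falls below
−35 dBFS) and the full 270-event calibration grid. Scene rendering is fully
deterministic given a seed: same `scene_spec` and seed give bit-identical
recordings. The −35 dBFS default, in contrast, reflects realistic ambient
noise floors (−60 to −45 dBFS rms in the simulated sessions) and is what the
field-style analysis scripts use.

## Known limitations

* The star-array contract is exactly four microphones, planar; other
  geometries are out of scope.
* Distances very close to the array plane (z ≈ 0) are ill-conditioned:
  TDOAs vary slowly along the mirror boundary.
* Range accuracy degrades quadratically with distance (baseline 0.6 m), so
  beyond ~10 m the method depends on high SNR — visible directly in the
  harness's by-distance spread.
* Without modelled directionality, simulated aSL distributions are narrower
  than field ones; recovery tests validate the chain, not the percentile's
  field behaviour.
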