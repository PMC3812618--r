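---
title: "A hands-free mouse pipeline: EMD denoising, double-blink detection, and Kalman cursor tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hands-free mouse pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdmouse)
```

This vignette is the package's account of its science: the models and
procedures, the parameters that matter and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

A consumer EEG headset provides two usable control channels for a
hands-free mouse: a two-axis gyroscope (head velocity, deg/s) for cursor
position, and the frontal electrodes AF3/AF4, where deliberate double
blinks appear as large EMG/EOG pulses. Both channels are dirty. Head
movement — the very thing driving the cursor — drags the electrodes over
the scalp and contaminates every channel with a low-frequency artifact of
the same order of magnitude as the blink pulses; and the gyroscope carries
tremor jitter that makes the raw integrated cursor shake. The pipeline
therefore has three stages: suppress the movement artifact using its
cross-electrode correlation, detect double blinks from the energy signature
of their intrinsic mode functions, and smooth the cursor with a
constant-velocity Kalman filter.

## Empirical mode decomposition

EMD represents a signal as a sum of intrinsic mode functions (IMFs):
locally zero-mean oscillations whose extrema and zero-crossing counts
differ by at most one. One IMF is extracted by *sifting* — subtracting the
mean of the spline envelopes through the local maxima and minima until the
detail satisfies the IMF criterion — and the procedure then iterates on
the residual. The decomposition is adaptive (no fixed basis), which is why
it handles the non-stationary EEG background better than a fixed filter
bank, and it is complete by construction: IMFs plus residual reconstruct
the input to machine precision, which the tests assert at 1e-9 relative
tolerance.

Numerical choices:

* **Envelopes.** Natural cubic splines through the extrema; monotone
  Hermite (`"pchip"`) is available where overshoot matters. Boundaries are
  handled by mirroring the two extrema nearest each end across it
  (`"clamp"` pins the envelopes to the endpoint samples instead).
* **Sifting stop.** Cauchy criterion `sum((d_prev - d_new)^2) /
  sum(d_prev^2) < 0.3` *and* the IMF criterion, with a hard cap of 50
  sifts. A candidate that still fails the IMF criterion when sifting can
  go no further (degenerate envelopes) is folded back into the residual
  rather than emitted — this is what lets the suite assert the
  extrema/zero-crossing criterion exactly for every returned IMF.
* **Decomposition stop.** Residual monotone, fewer than 3 extrema, or 16
  IMFs.
* **Orthogonality index.** Printed forms of this diagnostic are
  typographically inconsistent about the normalization; this package
  normalizes the summed cross-products of distinct components (IMFs plus
  residual, diagonal excluded) by the total source energy. A per-sample
  normalization would be undefined wherever the source crosses zero.

## Artifact suppression by cross-electrode IMF correlation

The movement artifact appears on *all* electrodes with small variations;
blinks are confined to the frontal pair (with faint volume-conduction
residue elsewhere). Per 10 s window, every channel is decomposed and each
IMF is correlated with the reference electrode's corresponding IMF
(Pearson, two-sided t test). An IMF voted significant (p < 0.05) on
strictly more than half of the electrodes is treated as common mode and
withheld from the reconstruction; everything else, plus the residual,
passes. Windows are rejoined with a 0.25 s linear cross-fade.

Three design points deserve explanation, because each was forced by a
measurable failure of the naive alternative:

* **Degrees of freedom of the correlation test.** With n taken as the
  window sample count (1280), p < 0.05 corresponds to |rho| > ~0.055 — and
  at that sensitivity the test is also *miscalibrated* for IMF pairs: IMFs
  are narrowband, their effective sample size is far below the window
  length, and corresponding IMFs of fully independent channels reach
  "significance" about half the time (the suite demonstrates the
  calibration only for white sequences, where the t transform is exact).
  The default therefore takes n as the *electrode count* — the rows of the
  electrode correlation matrix — so that with 14 channels only
  |rho| > ~0.53, i.e. genuinely common-mode structure, gates an IMF. Both
  conventions are exposed (`p_n = "channels"` / `"samples"`).
* **Broadband input.** Gating runs on the raw recording, and the 0.5–10 Hz
  detection band-pass is applied afterwards. Decomposing an already
  band-limited signal leaves only ~4–5 poorly anchored modes and the vote
  collapses; the broadband signal gives each channel a stable dyadic
  ladder to correlate across.
* **Adjacent-index alignment.** EMD mode boundaries on noisy channels are
  unstable — adding 64 samples to a window can flip a channel's IMF count
  and shift the artifact-bearing mode by one index. The gating path
  therefore matches reference IMF k against the channel's best-correlated
  IMF among k−1, k, k+1, and, once an index wins the majority vote,
  suppresses every adjacent candidate that individually exceeds the
  significance cut (a split mode leaves its second shard in a neighbouring
  IMF). `correlate_imfs()` keeps exact index alignment as its default
  contract; `denoise_recording()` uses the adjacent rule.

The vote, once passed, is applied unconditionally to every channel: the
IMF is "prevented from passing to the integration module" across the
montage. Re-testing per channel before applying the gate looks prudent but
systematically spares the frontal channels (their blink content dilutes
the correlation just below the cut) — which is precisely where the
artifact must be removed.

## Double-blink detection

A double blink is two ~0.2 s biphasic pulses whose maxima fall within
0.5 s. Detection windows are 2 s (256 samples at 128 Hz) sliding 128
samples; a 91 s session yields exactly 90 windows. Each window is reduced
to the energies of its first three IMFs plus residual (the components
where double-blink energy concentrates), and classified by Mahalanobis
distance to the blink class, fit as the sample mean and ridge-regularized
covariance (`1e-6 * trace/dim`) of cue-aligned training windows. A
second-derivative double-peak scan (Savitzky–Golay smoothed, prominence
floor median + 3·MAD) gates candidates, and a 1 s refractory debounce
suppresses duplicates; at 2 s windows plus 1 s debounce the selection
channel carries 20 bits/min.

* **Decision distance.** The canonical 0.95 threshold is specific to one
  hardware/feature combination and was found experimentally there. With
  4-dimensional energy features, blink distances concentrate near
  `sqrt(dim)` ≈ 2, so the package recalibrates by the same experimental
  route: a 2-fold split of the training vectors, each fold's model scoring
  the held-out fold, threshold at 1.2× the 90th percentile of held-out
  distances (the literal maximum is unstable — held-out distances from
  20-vector covariance fits are heavy-tailed). The uncalibrated default
  remains 0.95.
* **Training windows.** Each cue contributes its onset-aligned window and
  a half-stride-early copy, so the training distribution covers the event
  offsets that sliding-window evaluation produces.
* **Evaluation.** The true-positive rate is per event — a cued double
  blink counts as recovered when any window fully containing it scores
  below threshold, which is what a detection rate over cues measures —
  while the false-positive rate is per event-free window. ROC curves sweep
  the threshold 0–1.91 in steps of 0.01 and are averaged vertically over
  test sessions at the fixed grid.
* **DWT comparison.** The comparison extractor is a 5-level periodized
  Daubechies-2 pyramid (orthonormal, so energy is conserved exactly),
  with detail-level energies (levels 2–5, ~1–16 Hz dyadic bands at
  128 Hz) as features. The acceptance suite reports both extractors' AUCs
  and the acceptance script draws the averaged ROC comparison; the
  ordering is reported, not asserted.

## Cursor tracking

Gyro rates integrate (trapezoid) to screen coordinates through a
pixels-per-degree scale. The smoother is the textbook constant-velocity
Kalman filter: state (x₁, x₂, ẋ₁, ẋ₂), position observations, Riccati
gain recursion. Process noise enters as white acceleration — a scalar
intensity q per axis discretized to the full
`q [[Ts³/3, Ts²/2], [Ts²/2, Ts]]` block — estimated from the gyro at rest
(per-axis rate variance); measurement noise R from a moving segment's
residual about a zero-phase 5 Hz low-pass reference.

Defaults `Q = 25 (deg/s)²`, `R = 0.1 deg²` place the closed-loop bandwidth
near 1.5 Hz: flat over the ≤ 0.5 Hz pursuit movement, strongly attenuating
the 4–12 Hz tremor band. Two structural facts, both verified numerically
in this package's development and reflected in the tests:

* The position–velocity filter's transfer function has a zero, so its
  roll-off is first-order and its passband shows mild peaking. The
  practical consequence: the filter decisively beats the ADC *dead-band*
  baseline (which must grow to ~30 steps ≈ 4.5 deg/s to cover fast
  movements, destroying slow-movement information), but it cannot beat
  ideal numerical integration of the same rates on RMSE — the peaking
  distortion is about the size of the tremor benefit. The tests assert
  the comparison the method actually wins.
* With white (unbounded-walk) rate noise no causal position filter can
  reduce tracking RMSE at all; the meaningful notion of "jitter" is
  band-limited tremor, which is how the generator models it.

The dead band itself, quantization to the ADC integer span, and their
round-trip bounds are implemented as the comparison baseline.

## The synthetic world

`make_scene(preset = "paper91s")` builds the full evaluation condition:
91 s at 128 Hz on the 14-electrode consumer montage, 10 cued double blinks
at random non-overlapping times, movement artifact throughout (the worst
case: the user sways while blinking), and a pursuit gyro trace. Levels are
grounded in the physiology rather than chosen for convenience:

* **Background**: independent AR(2) noise (0.8, 0.05) per channel, ~1/f
  power across the band, 10 µV RMS.
* **Blinks**: difference-of-Gaussians biphasic pulses, 100 µV peak on
  AF3/AF4 (the corneo-retinal potential yields 0.4–1.0 mV at the eye, of
  which frontal scalp electrodes retain a fraction), 0.1× residue on all
  other channels, two pulses 0.3 s apart, ±10% amplitude jitter.
* **Artifact**: one shared quasi-periodic head sway — a 0.25→1.2 Hz chirp
  with a random amplitude envelope plus a small 1/f residue, everything
  below 3 Hz — at 35 µV RMS so its peaks reach blink amplitude, with
  per-channel gains in 0.8–1.2 and ±2-sample phase jitter. A *narrowband*
  sway is what deliberately following an oscillating target produces; it
  is also the honest stress case for the gating method, since a broadband
  artifact is provably beyond per-IMF index gating (different channels'
  IMFs slice different sub-bands of a broadband process, capping
  cross-channel correlation near 0.5 regardless of amplitude).
* **Gyro**: amplitude-ramped chirp target velocity (peak 60 deg/s) plus
  4–12 Hz tremor jitter at 5 deg/s.

What the generators do **not** emulate: mains interference, electrode pops
and drift, physiological EEG rhythms (alpha spindles), single blinks and
saccades, inter-subject variability of blink morphology, or genuinely
broadband movement artifacts. A green test therefore establishes that the
pipeline does what the method claims *in its intended regime* — it does
not establish hardware-grade detection rates, which is also why the
acceptance suite checks analytic invariants and property-level performance
(TPR ≥ 0.9 at FPR ≤ 0.1 on the sweep) rather than reproducing a headline
percentage measured on human subjects.

## Known limitations

* Per-IMF gating removes whole modes per 10 s window; a blink sharing a
  gated mode loses part of its amplitude (the suite requires median peak
  retention ≥ 70%, not exactness).
* The correlation vote needs most electrodes to see the artifact; gating
  degrades gracefully but noticeably when the montage is small.
* The calibrated decision distance depends on the training SNR; across
  hardware it must be re-derived, exactly as the original 0.95 was.
* EMD mode assignment is input-sensitive; the adjacent-alignment rule
  absorbs off-by-one splits but not pathological fragmentations.
* The Kalman stage smooths jitter; it cannot remove integration drift
  (gyro bias) — that requires a reference sensor, out of scope here.
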