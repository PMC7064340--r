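---
title: "Modeling overtone focusing in biphonic throat singing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling overtone focusing in biphonic throat singing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sygyt)
```

## The problem

In Sygyt-style Tuvan throat singing a single vocal source produces two
perceived pitches: a low drone at the fundamental frequency f0 and a
whistle-like melody carried by one strongly amplified overtone in the
1.5-2 kHz region. The mechanism modeled here is purely linear filtering:
the singer reshapes the vocal tract so that the second and third formants
(F2, F3) of the tract's frequency response merge into a single narrow,
high-gain peak — the *focused state* — that sits on top of one harmonic of
the source (for example the 12th harmonic of a 150 Hz source, 1800 Hz).
The package implements the full chain needed to study this quantitatively:

1. tract geometry (traced midsagittal profiles → centerline →
   cross-distance → area function),
2. tract acoustics (lossy transmission-line frequency response, formants,
   acoustic sensitivity functions, and the iterative perturbation that
   produces the merge),
3. linear source/filter synthesis (static and dynamic normal→focused
   transitions),
4. spectral analysis (STFT spectrograms, harmonic ladders, envelope
   trends, the band energy-ratio statistic eR, transition detection), and
5. synthetic-data generation so that every stage is testable without any
   external recordings.

## Tract geometry

A traced profile consists of two polylines (inner and outer contour,
glottis-first, in cm). `extract_centerline()` walks from the midpoint of
the glottis-end segment in fixed arc steps (default 0.25 cm); at each step
the provisional point is corrected along the local normal — by root
bisection of the difference of distances to the two contours — until it is
equidistant from both. The cross-distance `D(x)` is the sum of the two
contour distances at the balanced point, and `x` is cumulative arc length.
The first and last 0.5 cm are flagged low-confidence: there the
perpendicular does not cleanly intersect both contours, and distances are
dominated by the contour end segments. Accuracy checks exclude these
flagged points; on synthetic profiles with known geometry the recovered
cross-distances agree with ground truth within 2% elsewhere.

Cross-distances become areas through the power law `A(x) = k D(x)^alpha`.
Only the circular-section approximation (`k = pi/4`, `alpha = 2`) is built
in as a default; published alternatives exist for non-circular sections
but no agreed set of constants, so both parameters stay exposed.

## Transmission-line acoustics

`compute_frequency_response()` treats the tract as a cascade of uniform
tube sections (default 44 sections over 17.5 cm). Each section contributes
a two-port chain matrix with complex propagation constant derived from a
per-unit-length series impedance and shunt admittance in CGS units:

* air inertance `j w rho / A` and compliance `j w A / (rho c^2)`,
* viscous series resistance `(S/A^2) sqrt(w rho mu / 2)` and thermal shunt
  conductance `S (eta - 1)/(rho c^2) sqrt(lambda w / (2 c_p rho))`, with
  `S` the section circumference,
* a yielding-wall shunt branch `S / (r_w + j w m_w + k_w/(j w))` with the
  classic soft-tissue values `r_w = 1600 dyn s/cm^3`, `m_w = 1.5 g/cm^2`,
  `k_w = 3e5 dyn/cm^3`.

The lips are terminated by a piston-in-baffle radiation load, the glottis
by an ideal volume-velocity source. The default transfer function is the
volume-velocity gain `U(lips)/U(glottis)` in dB; the `radiated_pressure`
variant adds the +6 dB/octave lip radiation characteristic and represents
what a microphone records. Formant frequencies are insensitive to the
choice; synthesis uses the radiated-pressure form because the synthesized
clips emulate recordings.

All constants live in `acoustic_constants()`. They are the standard values
of the transmission-line literature, chosen once: with all losses enabled
a uniform 17.5 cm tube gives formant bandwidths of roughly 35-70 Hz for
F1-F3, consistent with measured vocal-tract bandwidths. With losses
disabled the model reduces to the rigid lossless tube, and the first three
resonances of a closed-open uniform tube land on the quarter-wave series
`(2i-1) c / 4L` to within 1% on a 1 Hz grid — the package's primary
analytic anchor.

## Sensitivity functions and the formant merge

The sensitivity of formant `Fi` to a fractional area change in section `n`
is computed from the acoustic energy distribution at `Fi`:
`S(n) = (KE_n - PE_n) / sum(KE + PE)`, with kinetic energy
`rho l |U_n|^2 / (2 A_n)` and potential energy
`A_n l |P_n|^2 / (2 rho c^2)` from the internal pressure/flow profile.
It predicts `dFi/Fi ~ sum_n S(n) dA(n)/A(n)`. In the lossless model this
identity is exact to first order: against a finite-difference oracle
(perturb one section by 1%, relocate the formant by golden-section search
on the continuous response) predictions agree within a few percent, and
the package asserts 10%. With the full loss model the energy form is only
a first-order approximation — wall impedance biases the low formants by up
to ~25% — which is acceptable because the perturbation loop only needs the
direction and rough magnitude of the gradient.

`perturb_to_focus()` drives formants i and j (default 2 and 3) onto a
target frequency with the multiplicative update

```
dA(n)/A(n) = step * [ Shat_i(n) (T - Fi)/Fi + Shat_j(n) (T - Fj)/Fj ]
```

where `Shat = S / sum(S^2)`. The normalization matters: a raw-sensitivity
update moves a formant by only fractions of a hertz per iteration (each
`S(n)` is O(1/N)), whereas the normalized form closes a fixed fraction
`step` of the remaining relative gap per iteration and converges
geometrically. Updates are smoothed with a 3-section moving average,
clipped at ±20% per iteration, and areas are floored at 0.05 cm^2. The
loop declares success when both formants are within 1% of the target or
when the picked response shows a single merged peak within 1% of it. Peak
coalescence is detected by a drop in the peak count below 5 kHz or by the
peak-picker's minimum-separation rule (80 Hz, ties toward the lower
frequency).

Merging alone leaves the two underlying poles stalled roughly 150 Hz
apart: the response shows one broad asymmetric peak whose skirts suppress
the neighboring harmonics by only a few dB, far short of the 15-35 dB
measured on real singers. The final *deep focus* stage closes this gap by
making the oral-constriction mechanism explicit: the deepest interior
local minimum of the area profile (the alveolar constriction CO; the
boundary taper at the glottal end is excluded because it is not an
articulator) is tightened by 20% per step toward the area floor, with one
or two sensitivity-based re-centering updates after each step to hold the
merged peak on the target. The result is a single peak within a fraction
of a percent of the target whose ±1-overtone suppression is ~26 dB, inside
the measured range.

Degenerate inputs are reported, not thrown: a target below ~0.8 F1 returns
a non-convergence result flagged `unreachable`; hitting the iteration cap
returns the trace with reason `max_iter`; a tract whose formant i already
sits on the target while formant j is far above is recognized as already
merged and returned unchanged.

## Source/filter synthesis

The glottal source is a harmonic comb with a constant spectral tilt.
The default tilt is **-8 dB/octave**. This is a deliberate design choice:
the modal-voice textbook value of -12 dB/octave, combined with the
+6 dB/octave radiation characteristic, leaves the low drone harmonics
carrying so much spectral magnitude that no physically attainable filter
sharpness brings the focused-band energy ratio up to the levels measured
on real performances (the integral in eR is over linear magnitude, which
weights the strong low harmonics heavily). Sygyt is sung loudly with
pressed phonation, which is known to flatten the source spectrum; -8
dB/octave reproduces the measured focused-state contrast (median eR(1,2)
around 0.55 focused versus 0.05 normal) while remaining a conservative
glottal slope. The tilt is a single exposed parameter, and nothing else in
the model was adjusted to meet the contrast.

`synthesize_static()` is additive synthesis: harmonic k has amplitude
`source_level(k) * |H(k f0)|`, launched sine-phase, peak-normalized.
`synthesize_dynamic()` renders a scenario timeline frame-wise (20 ms Hann
frames, 50% overlap-add): per frame the normal and focused tracts are
geometrically interpolated (`A = A_a^(1-w) A_b^w`, which keeps areas
positive) at the scenario's focus weight, responses are cached on a 0.05
weight grid, and partial phases run continuously across frames so the
overlap-add introduces no discontinuities. Vibrato is sinusoidal frequency
modulation in cents, applied to the instantaneous phase. A scenario's
optional second focus (3-3.5 kHz) is applied as a static parametric
resonance boost on the filter gains, emulating singers who hold a second
focused formant fixed.

## Spectral analysis

`compute_spectrogram()` mirrors the analysis settings used for the study's
recordings: Hamming window, 95% fractional overlap, and a window of 4096
samples at 96 kHz (~43 ms). At other sample rates the default window is
the power of two nearest the same ~43 ms span (2048 at 44.1 kHz), and the
hop is `floor(0.05 * window)` samples (204 at 4096). Magnitudes are dB re
the global maximum with a -120 dB floor. Harmonic levels are read with
parabolic interpolation around the bin maximum, which removes the window's
scalloping loss (up to ~1.8 dB for Hamming) from all level comparisons.

The energy ratio is
`eR(fL, fH) = ( int_fL^fH P df / int_0^fmax P df )^2` with `P` the linear
spectral magnitude — integrate the magnitude, then square the ratio. The
definition's prose and its typeset formula disagree (the prose squares the
magnitude before integrating); the typeset formula is the only fully
explicit statement, so it is the default, and the prose reading is
available as `variant = "power"`. Both are bounded in [0, 1]; the defaults
for the band and range are [1, 2] kHz and 8 kHz.

`detect_transitions()` is a Schmitt trigger on the eR trace: on at
`threshold` (default 0.35), off below `threshold - hysteresis` (0.1), with
on-periods shorter than `min_hold` (100 ms) discarded as chatter. The
thresholds are package choices — transitions in the study were annotated
by eye — sized so that the normal-state level (~0.05) and the
focused-state level (~0.55) of the synthetic material sit far on either
side. For timing recovery the spectrogram should be computed with a hop
comparable to the transition duration (~50 ms ramps; 50% overlap of a
~46 ms window gives a 23 ms hop); the detector then recovers the ramp
completion within one hop. With the default 95% overlap the trace is far
oversampled relative to the window length, and the detector's constant
bias (~15 ms early, because the threshold crossing happens about 70% of
the way through the ramp) spans several hops.

The envelope trend (`estimate_formant_trend()`) upsamples the
harmonic-level series by a factor of 10 with a lowpass interpolating FIR
filter (`signal::interp`), interpreting the published "scaling factor of
10" as band-limited upsampling of the harmonic-peak envelope; envelope
peaks are returned as formant estimates.

## Synthetic data: what it emulates, and what it does not

`make_designed_area_function()` builds the "designed" neutral tract: a
2.5 cm^2 baseline with a cosine taper to 0.5 cm^2 at the glottal end,
log-area Gaussian constrictions near the uvula (CP, 7 cm, 2.2 cm^2) and at
the alveolar ridge (CO, 14 cm, 1.6 cm^2, sigma 1 cm), and a large
sublingual expansion (9 cm^2) just anterior to CO representing the
retroflex tongue position. The expansion is essential to the control
topology: it turns the front cavity into a Helmholtz-type resonator whose
mode lies between the back-cavity modes, so that tightening CO
monotonically pulls F2 and F3 together while CP sets the frequency at
which they meet — the two-knob mechanism the imaging data identify. With
the defaults the neutral formants are widely spaced (about 590, 1550,
2260, 3340, 4480 Hz; F3 - F2 > 700 Hz), qualitatively matching a neutral
vowel; the exact published formant list for the original designed tract is
not reproducible because that area function exists only as a figure.

Scenario generation (`make_song_scenario()`) draws the focus frequency
uniformly from 1500-2000 Hz, the transition ramp from 40-60 ms (the
measured speed of real transitions), and, for the double-focus style, a
static second focus from 3000-3500 Hz; f0 defaults to 150 Hz and all draws
are seeded. `make_synthetic_profile()` wraps an area function into
inner/outer contours around a straight or circular-arc centerline and
returns the exact ground truth for geometry tests.

What the synthetic material does **not** emulate: breath and fry noise,
jitter/shimmer, room acoustics, the dental-post imaging artifact,
piriform-sinus side branches, subharmonic (Kargyraa-style) sources, and
singer-specific source spectra. Passing tests therefore demonstrate the
internal consistency of the model chain and its agreement with the
published analysis settings and claims — not that the pipeline recovers
these quantities from arbitrary real-world recordings.

## Numerical choices

* Frequency grids: 10-8000 Hz at 2 Hz for formant work, 1 Hz for the
  quarter-wave and sensitivity anchors; 5 Hz inside the dynamic
  synthesizer's response cache. `refine_formant()` locates peaks to
  sub-grid precision by golden-section search on the continuous transfer
  magnitude.
* Peak picking: prominence threshold 1 dB, minimum separation 80 Hz, ties
  broken toward the lower frequency, parabolic refinement of both
  frequency and level.
* Perturbation: step 0.1, at most 200 iterations, tolerance 1% of target,
  area floor 0.05 cm^2, 3-section smoothing, ±20% per-iteration clip;
  deep-focus stage: 20% tightening per step, at most 20 steps.
* Problem sizes: 44 tube sections; 2 s clips at 44.1 kHz for the
  contrast measurements; 4 s scenario clips for transition recovery.
  These sizes keep every documented computation in the seconds range
  while leaving all results stable to further refinement.

## Known limitations

* The energy-based sensitivity is exact only in the lossless model; with
  losses it remains a usable gradient but not a precision instrument.
* The deep-focus stage assumes the controlling constriction is an
  interior minimum of the area profile; a tract whose narrowest interior
  point is not the intended articulator would be tightened at the wrong
  place.
* The 1-D transmission line ignores side branches and 3-D effects; above
  ~5 kHz the plane-wave assumption itself is questionable.
* The linear source/filter model cannot express source-filter coupling or
  any nonlinear phonation regime; that is the point of the exercise — the
  focused state emerges without them — but it bounds the model's reach.
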