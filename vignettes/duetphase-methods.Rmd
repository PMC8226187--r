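---
title: "Models and methods behind duetphase"
author: "duetphase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duetphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duetphase)
```

# The phasing paradigm

Two performers repeat the same 12-note pattern. The first (the
*timekeeper*, top part) holds a steady tempo of 72 BPM, where one beat
is a dotted quarter — six sixteenth notes — so a sixteenth lasts
60/(72·6) ≈ 138.9 ms and the pattern cycles at 0.6 Hz. The second (the
*shifter*, bottom part) accelerates slightly during designated bars
until it has gained exactly one sixteenth, then locks back in. With 8
pattern repetitions per stable bar and 12 one-sixteenth shifts, the
piece consists of 25 alternating stable/shifting measures and visits
every cyclic phase relation 0–11 before returning to unison.

`duetphase` treats this structure as a measurement instrument: the
performance output, the performers' bodies, and their self-reports are
analyzed in three layers, and the similarity of those layers between a
mediated duet (virtual partner) and a real one is the quantity of
scientific interest. Because a single dyad's recordings are not
reproducible at a desk, the package ships a synthetic generator whose
defaults encode the compositional schedule above; all structural claims
in the test suite are made against it or against closed forms.

# The synthetic duet generator

## Schedule and ideal onsets

`generate_score()` expands the schedule: stable bars last
8 · 12 · 60/(72·6) = 13.33 s, shifting bars last `shift_duration_s`
(default 10 s; the score's guidance of 30–60 s per shift remains a
valid setting — the short default keeps simulated runs and test times
proportionate, and the margin analysis below still holds at longer
settings). The shifter's position in its part is described in
*sixteenth counts*: u₂(t) = u₁(t) + o(t), where u₁ is the timekeeper's
count and o(t) is the scheduled offset — constant k during stable bar k
and ramping linearly k−1 → k across a shifting bar. Onsets fall where
u₂ crosses integers; acceleration within a shifting bar is therefore
linear in rate, the simplest reading of a "very slight" tempo increase.
In the noiseless limit the relative-phase gain across every shifting
bar is exactly 2π/12 (asserted to 10⁻⁹ rad in the tests).

The simulation starts at the unison bar: a solo opening bar would have
no defined relative phase and contributes nothing to any analysis here.
Pattern pitches default to twelve distinct placeholder MIDI numbers;
only onsets enter the analyses.

## Timing noise: what is independent and what is shared

Two noise sources are modelled per performer:

* **Per-onset jitter** — Gaussian, truncated at ±3 SD, default 8 ms —
  a plausible keystroke dispersion for expert pianists, exposed in
  `performer_params()`.
* **Tempo drift** — a reflected random walk in BPM (step SD 0.2,
  bounded to ±3 BPM), modelling slow wander around the prescribed
  tempo.

A crucial modelling decision is that *drift is common-mode for a
coupled duo*. Two musicians playing together do not diffuse apart like
independent clocks: ensemble timing research consistently shows
per-onset phase correction that cancels slow relative drift. The
shifter therefore derives its grid from the timekeeper's realized
(drifted) beat; its own tempo deviations leak into relative timing only
through `1 − phase_correction`, and the default `phase_correction = 1`
(full correction) leaves per-onset jitter as the only relative noise.
Setting `phase_correction < 1` emulates weaker coupling, down to
independent drift at 0. Without this structure the synchronization
analysis below would be hopeless: independent ±3 BPM walks move the
relative phase by far more than a shifting bar does.

## Motion, gaze, sway, pupil

`synthesize_motion()` emulates the signals a motion-capture rig would
record, at 120 Hz:

* **Head position**: the score has two beats per pattern cycle, so the
  head oscillates at 2φ(t) — 1.2 Hz at 72 BPM — along one axis
  (amplitude 2 cm), phase-locked to the performer's own part, plus
  isotropic Gaussian noise with SD 0.3 of the amplitude.
* **Gaze**: the test performer looks forward, with the partner seated
  2 m away at 60° azimuth; at each shifting-bar start gaze reorients
  toward the partner's head for a 2 s dwell (transition-locked
  attention), with small angular noise.
* **Chair pressure**: four channels of a slow bounded random walk with
  one injected posture step change at the middle scheduled transition —
  the signature the sway recurrence plot is meant to reveal.
* **Pupil**: baseline 3.5 mm with slow modulation and Poisson-timed
  blink gaps of 60–200 ms (missing values).
* **Nods**: events at stable-bar starts (probability configurable),
  standing in for manual annotations.

What the generator does **not** emulate: expressive dynamics and
rubato, realistic nod kinematics (only event times), marker dropout,
skeleton artefacts, or any correlation between questionnaire answers
and performance. Passing tests therefore certify the analysis chain and
the schedule logic, not fidelity to any particular human recording.

Determinism: one master seed per call; every signal draws from its own
deterministically derived sub-seed, so identical (config, seed) give
byte-identical output regardless of evaluation order.

# The Kuramoto virtual partner

The agent is a single phase oscillator with a first-order frequency
attractor:

$$\dot\theta = \omega + K \sin(\theta_{live} + \Delta - \theta), \qquad
  \dot\omega = \gamma(\omega_0 - \omega) + K_f \sin(\theta_{live} + \Delta - \theta).$$

ω₀ is the cycle frequency equivalent to 72 BPM (2π · 0.6 rad/s), Δ the
scheduled offset (ramping linearly across shifting bars), K = 0.5 rad/s
the phase gain, K_f = K/10 the frequency gain (0 recovers phase-only
coupling), γ = 0.05 s⁻¹ the relaxation rate. There is no canonical value for any
of these gains; they are engineering choices, all exposed in
`agent_params()`. Their consequences are analytic: in free
run the tempo decays exponentially to 72 BPM (from 80 BPM the residual
after 5/γ is 8e⁻⁵ ≈ 0.054 BPM); for a constant live-rate mismatch the
locked phase error is arcsin(Δω_res/K), with locking lost when the
residual mismatch exceeds K — both regimes are asserted in the tests.

Live phase is tracked from onsets: phase 2πk/12 at the (k+1)-th onset,
linear extrapolation between onsets at the median rate of the last 12
IOIs, capped at one sixteenth so the estimate never overtakes the next
onset and is monotone under jitter. The cap also bounds the damage a
single late onset can do. Integration is explicit Euler at dt = 10 ms;
halving dt changes the end-of-run phase by well under 10⁻³ rad on the
default scenario, which is the guard for this choice.

`render_agent_stream()` replays a prerecorded bottom part by emitting
its k-th note when the agent phase crosses 2πk/12; the warp map is
monotone whenever the phase is (a non-monotone trajectory raises a
controller-instability error rather than silently reordering notes).
When a streaming latency matters it can be applied to the
agent's input (`latency_ms`, e.g. 54 ± 11 ms); a high-gain "rigid"
agent (K ≈ 2) then transmits tracked fluctuations into its output and
shows visibly higher IOI variability than a coupled human pair — the
behavioural signature used in the condition comparison.

# Layer 1 analytics

**Phase and SI.** Cycle phase interpolates linearly between onsets and
is resampled at 20 Hz — far above the phase bandwidth, and chosen so
the default RQA delay of 0.3 s is exactly 6 samples. The
synchronization index is the circular resultant length over a centered
10 s window, hopped at 0.05 s, truncated (never padded) at the edges.

**Why the 0.99 threshold separates the measures.** Over a window that
exactly spans one shifting bar the relative phase drifts by
Δ = 2π/12, giving SI = |sin(Δ/2)/(Δ/2)| ≈ 0.9886 < 0.99, while fully
stable windows give SI = 1. The margin is only ≈ 0.0015, which is why
the window (10 s, matching the default shift duration) matters: longer
shifts at the same window dilute the drift per window and raise the
dip; users changing `shift_duration_s` should revisit the threshold or
window. Under 8 ms jitter the dip fluctuates near the threshold, so
segmentation recovers the written 25 measures in most but not all runs
(18 of the 20 fixed-seed runs in the suite); with slow relative drift
(weakly coupled performers) recovery degrades further — a sensitivity
worth remembering with real data.

**Segmentation.** Runs of SI ≥ threshold are stable; runs shorter than
`min_segment_s` (2 s) are merged into a neighbour, longer neighbour
winning, processing the shortest run first — that order re-unifies dips
fragmented by near-threshold flicker. Stable segments are annotated
with the modal sixteenth offset.

**Joint RQA.** "Joint RQA of the relative phase" can mean either
embedding the scalar Δφ series or conjoining the two performers'
recurrence plots. The package defaults to the two-system reading —
each phase mapped to (cos φ, sin φ) before delay embedding (avoiding
wrap discontinuities), recurrence plots thresholded separately, then
AND-ed — since that is what makes the analysis genuinely *joint*; the
single-series route is available by building a recurrence plot of Δφ
directly. Defaults m = 4, τ = 0.3 s,
minimal diagonal/vertical length 0.3 s (6 samples), Theiler window
m·τ (the source is silent; m·τ removes the trivial tangential band),
radius 0.55 documented but `calibrate_radius()` — bisection to a 10%
recurrence target, guaranteed by the monotonicity of RR in the
radius — is the normative path. Windowed metrics use 10 s windows
stepped 1 s along the main diagonal, fully interior only.

**Embedding diagnostics.** `select_delay_ami()` uses equiquantile
binning with ⌊√(n/5)⌋ bins and takes the first *material* local minimum
(after light smoothing, requiring the subsequent rise to exceed 2% of
the lag-0 value), falling back to the 1/e rule — one sample for white
noise. Two caveats discovered while validating: binned AMI is
degenerate on noise-free periodic signals (the joint support is a thin
curve and bin-resonance ripple swamps the theoretical quarter-period
minimum), so the diagnostic is only meaningful for noisy, generic data;
and Kennel FNN has a duplicate-state floor on piecewise-linear
staircase signals such as the *noiseless* relative-phase trajectory —
with realistic jitter it converges cleanly (m = 4 on the default
simulation, consistent with the package default).

# Layer 2 analytics

**Head PC1.** PCA is per performer (centering only, no scaling): a
joint PCA over the dyad would mix the two bodies' scales and let one
performer's range dominate the shared component.
The sign is fixed by making the largest-magnitude loading positive and
the projection is z-scored.

**Wavelet coherence.** Morlet with ω₀ = 6, 12 voices per octave over
0.125–4 Hz, computed by FFT. Coherence is the magnitude-squared
smoothed cross-spectrum over the smoothed auto-spectra, with
Torrence–Compo-style smoothing: Gaussian in time with SD equal to the
scale, boxcar over 0.6 octave in scale. (A narrower time smoother was
considered; it inflates the white-noise null — median in-cone coherence
rose to ≈ 0.48 versus ≈ 0.36 at the classic bandwidth — so the classic
choice stands, and the Monte-Carlo null is part of the suite.) The cone
of influence uses the √2·scale e-folding time and is excluded from all
summaries. Band phase statistics (default 0.9–1.5 Hz) are
coherence-weighted circular means and resultant lengths, reported in
degrees in (−180°, 180°]; an unweighted mode exists. Wavelet family
and smoothing bandwidths differ across implementations, so phase
statistics printed by other toolchains are reference values, not
reproduction targets.

**Gaze.** The angle between the gaze unit vector and the head-to-partner
unit vector, in degrees; missing samples propagate; a coincident head
pair raises a geometry error rather than returning NaN.

**Sway.** The four pressure channels are summed, z-scored and decimated
to 10 Hz (sway bandwidth ≪ 1 Hz; this keeps the O(n²) plot tractable),
embedded with m = 5, τ = 0.35 s. The unthresholded plot divides
embedded distances by their maximum; thresholded metrics use the 10%
calibration. Mocap-style gaps under 0.25 s would be interpolated;
longer ones split analysis blocks.

# Layer 3

Questionnaire scales are defined structurally — item counts, 1–7
bounds, subscale keys — because the published instruments' item texts
are licensed material; a reverse-key map and an optional flow subscale
split are supported. Pupil preprocessing removes blink artefacts by a
dilation-speed filter (3 MAD on sample-to-sample speed) plus an
amplitude filter (3 MAD on diameter) for the occluded samples between
blink edges, interpolates gaps under 0.5 s, leaves longer gaps missing,
and z-scores over valid samples. Normalized pupil series are comparable
only within a recording — never across lighting conditions.

# Orchestration and problem sizes

`run_pipeline()` executes simulate → analyze → report from one config,
records a config hash, seed and package version in every report, and
writes CSV/JSON artifacts; `compare_conditions()` tabulates per-layer
summaries with absolute differences against a designated ground-truth
condition (the condition labelled `human` by default — ground truth is
a label, not a hard-coded condition). Plots are deliberately absent
from the tested surface; CSV/JSON are.

The test suite runs full-length performances (≈ 293 s, ≈ 2100 onsets
per part) for schedule-level claims and shorter 5-bar scores for
end-to-end plumbing; coherence operates on series decimated to 20 Hz.
These sizes were chosen to keep each check well-resolved while the
whole suite stays comfortably runnable on a laptop.

# Known limitations

* The generator's humans are schematic: no expressive timing beyond
  jitter/drift, no error notes, no genuine nod kinematics.
* The segmentation threshold's 0.0015 margin makes measure recovery
  sensitive to any slow relative-phase wander; treat the 0.99 value as
  calibrated to this schedule and window, not universal.
* AMI/FNN diagnostics require noisy, generic data (see above).
* The Kuramoto gains are plausible, not fitted; closed-loop behaviour
  with a human in the loop will differ from the simulated loop.
* Single-dyad scope: the comparison report is descriptive; no
  cross-dyad inference is provided by design.
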