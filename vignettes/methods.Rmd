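---
title: "Methods: traveling-wave detection, ensemble analysis, and the balanced-network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traveling-wave detection, ensemble analysis, and the balanced-network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexwaves)
```

`cortexwaves` implements an analysis chain linking cortical-surface
traveling waves, recorded with a dense electrode grid (micro-ECoG) over
mouse barrel cortex, to the translaminar circuit patterns that accompany
them: layer 2/3 calcium ensembles, laminar current sinks, whisker
kinematics, and a mechanistic spiking-network account of how motor-cortex
feedback sparsifies the local response. Every analysis runs on synthetic
data with planted ground truth, so each stage of the chain is testable in
isolation and end to end. This vignette describes the models and
estimators, the tunable parameters and their defaults, the numerical
choices, and what the synthetic tests do and do not establish about real
recordings.

## Generalized phase of the wideband LFP

Wave analysis starts from the instantaneous phase of the band-limited
surface potential. The grid LFP is zero-phase filtered (forward-backward
Butterworth, order 4) into a wideband 3-40 Hz signal — wide enough to track
evoked transients without committing to a narrow oscillation band — and the
analytic signal is computed per channel with the single-sided FFT (the
Hilbert transform). Phase is the argument of the analytic signal, amplitude
its modulus, and instantaneous frequency the time derivative of the
unwrapped phase (central differences).

On a wideband signal, fast low-amplitude components riding on a strong slow
component drive transient phase reversals: the unwrapped phase dips and the
instantaneous frequency goes negative. `gp_correct()` treats every sample
whose unwrapped phase falls below the running maximum as a discontinuity,
masks it, and re-interpolates the unwrapped phase across the masked runs
with a shape-preserving monotone piecewise-cubic interpolant
(`splinefun(method = "monoH.FC")`), then re-wraps. Because the retained
knots are non-decreasing by construction and the interpolant is monotone
between knots, the corrected instantaneous frequency is non-negative at
every sample; runs touching a record edge are held at the nearest valid
phase. The first and last 100 ms of each record are flagged low-confidence
(filter plus Hilbert edge effects) and excluded from wave evaluation. For a
pure in-band tone the correction is the identity and the phase agrees with
a plain narrowband Hilbert phase to better than 0.05 rad.

## Single-trial wave detection

Candidate waves are *evaluation points*: rising crossings of -pi/2 of the
corrected phase on a deterministic trigger channel (the channel with the
largest mean analytic amplitude), i.e. the positive-going upswings of the
LFP. For each evaluation point:

1. **Source.** The phase gradient is computed on the electrode lattice with
   wrapped differences mapped to (-pi, pi] (central in the interior,
   one-sided at edges), and the divergence `D` of the propagation field
   (the negative phase gradient, which points along the direction of
   travel) is maximized over electrodes. Two stabilizations are applied,
   both deterministic: the phase lattice is first smoothed with an NA-aware
   3x3 circular (phasor) mean, and the source is selected among the top-8
   divergence candidates as the electrode with the best circular-linear
   phase-distance fit. On noiseless fields these leave the argmax
   untouched; at an amplitude-to-noise ratio of 10 they raise exact source
   recovery from ~35% to ~100%. The same procedure runs inside the shuffle
   null, so detection thresholds remain calibrated.
2. **Correlation.** Mardia's circular-linear correlation between the phase
   and the Euclidean distance from the source, in [0, 1]; it is invariant
   to global phase offsets and rigid motions of the electrode coordinates.
   Waves need at least 5 unmasked channels and 60% channel participation.
3. **Null.** The detection threshold is the 99th percentile of the
   correlation under random permutation of the electrode locations, with
   source localization rerun on each shuffled copy (default 1000 shuffles,
   one null per dataset). On phase-randomized fields the accepted-wave rate
   is bounded near the nominal 1%.
4. **Kinematics.** For accepted waves the wavenumber `k` (rad/m) comes from
   a least-squares fit of the per-channel phase delay (source phase minus
   site phase). Two delay models are fitted — planar (`delay ~ x + y`, with
   `k` the norm of the fitted gradient) and radial (`delay ~ distance from
   the source`) — and the better-fitting one is kept. The single radial
   regression against Euclidean distance is exact for radial waves but
   biased for plane waves whose divergence source lands on a grid corner
   (distance inflates relative to the propagation coordinate and speeds
   read ~40% high on an 8x8 lattice); the two-model fit is exact for both
   geometries. Instantaneous frequency `f` is the grid average of the
   corrected frequency at the evaluation time, and the speed is
   `v = 2*pi*f / k`. Wave amplitude is the LFP value at the next rising
   zero-phase crossing on the trigger channel (the LFP peak). Planted plane
   waves at 0.1-0.6 m/s and 5-20 Hz are recovered with median speed errors
   of a few percent.

The phase-gradient directionality, `PGD = ||mean gradient|| / mean
||gradient||`, is 1 for an ideal plane wave; for independent random
gradient directions on n sites it concentrates near `1/sqrt(n)` (~0.11 at
n = 64, 99th percentile < 0.35).

## Trial structure and late-wave classification

A trial is *responsive* when the absolute wideband deflection within 70 ms
of touch exceeds 3x the SD of the 500-ms pre-touch baseline on the
reference channel (the channel with the largest mean evoked amplitude; the
signal is baseline-mean subtracted first). The same 3-SD logic classifies
the *late wave*: a trial is strong-late when the maximum amplitude in the
late window (default 80-200 ms post-touch for passive touch; ~50-100 ms is
appropriate for active touch, where the evoked LFP is more compressed)
strictly exceeds 3 baseline SDs; ties are weak. The late-wave amplitude of
an averaged trace is trough-to-peak: the late trough after an annotated
approximate onset, then the maximum in the 100-300 ms window. Wave counts
in randomly drawn 50-ms windows (default 10,000 draws per interval class)
feed nonparametric comparisons between behavioral states.

## Calcium ensembles

The ensemble pipeline works on deconvolved event rasters. Events below 2.5x
the per-cell noise floor are dropped; the noise floor is the MAD-based SD
of the dF/F on deconvolution-silent frames (robust, and independent of the
event amplitudes themselves). Binary events are summed in non-overlapping
300-ms bins into activity vectors, and all pairwise cosine similarities
form the similarity map. Statistical structure is calibrated by
spatiotemporal surrogates: per-neuron temporal permutation followed by an
event shuffle across ROI pairs, repeated (default 1000 times), yielding
99th-percentile thresholds for population coactivity, pairwise similarity,
and — from the eigendecomposition of the surrogate similarity maps — the
leading eigenvalue. Ensembles exist only when an observed eigenvalue beats
the shuffled eigenvalue threshold; retained components are the smallest
significant set capturing 90% of the spectrum. Bins with at least one
significant similarity partner are the candidate state bins (the per-bin
fraction of significant partners is the *reactivation index*).

Functional connections come from the Sorensen-Dice coefficient of event
trains restricted to the candidate state frames: `2|A n B| / (|A| + |B|)`,
connected when above 0.25. Two curation choices are the package's own.
First, an edge must also pass a Bonferroni-corrected hypergeometric test of
the overlap count (familywise alpha 0.01 across active pairs): with ~200
cells a raster contains ~2x10^4 pairs, and background cells with a handful
of events chance-overlap in 2 frames often enough to seed spurious 2-cell
groups that the fixed Dice cut-off cannot reject. Second, membership is
assigned by deterministic greedy modularity clustering (igraph) of the
retained weighted graph rather than by connected components: ensembles that
independently reactivate at 0.3 per frame chance-co-occur in ~9% of frames,
which puts cross-ensemble Dice right at ~0.3 and would otherwise merge
distinct ensembles. With both in place, 2-4 planted disjoint ensembles of
6-10 cells among 200 are recovered with mean Jaccard ~1.0, and
structureless rasters return zero ensembles in >= 95% of seeds. Ensemble
reactivation is the mean proportion of members co-active on state frames
whose member coactivity exceeds the ensemble's share of the shuffled
coactivity threshold. Per-trial-class analysis (strong vs weak late wave)
reruns the pipeline on each class's frames (window -500 ms to +4 s around
touch in the intended use) and reports sizes, connection counts,
reactivation, and weight distributions; groups under 3 trials are flagged
unstable.

Touch-evoked transient onsets use each cell's 99th-percentile event
threshold; within 1 s of touch (configurable for dendrites) the largest
supra-threshold event is located and its onset is the preceding inflection
of the deconvolved trace, alongside the time of maximal dF/F slope. Cells
are touch-responsive when the trial-averaged evoked dF/F exceeds 3x the
baseline SD within 2 s. Onset-time dispersions are compared by resampling
100 onsets with replacement (default 10,000 draws) and comparing the SD
distributions.

## Laminar analyses

The CSD is the discrete second depth-derivative,
`I_i = (V_{i+n} + V_{i-n} - 2 V_i) / (n * dz)^2` with a channel step of
`n = 2` by default; the step enters the denominator as `n * dz` so the
estimator converges to the second derivative for any `n`. Vaknin padding
(duplicating the boundary channels) extends the estimate to the full
shank; the padded boundary rows are estimates, not second differences, so
exactness statements (affine profiles annihilate exactly; linearity to
machine precision; planted sinks localize to the planted channel) apply to
the interior rows. Sinks are negative by convention.

Spectrograms use complex Morlet wavelets (time-bandwidth parameter 6) on a
log-spaced frequency grid, computed by FFT convolution; frequencies whose
wavelet support exceeds the record are dropped with a warning. Band-power
ratios sum spectrogram power in the canonical bands (gamma 30-90, beta
15-30, theta 4-12 Hz) inside early (0-60 ms) and late (100-200 ms) windows
— the windows are arguments, since figure-level analyses elsewhere use
0-50/100-250 ms. The relative laminar power profile is a per-channel Welch
PSD inside a -100 to +200 ms peri-touch window, normalized per frequency
column to its cross-channel maximum; it is invariant to any global gain.
The late-sink bootstrap resamples 20 trials per late-wave class (50
iterations by default), averages, computes the CSD, and records the most
negative value over the configured superficial (L2/3) channels in the late
window; which channels count as L2/3 is dataset anatomy and stays a
parameter.

## Behavior

Whisker angle is measured from the base label relative to a whisker-pad
reference point, band-pass filtered 1-30 Hz, and its phase taken from the
analytic signal with phase 0 at maximal protraction. Whisker bend is the
Menger curvature of the three distal labels, `c = 4A / (|x-y||y-z||z-x|)`
(the inverse circumradius): zero for collinear labels, rotation and
translation invariant, scaling as `1/s`. Touches are first frames of
entries of the distal label into the touch-surface ROI polygon (even-odd
rule), debounced per episode, and optionally filtered so consecutive
touches are separated by more than 100 ms (keeping the first touch and
every touch whose gap to the last *retained* touch exceeds the minimum —
an idempotent rule). Task outcomes follow the go/no-go contingency with a
1.3-s response window, and discriminability is
`D' = Z(hit rate) - Z(false-alarm rate)`; rates of exactly 0 or 1 are
clamped by the 1/(2N) convention.

## The balanced-state spiking network

The mechanistic model is a conductance-based leaky integrate-and-fire
network on a 2-D lattice with periodic boundaries, 80% excitatory and 20%
inhibitory (exact split), integrated by forward Euler at dt = 0.1 ms.
Connectivity is local — each neuron sends `K` synapses whose displacements
are drawn from a discretized Gaussian (sigma = 300 um) — and every synapse
carries a conduction delay `tau_ij = tau_s + d_ij / v_c` with
`tau_s = 0.5 ms` and `v_c = 0.3 m/s`, inside the unmyelinated horizontal
fiber range (< 1 m/s); delays round to integration steps and delivery goes
through a circular event buffer. The simulated LFP is the summed absolute
excitatory and inhibitory synaptic current in adjacent non-overlapping
10x10-neuron pools, sampled at 1 kHz.

The scaled-down default is 20,000 neurons (100 x 200 at 6.78 um spacing,
the full-scale density) with `K` scaled to preserve the full-scale
connection probability (1000 synapses per cell among 450,000 neurons, so
K = 44 here). Synaptic weights are expressed in units of the leak
conductance and calibrated by `1/sqrt(K)` scaling from the K = 80
balanced-state reference values (0.6 excitatory, 6.7 inhibitory); the
alternative of keeping ~1000 synapses per cell with `1/sqrt(K)` weights
was tested and the self-sustained state collapses (the mean inhibitory
current grows with `sqrt(K)` while the fluctuations that drive firing stay
constant), so the low-in-degree fluctuation-driven regime is the one that
self-sustains at this scale. Remaining constants are standard cortical
values, with two calibrated to hold the asynchronous-irregular state:
reset -65 mV (below the -60 mV leak) and a 10-ms refractory period that
lumps absolute and relative refractoriness; without them the low in-degree
makes inhibitory shot noise drive bursty trains (ISI CV ~1.8). A 50-ms
Poisson kick seeds the state; there is no external drive afterwards. At
defaults the network self-sustains indefinitely at ~16 Hz with ISI CV
~1.1 and mean pairwise spike-count correlation below 0.01, and a runaway
guard aborts if the population rate exceeds a ceiling (80 Hz default,
below the refractory saturation rate).

The connectivity range matters for wave speed: with short-range
connectivity the per-hop latency is dominated by the fixed `tau_s` plus
synaptic integration and the detected wave speed falls well below `v_c`;
at sigma = 300 um the axonal term dominates and waves detected in the
pooled LFP by the standard pipeline travel at roughly 0.2-0.4 m/s across
seeds for `v_c = 0.3 m/s` — within a factor of 2 of the conduction speed,
which is the meaningful self-consistency bound for a speed set by
conduction delays.

Motor-cortex feedback is modeled as external Poisson fibers (default 300
fibers at 500 Hz, 20 synapses each, weight 0.8) delivered for 20 ms to a
400-um patch, each synapse landing on an inhibitory neuron with
probability `p_target_inhibitory` (default 0.8, sweepable). Paired runs
share a seed and differ only in the feedback (the feedback RNG stream is
separate from the main stream, so spike records are bit-identical before
the onset). Inhibitory-biased feedback roughly halves the fraction of
patch excitatory cells spiking while a wave passes, and at feedback
cessation both excitatory *and* inhibitory patch rates transiently dip
below baseline — the inhibitory-stabilization signature: the silenced
excitatory population no longer sustains the interneurons once their
external drive stops.

## What the synthetic data do and do not establish

The generators plant exactly the structure each estimator assumes:
sinusoidal phase propagation with additive white Gaussian channel noise,
ensemble reactivations that are Bernoulli per frame with all members
participating, a noiseless dipole with separable time course, and
noise-free collinear whisker labels outside touch. Passing tests therefore
establish correctness of the estimators under their own assumptions
(parameter recovery, calibrated nulls, exact oracles), not robustness to
colored noise, electrode artifacts, partial ensemble participation,
overlapping memberships, drifting baselines, or pose-estimation errors —
all of which real recordings contain. Noise is additive white Gaussian and
independent across channels/cells by design; users probing robustness
should extend the specs. Problem sizes in the tests (8x8 grids at 1 kHz,
1-10 s records, 200-cell rasters, a 20,000-neuron network run for 5 s,
bootstraps of 10^3-10^4 draws) were chosen so the whole suite documents
the pipeline's statistical behavior while remaining comfortable to run on
a laptop.

## Numerical and reproducibility notes

All filters are applied forward-backward (zero phase); narrow bands at
high sampling rates go through a low-pass/high-pass cascade for numerical
robustness. Wrapped phase differences are mapped to (-pi, pi] before any
spatial differencing, avoiding unwrap ambiguity across the grid. Ties in
the divergence argmax break to the lowest channel index; the Dice
threshold is a strict inequality; the late-wave rule is a strict
inequality (ties are weak). Every stochastic step takes an explicit seed
and restores the caller's RNG state; the C++ simulator uses its own
explicitly seeded mt19937_64 streams, so builds and paired runs are
bit-reproducible across sessions. Record and raster containers persist as
TSV matrices with JSON sidecars; `run_pipeline()` re-executes stage
chains and writes a manifest, and identical configurations reproduce
identical artifacts byte for byte.
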