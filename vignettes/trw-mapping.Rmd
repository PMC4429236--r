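---
title: "Mapping temporal receptive windows from inter-subject correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping temporal receptive windows from inter-subject correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trwmap)
```

## The problem

Naturalistic auditory stimuli — music, speech — carry structure at many
timescales at once: a musical measure lasts on the order of a second, a
phrase several seconds, a section tens of seconds, and the form of a whole
movement unfolds over minutes. Cortical regions differ in how much of the
preceding stimulus can influence their current response; this span is the
region's *temporal receptive window* (TRW). TRWs can be mapped without a
task: present the same extended stimulus to every listener, scramble it at
a range of structural levels, and ask at which level of scrambling each
voxel's response stops being reproducible across listeners.

The logic rests on the inter-subject correlation (ISC) statistic. A voxel
that only tracks instantaneous acoustic features responds the same way to
a segment regardless of what preceded it, so its time course is
reproducible across listeners even for heavily scrambled (or time-reversed)
audio. A voxel integrating over tens of seconds loses its stimulus-locked
response as soon as scrambling destroys structure at that scale. Labelling
every voxel with the *shortest* coherent timescale that still evokes
reliable responses yields a topographic map of processing timescales.

`trwmap` implements this entire analysis as a tested package: stimulus
construction (segmentation, scrambling, reversal, compression), a
synthetic-cohort generator with known ground-truth TRW structure, BOLD
preprocessing, the ISC statistic with its phase-randomization null and FDR
control, TRW classification, and ROI reliability profiles. The numbered
scripts under `analysis/` run the pipeline end to end on a simulated
cohort.

## The statistic and its null

For each voxel and condition, subject $j$'s time course $TC_j$ is
correlated with the average of the remaining $N-1$ subjects' courses:

$$ r_j = \mathrm{corr}\big(TC_j,\ TC_{\mathrm{All}-j}\big), \qquad
   R = \frac{1}{N}\sum_{j=1}^{N} r_j . $$

$R$ averages raw correlations — no Fisher transform — matching the
definition the analysis is built around; `loo_isc(fisher_z = TRUE)`
averages in $z$ space for users who prefer it. A subject whose series (or
whose leave-one-out average) is constant contributes an undefined $r_j$;
such subjects are excluded from $R$ with a warning rather than propagating
`NA`.

Significance uses surrogate data: each subject's series is Fourier
transformed, every component's phase is rotated by an independent uniform
angle (conjugate-symmetrically, so the surrogate is real; the DC component
is untouched and an even-length Nyquist component keeps a random sign),
and the transform is inverted. The surrogate preserves the power spectrum
— hence variance and autocorrelation — while destroying temporal alignment
across subjects, so the correlation of two surrogates has expectation
zero. Recomputing $R$ for 5000 independently surrogated cohorts gives each
voxel its own null distribution; the one-sided p-value uses the add-one
estimator $p = (1 + \#\{R_{null} \ge R_{obs}\})/(1 + n_{perm})$, which is
never zero and matches the discreteness of a permutation test.

Multiple comparisons are controlled with the sorted-p-value FDR rule:
reject up to the largest $k$ with $p_{(k)} < (k/N)\,q^*$ at $q^* = 0.05$.
The strict inequality in the rule is applied exactly, with no tie-breaking relaxation.
`fdr_threshold(by_correction = TRUE)` divides $q^*$ by $\sum_{i=1}^N 1/i$,
the correction valid under arbitrary dependence; the default is the
uncorrected rule, which is what the thresholded maps here use.

Two implementation notes. First, the per-voxel null is computed in a
compiled kernel that phase-randomizes in the frequency domain and
evaluates the correlations through Parseval's identity — algebraically
identical to inverting the FFT and correlating in time, but an order of
magnitude faster; a test verifies the kernel against a literal
surrogate-then-correlate loop written in R. Second, the kernel draws from
its own seeded mt19937-64 stream, so null samples are bit-reproducible
given the seed and independent of R's RNG state; phases are independent
per voxel, per subject, and per replicate (the null is strictly
voxel-wise).

## Stimulus construction

`gen_segmentation` builds a strictly nested three-level segmentation.
Durations at each level are drawn from a gamma distribution matched to the
requested mean and sd (defaults 1.29 ± 0.12 s measures, 6.32 ± 1.91 s
phrases, 38.28 ± 12.46 s sections over a 255 s stimulus) and rescaled to
tile the total exactly. The segment count at each level is fixed at
`round(total / mean)` — 198 measures, 40 phrases, 7 sections at the
defaults — and coarser boundaries are snapped to the nearest finer-level
boundary, so nesting holds by construction and the level counts are
deterministic rather than a by-product of greedy grouping. This was a
deliberate choice: with purely greedy grouping the section count would
fluctuate between 6 and 8 across seeds, and the generator is supposed to
emulate a fixed, hand-segmented score.

Scrambling permutes the segments of one level under the constraint that no
segment is immediately followed by its natural successor — sampled by
seeded rejection, which is exactly uniform over the admissible set (a test
enumerates the sets for $n \le 7$ by brute force and checks both
membership and uniformity). Reassembly overlap-adds 10 ms linear
crossfades whose up/down ramps sum to one, so a constant signal passes a
joint unchanged and each joint shortens the output by exactly one
crossfade. Overlapping (rather than inserting) the fades was chosen
because it removes clicks without adding material; an equal-power fade is
a one-line variant the linear ramp deliberately keeps simple. Dynamic
range compression — applied to the scrambled conditions, whose abrupt
loudness contrasts it softens — is a feed-forward peak compressor: an
instant-rise, release-decay peak detector drives the static law
$\mathrm{out}_{dB} = T + (\mathrm{in}_{dB} - T)/\rho$ above the threshold
$T = -20$ dBFS with ratio $\rho = 4$, and the gain is smoothed with 10 ms
attack / 100 ms release time constants. On a steady tone the output
follows the static law to within a fraction of a dB, which is the
analytically checkable property the tests use.

## The synthetic cohort

No imaging data are distributed with the analysis this package
re-implements, so everything downstream is validated against a simulated
cohort with known answers. The generator assumes exactly the response
model the TRW logic presupposes: a voxel with ground-truth level $L$
produces, under condition $c$,

$$ y = \alpha\, z + \sigma\, \varepsilon, $$

where $z$ is a smooth latent time course *shared across subjects* when
$\mathrm{coherence}(c) \ge L$ and subject-specific otherwise, and
$\varepsilon$ is white subject noise. Latents are Gaussian-filtered white
noise (3 s FWHM in time, so the high-pass filter and HRF leave usable
signal), optionally convolved with a canonical double-gamma HRF (response
peak 5 s, undershoot 15 s, peak:undershoot 6:1), and standardized.

Defaults mirror the emulated study design: 15 runs per condition, TR
1.5 s, 3 s of silence before a 255 s stimulus (172 volumes per run, 157
after cropping), five conditions ordered backward < measure < phrase <
section < intact, and a 12×12×12 grid of 3 mm voxels whose ground truth
tiles the x axis in six slabs (the five levels plus "none"), emulating a
temporo-parietal axis. The stimulus-locked amplitude relative to noise has
no canonical reference value; $\alpha/\sigma = 1$ was fixed
once as a mid-range value at which recovery is achievable but not trivial,
and it is the condition under which the calibration claims below are
stated.

What the generator does *not* emulate: anatomy, physiological noise and
motion artifacts, spatial autocorrelation of noise, and any nonlinear
coupling between timescales. Passing tests therefore demonstrate that the
statistical machinery recovers the model's own ground truth at realistic
sizes — not that real cortex behaves like the model.

## Preprocessing

`preprocess_run` applies, in fixed order: per-voxel linear detrending and
a zero-phase (forward-backward) second-order Butterworth high-pass at
0.01 Hz; volume-wise separable Gaussian smoothing specified by FWHM in mm
(σ = FWHM/2.355, converted per axis to voxel units, nearest-edge padding);
and cropping of the first 15 volumes. Only the cutoff frequency is
constrained by the design; the Butterworth family is this package's
choice, exposed in the config. Filtering
precedes cropping so that filter warm-up falls in the cropped region.

Numerical points worth knowing. The zero-phase filter uses odd-reflection
padding with steady-state initial conditions (the conventions of the
widely used `filtfilt` implementations); the pad length
scales with the filter time constant (~`6/W` samples at normalized cutoff
`W`), because the 9-sample default inherited from short filters leaves
visible edge transients at a 0.01 Hz cutoff. Zero-phase IIR filtering is
*not* exactly idempotent: components near the cutoff see gains strictly
between 0 and 1, so a second pass moves them again at the percent level,
and edge samples carry a boundary transient. The tests assert repetition
stability in the interior and exact fixed points for fully removed
components, which is what the filter actually guarantees.

The TRW-recovery runs in `analysis/` and in the acceptance tests disable
spatial smoothing. The ground-truth layout changes label every two voxels
along x while a 6 mm kernel has σ ≈ 0.85 voxels; smoothing therefore leaks
shared signal across truth-region boundaries and the recovery score would
measure the synthetic layout, not the classifier. Smoothing itself is
verified separately (impulse response at half maximum, mass preservation,
offset equivariance).

## TRW classification and scoring

`classify_trw` labels each voxel with the lowest-coherence condition whose
FDR mask is significant there, `"none"` if no condition is. The "shortest
significant" rule is applied literally even to non-nested patterns —
significant at measure and section but not phrase — and such voxels get an
explicit nesting-violation flag rather than being silently recolored into
a nested pattern.
`score_against_truth` reports exact-label accuracy, adjacent-label
accuracy (within one step in the ordering backward … intact, none), and
the full confusion matrix. On the default cohort the dominant error mode
is a voxel acquiring a spurious significance at one lower condition
(permutation p floor 1/501 against an FDR threshold of a few times that),
which relabels it one or more steps down the hierarchy.

## ROI analyses

The early-auditory ROI (A1+) is defined operationally as the `k = 50`
voxels whose cohort-average time course correlates best with the stimulus
audio envelope. The envelope is computed by band-passing 4–4000 Hz
(zero-phase Butterworth: 2nd-order high-pass cascaded with 4th-order
low-pass), taking the magnitude of the analytic signal, and decimating to
the BOLD rate through a cascade of 30-tap FIR anti-aliasing low-pass
stages (each stage factor ≤ 13; kernels renormalized to unit DC gain
because the installed `fir1` does not scale). Top-`k` selection is used instead of a
correlation cutoff, which would need an arbitrary threshold; and
the envelope is HRF-convolved before correlation by default, because
without lag compensation the comparison is physiologically misaligned —
`hrf = FALSE` disables it.

Axis ROIs project every voxel of a significance mask orthogonally onto a
start→end line and cut the projection range into equal-length bins — an
algorithmic counterpart of manually partitioning the reliable extent into
adjacent sub-regions of approximately equal size. Per-ROI profiles
average the time course over ROI voxels within subject *before*
correlating (stabler than averaging voxelwise correlations at small ROI
sizes), and annotate each
scrambled condition with a one-tailed paired t-test against intact.

## Problem sizes and calibration claims

The shipped test suite and acceptance checks use the study-scale defaults
wherever the quantity is cheap (172 volumes, 157 after crop, 5000
surrogates for the null-centering check) and the following sizes for the
expensive simulations: TRW recovery on the full 12³ grid, 15 subjects, 500
permutations per voxel per condition; FDR control over 20 independent
global-null cohorts of 500 voxels at 500 permutations. At these sizes the
pipeline recovers exact labels for ≥ 85% of voxels (≥ 95% within one
hierarchy step), detects the exact significance pattern for ≥ 90% of
signal voxels, and keeps the realized false-positive fraction under the
global null at or below 0.08 on average. These are calibration statements
about the generator's conditions, recomputed on every test run, not
imported results.

## Known limitations

- The generator's sharing model is binary (a condition either carries a
  voxel's timescale or not); real responses degrade gradually with
  scrambling, so graded profiles arise here only from mixing voxels
  within an ROI.
- The phase-randomization null assumes second-order stationarity per
  voxel; slow nonstationarities would widen the true null.
- `R` averages as few as `N - #undefined` subject correlations when
  degenerate series occur; with small cohorts this changes the effective
  null, which the per-voxel surrogates do track but summary comparisons
  across voxels do not.
- Registration, motion/slice-time correction, surface projection, and
  anatomical ROI lookup are out of scope; inputs are assumed aligned.
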