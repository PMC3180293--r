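---
title: "Methods: ROC-based premovement analysis of collicular spike trains"
author: "spikeroc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROC-based premovement analysis of collicular spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeroc)
```

## The scientific setting

Rats performing a two-alternative spatial discrimination task hold their nose
in a central port, wait through a randomized 400–800 ms foreperiod, and then
orient left or right toward a 100-ms visual, auditory, or combined
audiovisual cue. Reaction time (RT) is the interval from cue onset to nose
withdrawal. Audiovisual cues yield reliably faster reactions than either
unisensory cue. Extracellular recordings from one hemisphere of the superior
colliculus (SC) during this task show neurons whose firing in the last
100 ms before withdrawal — the *premovement* epoch — is direction-selective
and co-varies trial-by-trial with RT.

`spikeroc` implements the full analysis chain for such recordings, plus a
synthetic-session generator with known ground truth, so every statistic in
the chain can be validated end-to-end. Because the original recordings are
not publicly deposited, all validation here is against simulated sessions
whose behavioral parameters are set to the published summary statistics.

## The generative model

`generate_behavior()` draws a session trial table. Catch trials (16.7%,
requiring a 1000-ms hold) are Bernoulli; cued trials draw modality
equiprobably from {V, A, AV} and side from {left, right}. RTs follow a
**shifted log-normal** law (shift 100 ms) parameterized directly by the
target mean and SD per modality; the defaults are the published means/SDs
(V 386.3±98.7, A 394.9±101.6, AV 322.4±86.5 ms). The shifted log-normal was
chosen because it is strictly positive, right-skewed like empirical RT
distributions, and exactly mean/SD-matchable in closed form. False-hit
errors occur at a configurable rate (default 0.15, matching the ~81%
published success rate once catch trials are counted); after an error the
next scheduled non-catch trial repeats the same stimulus and is flagged as a
correction trial. Correction repeats never displace catch draws, so the
catch fraction stays exactly Bernoulli.

Features of real data the generator deliberately does **not** emulate:
express responses (the published 6.2% of trials with RT < 150 ms arise from
anticipatory behavior our RT law does not produce — the 150-ms filter is
still applied everywhere), session-to-session drift, bursting/refractory
spike statistics (trains are exactly Poisson), and electrode drift. Passing
tests therefore demonstrate correctness of the statistics under the stated
model, not robustness to every property of in vivo data.

Each synthetic neuron (`neuron_params()`) contributes an inhomogeneous
Poisson rate per trial:

* a constant baseline (default 10 sp/s);
* Gaussian sensory bumps after cue onset (per-modality amplitude, latency,
  width; under AV both bumps are present, each scaled by `av_sensory_gain`);
* a linear premovement ramp from `premove_onset_ms` (default −150 ms) to
  withdrawal, decaying back over 100 ms, with signed amplitude

  `gain(direction) × (premove_amp + beta × (RT − median RT)) × (av_factor if AV)`

The summed rate is clamped at zero and sampled by thinning against an
analytic upper bound, which is exact for inhomogeneous Poisson processes.
The RT coupling `beta` is the generative counterpart of the measured
RT–rate Pearson correlation; its sign determines the correlation's sign,
and the default magnitude in `typed_population()` (0.05 sp/s/ms) was chosen
so the measured |r| is ≈ 0.3 at 200 trials, the regime the classification
analysis targets. `av_modulation_factor` controls multisensory
enhancement (> 1) or depression (< 1) of the ramp independently of the
evoked bumps.

One interaction deserves emphasis: because AV trials are faster, a nonzero
`beta` feeds the RT difference back into the ramp amplitude. For a type-2
cell (`beta < 0`) this *mimics* AV enhancement, and can mask a generated
depression factor. Experiments that probe the MSI machinery therefore use
`beta = 0` populations, so the AV factor is the only multisensory influence
on the ramp.

## Spike detection front-end

`synthesize_wideband()` renders ground-truth trains as a 4-channel tetrode
trace at 25 kHz: Gaussian noise plus a biphasic 32-sample template
(trough at sample 10) with per-channel gains. `detect_spikes()` follows the
published front-end: 0.8–5 kHz zero-phase Butterworth band-pass (order 3,
applied forward and backward via `filtfilt`), RMS power in a 0.2-ms sliding
window, per-channel threshold at mean power + 5 SD of the power over time,
events merged within one waveform span and trough-aligned. The "SD of the
mean power" wording is ambiguous in the source; we read it as the SD over
time of the windowed RMS signal. Cluster quality uses the published gates:
refractory violations < 1% (window 1.5 ms by default — the period itself is
unstated upstream and configurable here) and isolation distance > 20, with
the isolation distance defined as the squared Mahalanobis distance of the
n-th closest non-cluster spike (n = cluster size) under the cluster's own
covariance, on the stated feature set (energy, peak, valley, first two
principal components per channel).

## Spike density functions and epochs

SDFs convolve spike times with a Gaussian kernel (σ = 15 ms; σ = 4 ms for
sensory analyses) on a 1-ms grid. The kernel is truncated at ±4σ with the
pedestal subtracted and the area renormalized, so it reaches zero
continuously at the cutoff; this keeps trapezoid integration of the gridded
SDF accurate to ~10⁻⁷ of a spike, which the normalization property test
exploits. Epoch rates (baseline [−100, 0) before cue; evoked [0, 100) after
cue; premovement [−100, 0) before withdrawal) are computed from raw counts
over half-open intervals — a spike exactly at cue onset belongs to the
evoked epoch. Trials entering any neural statistic are correct, non-catch,
non-correction, with RT ≥ 150 ms (so evoked activity cannot leak into the
premovement epoch); error analyses use false-hit errors with a minimum of
four trials.

## The scaled ROC index and its permutation test

`roc_index(a, b) = 2·AUC − 1 ∈ [−1, 1]` where AUC is the Mann–Whitney
probability that a draw from `a` exceeds a draw from `b`, ties counted ½.
The implementation is rank-based and is checked exhaustively against
brute-force pair counting for all multiset pairs of sizes ≤ 8 over a small
value grid. The index is computed as `(2U − n_a n_b)/(n_a n_b)` with a single
division so that swapping the groups flips the sign bit-exactly. Significance
comes from a label permutation test (500 repetitions by default) with the
add-one correction `p = (1 + #{|index*| ≥ |index|})/(n_perm + 1)`, two-sided
because both positive and negative preferences occur; the smallest
attainable p is 1/501. Time courses use 100-ms windows stepped by 20 ms,
fully contained in the grid, each window feeding the per-trial mean SDF into
the same test; the *direction preference index* contrasts contraversive vs
ipsiversive movement trials and the *premovement activity index* contrasts
the premovement epoch against baseline. The center of mass of significant
positive windows summarizes each unit's preference timing.

## Evoked responses

A response is present when the trial-mean σ = 4 SDF exceeds baseline mean
+ 2 baseline SDs for more than 15 ms (≥ 16 contiguous 1-ms samples, reading
"over 15 ms" strictly), starting within 0–100 ms after cue onset or offset.
Runs are clipped at the search-window start: a run whose kernel-smeared
flank crosses threshold a few ms before the window would otherwise be
rejected wholesale, which systematically misses strong responses. Two
estimators of the baseline SD of the mean trace are available: the SD
across baseline time points (`detect_evoked()` default) and the
across-trial standard error averaged over baseline time points
(`detect_evoked_sdf()`). Both estimate the same sampling SD; the across-time
version has only ~7 effective degrees of freedom once the 4-ms kernel
correlates neighboring samples, and its sampling error alone nearly doubles
the false-positive rate of the rule. The SEM version lands the rule at its
nominal ~5% per-condition false-positive level (measured 5.0% on
baseline-only units) and is what the classification pipeline uses. Cells
are visual or auditory if the rule fires on the respective unisensory
condition; multisensory if both fire, or if only the AV condition fires
(subthreshold summation — a cell evoked by one modality alone necessarily
also responds under AV, so AV-only detection is informative only in that
case). Mean evoked rates use 0–40 ms (auditory) and 50–100 ms (visual)
windows.

## Neuron typing and the multisensory modulation index

Per movement direction, each unit receives its premovement activity index
(with permutation p), and the Pearson correlation between premovement rate
and RT across trials. Units with permutation p ≥ 0.05 versus baseline are
unclassified; otherwise the quadrant of (index sign, r sign) gives types
1–4, and the *representative* flag additionally requires |index| > 0.1 and
|r| > 0.1 (both magnitudes: the published wording names both quantities).
Exact zeros of either quantity are unclassified (a measure-zero tie rule).

The MSI contrasts the premovement rate under AV with the mean of the
unisensory rates:

MSI = (AV − UNIave) / (AV + UNIave),  UNIave = (V + A)/2.

The exact normalization is shown only as an image in the source paper; this
bounded form matches the printed index magnitudes (≈ ±0.2) and the stated
enhancement/depression sign convention, and it is scale-invariant and
strictly increasing in AV — properties the tests pin down. This is the
package's key interpretive decision and the main caveat when comparing MSI
magnitudes against other normalizations (e.g. the classic percentage form
(AV − max(V, A))/max(V, A), which is unbounded).

## Behavioral statistics

Per-session modality mean RTs feed a repeated-measures one-way ANOVA
(sessions as blocks; with one observation per cell the blocked two-way
`aov` yields the classical repeated-measures F) with Tukey HSD post hoc
contrasts. Fully degenerate input (zero variance) reports F = 0 rather than
0/0. Muscimol-injection sessions are compared to control by within-animal
paired t-tests per modality and injection side, Bonferroni-corrected over
the default family of 6 (3 modalities × 2 sides; the family size is
configurable because the published family is unstated). The per-animal
facilitation test compares AV trial RTs against the *faster* unisensory
modality (smaller mean) with a one-sided two-sample t-test, matching the
claim direction of the inactivation experiments.

## Problem sizes and numerical choices

Validation experiments use: 200 neural-filtered trials per direction
(trimmed from larger generated sessions so attrition from catch, error and
correction trials never changes the analyzed count); 40 units (10 per type)
for type recovery; 20 units per group at 200 trials per direction × modality
cell for MSI sign recovery; 1000 replicates for permutation and ANOVA null
calibration; 100 replicates for ANOVA power; and a 50-s, 500-spike trace at
SNR 10 for detection (500 spikes at the canonical 10 sp/s baseline).
Windows are half-open everywhere; the time base is milliseconds as doubles
on a single session clock; all randomness flows from one master seed through
`derive_seed()` so that every unit, trial and test has its own reproducible
stream.

## Known limitations

* Poisson spiking understates the dispersion of bursty SC neurons; the
  permutation machinery is rank-based and robust to this, but absolute
  index magnitudes on real data will differ.
* The ramp + bump rate model is a deliberately minimal account of
  premovement dynamics; it is the validation scaffold, not a scientific
  claim about SC computation.
* Premovement ramps bleed into the post-cue analysis windows on short-RT
  trials and can register as evoked responses in sensorimotor cells — a
  real phenomenon in this preparation. The sensory classifier is therefore
  validated on ramp-free populations, and sensory/premovement mixtures are
  expected to inflate evoked-detection rates on mixed units.
* The MSI normalization is an inference from printed magnitudes (see
  above); all MSI values are interpretable relative to this definition.
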