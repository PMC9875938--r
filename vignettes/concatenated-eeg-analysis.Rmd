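---
title: "A concatenated decomposition–decoding analysis of simulated Simon Go/Nogo EEG"
author: "simonEEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A concatenated decomposition–decoding analysis of simulated Simon Go/Nogo EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package does

`simonEEG` implements, end to end, an analysis chain used to study how the
response-selection mode (automatic vs. controlled, operationalised as
stimulus–response congruency in a Simon-type Go/Nogo task) shapes the neural
representations underlying response inhibition:

1. **Task and EEG simulation** with known ground truth (`generateTrialTable`,
   `simulateBehaviour`, `simulateEpochs`);
2. **Pre-processing**: zero-phase band-pass, resampling, automated artifact
   rejection, spherical-spline current source density (CSD), baseline
   correction (`preprocessChain`);
3. **Residue iteration decomposition (RIDE)** of single trials into a
   stimulus-locked S cluster and a latency-variable C cluster
   (`rideDecompose`);
4. **Group spatial ICA** with subject back-reconstruction and rank-1
   back-projection (`fitGroupICA`, `backReconstruct`, `backprojectIC`);
5. **Cross-condition component matching** by topography correlation
   (`matchComponents`);
6. **Time-resolved and temporal-generalization MVPA** with group-level
   Wilcoxon-versus-chance statistics and cluster-based sign-flip permutation
   correction (`decodePair`, `groupClusterTest`);
7. **Standardized minimum-norm (sLORETA) source contrasts** on a simulated
   lead field with max-statistic nonparametric correction
   (`sloretaLocalize`, `snpmContrast`);
8. **Behavioural inference** with paired *t* tests, the within-subject
   effect size `dz = t / sqrt(n)`, and an exact/approximate Wilcoxon
   signed-rank fallback (`pairedT`, `wilcoxonSignedRank`).

`runPipeline` ties all stages together for a simulated cohort. Because no
recorded EEG accompanies the design, every claim the package makes is
validated on synthetic data whose generating process is known exactly; this
vignette states what those validations do and do not show.

## The task generator

The simulated task is a Simon-type Go/Nogo experiment: 720 trials, 70 % Go
(504) and 30 % Nogo (216), half congruent and half incongruent, in 6 blocks
of 120 with all four trial-type cells balanced within every block. A letter
("A" → left hand, "B" → right hand) appears left or right of fixation;
congruent trials present the letter on the side of the responding hand.
Responses are accepted up to 1700 ms; the inter-trial interval is jittered
between 1300 and 1700 ms.

Behaviour follows standard conflict-task phenomenology:

* Correct-Go RT is log-normal (right-skewed, positive support; draws beyond
  the deadline become misses), mean 539 ms congruent vs. 550 ms incongruent,
  trial-level SD 110 ms. The means match the behavioural regime the design
  targets; the SD is a typical single-trial RT dispersion.
* Nogo false alarms are Bernoulli with rates 6.1 % (congruent) vs. 4.7 %
  (incongruent), so that expected Nogo accuracies are 93.9 % and 95.3 % —
  congruent Nogo trials, where the prepotent response is stronger, fail
  inhibition more often.

## The EEG generator and its regime

Each trial is the sum of two spatially fixed sources plus noise:

* an **S source** (stimulus-locked): a Gabor-like biphasic wave (Gaussian
  envelope SD 60 ms on a 4 Hz carrier) at a fixed 180 ms latency with a
  fronto-central unit-norm topography;
* a **C source** (latency-variable): the same waveform family with a
  centro-parietal topography whose per-trial peak latency is
  `450 ms ± 50 ms`, correlated `r = 0.8` with that trial's RT (trials
  without an RT draw a surrogate RT from the same log-normal family, so Go
  and Nogo latency distributions match);
* spatially smooth 1/f-like background (AR(1) with pole 0.97 through eight
  smooth spatial basis maps, SD 4 µV) plus white sensor noise (SD 2 µV).

Per-condition amplitudes default to S 32/32 µV and C 22/26 µV
(congruent/incongruent), i.e. a modest C-amplitude congruency effect in the
300–600 ms range where the C source lives.

**Why this signal-to-noise regime.** The amplitude-to-noise ratio was fixed
once so that single-trial C-latency estimation is *informative*: at a
substantially lower ratio, even an oracle matched filter given the true
template and the true S waveform recovers latencies barely above chance —
no algorithm can be validated in a regime where the estimand is not
identifiable. The
absolute scale (tens of µV against a ~3 µV background) was then chosen so
that the fixed rejection thresholds (±100 µV, 0.5 µV flatline) operate as
intended. This favours recoverability over realism: real single-trial EEG
is noisier, and recovery correlations reported by the package's tests are
upper bounds on what real data would allow, not estimates of it.

What the generator deliberately omits: ocular and muscle artifacts (hence no
ICA-based artifact correction stage), volume-conducted source mixtures
beyond two sources, inter-subject topography variability, and any
trial-history or learning effects.

## Pre-processing

The chain order is fixed — filter → resample → reject → CSD → baseline —
and each stage records itself, so calling a stage after a later one is an
error rather than a silent reordering. Defaults: 0.5–40 Hz zero-phase
Butterworth (order 4 per pass, applied forward–backward), Fourier-domain
resampling (spectrum truncation at the new Nyquist — exact for band-limited
content on the finite epoch), rejection at ±100 µV amplitude or < 0.5 µV
peak-to-peak within any sliding 100 ms window (the printed "V" thresholds
are read as µV), spherical-spline surface Laplacian (stiffness m = 4,
regularisation λ = 1e−5, 50 Legendre terms — canonical CSD settings), and a
−300–0 ms baseline. The epoch time axis is half-open: sample *k* lies at
`tmin + k/srate`, so a 4 s epoch at 256 Hz has exactly 1024 samples.

## RIDE: model, algorithm, and the choices that matter

The RIDE model writes each trial as
`x_i(t) = S(t) + C(t − τ_i) + noise`, with one latency `τ_i` per trial
shared across channels. No response-locked (R) cluster is estimated: in a
Go/Nogo design the withheld-response trials carry no response marker.
Waveforms are extracted as medians over trials (robust to amplitude
outliers — a property the tests verify against a mean-based variant) and
tapered by cosine-edged (Tukey, 10 % ramps) windows: S in −200–600 ms,
C in 150–800 ms, which is also the latency search window.

The estimation alternates three ingredients until the median **and** mean
absolute latency change are within one sample (at least 3, at most 20
iterations):

1. an **inner S/C alternation** (up to 30 passes, relative change < 1e−5)
   that decomposes S and C to self-consistency for the current latencies —
   a single pass leaves part of the average C inside S, and that residue
   biases the subsequent latency matching;
2. **latency re-estimation by template matching**: the C template is
   cross-covaried, summed over channels, with `trial − average + expected
   smeared C`. Subtracting the stimulus-locked *average* (rather than the
   estimated S) cancels the S content exactly, and adding back the
   latency-distribution-smeared template removes a self-subtraction dip
   that would otherwise be imprinted identically on every trial's score
   function and trap the iteration in poor fixed points;
3. a **trust region** of 100 ms per iteration on each trial's latency move
   (configurable, `maxStepMs`): once the template sharpens, occasional
   low-signal trials would otherwise jump to distant spurious score peaks,
   which degrades Pearson recovery badly even when most trials are right.

Initial latencies come from a Woody-style first pass matching
`trial − average + template` against the C-windowed grand average. Ties in
any argmax break toward the smallest absolute shift. A decomposition whose
C energy vanishes (pure stimulus-locked data) returns early with a zero C
waveform and the convergence flag set.

On full-size synthetic data (216 trials × 60 channels × 256 Hz, latency
jitter SD 50 ms, default SNR) the acceptance script and test suite verify
latency recovery above r = 0.8 and S-waveform recovery above r = 0.9 at the
peak channel; the values the script reports for its seed are considerably
higher.
The S/C split inside the window overlap is only weakly identified — the
self-consistency test therefore checks the reconstructed single-trial model
(which is stable) alongside the individual waveforms (which agree more
loosely).

## Group ICA, back-reconstruction, and matching

Subjects share a montage, so group ICA concatenates all subjects' samples in
channel space, performs one group PCA to `nComponents` (default 20)
dimensions, and unmixes with FastICA (tanh contrast; deflation first, then
symmetric decorrelation; 5 restarts). Each subject must individually retain
at least `varThreshold` of its variance in the group subspace, otherwise
fitting stops — the subject would not be represented by the group model. On
near-Gaussian data the fixed-point iteration has no stable contrast optimum;
the symmetric estimate after the iteration cap is then accepted as a
deterministic (seed-fixed) rotation of that subspace, which is exactly the
behaviour wanted for EEG background dimensions.

Component scale and sign are fixed by storing unit-norm topographies with
the maximal-|loading| channel positive; the spatial filters carry the
compensating factors, so `unmixing %*% mixing` is the identity on the
retained subspace, back-projections are invariant to the normalisation,
and the sum of all rank-1 back-projections equals the PCA-subspace
projection of the input.

Matching across condition models correlates topographies over channels and
uses `|r|` (ICA polarity is arbitrary) with threshold 0.85 and at most three
components per condition per cluster; every component serves once as a
template seed, reported pairs are reciprocal best matches, and a component
appears in at most one pair (largest `|r|` wins, then the lowest index —
overlap resolution across seeds is this package's choice). On 60-channel
random topographies the probability of `|r| ≥ 0.85` is far below 1e−6 per
comparison, and the tests confirm zero false pairs over 1000 replicate
model pairs while planted correlations of 0.90 and 0.97 are recovered
exactly.

**ICA retention threshold in the pipeline.** On real EEG, 20 components
retain ≈ 98 % of the variance because scalp data are spatially very smooth.
The synthetic background is deliberately simpler (eight smooth basis maps +
white sensor noise), and the CSD stage amplifies the spatially white part,
flattening the eigenspectrum: 20 of 60 channels retain ≈ 87 % here. The
pipeline therefore defaults to `icaVarThreshold = 0.8` while
`fitGroupICA`'s own default stays 0.98 — the parameter describes the data
regime, not the method.

## MVPA and cluster inference

Decoding is binary (congruent vs. incongruent), per subject and matched
component pair, on channel amplitudes (60 features on the standard montage)
within 0–1000 ms. Classes are balanced by undersampling; five-fold
cross-validation is repeated twice; features are z-scored per time point
with training-fold statistics; the classifier is a linear SVM (cost 1 — the
only kernel defensible with tens of features and low trial counts), scored
by AUC computed from decision values via the rank formula; for temporal
generalization the model trained at one time is applied at every other.

Two structural choices deserve emphasis:

* **One common projector per pair.** Back-projecting each condition through
  its own model's rank-1 component puts the two classes on two *different*
  lines in channel space; any linear classifier then separates them
  perfectly regardless of any condition effect (empirically AUC ≈ 1 under a
  null generator). The pipeline instead projects both conditions onto the
  2-D span of the matched pair's topographies (`projectPair`), restoring a
  calibrated null. `backprojectIC` remains available and tested for
  single-model uses.
* **One RIDE fit per subject.** Decomposing each congruency separately
  gives each class its own S/C waveform split; that class-constant offset
  is indistinguishable from a real condition effect for the classifier and
  inflates null AUC to ≈ 0.77 with spurious significant clusters. The
  pipeline fits RIDE once on the pooled arm trials (latencies stay
  per-trial) and splits the single-trial clusters by congruency afterwards.
* **Split-half model fitting vs. decoding.** The condition-specific ICA
  models chase their own condition's sample noise; because every subject's
  trials sit in that fit, the matched-pair projection would carry a
  cohort-shared condition artifact (observed as reproducibly significant
  null clusters at chance-level mean AUC). The pipeline therefore fits the
  group models and the matching on each subject's odd trials and decodes
  (and localizes) only the even trials. With held-out trials the two
  classes are conditionally exchangeable given the projector, relabelling
  maps AUC to 1 − AUC, and the sign-flip group test is exact again.

Group inference: point-wise one-sided Wilcoxon signed-rank versus AUC = 0.5
(tie-corrected normal approximation; exact enumeration below 12 subjects),
cluster forming at point-wise p < 0.05, cluster mass = sum of signed-rank z,
and a max-cluster-mass null from 1000 random per-subject sign flips;
cluster p = (1 + #{null ≥ observed})/(1 + N). Clusters are contiguous runs
in 1-D and 4-connected components in the temporal-generalization matrix.
Under the null the familywise error rate is verified to sit in
[0.03, 0.07] at α = 0.05 over 500 replicates.

## Source localization

The lead field is simulated: 100 sources on interior shells of the montage
sphere with radially oriented dipoles in a homogeneous conductor (or,
alternatively, smooth random gain fields), average-referenced. The inverse
is a Tikhonov-regularised minimum norm on the average-reference subspace
(α defaults to 1 % of the mean gain-Gram trace) standardized per source by
its resolution variance: `power_i = (T x)_i² / (T K)_ii`. This
standardization is what restores **zero localization error** for noiseless
single sources — verified exhaustively over every source and both
geometries — whereas the plain minimum norm demonstrably mislocalizes deep
sources on the same inputs. Fixed scalar orientations keep the
standardization a scalar division; power is untransformed (no log).
Condition contrasts are paired t statistics per source with a max-|t|
sign-flip null (familywise-calibrated in [0.03, 0.07] under the null), fed
with per-subject standardized power averaged over the window where decoding
was significant. No realistic head model, anatomical template or region
labelling is attempted: only the localization machinery is validated.

## Behavioural statistics

`pairedT` reports `dz = t/√n`, the convention under which published paired
(t, n, d) triplets like (1.107, 39, 0.18) and (−2.86, 39, −0.46) are
mutually consistent — both are reproduced to two decimals by the tests.
The signed-rank test drops zero differences, enumerates the exact null for
up to 12 nonzero differences (e.g. three positive differences give one-sided
p = 1/8 = 0.125), and otherwise uses the tie-corrected normal z, which the
tests check against `stats::wilcox.test`.

## Problem sizes and reproducibility

Validation runs use reduced sizes chosen to keep the full suite affordable
while leaving each check statistically meaningful: full-size RIDE recovery
(216 × 60 × 256 Hz) runs once; calibration studies use 500 replicates with
1000 permutations (the max-statistic contrast is specified at 2000
permutations for real analyses; its calibration here uses 1000 — the
familywise error of a permutation test does not depend on the permutation
count beyond Monte-Carlo resolution); pipeline cohorts use 6–12 subjects at
32 channels and 128 Hz with 120–160 trials. Every stochastic step draws
from one seeded generator per call and stage seeds derive from a single
master seed, so identical configurations give byte-identical reports; the
package swaps its RNG state in and out, leaving the caller's stream
untouched.

## Known limitations

* The generator's SNR regime is favourable by design (see above); recovery
  statistics do not transfer to real recordings.
* Latency estimation assumes one latency per trial shared across channels;
  channel-specific latencies would break the template-matching model.
* The S/C split is not identified inside the window overlap; only
  latency-dependent quantities and full reconstructions are stable.
* FastICA components of near-Gaussian subspaces are deterministic rotations,
  not meaningful sources; matching and decoding must not over-interpret
  them (the matching threshold makes accidental pairs vanishingly rare).
* The lead field is geometric, not biophysical; localization results
  validate the sLORETA property, not anatomical claims.
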