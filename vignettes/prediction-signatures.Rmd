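---
title: "Detecting condition-specific prediction signatures in ERPs"
author: "erpsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-specific prediction signatures in ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpsig)
```

## The analysis problem

An observer who knows what is about to happen — a hand about to grasp a
ball, a ball about to roll into a resting hand, or nothing at all — shows
anticipatory EEG activity over sensorimotor cortex in the final moments
before the event. The question this package addresses is whether those
anticipatory signals are *condition-specific*: does the brain produce a
distinguishable signature for each predicted event class?

The unit of analysis is one subject and one four-electrode set. After
preprocessing, the subject contributes 12 averaged waveforms (4 electrodes
× 3 conditions) per set. The inferential logic is deliberately
hierarchical:

1. **Averaging.** For each electrode and condition, average the surviving
   epochs of the 500 ms pre-event analysis window. Averaging suppresses
   non-phase-locked background activity by a factor of roughly $\sqrt{n}$.
2. **Clustering.** Partition the 12 averaged waveforms into $k = 3$
   clusters (labelled A, B, C) by k-means under squared Euclidean distance.
   If the region truly distinguishes the conditions, waveforms should
   cluster by condition; if two conditions are indistinguishable there,
   their waveforms should mix.
3. **Exact testing.** For each pair of conditions, cross-classify the
   involved 8 waveforms by condition and cluster label and test the null
   hypothesis that *cluster label is independent of condition* with an
   exact test (all margins fixed; the p-value is the total probability of
   tables no more probable than the observed one). With row sums of 4 the
   table space is tiny and enumeration is exact — no asymptotics.
4. **Multiplicity control.** Benjamini–Hochberg step-up adjustment over the
   family of pairwise tests; rejection means the two conditions are
   distinguishable in that electrode set.

Group results are reported as counts of rejecting subjects per condition
pair, hemisphere relative to the viewed hand, and hand (dominant or
nondominant) shown in the block — negative-control (temporal) sets are
always analyzed alongside the sensorimotor sets.

## Preprocessing model and parameters

| Parameter | Default | Why |
|---|---|---|
| band-pass | 0.3–30 Hz, zero phase, Butterworth order 4 | standard slow-potential ERP band; zero-phase (forward–backward) so component latencies are not shifted |
| reference | mean of the two auricular channels | removes the common recording reference |
| analysis window | 2500–3000 ms after trial onset, half-open | the anticipatory interval immediately before the predicted event |
| decimation | keep every 2nd sample (500 → 250 Hz, L = 125) | the 30 Hz low-pass leaves no energy near the new Nyquist; matches the 125-point waveform convention |
| artifact threshold | ±50 µV on Fp2/FpZ/Fp1, strict inequality | ocular artifacts project maximally to frontal sites; boundary values survive |
| k, restarts | 3 clusters, 200 k-means++ restarts | with 12 points, 200 seeded restarts reach the enumerable global optimum in practice |
| α | 0.05 | conventional; configurable |

Artifact rejection is deliberately deterministic (threshold only). A
visual-inspection step cannot be reproduced; the generic
`exclude_epochs()` hook accepts externally determined exclusions (e.g.
EMG-detected movements) instead.

The threshold is interpreted in microvolts. A ±50 mV threshold would be
three orders of magnitude above physiological EEG and could never
trigger; ±50 µV on frontal channels is the standard blink criterion.

## The clustering stage in detail

Waveforms enter clustering exactly as averaged — no standardisation,
smoothing or feature extraction — because amplitude differences between
conditions are the signal of interest. Distance is squared Euclidean on
the raw L-dimensional vectors.

k-means is run as best-of-200 restarts with k-means++ seeding. Two
numerical conventions make the solution reproducible:

* among restarts with equal inertia (relative tolerance $10^{-9}$) the
  lexicographically smallest canonical assignment wins;
* cluster letters are assigned in order of first appearance, so the labels
  carry no information — downstream inference depends only on the
  partition (this invariance is asserted in the tests).

Internally the 12 waveforms are first rotated onto the orthonormal basis
of their own span (via SVD). This is an isometry, so partitions and
inertia are mathematically unchanged, but each k-means iteration then
works in at most 12 dimensions instead of 125.

Degenerate inputs are flagged rather than rejected: if fewer distinct
waveforms than $k$ exist (e.g. a noiseless control set), every distinct
waveform forms its own cluster, inertia is 0, and `degenerate = TRUE` is
recorded. A single-label solution then produces one-column contingency
tables, for which the exact test correctly returns $p = 1$.

`brute_force_partition()` enumerates all $3^{11}$ label assignments (first
label fixed by symmetry) and is the independent optimality oracle for the
restarted k-means in the test suite.

## The exact test and the multiplicity family

For a 2 × c table with fixed margins the probability of a table is
multivariate hypergeometric; the two-sided p-value sums the probabilities
of all tables whose probability is at most that of the observed table
(relative tie tolerance $10^{-12}$). Columns empty among the 8 involved
waveforms are pruned first, so a 2 × 3 design may reduce to 2 × 2 or
2 × 1; a 2 × 1 table is evidence-free and yields $p = 1$.

The smallest attainable p-value with row sums (4, 4) is
$2/\binom{8}{4} = 2/70 \approx 0.02857$, reached only by a perfect
condition-aligned split. This discreteness has a structural consequence
for the multiplicity family. If the BH family pooled all 12 tests of a
subject (3 pairs × 4 sets), then with temporal control sets behaving as
nulls the smallest possible adjusted value is
$0.02857 \times 12/6 = 0.0571 > 0.05$: *no rejection would ever be
possible*. The default family is therefore the three pairwise tests of
one electrode set (`bh_family = "per_set"`), under which a set whose
three pairs split perfectly attains adjusted p = 0.02857, and at least
two perfect pairs are needed for any rejection. The pooled alternative
(`"per_subject"`) remains available for sensitivity analyses.

A further consequence: the pipeline is conservative. Under a true null,
rejection requires at least two chance-perfect splits, so the empirical
type-I error sits well below α (the Monte-Carlo acceptance check asserts
the one-sided bound rate ≤ α plus a 99% Monte-Carlo margin; observed
rates are a few per mille).

## The synthetic ERP generator

Because the recordings behind the original design are not publicly
available, every stage is validated against a generator with known ground
truth. The generator emulates the design constants of the experiment: 500
Hz sampling, three conditions × 60 trials of 3 s, a 1 s inter-trial gap,
event-locked components confined to the 2500–3000 ms window, a montage of
two 4-electrode sensorimotor sets, two temporal control sets, two
auricular references and three frontal artifact channels.

Condition templates (microvolt scale, zero outside the window):

* *hand movement*: linear ramp 0 → −10 µV — a readiness-potential-like
  anticipatory negativity;
* *ball movement*: one biphasic sine cycle peaking at 10 µV — a
  deliberately different, equally energetic shape for the tactile-event
  prediction;
* *no movement*: flat.

Background noise is AR(1) with coefficient 0.95 and marginal sd 10 µV per
scalp channel — low-frequency-dominated like resting EEG, at an amplitude
in the usual band-limited range. The 10 µV template amplitude is at the
upper end of reported slow anticipatory potentials; together with n = 60
epochs it puts the per-waveform averaged noise well below the template
contrast, which is what the strong rejection counts of the original
control group imply about its data. Reference channels receive noise
scaled by 0.2: auricular electrodes sit off the scalp and carry far less
background EEG, and modeling them as scalp-noisy would let re-referencing
inject a shared per-condition offset (half a channel's noise power) that
spuriously aligns clusters with conditions in every set — a generator
artifact, not a property of the analysis.

Ground truth records, per set and condition pair, whether the effective
(gain-scaled, override-resolved) templates differ, plus the indices of
artifact-injected epochs. Per-set template overrides express lesion-like
scenarios, e.g. setting the ball-movement template flat in one hemisphere
reproduces the patient-group pattern in which the tactile contrast
vanishes contralaterally while the action contrast persists.

What the generator does *not* model: volume conduction and electrode
covariance (channels are independent), eye-blink morphology (artifacts are
single-sample excursions placed on the retained decimation grid so that
threshold rejection can be verified exactly), source geometry of the
128-channel net, and attention-catch trials. Passing tests therefore show
that the *pipeline logic* is correct under realistic amplitudes and
spectra, not that the original biological effect sizes are reproduced.

## Simulation sizes used by the tests

The acceptance checks use 1000 random contingency tables against the
enumeration oracles, 50 twelve-point instances (length 8) against the
brute-force partition oracle, 500 null subjects for the type-I error
bound, 9 control-like subjects for signature recovery and 6 patient-like
subjects for the blurring scenario. Unit tests run on a miniature design
(100 Hz, 6 epochs per condition, 1 s trials) that exercises identical code
paths.

## Known limitations

* The independence test treats the four electrodes of a set as independent
  observations; spatial correlation between neighbouring electrodes makes
  the test anticonservative in principle, though the discreteness-driven
  conservatism dominates in all simulated regimes.
* The per-set BH family is a design choice forced by the discreteness
  analysis above; the original family definition is ambiguous.
* Block structure (three blocks per viewed hand) is pooled into 60 epochs
  per condition per hand view; block-level drift is not modeled.
* No grand-averaging or between-group inference: the analysis is strictly
  per subject, and group tables are descriptive counts.
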