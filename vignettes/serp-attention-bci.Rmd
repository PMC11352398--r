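---
title: "Classifying selective tactile attention from somatosensory ERPs"
author: "serpBCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying selective tactile attention from somatosensory ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpBCI)
```

## The problem

After stroke, somatosensory deficits are common and sensory training
interventions typically deliver repeated tactile or electrical stimulation to
the paretic limb. A reactive brain--computer interface (BCI) can add a
top-down component to such training: while pulses are delivered alternately
to two forearm sites — dorsal ("D", over the radial nerve) and volar ("V",
over the median nerve) — the user covertly attends to one site and ignores
the other, and the BCI decides *which* site is being attended from the
stimulus-locked EEG alone, returning that decision as feedback. The neural
carrier is the somatosensory event-related potential (sERP): attention
enhances the amplitude of response components beyond roughly 150 ms after
stimulus onset, while early components are unaffected.

This package implements the complete pipeline of such a system — protocol
scheduling, preprocessing, feature screening, per-channel classification,
online trial simulation and reporting — together with a synthetic EEG
generator so every stage is testable without recordings.

## The protocol

Constants live in a `ProtocolConfig` object (`protocolConfig()`); defaults
encode the clinical protocol:

* EEG at 1200 Hz on six sites, generalized as Ci, CPi, Pi (ipsilesional
  central/centro-parietal/parietal), Cz, Cc (contralesional central) and
  Fp1 (ocular monitor).
* **Training phase**: 30 blocks, 15 per attention task (attend-D, AD, vs
  attend-V, AV), alternating. Each block delivers 30 pulses — 15 per
  location in randomized order — at a 700 ms inter-stimulus interval.
* **Test phase**: 20 online trials (10 per target, pseudo-randomized), each
  delivering stimuli until 10 artifact-free epochs per location are
  collected, within a budget of 30 stimuli.

Two timing constants coexist: onset-to-onset spacing is the 700 ms ISI,
while *scheduled duration* accounting uses a 750 ms per-stimulus period, so
a 30-stimulus block occupies 22.5 s and a 20--30 stimulus trial 15--22.5 s.
Both are config fields; which one governed true onset spacing in the
original hardware cannot be determined from the published timing, so the
package keeps the conventional roles above.

```{r}
cfg <- protocolConfig()
c(epoch = epochSamples(cfg), downsampled = nFeatureSamples(cfg),
  block_s = blockDuration(cfg))
```

## Signal processing

Recordings are band-pass filtered at 0.1--25 Hz with 4th-order Butterworth
sections, **causally** (forward-only): the online phase must be causal, and
using the identical filter in training keeps the train/test feature
distributions matched. Numerically the band-pass is realized as a cascade
of a 4th-order high-pass (0.1 Hz) and a 4th-order low-pass (25 Hz); a
direct 8-pole band-pass design at a 0.1 Hz corner and 1200 Hz sampling
places poles so close to the unit circle that the recursion diverges in
double precision, while the cascade is stable and meets the band edges
(50 Hz is attenuated by ~24 dB, 10 Hz passes within 0.01 dB).

Epochs span −100..600 ms around each pulse (840 samples), are
baseline-corrected by subtracting the mean of the 100 ms pre-stimulus
window, and rejected if any baseline-corrected sample exceeds ±50 µV on the
five somatosensory channels or ±80 µV on Fp1. Thresholds are applied to
baseline-corrected amplitudes — the conventional reading of drift detection
after DC removal. The first 5 s of every recording are stimulus-free by
construction, absorbing the causal filter transient.

Accepted training epochs form four condition clusters — ADSD, ADSV, AVSD,
AVSV (attended × stimulated) — and larger clusters are trimmed to the
smallest by dropping their chronologically last epochs. At the stated
design (15 blocks/task × 15 stimuli/location) each cluster holds 225 epochs
before rejection.

## Features and classifier

Each balanced cluster is partitioned chronologically into non-overlapping
groups of 10 epochs (remainder discarded); group averages are cropped to
the 600 ms post-stimulus window and decimated by stride 8 to 90 samples.
No extra anti-aliasing is applied before decimation: the 25 Hz low-pass
already band-limits far below the 75 Hz post-decimation Nyquist. Grouping
is consecutive and chronological so the resulting vectors stay independent
across groups, which leave-one-out cross-validation relies on.

For each channel and each of the 90 indices, a two-sided Wilcoxon rank-sum
test compares attended vs unattended sub-averages per stimulated location
(ADSD vs AVSD giving index set iD; AVSV vs ADSV giving iV) at α = 0.05,
deliberately without multiplicity correction — the raw per-index rule is
part of the method. Ties are midranked; for group sizes ≤ 8 the p-value is
an exact enumeration, otherwise a tie-corrected normal approximation with
continuity correction (exact size 0.049 at the ~21 sub-averages per
condition the protocol yields). If a location yields no significant index
the single minimum-p index is kept and the channel flagged, so the
classifier always receives a non-empty vector.

Feature vectors pair sub-averages by group index:
`[ADSD(iD), ADSV(iV)]` labelled AD and `[AVSD(iD), AVSV(iV)]` labelled AV.
Each of the five somatosensory channels gets its own RBF-kernel SVM with
kernel scale set by the median pairwise Euclidean distance heuristic
(parameter-free, computed once on the training vectors), regularization
constant 1, and no feature standardization (all amplitudes share µV
units). Channel performance is estimated by plain leave-one-out
cross-validation and the best channel (ties broken Ci > CPi > Pi > Cz >
Cc, ipsilesional first) becomes the online feedback source.

Two statistical properties of this procedure are worth knowing:

* **Null LOOCV is not centred on 0.5.** Because the screened indices are
  chosen on the same sub-averages the classifier is trained on, LOOCV
  accuracy is optimistically biased on data containing no effect (typically
  0.6--0.9 at this sample size); conversely, on label-permuted vectors
  *without* screening, LOOCV is pessimistically biased below chance (the
  held-out vector's class becomes the minority of the n−1 training set).
  Neither bias affects online accuracy, which is measured on fresh trials;
  the test suite checks null behaviour at the online stage and checks
  LOOCV for absence of *optimistic* bias under label permutation.
* The selection step inherits the same optimism, so the feedback channel's
  LOOCV estimate overstates its online accuracy; the online tally is the
  honest estimate.

## The online loop

A trial consumes epochs in delivery order, applying exactly the training
rejection rules, until 10 clean epochs per location are collected; the two
location averages are decimated, the stored indices extracted, and the
vector `[avgD(iD), avgV(iV)]` classified by all five channel models. Extra
stimuli beyond the balanced 20 are directed to the location(s) still
lacking clean epochs (alternating only if both lack), so an artifact-free
trial uses exactly 20 stimuli and each rejection costs one extra. If the
30-stimulus budget is exhausted first, the trial is aborted and excluded
from tallies — an accounting state the original report never reaches but a
simulator must define.

Per-channel accuracy is
$\mathrm{Acc} = 100\,(TP_{AD}+TP_{AV})/(TP_{AD}+TP_{AV}+FP_{AD}+FP_{AV})$,
and the information transfer rate uses the Wolpaw form with N = 2 targets
at the session's mean decision time (stimuli × 700 ms; 14 s for a clean
trial, giving 4.29 bits/min at perfect accuracy).

## The synthetic generator

`generateSession()` emulates the study conditions:

* **sERP templates** (`defaultTemplates()`): gamma-envelope sinusoids
  $A\,(t/\tau)\,e^{1-t/\tau}\sin(2\pi f t)$ peaking between 100 and 250 ms
  (D: A = 6 µV, f = 2.2 Hz, τ = 160 ms; V: A = 5.5 µV, f = 2.6 Hz,
  τ = 140 ms), with per-channel gains largest ipsilesionally
  (Ci 1.0, CPi 0.9, Pi 0.75, Cz 0.5, Cc 0.35, Fp1 0). Attention multiplies
  the 150--600 ms window by `attentionGain` (default 2) with a 20 ms
  raised-cosine ramp so no step discontinuity is introduced. The
  attended-vs-unattended amplitude ratio is not quantified in the
  underlying clinical data; the default gain is a simulator choice, not a
  claim about patients.
* **Background noise**: an AR(2) process (coefficients 1.0, −0.3; low-pass
  character so filtering acts realistically) with 5 µV stationary SD, a
  typical ongoing-EEG amplitude relative to the few-µV evoked response.
* **Artifacts**: Hann-shaped blinks on Fp1 (300 µV, 150 ms, 1.2/min) and
  signed drift excursions on a random somatosensory channel (150 µV,
  400 ms, 0.8/min). Amplitudes exceed the rejection thresholds by a wide
  margin, so injected artifacts are rejectable by construction; at these
  rates a session loses ~30 of 900 training epochs, matching the rejection
  counts reported clinically (33 ± 11). Ground truth records each
  artifact and every epoch whose window overlaps an artifact's
  above-threshold core.
* Overlapping responses sum linearly; with the 700 ms ISI a template never
  extends into the next epoch's window.

What the generator does **not** emulate: volume-conducted spatial
correlation between channels (noise is independent per channel), 1/f
spectra, habituation or fatigue drift over the session, SSSEP components,
and any realistic head-model projection of the sources. Passing tests on
synthetic sessions therefore validate the *pipeline mechanics and
statistical calibration*, not clinical effect sizes; the published
per-patient accuracies are not desk-reproducible and are represented by
the shipped cohort table instead.

Trial extension slots are assigned at generation time using the
generator's own artifact flags (padded by 0.3 s for filter ringing), so
the delivered stream is consistent with the online collection policy that
will consume it.

## Reporting

`summarizeCohort()` recomputes row-wise maxima over all channels and over
the two subsets (subset 1: Ci, CPi, Pi; subset 2: Cz, Cc) and summarizes
every column as median (Q1--Q3). The quartile convention is fixed to
`quantile(type = 2)` — the inverse empirical CDF with averaging at
discontinuities — because it is the convention that reproduces every
published summary cell of the shipped ten-patient table exactly; linear
interpolation (type 7) does not. `compareSubsets()` applies a two-sided
Wilcoxon signed-rank test to the paired subset maxima (zeros dropped,
midranks, exact convolution-based null for n ≤ 25 — exact even under
ties — normal approximation beyond).

`grandAverage()` averages accepted epochs per condition and channel and
estimates the divergence onset: the earliest post-stimulus time at which
attended and unattended waveforms for one stimulated location differ
beyond a criterion for ≥ 5 consecutive samples. The default criterion is
3× the baseline-period SD of the difference waveform; on noiseless
synthetic data the onset lands just past the 150 ms late-window edge
(the 20 ms taper delays the crossing slightly).

```{r}
s <- summarizeCohort(readCohortTable())
s$summary
compareSubsets(readCohortTable())$p.value
```

## Numerical and design choices

* Sample indices are 0-based in event tables; epochs are the half-open
  window `[onset − 120, onset + 720)` samples.
* Randomization uses a uniform shuffle of the balanced location multiset,
  with no run-length constraint, seedable end to end; a seeded session is
  bit-reproducible.
* The kernel-scale heuristic, regularization constant (1), sub-average
  grouping and condition pairing, fallback index rule, and the
  extension-stimulus policy are all underdetermined by the published
  description; the choices here are documented above and kept fixed.
* Degenerate inputs: empty condition clusters are a hard error; a
  rank-sum test on fully tied data returns p = 1; an all-zero difference
  vector gives a signed-rank p of 1; trials that exhaust their budget are
  logged and excluded from tallies.
* EDF output uses 16-bit quantization per one-second record; events stay
  in a sidecar TSV so sample indices remain lossless integers.

## Problem sizes used by the test-suite simulations

Unit tests run a scaled-down protocol (2 blocks/task of 12 stimuli, 4
trials needing 3 clean epochs per location) so each end-to-end run takes
about a second; calibration properties (screening type-I, parameter
recovery, laterality) run the full 30-block/20-trial protocol across 20 to
100 seeded sessions, the sizes at which the binomial bands being asserted
are meaningful.

## Limitations

Simulated accuracy under strong attention gain saturates at 100% and so
exercises the pipeline's ceiling, not the 70--100% range seen clinically;
intermediate gains produce intermediate accuracies but the mapping from
gain to accuracy is generator-specific. The per-channel noise independence
makes channel selection easier than on real EEG, where neighbouring
channels are strongly correlated. Real ocular artifacts are corrected by
thresholding only, as in the protocol — no ICA or regression cleaning is
attempted.
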