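---
title: "Predicting MoRFs by trisecting disordered sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MoRFs by trisecting disordered sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimorf)
```

## The problem

Molecular recognition features (MoRFs) are short regions — here 5 to 25
residues — inside intrinsically disordered proteins that fold upon binding
a structured partner. Identifying them computationally is a per-residue
binary classification problem: given a disordered protein sequence, assign
each residue a propensity of belonging to a MoRF.

A residue is classified from a window of its neighbourhood. Residues near
the sequence termini lack part of that neighbourhood, so a single model
must reconcile truncated and full-width windows. `trimorf` instead
*trisects* every sequence into two terminal zones (the first and last
`flank = 20` residues) and a middle zone, and trains a separate support
vector machine for each: a terminal model scores positions `j <= 20` or
`j > n - 20`, a middle model scores the rest. For sequences of length
`<= 40` the middle zone is empty and the terminal model scores everything.

## Features

Residue `j` of a length-`L` sequence is represented by the window
`[max(1, j - 20), min(L, j + 20)]` (width 41 in the interior, truncated at
the termini). For a window of length `l` and `u` selected structural
channels, the `l x u` slice of the per-residue structural trace is reduced
to a fixed-length descriptor by the lagged second moment

$$AC(k, j) = \frac{1}{l} \sum_{i=1}^{l-k} M_{i,j}\, M_{i+k,j},
\qquad k = 1, \dots, DF,\; j = 1, \dots, u,$$

flattened channel-major into a vector of length `DF * u` (`DF = 10` by
default). Two deliberate points:

* the divisor is `l`, not `l - k`, and the channel is **not** mean-centred
  — this is exactly the descriptor the method is defined with, although it
  differs from the textbook "auto-covariance";
* when `l <= k` the sum is empty and the lag is 0, so short windows still
  yield full-length vectors.

Structural channels come from a per-residue trace (3-state secondary
structure probabilities, ASA, backbone angles phi/psi/theta/tau,
half-sphere exposure counts, contact number), as produced by structural
predictors such as SPIDER2 — the package only reads such output (the
`spider2` reader is best-effort, since column sets vary between output
files; the mapping is documented in `?read_structural_table`). The default
configuration uses the single channel `HSEa_up` (the upper-sphere count of
HSE-alpha); "HSEu" is interpreted as HSE-alpha-up, the only reading
consistent with the channel's description. Forward selection over channels
is not automated: re-running the pipeline with a different
`feature_config(channels = ...)` and comparing AUC is the supported route.

## Training

For each maximal MoRF run, the run plus 20 residues of flank on each side
(clipped to the sequence) is one positive segment. Its zone is decided by
the run's residues: any terminal residue sends a copy to the terminal
pool, any middle residue a copy to the middle pool — a run straddling the
zone boundary therefore feeds both pools once, which keeps boundary signal
that a hard assignment would discard. For each positive segment a negative
segment of identical length is placed uniformly at random among positions
that share no residue with any MoRF run's *flanked extent* (not merely the
run), so positive and negative windows never overlap and labels cannot
leak; the placement must also touch the positive's zone so that both
pools see both classes of the same context. When no placement is feasible
(common in short sequences, where the flanked extent can cover most of
the sequence) the positive is kept alone and a warning is recorded —
class balance is therefore exact *up to* infeasible placements, and the
training manifest records the realized counts.

Each pool's descriptors are z-scored (the scaler is stored with the
model) and an RBF-kernel SVM is fit with `C = 1000`,
`gamma = 0.0038` — the settings the method was developed with, which
presuppose features on a controlled scale; that is why standardization is
built in rather than optional. Decision values are oriented so larger
means more MoRF-like, then min-max normalized to `[0, 1]` using the
training-set decision-value range (clipped outside it). Normalization
makes the two models' tracks, and external predictors' tracks,
commensurable for averaging; no probability calibration is applied since
every reported metric is rank-based.

## Score post-processing and fusion

A true MoRF residue sits inside a region of at least 5 high-scoring
residues, so each residue's score is replaced by

$$\mathrm{score}_j = \frac{\max(W_j) + \mathrm{median}(W_j)}{2},$$

where `W_j` is the score window of half-width `w` around `j` (truncated at
the termini; even windows take the mean of the two central order
statistics). The phrase "maximum plus median divided by two" is grouped as
`(max + median)/2`, not `max + median/2`: the former stays on the input
scale, which normalized tracks and their averages require — this is the
single most consequential reading choice in the package. Default
half-widths: 12 for the package's own track, 4 and 15 for
MoRFpred-plus- and MoRFchibi-style external tracks, 8 for the re-smoothing
of the combined track; PROMIS-style tracks default to no smoothing, since
no half-width is established for them. Fusion is the plain arithmetic
mean of the aligned tracks, optionally re-smoothed.

## Evaluation

Scores and labels are pooled across all evaluation sequences into one
global ROC curve (per-sequence AUCs are available as a diagnostic); the
AUC is the trapezoidal area over tie-grouped thresholds, which equals the
Mann–Whitney statistic with half credit for ties. `fpr_at_tpr()` reports
the smallest FPR among curve points whose TPR reaches the target — a
conservative, interpolation-free convention, so on a heavily tied curve it
returns the next attained curve point rather than an interpolated one.

## The synthetic generator

`simulate_dataset()` emulates the regime the method targets: sequences of
60–600 residues, exactly one MoRF of 5–25 residues per sequence, the MoRF
touching a terminal zone with probability 0.3 (roughly the terminal share
observed in curated MoRF benchmark sets). The signal channel (`HSEa_up`)
is Gaussian background (mean 10, sd 2 — plausible for upper-half-sphere
C-alpha counts) given residue-level autocorrelation by moving-average
smoothing (half-width 2, rescaled by the square root of the window so the
marginal sd stays at `background_sd`), plus a mean shift of
`effect_size * background_sd` inside the MoRF. The shift is added *after*
smoothing so the realized MoRF/background contrast equals the configured
effect size exactly; smoothing a pre-shifted channel would smear about
`1.2 x` shift out of each MoRF and silently bias the effect downward. All
other channels are label-independent plausible noise (normalized positive
triples for SS, bounded noise for ASA/angles/HSE/CN), so only the
configured channel is informative — which makes the channel-selection
narrative testable in miniature: models trained on SS channels alone
score measurably worse than models trained on `HSEa_up`.

What the generator does *not* emulate: the error structure of real
structural predictors (whose residuals correlate with local sequence
composition), amino-acid composition biases of disordered regions,
multi-MoRF sequences, and cross-channel correlations. Passing tests on
synthetic data therefore demonstrate that the pipeline's machinery —
segmentation, featurization, dispatch, smoothing, evaluation — is correct
and that it recovers a planted signal of realistic size; they do not
certify performance on real proteomes.

## Numerical and design choices

* Coordinates are 1-based inclusive in every file format and error
  message; `X` is accepted in sequences but structural channels must be
  numeric at every row.
* Descriptor flattening order is channel-major, lag-minor, fixed and
  documented; any consistent order works, but it must never vary between
  training and prediction.
* Middle-zone segments use the same descriptor as terminal ones by
  default; `feature_config()` is the seam for substituting an alternative
  middle-zone extractor.
* Degenerate inputs: single-residue sequences yield one truncated window
  with an all-zero descriptor; constant tracks are fixed points of the
  smoother; training aborts with a zone-naming error when a zone has no
  positive (or no negative) segments; a degenerate decision-value range
  aborts training rather than dividing by zero.
* Determinism: dataset generation, negative placement and SVM fitting are
  fully determined by the configured seeds; the caller's RNG stream is
  restored afterwards.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` train on 150–200 simulated
sequences and evaluate on 80–100 held-out ones (about 30k residues per
evaluation), averaging 3 seeds for signal-recovery checks and 5 for the
trisection-versus-pooled comparison — sizes at which the pooled AUC of
the default configuration is stable to about ±0.01 while the whole
acceptance run stays under a minute on one core.

## Known limitations

* The trisection benefit on synthetic data is real but small (of order
  0.01 AUC), because the generator's terminal and middle windows differ
  only through truncation; on real data the terminal signal differs in
  kind, not just in width.
* Scores of sequences shorter than 41 residues come from the terminal
  model alone; whether the original method consulted both models there is
  unknowable from its description, and the zone inequalities force the
  terminal-only choice.
* The `spider2` reader trusts column names; concatenations that rename
  columns need the native format instead.
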