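---
title: "Identifiability-filtered connectome predictive modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifiability-filtered connectome predictive modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connfinger)
```

This vignette is the package's own account of the model it implements, the
assumptions behind the synthetic cohorts it is tested on, and the numerical
and design choices made where more than one reasonable option existed.

## The model

### Functional connectomes and edges

A functional connectome over R regions is the symmetric R × R matrix of
Pearson correlations between regional BOLD time series, with unit diagonal.
All computation happens on the canonical edge vector: the row-major upper
triangle, E = R(R−1)/2 entries, in the order fixed by the parcellation's
region order. Every mask, group matrix and model in a workflow shares that
one order; mixing parcellations is an error, not a silent misalignment.

Two "sessions" per subject are surrogate test/retest data: one acquisition
split in half (contiguous halves, or interleaved frames when the split must
precede preprocessing — the interleaved outputs carry twice the repetition
time because their effective sampling interval doubles). Which half becomes
restA is a seeded per-subject coin flip, so no session systematically
contains the scan's first minutes. Subjects with more than 30% of frames
censored (strict inequality) are excluded; censored frames are deleted, not
interpolated, before correlating.

### Differential identifiability

With edge vectors stacked into an E × 2N group matrix (all restA columns,
then all restB), the identifiability matrix is
I(i, j) = cor(restA_i, restB_j): its diagonal holds within-subject
test/retest similarity, the off-diagonal between-subject similarity. The
cohort fingerprint statistic is

* I_self — mean of the N diagonal entries,
* I_others — mean of the N(N−1) off-diagonal entries,
* I_diff = 100 × (I_self − I_others).

The filtering step decomposes the group matrix by SVD, reconstructs all
columns from the first m components for each m in the sweep range, computes
I_diff at each m, and keeps the reconstruction at the smallest maximizing
m\*. Edge-level reliability before/after filtering is measured by the
Shrout–Fleiss ICC(2,1) (two-way random effects, absolute agreement, single
measure), computed edgewise from the N × 2 subject-by-session table:
(MSR − MSE) / (MSR + MSE + 2(MSC − MSE)/N). Negative ICC estimates are kept
as computed — clamping would distort the distributional comparison between
full-rank and optimal reconstructions — and zero-variance edges yield `NA`,
never 0.

### Why the sweep does not center the group matrix

Whether the group PCA should subtract per-edge means is a genuinely open
choice, and it changes the answer. After row-centering, the 2N columns of
an N-subject stack contain at most N − 1 independent subject-stable
directions (the N subject means, minus one for the removed grand mean), so
the I_diff sweep tops out when those N − 1 directions are in — at m = N − 1.
Decomposing the raw matrix keeps the grand connectivity pattern as the
dominant leading component, the subject-stable subspace has dimension
exactly N, and I_diff peaks at the cohort size for essentially every seeded
cohort we generate — a cohort-size phenomenon, stable across repetitions,
rather than a knife-edge spectral accident. That robustness is why
`sweepIdentifiability()` defaults to `center = FALSE`. `decomposeGroup()`
itself defaults to `center = TRUE`, the textbook convention, for use as a
general-purpose PCA (its explained-variance ratios then have the usual
meaning); `reconstructAt()` restores whatever means were removed, so
full-rank reconstruction reproduces the input to 1e−10 in both modes.
Two further conventions make results deterministic across linear-algebra
backends: each component's sign is fixed by making its largest-magnitude
loading positive, and sweep ties resolve to the smallest m. m = 1 is
excluded from the default sweep range because correlations between rank-1
reconstructions are degenerate.

### Connectome predictive modeling

Per outcome, training scores are z-scored with training-cohort mean and SD
(validation scores reuse the training parameters — the validation cohort
never informs the scale). Edge selection correlates each edge with the
outcome across training subjects; edges with r strictly above the threshold
(default 0.1, the conventional choice) form the positive mask, r strictly
below −0.1 the negative mask. Ties at the threshold are excluded (a
measure-zero event on real data); zero-variance edges belong to neither
mask. Mask strengths — the summed edge values per side — are the two
predictors of an ordinary least-squares model with intercept. An empty mask
side drops its predictor (recorded as `NA`) rather than failing, so long
cross-validation runs survive degenerate repetitions while flagging them;
only a model with both sides empty is an error.

Two session protocols coexist, matching how original and filtered
connectomes are best used. Full-rank connectomes: selection and fitting on
the restA/restB average, applied to averaged validation connectomes
(`--session-mode averaged`). Optimal connectomes: selection separately per
session, same-sign mask intersection, one fit per session, elementwise
coefficient averaging, and validation predictions averaged over the two
sessions (`--session-mode dual`). When restA = restB the two protocols
coincide exactly, which the tests assert.

### Evaluation harness

`runSplitHalfCV()` repeats, for each seeded half/half split of the cohort:
identifiability sweeps run independently on the training and validation
halves (they never share data, and each half gets its own m\*); z-scoring
to the training half; both pipeline modes; and the diagnostics —
Frobenius divergence between the restA and restB edge–outcome correlation
vectors, same-sign mask overlap (|same-sign intersection| / |union|,
undefined when both masks are empty), test/retest generalization (model
fit on restA evaluated on restA and restB), validation correlation, and
specificity (mean pairwise Frobenius/overlap across outcomes on restA
only). Failed repetitions are flagged rows, excluded from summaries,
never silently dropped. Per-repetition seeds derive from the master seed
by a counter scheme, so any single repetition is reproducible in
isolation.

Pipelines are compared by a paired sign-flip permutation test on the
per-repetition differences: the statistic is the paired t (a plain mean
difference is available), the same flips apply to all outcomes to preserve
their dependence, and each outcome's observed statistic is referred to the
permutation distribution of the maximum across outcomes, controlling the
family-wise error rate. The test is one-sided by default (the filtering is
hypothesized to help), two-sided on request. The observed arrangement
counts as one permutation, so p ≥ 1/n_perm and p = 0 is impossible;
significance uses p ≤ α, which makes the discrete test exact at attainable
levels — the suite verifies the 5% level empirically over 1000 null
datasets.

### Consensus masks and network enrichment

Edges selected in at least ⌈freq × n_reps⌉ repetitions (default freq 0.95;
at least one, so freq = 0 degenerates to the union) form per-outcome,
per-sign consensus masks. For each of the 45 unordered pairs of the nine
resting-state networks, a one-sided exact binomial test asks whether the
mask holds more edges of that pair than a uniform draw of the same size
from all E edges would: with t_P pair edges, background probability
p₀ = t_P/E and k of n mask edges observed, p = P(X ≥ k), X ~ Binomial(n, p₀).
The default α is 0.05 without correction across the 45 pairs — the test is
descriptive, enumerating which interactions are over-represented — and a
stricter α (e.g. 0.01) is a parameter for figure-grade reporting. Positive
and negative masks are tested separately. Export for BrainNet Viewer
writes `.node` files (coordinates, RSN color index, degree-based size,
label) and symmetric 0/1 `.edge` matrices, optionally restricted to
significant pairs.

## The synthetic cohort generator

The generator is first-class, tested code: every pipeline stage must be
exercisable with no data download. At the connectome level, the edge vector
of subject i, session s is

> baseline + group pattern × (wᵢ + ηᵢₛ) + fingerprintᵢ + noiseᵢₛ,

clipped to [−1, 1], where

* **baseline** — block structure over nine RSN blocks (0.25 within, 0.05
  between, small frozen jitter): realistic mean connectivity for the
  enrichment machinery to sit on;
* **group pattern** — one shared pattern (loading scale 0.1) whose
  expression wᵢ ~ N(1, 0.3) is subject-stable, with session fluctuation
  ηᵢₛ of SD 2 × sessionNoiseScale (a global-signal-like state effect);
* **fingerprintᵢ** — iid N(0, fingerprintScale) per edge, drawn once per
  subject and reused identically in both sessions; default scale 0.1
  (correlation units), the component identifiability is about;
* **noiseᵢₛ** — 40% spatially structured (40 shared patterns with
  per-session amplitudes, emulating motion/physiology/drift residuals,
  which is precisely the kind of noise a truncated reconstruction removes
  entirely while session averaging only halves it) and 60% independent per
  edge; total per-edge SD sessionNoiseScale, default 0.04.

Defaults (41 subjects, 100 regions) describe the study conditions the
package is built around; with them the sweep peaks at m\* = 41 for every
seed we have tried, and clipping touches well under 0.1% of edges (the
tests assert this). Outcomes are linear in the strengths of planted signed
edge masks (positive sets drawn from within-network edges, negative from
between-network edges), computed on the noise-free subject component so
the planted signal is session-stable, plus Gaussian noise scaled to the
noise-free outcome SD. Zero outcome noise therefore permits exact
coefficient recovery, which the acceptance suite checks to 1e−6.

A time-series mode generates regional signals as mixtures of nine latent
network signals (drawn per session, shared across subjects) through a
mixing matrix with a subject-specific perturbation reused across sessions;
connectomes computed from it are valid correlation matrices by
construction. It exists for tests that need positive semidefiniteness; the
faster edge-level mode does not enforce it, because the pipeline only ever
consumes edge vectors.

What the generator does **not** emulate: hemodynamics, realistic noise
spectra or autocorrelation, motion with its subject-stable component,
site/scanner effects, nonlinear edge–outcome coupling, or missing data.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative phenomena (fingerprint denoising, cohort-size optimum, mask
stability gains), not performance on any real cohort.

## Known limitations

* In this linear Gaussian edge model, truncating the group SVD at
  m\* ≈ N of 2N components retains roughly the m\*/2N share of isotropic
  session noise — about the same as plain restA/restB averaging — so the
  filtering's advantage rests on the structured noise share it removes
  outright and shows up most clearly in selection-level statistics
  (edge-selection stability, ICC, planted-edge recovery). The acceptance
  suite runs the directional comparison of the dual-session optimal
  pipeline against the averaged full-rank pipeline on validation
  correlation over 100 seeded cohorts; the selection-level gains
  reproduce robustly, while the validation-correlation gain is at the
  mercy of the intersect mask's recall loss and need not emerge under
  these generative assumptions — a structural caveat worth knowing before
  expecting it on data whose noise is closer to isotropic.
* The permutation test assumes exchangeable signs of per-repetition
  differences; repetitions of a split-half scheme share subjects, so the
  1000 repetitions are not independent samples and the test is calibrated
  for the null of no systematic difference, not for effect-size inference.
* ICC(2,1) is computed per edge independently; no spatial regularization.
* Enrichment treats edges as exchangeable within the full edge space; the
  background model knows nothing about distance or hemispheric structure.

## Problem sizes used by the test suite

The suite's simulations are sized for a single CPU: sweeps at N = 41,
R = 100 for the cohort-size optimum (three seeds in the unit suite, five
in the acceptance script), the 100-cohort directional comparison at
41/41 training/validation subjects over 60 regions, 1000 null datasets of
16 repetitions for permutation calibration, and 2000 random masks for
enrichment calibration. Larger cohorts change nothing structurally; they
only tighten the same comparisons.
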