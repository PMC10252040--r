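---
title: "Methods: sweat volatolomics discrimination with sweatvoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweat volatolomics discrimination with sweatvoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comprehensive two-dimensional gas chromatography–mass spectrometry
(GC×GC–MS) of sweat yields, after peak integration against a fixed
compound library, one vector of peak areas per measurement: here 761
*descriptors*, each a library compound, with area 0 when the compound is
not detected. `sweatvoc` implements the downstream statistics for a
paired pre/post-surgery discrimination design: the same subjects are
sampled before tumor-removing surgery ("pre", the sick state) and after
("post", the healthy state), on one or more body sites, with up to four
technical replicates (sorbent polymers) per sampling. The goal is
threefold: classify pre vs post status, attribute the classification to
individual descriptors, and decide which descriptors are *relevant* —
better than an uninformative feature — with a controlled risk.

The pipeline is, in order: natural-log transform, group-aware train/test
split, per-descriptor Mann–Whitney screening, standardization, PCA
visualization artifacts, SMOTE class rebalancing on the learning set,
L2-regularized logistic regression with an (C, N) grid search scored by
leave-one-group-out cross-validated weighted F1, holdout evaluation,
exact SHAP attribution, probe-variable relevance selection, and Jaccard
comparison of retained descriptor sets across datasets.

## Data model and invariants

A `voc_dataset` couples an n × 761 area matrix (columns in library
order) with per-measurement metadata (`subject_id`, `site`, `status`,
`batch`, `replicate`). The metadata vocabulary is closed; unknown tokens
are an error, because silently coerced labels would corrupt every group
comparison downstream. A `transform_state` tag (`raw` → `logged` →
`standardized`) makes the stage order machine-checked: logging a logged
dataset, or running PCA on an unstandardized one, fails.

All resampling is *group-aware*: the unit of splitting is the
(subject, status) sampling group, never the row, because technical
replicates of one sampling are near-duplicates and would leak across
folds. `evaluate_holdout` refuses train/test sets that share a group.

## Preprocessing

**Log transform.** Areas are mapped to `ln(1 + a)`. The `+1` offset is a
deliberate choice: absent descriptors (area 0) must stay 0 to preserve
the fixed-length vector model, and the transform must stay monotone.
Dropping zeros instead would destroy the vector alignment.

**Mann–Whitney screening.** Each descriptor is tested pre vs post with a
two-sided Mann–Whitney U test (two-sided is the conservative default; the
direction of a marker is not known in advance). P-values are exact —
computed from the full permutation distribution — when both groups have
at most 8 observations and there are no ties; otherwise the tie-corrected
normal approximation with continuity correction is used. The cutover at 8
keeps small-cohort results identical to exhaustive enumeration (the test
suite checks every no-tie instance with group sizes up to 4) while
remaining fast at cohort scale. Descriptors are ranked by ascending
p-value with library-order tie-breaks, so rankings are deterministic.
Significance screening (`p < 0.05`) is deliberately uncorrected for
multiplicity: it is a permissive pre-filter, and relevance control is the
probe-variable stage's job.

Ranking and scaler fitting always operate on an explicit row subset.
Inside cross-validation and holdout evaluation that subset is the
training rows only; ranking on all rows before splitting is possible but
leaks test information into descriptor selection and is not what the
pipeline does.

**Standardization.** Per-descriptor centering and scaling to unit
*population* variance, fitted on the learning rows and applied without
refitting to held-out rows. Descriptors constant on the fitting rows are
flagged and mapped to 0.

## Modeling

**SMOTE.** The learning set is class-imbalanced (more pre than post
samplings because some subjects have no post visit). Minority rows are
oversampled by convex interpolation toward one of the k = 5 nearest
minority neighbors, `x + u (x_nn − x)` with `u ~ U(0, 1)`, until classes
balance. Rebalancing happens after descriptor selection, in the reduced
feature space — nearest-neighbor geometry in the full 761-dimensional
sparse space is unstable — and only ever on learning rows; the returned
provenance flags make the no-synthetic-rows-in-validation invariant
auditable.

**Classifier.** L2-penalized logistic regression minimizing
`−loglik + (1/(2C)) ||w||²` with an unpenalized intercept, fitted via
ridge glmnet with `lambda = 1/(nC)` (same minimizer) at tolerance 1e−12,
so fits are deterministic. The test suite cross-checks coefficients
against an independent Newton solver. The positive (modelled) class is
`post`; sensitivity and specificity are reported for `pre` — the disease
state — as the positive label.

**Grid search.** `C` ranges over half-decade steps `1e−4 … 10` and `N`
(descriptor count) over `5 … 250` by default. Each cell is scored by
leave-one-group-out CV with all learning-set-only hygiene above and the
pooled held-out predictions' support-weighted F1 (per-class F1 defined as
0 when precision + recall = 0, the standard convention that keeps the
weighted sum total). Among equal-scoring cells the least complex model
wins — smallest N, then smallest C — and the selection is invariant to
grid enumeration order (cells are canonically sorted before comparison).
Per-fold rankings are computed once and shared across all grid cells.

## Attribution and relevance

**SHAP.** For a linear decision function the SHAP value of feature j on
row i is exactly `φ_ij = w_j (x_ij − mean_bg_j)`; attributions sum to
`f(x_i) − f(x̄)` (checked to 1e−10). Negative values push toward
pre-surgery, positive toward post-surgery. Descriptor importance is mean
|φ|, ranked with library-order tie-breaks.

**Probe variable.** A label-independent standard-normal probe column is
appended, the model refitted at the same C, SHAP importances recomputed
over N + 1 features, and the probe's rank recorded; over R realizations
this yields the probe-rank CDF `F(r)`. At risk δ the cutoff is
`r_δ = max{r : F(r) ≤ δ}` and the retained set is the descriptors whose
rank in the single probe-free reference fit is ≤ r_δ. Retained sets are
therefore nested across increasing δ by construction. Design choices
worth stating:

- The probe is population-standardized after drawing, matching the
  scaler's convention for real features, so its importance is on the same
  scale and — on standardized noise features — exactly exchangeable with
  them.
- The model *is* refitted with the probe each realization. A fixed model
  would give the probe weight 0 and rank N + 1 always, a degenerate CDF
  incompatible with probes occasionally out-ranking weak real features.
- Retained-set membership uses the probe-free reference ranks, not
  per-realization ranks, so the retained set is a deterministic function
  of the reference fit plus the estimated cutoff.
- One probe per realization.

A subtlety the test suite respects: under an exchangeable-noise null the
probe rank is *marginally* uniform. Conditional on one fixed noise
dataset the rank CDF carries an O(1/√N) bias from that dataset's realized
column importances, so the null-uniformity check pools realizations over
independent null datasets rather than conditioning on a single one.

**Jaccard comparison.** Retained sets from two analyses (body sites,
instrument batches) are compared by |A∩B| / |A∪B|, plus a curve of the
index over nested top-m prefixes of the two reference rankings. Two empty
sets compare as 1 with a warning.

## The synthetic cohort generator

The patient data behind this design are not publicly deposited, so the
generator produces cohorts with the statistical structure the analysis
assumes, making every stage testable end to end:

- **Zero-inflation:** presence is Bernoulli, abundance log-normal —
  the simplest mechanism reproducing both the occurrence-frequency
  histogram and the area-sum spread.
- **Occurrence profile:** per-descriptor probabilities follow a U-shaped
  Beta(0.25, 0.7): frequencies spread over [0, 1], both extremes
  over-represented (some compounds always present, some never). The law
  is deliberately asymmetric (mean ≈ 0.26): per-measurement non-zero
  counts of roughly 77–242 out of 761 descriptors imply a mean occurrence
  far below one half, so a symmetric U would be internally inconsistent
  with the count envelope.
- **Per-measurement richness:** presence probabilities are scaled
  `min(1, q s)` with s solved per sampling so the expected non-zero count
  hits a target drawn from a truncated normal centered mid-envelope
  (sd = width/6). The envelope's endpoints are treated as observed
  min/max of a cohort — roughly ±3 sd tails — not as uniform bounds;
  uniform targets would inject a large label-independent richness factor
  that chance-correlates with class in small cohorts.
- **Replicates:** abundances are drawn at sampling level with
  replicate-level log-scale noise (sd 0.25 by default; within-subject
  replicate correlation is not quantified in the source data, so this is
  an exposed knob, not an asserted value). Presence is drawn per
  replicate: each replicate is a separate injection, and detection near
  the limit is stochastic per chromatogram.
- **Planted effect:** a configurable descriptor subset carries the
  pre/post signal — a log-scale abundance shift of random per-descriptor
  sign (both directions occur in real attributions) and an occurrence
  shift of the *same* sign (a marker elevated pre-surgery is also
  detected more often). The study-sized cohort pair plants markers only
  among descriptors whose scaled occurrence sits in [0.35, 0.9] at both
  sites: a biomarker must be detectable but unsaturated to be
  discoverable.
- **Batch confound:** the GC column replacement is modeled as a global
  multiplicative log-scale shift plus per-descriptor jitter, strong
  enough to dominate the leading principal components when enabled —
  which is why the pipeline analyzes batches separately by default and
  only pools them on explicit request.
- **Scale:** per-measurement area sums spread over about two orders of
  magnitude via a shared log-uniform factor.

`make_study_cohort_pair()` assembles two linked cohorts at the study's
sample-size envelope (hand 21 subjects pre / 13 post, breast 20/12, 3–4
technical replicates, site-specific count envelopes 77–242 and 82–348)
with a configurable overlap between the two planted marker sets. The
default effect — a 2.5 natural-log abundance shift (≈ 12-fold) plus a
0.25 occurrence shift — is what this package treats as a *strong* marker
signal.

What the generator does **not** emulate: retention times, spectra, and
chromatogram structure; subject-level covariates (age, diet,
medication); descriptor–descriptor correlation beyond the shared
richness and scale factors; drift within a batch. Passing tests on
synthetic cohorts therefore demonstrate the statistical machinery under
the assumed data model, not clinical validity on real sweat data.

## Numerical choices and degenerate inputs

- Mann–Whitney with every value tied (e.g. a never-observed descriptor)
  has a zero-variance rank sum; its p-value is defined as 1.
- `select_significant` may legitimately return an empty set (warned).
- Constant descriptors standardize to 0 and are flagged.
- SMOTE with a single-row minority class errors (no neighbor exists);
  with fewer than k + 1 minority rows, k is reduced with a warning.
- glmnet requires two columns; single-descriptor fits are padded with a
  constant zero column whose coefficient is discarded.
- `probe_relevance` requires R ≥ 100 (a coarser CDF cannot resolve a 5%
  risk) and errors on an empty feature set.
- Jaccard of two empty sets is 1, with a warning.
- All stochastic stages (generator, fold assignment, SMOTE draws, probe
  realizations) derive from explicit seeds; a pipeline rerun with the
  same inputs and config reproduces every number bit-identically.

## Problem sizes used for verification

The package's own checks run at desk scale, chosen once: probe-rank
analyses use R between 400 and 2000 realizations (the reference
procedure's 100,000 remains the default for production runs);
null-calibration and power properties use 100–500-descriptor cohorts
with 10–30 subjects over 10 seeds; holdout-performance checks use the
full 761-descriptor study-sized pair over 10 seeds with a fixed
(C = 0.1, N = 80). At these sizes a strong-signal cohort yields median
holdout weighted F1 above 0.9 with sensitivity 1 and a null cohort stays
within the chance band — the same magnitudes the underlying study design
reports.

## Known limitations

- Relevance selection conditions on one reference ranking; rank
  instability across probe realizations is summarized only through the
  probe's own rank distribution.
- The probe method controls the risk of accepting a feature ranked below
  an uninformative probe; it is not an FDR guarantee over the retained
  set.
- Specificity is structurally the weaker metric in this design: the
  minority (post) class has fewer subjects, and selection-plus-rebalance
  biases calibrate the boundary toward the majority class. The holdout
  metrics make this visible rather than correcting it.
- With heavy class imbalance *within a fold's training split*, folds can
  degenerate to a single class; such folds are skipped with a recorded
  warning rather than silently scored.
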