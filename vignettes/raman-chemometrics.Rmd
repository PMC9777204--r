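---
title: "Chemometric classification of serum Raman spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometric classification of serum Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanclass)
```

## The analysis problem

Serum Raman spectra are intensity read-outs over Raman shift
(wavenumber, cm^-1) whose band intensities scale with the
concentrations of the biomolecules in the sample. Disease alters that
composition, so a disease signature appears as a pattern of relative
band-intensity changes. The package implements a complete workflow for
a case/control (and serology-subgroup) classification study on such
spectra:

1. **Pre-processing** — cut to the biological fingerprint region,
   rubber-band baseline correction, vector normalisation;
2. **Classification** — PCA-LDA and PLS-DA;
3. **Marker discovery** — cluster-vector analysis of the PCA model,
   peak ranking, per-peak ANOVA;
4. **Validation** — Monte Carlo cross-validation with
   accuracy/sensitivity/specificity;
5. **Synthetic cohorts** — a generator that emulates the replicate
   structure and class effects the analysis assumes, so the whole
   pipeline is testable without instrument data;
6. **Clinical-audit statistics** — ELIA/CLIFT anti-dsDNA cascade
   summaries, diagnostic 2x2 metrics and nonparametric group tests.

## Pre-processing

**Fingerprint cut.** Biofluid information concentrates in
900–1800 cm^-1; the cut is a closed interval on the stored (always
ascending) axis. Default window 900–1800, configurable via
`preprocess_config()`.

**Rubber-band baseline.** Fluorescence produces a broad additive
background. The rubber band is the lower convex-hull envelope of the
(wavenumber, intensity) points, linearly interpolated between hull
vertices, computed with a monotone-chain lower hull (no iterative
windowing). Consequences used as test invariants: the baseline never
exceeds the spectrum; the corrected spectrum is nonnegative and zero
at hull vertices (including both endpoints); adding any affine
function of wavenumber leaves the corrected spectrum unchanged; and
the envelope equals the chord oracle
`min over chords (j <= i <= k)` of the interpolated chord value — the
greatest convex minorant.

**Vector normalisation.** Each corrected spectrum is scaled to unit
Euclidean norm over the cut region, leaving only relative intensities.
An important, often overlooked consequence: an effect that *raises*
total intensity must, after normalisation, *lower* the relative
intensity everywhere else, in proportion to the mean spectrum. The
synthetic generator was designed with this in mind (below).

**Order of steps.** Cut → baseline → normalise by default. Cutting
first keeps the hull from anchoring on regions that are discarded
anyway; `preprocess_config(baseline_before_cut = TRUE)` gives the
other order for sensitivity analyses.

## Classifiers

**PCA-LDA.** PCA is the mean-centred thin SVD; loadings are
orthonormal rows, explained variance comes from the squared singular
values, and loading signs are fixed (largest-magnitude element
positive) purely for determinism. LDA operates in the truncated score
space: per-class mean score vectors, the pooled within-class
covariance `S = sum_k sum_i (x - xbar_k)(x - xbar_k)' / (n - K)`, and
priors (training proportions by default; a `uniform` switch exists
because study reports rarely state the convention). A spectrum is
scored per class by the squared Mahalanobis distance to the class
centroid plus `-2 log(prior)` and assigned to the arg-min. The
quadratic score is invariant under any invertible linear
re-parameterisation of the score space applied consistently to
scores, means and covariance, and reduces to nearest-centroid
assignment under equal priors and spherical covariance — both are
property tests. A separate `lda_projection()` provides the 1-D (or
K-1-dimensional) canonical discriminant axes used for score plots,
box plots and ANOVA/MANOVA on scores; classification and plotting are
deliberately distinct code paths because they answer different
questions.

**PLS-DA.** Classes are indicator-coded (a single 0/1 column for two
classes, one column per class otherwise), X and Y are mean-centred,
and a NIPALS latent-variable regression yields the regression matrix
`b = W (P'W)^{-1} Q'`; prediction is `yhat = X b` on centred data with
the intercept restored. The decision rule is `yhat >= 0.5` for the
positive class in the binary case (a response of exactly 0.5 goes to
the positive class, with a warning) and arg-max across columns for
multiclass. With as many latent variables as the rank of the centred
training matrix, PLS regression coincides with ordinary least squares;
that closed-form identity is the independent oracle for the NIPALS
code. Component counts are fixed by configuration (10 PCs; 6 LVs
two-class, 8 LVs four-group — the models this package is built to
reproduce); no automatic selection is performed.

**Tie-breaking.** All arg-min/arg-max ties resolve to the first class
in the declared class order and emit a warning; determinism beats
silent arbitrariness.

## Marker discovery

The cluster vector of class *k* is
`sum_{j in triplet} median(score_j | class k) * loading_j`,
a loadings-like spectrum through the class cluster median in the
3-PC subspace whose projection best separates the classes. The
triplet is chosen by exhaustive search over all 3-combinations of the
leading PCs, scored by the Fisher criterion
`trace(Sw^-1 Sb)` of the 3-D projection (deterministic;
lexicographically first on ties). The disease-minus-control contrast
of cluster vectors is the ranking signal: its local extrema, ordered
by absolute magnitude and greedily thinned to a minimum pairwise
separation (default 10 cm^-1, so one broad band cannot occupy several
of the reported slots), are the candidate marker wavenumbers. The
per-class median weighting follows the cluster-vector literature; the
contrast direction (disease minus control) is this package's choice of
how to reduce per-class vectors to a single ranked spectrum.

`peak_stats()` then tests each reported wavenumber (nearest axis
point) with a one-way ANOVA across classes and reports the direction
of the disease-minus-control mean difference. P-values are unadjusted
by default, matching how such per-peak significance is conventionally
reported; a `p_adjust` argument exposes `p.adjust` methods for readers
who want the multiplicity handled.

## Monte Carlo cross-validation

Each iteration draws a stratified random hold-out (default 20% per
class, minimum one spectrum per class), fits the classifier on the
remainder, predicts the hold-out and accumulates the K x K confusion
table. Stratification is not optional: with a 37-spectrum class, an
unstratified 20% draw would regularly lose a class from the test (or
training) side. Accuracy is the table trace over the total (micro
accuracy); sensitivity and specificity are per-class one-vs-rest, with
unweighted class means reported for multiclass runs; zero-denominator
ratios are `NA`, never silently 0. Reported metrics are means over
iterations, alongside the mean confusion table.

`split_level = "spectrum"` (default) reproduces the classical
procedure in which replicate spectra of one subject can straddle the
split. With 17–20 replicates per subject this is *optimistically
biased* — the model has seen near-copies of every test spectrum — so
`split_level = "subject"` is provided, holding out whole subjects; it
is the honest generalisation estimate for new patients and is used in
this package's own null-effect tests. Neither level is asserted to be
"correct"; they estimate different things.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions for the rest of the package.

**Design.** `default_two_class()` builds 4 control subjects x 20
replicates (80 spectra) and 8 disease subjects with
20, 20, 18, 19, 20, 20, 20, 17 replicates (154 spectra; 234 total).
The three sub-20 counts are fixed at 17/18/19 so the serology
subgroups total 40/37/77; only the group totals and the minimum of 17
are externally constrained, so the per-patient split is a stated
default, not an estimate. `default_four_group()` relabels the same
design as healthy controls plus three serology subgroups.

**Spectral model.** Each clean spectrum is a fixed library of ~35
Gaussian serum bands (strong bands at 1002, 1452, 1655 cm^-1) plus a
very broad underlying protein envelope (center 1400 cm^-1, SD
230 cm^-1) — real serum fingerprints do not fall to zero between
bands — on top of a decaying fluorescence background. Noise has three
components, each with a stated default:

* `subject_sd = 0.01`: between-subject SD of each band's relative
  amplitude. Deliberately below the class effect: the reference
  regime this generator emulates is one where every subject's spectra
  cluster tightly by class (that is what makes near-perfect
  spectrum-level CV possible at all).
* `replicate_sd = 0.02`: additive per-point noise, in units of the
  strongest band.
* `gain_sd = 0.05`: log-normal whole-spectrum replicate gain
  (removed, by design, by vector normalisation).

**Class effect.** Twelve discriminatory bands (1002, 1070, 1113,
1155, 1286, 1346, 1408, 1452, 1527, 1596, 1639, 1727 cm^-1) shift in
the disease class by an absolute band intensity of
3 x `replicate_sd` — eleven up, 1155 cm^-1 down — applied as the
equivalent relative band-amplitude multiplier. The broad envelope is
simultaneously reduced by the small fraction that makes the effect
norm-neutral over the fingerprint window: disease *redistributes*
relative intensity at constant total scattering. This matters because
vector normalisation turns any net intensity gain into a diffuse
relative decrease proportional to the mean spectrum; without the
envelope compensation that decrease concentrates at the strongest
uninvolved bands and produces spurious "markers" that outrank the
genuine ones. Because the compensation rides on a featureless
envelope, it adds no sharp extrema of its own. The four-group cohort
adds smaller (2 x `replicate_sd`) modulations of two
non-discriminatory bands per subgroup on top of the shared disease
effect, so subgroup separation is genuinely harder than
disease-vs-control.

**What the generator does *not* emulate.** Shot-noise physics, cosmic
rays, detector response, wavenumber miscalibration, and — most
importantly — realistic between-subject biological heterogeneity.
Passing tests on these cohorts demonstrates that the *pipeline*
recovers what was planted under the stated conditions; it is not
evidence about the difficulty of any real cohort.

**Audit generator.** `generate_audit()` draws per-request ELIA titres
from truncated log-normal mixtures (negatives below the 10 IU/mL
threshold; positives in three clusters: low, 100–170, and >379
IU/mL), applies the reflex cascade (CLIFT only on ELIA positives),
and assigns diagnoses with stratum-specific rates. Marginal rates
hold in expectation, not exactly, per draw.

## Numerical choices and degenerate inputs

* Axis handling: descending instrument axes are flipped on read;
  duplicate wavenumbers are a hard error (silent averaging hides
  acquisition faults); non-numeric cells are reported by row/column.
* PCA refuses constant matrices and `n_pcs > min(n-1, p)`; PCA-LDA
  refuses single-spectrum classes and (near-)singular pooled
  covariances (`rcond < 1e-12`), advising fewer PCs.
* PLS-DA checks the rank of the centred training matrix up front via
  QR and stops NIPALS if a component's score variance collapses.
* The rubber-band hull uses exact arithmetic on the input points; the
  corrected spectrum is guaranteed nonnegative only to ~1e-12 because
  of interpolation round-off.
* The all-tied Kruskal–Wallis case (every titre equal) is defined as
  H = 0, p = 1 rather than the 0/0 the tie-correction formula gives.
* Mann–Whitney uses the exact two-sided distribution when both groups
  have at most 8 values and no ties force the approximation;
  otherwise the tie-corrected normal approximation.
* Percentages in audit reports are rounded half-up to integers (as
  printed summaries conventionally are); full precision is retained
  in the returned objects.

## Problem sizes used by the test-suite and acceptance script

The packaged test-suite runs Monte Carlo CV at 200 iterations on the
234-spectrum cohorts and at 20–50 iterations on smaller 36–60
spectrum cohorts for property checks; `scripts/acceptance.R` runs the
full 1000 iterations for the two-class models and 200 for the
four-group model. These sizes were chosen so the whole suite
completes in about half a minute while leaving the Monte Carlo means
stable to well under a percentage point.

## Known limitations

* Spectrum-level CV on replicate-heavy designs is optimistic; use
  subject-level splits for honest generalisation claims.
* The cluster-vector contrast is defined for one disease class versus
  one control class; multi-class discovery requires choosing the pair.
* The audit module's Table-3-style diagnostic metrics depend on the
  diagnosis-set convention (overlap syndromes in or out); both are
  implemented, neither is asserted as the convention of any external
  report, and no attempt is made to reproduce any specific published
  audit's exact values, which would require the underlying records.
* Model serialisation is R-native (`saveRDS` by the user if desired);
  no cross-language container is provided.
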