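---
title: "Modelling versus training surrogate multigene risk scores"
author: "surrosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling versus training surrogate multigene risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrosig)
```

## The problem

Commercial multigene assays — Prosigna (ROR risk-of-recurrence family),
Oncotype DX (Recurrence Score, RS) and MammaPrint (gene70 binary risk) —
stratify early ER+ breast cancer for chemotherapy decisions, but they often
disagree at the individual-patient level. Studying that disagreement at
cohort scale would require running every commercial assay on every sample,
which is cost-prohibitive. `surrosig` implements two surrogate strategies
for computing assay-style scores from a single NanoString-style expression
panel:

* **Signature-like** (modelling): apply the published algorithm of each
  assay directly, after one global normalization of the cohort, with no
  reference to real test results.
* **Signature-trained** (training): split the cohort 50:50, calibrate each
  surrogate against true assay results on the training half, freeze the
  fitted parameters, and validate on the held-out half.

Because no suitable public cohort carries both panel expression and all
three commercial results, the package ships a synthetic cohort generator
with known ("hidden") generative parameters, so that calibration,
parameter recovery and concordance can be evaluated end to end.

## The scoring engines

**Prosigna/ROR.** For each sample: (1) log2 ratio of each gene to the
geometric mean of the 8 housekeeping genes; (2) per-gene row-scaling
$(x_g - c_g)/s_g$ with assay-specific centering/scaling factors $c, s$;
(3) Pearson correlation $r_k$ of the row-scaled 46-gene profile with each
of four intrinsic-subtype centroids (LumA, LumB, HER2-enriched, Basal);
(4) proliferation score $p$ = mean of 18 proliferation genes;
(5) the linear combinations

$$\mathrm{ROR} = \textstyle\sum_k w_k r_k,\qquad
  \mathrm{ROR\!-\!P} = \mathrm{ROR} + w_p\, p,\qquad
  \mathrm{ROR\!-\!PT} = \mathrm{ROR\!-\!P} + w_t\, \mathbf 1[\text{size} > 2\,\mathrm{cm}],$$

followed by an affine map onto 0–100 with truncation. The vendor's
reference-sample normalization step is omitted (the reference material is
not available outside the kit), and the row-scaling and final-rescale
constants are treated as unknowns to be estimated — exactly the quantities
the training stage fits.

**Oncotype DX.** Metagene scores are weighted within-group averages of
housekeeping-normalized values — proliferation (5 genes), HER2
(0.9·GRB7 + 0.1·ERBB2), ER ((0.8·ESR1 + 1.2·PGR + BCL2 + SCUBE2)/4),
invasion (2 genes) — plus the CD68, GSTM1 and BAG1 singletons. The
unscaled RS is the published weighted sum (proliferation +1.04, HER2
+0.47, ER −0.34, invasion +0.10, CD68 +0.05, GSTM1 −0.08, BAG1 −0.07),
affinely mapped to 0–100 and truncated. Two data-handling rules are on by
default and switchable: GSTM1 (bimodal, with about half of samples below
background) is thresholded at its background level, and Cathepsin-L2
(CTSV; consistently below background) is excluded, leaving MMP11 as the
invasion group.

**MammaPrint.** The gene70 index is the Pearson correlation of a sample's
70-gene profile with the good-prognosis template; samples at or above the
correlation cutoff are low risk.

Risk categories use 40/60 cuts for ROR-PT and 18/25 for RS. The printed
ranges ("0–40, 40–60, >60") are ambiguous exactly at the cuts; the package
fixes low = [0,40), intermediate = [40,60], high = (60,100] (RS
analogously, so that 25 is not-high, matching the use of 25 as the
intermediate/high cut), defined once in `classifyRisk()` and used
everywhere. The binary scheme collapses low with intermediate; for
Prosigna, whose binary grouping is not standardised, the same
{low+intermediate} vs high collapse at 60 is used.

## Training (the calibrated surrogates)

**Prosigna-trained.** The untrained initialization takes each gene's
centering factor as its training-set mean and its scaling factor as its
training-set SD (floored at 1e-8 for degenerate genes). Training then
alternates: hold centering fixed and optimize the 46 scaling factors, then
hold scaling fixed and optimize the 46 centering factors. Each block is
optimized with derivative-free Nelder–Mead simplex search (the objective
is piecewise smooth because of truncation, and 46-dimensional per block);
scaling is optimized on the log scale to enforce positivity. Every
objective evaluation recomputes subtype correlations and the proliferation
score, refits the 0–100 rescale by least squares for ROR-P and ROR-PT
separately, and returns the mean of the two truncated-prediction MSEs
(`objectiveMode = "both"`; `"ror_pt"` scores ROR-PT alone — both
conventions appear in practice, and the averaged form is the default
because it constrains the shared factors with both scores). The number of
iterations is a tuning parameter chosen by 5-fold cross-validation: each
fold's complement is optimized for up to 20 iterations, held-out MSE is
recorded after every iteration (iteration 0 = untrained), and the
iteration minimizing mean held-out MSE is selected, ties going to fewer
iterations. The final model re-runs the optimization on the full training
split, stops at the chosen iteration, and freezes factors and rescales.

Numerical defaults: simplex relative tolerance 1e-8 with a budget of 2000
objective evaluations per half-iteration. The budget was set by measuring
where validation performance saturates: with the default study conditions
the validation MSE of the fitted model is overfitting-limited, not
optimizer-limited (scoring with the generator's own hidden factors gives
the same validation MSE as the fitted model up to the measurement-noise
floor), so larger budgets buy runtime, not accuracy. The cap is
configurable through `control`.

**Oncotype-trained.** The metagene design (with the GSTM1/CTSV rules) is
fit to the true RS by ordinary least squares with an intercept; a
collinear design is an error. The refit absorbs the unknown rescale, so
fitted coefficients are the published weights times the (unknown) rescale
slope; the published-vs-fitted comparison is stored with the model. Plain
least squares is used rather than shrinkage toward the published weights:
with 7 regressors and ≥ 100 training samples the refit is well-posed, and
the comparison of interest is precisely how far the refit moves.

**MammaPrint-trained.** Because the original algorithm's description is
not sufficient for exact reimplementation, the trained surrogate is
L2-penalized (ridge) logistic regression on the 70 standardized genes
(standardization frozen from the training split), with the penalty chosen
on a 40-point log-spaced grid by 5-fold cross-validation minimizing
held-out misclassification; ties break toward the larger penalty, and the
decision threshold is 0.5 on the probability scale (the assay defines no
continuous score to calibrate a threshold against).

All three trained models are frozen objects: `applyTrained()` never
re-estimates anything from the data it scores, and the package's tests
verify that permuting the validation samples leaves every fitted parameter
unchanged.

## Evaluation

`regressionMetrics()` reports Pearson r and the least-squares fit of the
*estimated on the true* scores (slope/intercept are direction-dependent;
this direction matches how such comparisons are usually printed).
`concordanceTable()` cross-tabulates risk categories; concordance is the
diagonal fraction, and the discordance-direction fractions order
low < intermediate < high. Signature-like comparisons use all samples;
signature-trained regressions use the validation half only, while trained
cross-tabs use all samples. MammaPrint, being binary, gets concordance
only.

## The synthetic cohort generator

`generateCohort()` emulates a NanoString-profiled high-risk ER+ cohort:

* **Subtype structure.** Each sample draws a latent 4-subtype label
  (defaults 45/35/12/8% LumA/LumB/HER2-E/Basal, a luminal-heavy mix) and a
  latent expression profile centred on its subtype's centroid, with
  log-scale noise (sd 0.35). A continuous per-sample "grade" axis (sd 0.6
  along the LumB-minus-LumA direction) gives the proliferation continuum
  real cohorts show — without it the true risk-score distribution has an
  empty intermediate band.
* **Hidden distortions.** The packaged per-gene baseline location/gain
  maps the standardized latent onto log2-ratio scale; the vendor-truth
  factors are a perturbation of that baseline (centering shifts of sd 0.5,
  scaling multipliers in [0.8, 1.25]). Expression is generated under the
  baseline while the true scores are computed with the hidden perturbed
  factors: the per-gene data moments therefore sit near the baseline, not
  the truth, which is precisely the estimation problem the training stage
  must solve. (Generating through the hidden factors instead would let the
  mean/SD initialization read them off exactly, and training would have
  nothing to recover.)
* **Truth.** ROR-family truth runs the Prosigna engine with the hidden
  factors and synthetic vendor rescales; RS truth runs the metagene engine
  with the published weights; MammaPrint truth thresholds the gene70
  correlation of the latent profile and flips 2% of labels to emulate
  assay discordance. Measurement noise (sd 2 on the 0–100 scale) is added
  and scores are truncated to [0, 100]. Tumour sizes are log-normal around
  a 2 cm median so the size indicator splits roughly evenly.
* **Determinism.** All draws flow from the config seed through fixed
  per-component sub-streams; regeneration is bit-identical.

What the generator does *not* emulate: batch effects, missing genes,
probe-level artefacts, or the empirical score distributions of any real
cohort (none are published for the data the method was developed on). A
passing closed loop therefore shows the machinery is correct and the
calibration identifiable under the stated noise model — not that any
particular real cohort would reach the same accuracy.

Packaged constants deserve a caveat: the Oncotype metagene structure and
weights are the published values, but the subtype centroids, ROR weights,
0–100 rescale constants, gene70 template/cutoff and the MammaPrint roster
are synthetic stand-ins (vendor values are unpublished and the reference
implementations were unavailable), labelled `_synthetic` in
`inst/extdata/` and swappable for real values without code changes.

## Study conditions used by the tests and the acceptance script

The default study is a 200-sample cohort with the parameters above; the
acceptance script runs it end to end (5-fold CV over 20 iterations). The
factor-recovery analysis uses the default perturbation with measurement
noise set to zero, so that the trained-vs-untrained validation-MSE ratio
measures recovery of the hidden factors rather than the shared noise
floor (with noise sd 2, both MSEs contain an irreducible 4). Weight
recovery for Oncotype uses n = 150 (exact recovery without noise, r
against truth with noise sd 2); the ridge experiment uses n = 300 with 2%
label flips; the reproducibility check runs a reduced study (n = 60,
3 folds, 2 iterations) twice and compares artifacts byte for byte. These
sizes are the package's test-scale choices; larger cohorts only tighten
the same comparisons.

## Known limitations

* The 46-gene reporter roster and all synthetic constants are structural
  reconstructions; absolute score values are not comparable to real
  vendor reports, only the relationships between methods are meaningful.
* The alternating optimization is a local search from the untrained
  initialization; it is accurate when data moments start near the truth
  (the regime the method assumes) and is not a global optimizer.
* The like-pipeline's measurement-range transform target (default
  [2.5, 12.5]) is a convention, and like-score scale artefacts depend on
  it; the trained pipeline is insensitive to it by construction.
* No survival modelling: the package compares surrogate scores with true
  assay scores, not with outcomes.
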