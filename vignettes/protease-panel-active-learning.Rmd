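---
title: "Methods: simulating and classifying serum protease-activity panels"
author: "proteaseAL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying serum protease-activity panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteaseAL)
```

## The measurement being modelled

A graphene-based nanobiosensor (G-NBS) tethers a fluorophore-labelled
consensus oligopeptide to few-layer graphene, which quenches the
fluorophore. A protease in serum that recognizes the substrate cleaves the
peptide, the fluorophore escapes the quencher, and fluorescence rises. One
endpoint read per well after incubation therefore reports the activity of
one protease in one serum sample, in arbitrary fluorescence units (a.u.).

The plate protocol runs three solutions, each in triplicate, per sample and
protease:

* **SC** (sample control): buffer + serum — serum autofluorescence;
* **AC** (assay control): nanobiosensor + buffer — the intrinsic
  leak/quench baseline of the sensor;
* **ASSAY**: nanobiosensor + serum — baseline plus cleavage signal.

Both controls sit far below the assay wells when protease is present.

The panel has seven proteases, in the fixed order MMP3, MMP28, CTSK, MMP24,
ADAM15, ADAM10/12, ADAM17. ADAM10 and ADAM12 are a single feature because
their active centres are too similar for a substrate to separate them. Each
sample thus becomes a 7-vector of activities plus one of three diagnostic
labels: healthy, localized (stage I–II) or metastatic (stage III–IV)
ovarian cancer. The default cohort design is 50 / 46 / 50 samples.

## The synthetic-data generator

No public dataset accompanies this analysis, so the package ships a
generator (`generateCohort()`, `generatePlateReadings()`) whose defaults
*are* the study conditions every downstream test assumes.

Per-sample activities are drawn independently per protease from a
**lognormal** distribution parameterized by a per-group mean and standard
deviation on the natural scale (fluorescence intensities are positive and
right-skewed; a truncated-normal option exists for analyses, such as
level checks of the t-test, where its own distributional assumption is
wanted). The shipped group means encode the qualitative structure the
analysis assumes:

* healthy > localized > metastatic mean activity for MMP3, MMP28, CTSK,
  MMP24 and ADAM10/12 (most serum proteases are *less* active in disease
  here, consistent with under-expression of the corresponding genes);
* for ADAM15 the metastatic mean (830 a.u.) sits close to the healthy mean
  (850 a.u.), well above localized (560 a.u.), so localized-vs-control and
  localized-vs-metastatic separate while metastatic-vs-control does not;
* ADAM17 is a **designed null biomarker**: all three group means equal
  (595 a.u.). A biomarker with no real group effect is the cleanest way to
  obtain a panel member that is consistently *not* significant while the
  other six are; any nonzero residual effect would inflate its
  false-positive rate above the nominal level.

Means sit at 400–1100 a.u. with coefficients of variation near 0.2, values
chosen once so that two-sample tests at the design sample sizes give the
intended pattern — the six structured biomarkers strongly significant for
localized-vs-control (p-values in the 1e-6 to 1e-16 range), ADAM17 not —
and so that the three class-conditional distributions are separable but
not trivially so (reference measurements: mean held-out accuracy ≈ 0.96
for the two-layer network over 50 seeds; individual runs range down to
≈ 0.87). These parameters are synthetic and documented as such; they are
not measurements.

Plate simulation draws one baseline per sample × protease block
(`Normal(50, 5)` a.u., shared by all nine wells of the block), adds the
sample's true activity to ASSAY wells only, and adds independent
`Normal(0, plateNoiseSd)` well noise (default 10 a.u.). Subtracting the AC
triplicate mean from the ASSAY triplicate mean therefore recovers the true
activity with error standard deviation `plateNoiseSd * sqrt(2/3)` and no
bias — the round-trip property the tests exercise.

**What the generator does not emulate:** inter-plate drift,
plate-position effects, enzymatic time courses (a single endpoint is
modelled), correlated activities across proteases within a sample, batch
effects between sensor lots, or label noise in the clinical annotation.
Passing tests on these cohorts shows that the pipeline's statistics,
learning dynamics and attributions behave as designed under the assumed
generative model — not that comparable accuracy would be obtained on real
serum.

One global integer seed drives every run; stage-specific sub-seeds
(cohort, plate, split, per-iteration model initialization) are derived
deterministically from it with `deriveSeed()`, so stages are individually
reproducible and an identical (config, seed) pair reproduces every
artifact byte for byte.

## Well summarization and QC

`summarizeWells()` computes `activity = mean(ASSAY) − mean(AC)`, floored at
zero. The assay control is the subtracted baseline because it shares the
fluorophore source with the assay wells; serum autofluorescence (SC) is
retained for quality control only. Flooring (rather than keeping negative
net signals) keeps the activity scale non-negative, consistent with the
lognormal feature model; floored wells are flagged `below_baseline`.
Triplicates whose coefficient of variation exceeds `cvThreshold`
(default 0.2, a conventional plate-assay repeatability bound) are flagged,
never dropped — downstream exclusion is an analyst's decision.

## Group statistics

For every biomarker and each group pair (localized vs control, metastatic
vs control, localized vs metastatic):

1. an F-test on the two sample variances (two-sided, gate level 0.05 — the
   same level used for the comparisons themselves, since no separate gate
   level is conventionally agreed);
2. a pooled-variance Student t-test if the gate accepts equality,
   otherwise Welch's t-test with Welch–Satterthwaite degrees of freedom;
3. classification of the two-sided p-value: `significant` if `p ≤ 0.05`,
   `borderline` if `0.05 < p < 0.10` (strict inequalities), else `ns`.

Raw p-values are reported without multiple-testing adjustment: the table is
a per-biomarker screen, mirroring common practice for small fixed panels,
and the calls are qualitative labels, not error-rate guarantees. The level
of the composite gate-then-test procedure is checked by simulation on null
cohorts drawn with the normal noise option (the t-test's own assumption);
the lognormal default is mildly skewed, and level checks under it would
confound the procedure with its distributional robustness.

## Base classifiers

**Hierarchical kNN.** Stage 1 votes healthy vs non-healthy among the `k`
nearest labeled samples; stage 2, trained only on non-healthy labeled
samples, votes localized vs metastatic. The posterior is the product
through the hierarchy: `P(localized) = (1 − P(healthy)) · v` where `v` is
the stage-2 vote fraction, so hierarchical consistency
(`P(loc) + P(met) = 1 − P(healthy)`) holds exactly. Distances are Euclidean
on per-feature z-scores from the current labeled set (refit at every
iteration); `k = 5` by default — odd to avoid vote ties, small enough for
the ≈ 29-sample initial labeled sets. Posteriors are raw vote fractions,
with no distance weighting or smoothing. Deterministic tie-breaks
throughout: neighbours are ordered by (distance, sample index); class
ties resolve in the fixed order healthy < localized < metastatic. `k`
larger than a stage's training size is clipped to the largest feasible odd
value with a warning; features with zero variance in the labeled set are
dropped from the distance with a warning (at zero noise the designed-null
ADAM17 is constant, so this arises by construction there). When fewer than
two non-healthy classes are labeled, stage 2 is absent and the conditional
is uniform.

**Two-layer linear-activation network.** Taken literally: input → hidden
(identity activation) → output, then a normalized-exponential map onto the
class simplex so posteriors exist. With identity activations the composed
map is affine — the hidden layer (default width 8) does not enlarge the
model class, and a rank bound on the composed weight product verifies the
collapse — but the stated architecture is retained. Inputs are
standardized with labeled-set statistics; training is full-batch gradient
descent on the multinomial cross-entropy, learning rate 0.2, 300 epochs,
weights initialized `Normal(0, 0.1)` from the seeded sub-stream. These
values were fixed once: on standardized 7-feature inputs with ≤ 72
training samples the loss plateaus well before 300 epochs, and larger
rates begin to oscillate. A non-finite loss aborts with an error rather
than returning a silently broken model. If the labeled set contains a
single class, the cross-entropy optimum diverges toward certainty on that
class; the fitted model returns that limit directly (a large fixed output
bias) instead of pretending to train.

## Active learning

The protocol is pool-based uncertainty sampling with an oracle annotator:

* `floor(0.20 n)` samples form the initial labeled set, `floor(0.30 n)`
  the query pool, and the remainder — about half the data — the held-out
  test set on which confusion matrices are computed. Holding the
  remainder out for evaluation is this package's design choice: it is the
  only reading that leaves a test set large enough for a 3 × 3 confusion
  matrix at these cohort sizes. At `n = 146` the split is 29 / 43 / 74.
* The initial labeled draw is repeated (and the count logged) until it
  contains at least one healthy and one non-healthy sample, so stage 1 is
  trainable from iteration zero.
* Each iteration queries the pool sample with the smallest top-class
  posterior probability (least-confidence sampling, taken as printed;
  margin and entropy variants are available behind a switch but off by
  default), moves it with its true label into the labeled set, and refits
  the model from scratch with a fresh seeded initialization — determinism
  is preferred over warm-start convenience.
* Iteration stops when the pool is exhausted (default) or a query budget
  is reached. Test accuracy is recorded after every refit.

## Shapley explanations

Feature relevance uses interventional Shapley values: the value of a
coalition `S` at sample `x` is the mean model class-probability over
background rows with the features in `S` replaced by `x`'s values. With
`p = 7` panel features, full enumeration of all `2^p` coalitions is cheap
and axiom-exact (efficiency, symmetry, dummy, linearity hold to numerical
precision), so exact enumeration is the default and kernel-regression
approximations are unnecessary; a guard refuses `p > 12` and points to the
seeded Monte-Carlo permutation estimator (`shapleySampling()`), whose
error shrinks as `nSamples^(-1/2)`. The background is the labeled training
set, capped at 50 rows deterministically (first rows). Explanations target
the predicted class by default.

Per-class rankings aggregate mean `|phi|` across samples with ties broken
by panel order. On synthetic cohorts the *identity* of the per-sample
top-3 set varies — several panel features carry comparable information by
construction, so attributions have near-ties — and the stable property is
overlap with the class-level aggregate ranking (measured on the shipped
defaults: every healthy-class sample shares at least one aggregate top-3
feature, 77–100% share at least two). Strong within-class agreement of
the exact top-3 is a feature of real serum data that these synthetic
conditions do not reproduce, and the tests assert the measured overlap
property instead.

## Reporting conventions

Accuracy is `100 · trace / total`, reported **truncated** (not rounded) to
two decimals — a conservative convention under which a reported accuracy
never over-states the realized one (e.g. counts giving 93.8356% report as
93.83). Sensitivity and specificity are macro-averaged one-vs-rest
(unweighted mean over the three classes); other conventions
(micro-averaging, prevalence weighting) give different numbers, which is
why the convention is stated here and in the function documentation.

## Problem sizes used by the tests

The packaged tests run cohorts at the design size (146) where the claim
depends on it (split arithmetic, accuracy structure, 50-seed learning
averages), and smaller cohorts (30–60 samples) for loop-level properties
such as partition conservation and query replay, where size is
immaterial. Statistical level checks use 2000 null simulations of the
full cohort; the separation-monotonicity check uses 30 seeds at three
separation levels with 60-sample cohorts. These sizes are the package's
own choices balancing Monte-Carlo error against runtime.

## Known limitations

* Generator realism as listed above; in particular independence across
  proteases is a simplification — real protease networks co-activate.
* kNN posteriors are vote fractions from small neighbourhoods, so they are
  coarse (multiples of 1/k) and the least-confidence criterion often ties;
  ties resolve deterministically but a different tie rule would query a
  different sample order.
* The linear-activation network is an affine classifier; it cannot express
  non-linear class boundaries, and its competitive accuracy here reflects
  the near-linear separability of the synthetic cohorts.
* Exact Shapley cost grows as `2^p · |background|` model calls; beyond
  12 features use the sampling estimator.

## A worked run

```{r pipeline, eval = FALSE}
res <- runPipeline(seed = 1L, outDir = "run1")
res$report$hknn$accuracy   # held-out accuracy, hierarchical kNN
res$report$nn2$accuracy    # held-out accuracy, two-layer linear net
res$report$top_features    # per-class aggregate top-3 panel features
```
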