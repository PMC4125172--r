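---
title: "Quantitative CT analysis of ground-glass nodules with ggnquant"
author: "ggnquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT analysis of ground-glass nodules with ggnquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggnquant)
```

## The problem

Pulmonary ground-glass nodules (GGNs) that turn out to be adenocarcinoma
fall into three pathologic groups: adenocarcinoma in situ (AIS, purely
lepidic growth, no invasion), minimally invasive adenocarcinoma (MIA,
invasive component of at most 5 mm), and invasive adenocarcinoma (invasive
component larger than 5 mm). All three can look like a hazy GGN with little
or no solid component on CT, yet their management differs, so a
pre-operative, image-based separation of the invasive group from the other
two is clinically valuable.

`ggnquant` implements the quantitative-CT approach to this problem as a
tested pipeline:

1. first-order features of the voxel HU histogram inside a segmented
   nodule — size in the lung and mediastinal window, volume, density, mass,
   skewness, kurtosis, the 2.5th/25th/50th/75th/97.5th attenuation
   percentiles, and the texture pair uniformity/entropy;
2. a statistics stage — one-way ANOVA with Bonferroni correction across the
   three classes, Spearman correlation with the pathologic invasion extent,
   two-observer intraclass correlation, variance-inflation screening,
   backward-stepwise logistic regression of invasive vs. AIS-or-MIA, ROC
   analysis, and a fixed two-threshold decision rule
   (75th percentile $\ge -470$ HU **and** entropy $\ge 7.90$ bits);
3. a synthetic phantom generator that emulates a 191-nodule three-class
   cohort (38 AIS / 61 MIA / 92 invasive), so the whole chain can be
   exercised and tested without patient data, which is not publicly
   deposited for this problem.

## Feature definitions and numerical conventions

All features are computed from the multiset of integer HU values inside
the mask plus the mask geometry; voxel traversal order never matters.

* **Percentiles** use linear interpolation between order statistics
  (the common "type 7" convention), so a sample of $1,\dots,100$ has median
  $50.5$.
* **Texture histogram**: 1-HU-wide integer bins over the nodule's own
  occupied range. With $p_i$ the bin probabilities, uniformity is
  $\sum_i p_i^2$ and entropy is $-\sum_{p_i>0} p_i \log_2 p_i$ (bits).
  HU are stored as integers, so this binning is exact and a shift of all
  voxels by a constant leaves both measures unchanged. The magnitudes this
  produces (entropy around 7.4–8.1 bits, uniformity around 0.004–0.008,
  i.e. roughly 150–300 effective gray levels) are the ones reported for
  GGN cohorts, which is why fine HU-level binning rather than coarse
  re-quantization is the default; the bin width is a configuration knob.
* **Skewness / kurtosis** are the standardized third and fourth central
  moments; kurtosis uses the non-excess convention (Gaussian $\to$ 3),
  consistent with reported GGN values clustering near 3. A constant-HU
  nodule has undefined moments; they are recorded as `NA` rather than
  silently zeroed.
* **Density** follows the physical-density reading of CT attenuation
  (air = 0, water = 1): $(\overline{\mathrm{HU}} + 1000)/1000$, clamped at
  0; **mass** is exactly density × volume, and **volume** is the voxel
  count times the physical voxel volume.
* **Size in the lung window** is the largest in-plane Feret (caliper)
  diameter over axial slices, computed on the convex hull of voxel centres
  plus one pixel extent (a single voxel measures one pixel across).
* **Size in the mediastinal window** is the same caliper measure applied to
  the largest 26-connected component of in-mask voxels at or above
  $-160$ HU. The threshold stands in for soft-tissue-window visibility; the
  exact window/level protocol behind published mediastinal measurements is
  not specified anywhere we could follow, so $-160$ HU (a conventional
  soft-tissue bound) is the default and is configurable.

## The statistics stage

The chain mirrors standard radiology-cohort practice:

* **Group comparison**: classic one-way ANOVA per feature; pooled-variance
  pairwise t tests with Bonferroni multiplication by 3 (the number of class
  pairs); an additional family-level Bonferroni correction of the overall P
  (family factor 2 for the two size variables, 7 for the seven
  histogram-shape variables).
* **Candidate screen**: features with raw ANOVA $P < 0.10$ enter the
  multivariable stage. The screen uses the uncorrected P on purpose — the
  family correction protects the descriptive table, not the model entry.
* **VIF screen**: $\mathrm{VIF}_j = 1/(1-R^2_j)$ from regressing candidate
  $j$ on the others; candidates are removed one at a time, largest first,
  until all VIFs are at or below 10. A perfectly collinear candidate is
  treated as infinite VIF and removed first.
* **Backward-stepwise logistic regression** of invasive vs. AIS-or-MIA:
  starting from the full model, the variable whose likelihood-ratio removal
  test has the largest P is dropped while that P exceeds 0.10. Perfect
  separation is detected (all fitted probabilities at 0 or 1) and raised as
  an error instead of reporting divergent odds ratios. Odds ratios are
  reported with Wald 95% intervals on the log-odds scale, matching the
  usual presentation.
* **ROC**: AUC is the Mann–Whitney concordance (trapezoidal rule with half
  credit for ties). The 95% CI uses a seeded stratified bootstrap (2000
  resamples, resampling within each class); the method behind published
  CIs for this problem is unstated, and the bootstrap is distribution-free
  and reproducible. Both the fitted-probability ROC and the binary
  two-threshold-rule ROC are computed and reported separately, since the
  two are distinct analyses that are easy to conflate.
* **Two-threshold rule**: predicted invasive iff
  $p_{75} \ge -470$ HU **and** entropy $\ge 7.90$ bits, both comparisons
  inclusive. Cohort-level evaluation reports PPV among rule-positives,
  sensitivity and specificity.
* **Interobserver agreement** uses the two-way random-effects,
  absolute-agreement, single-measure ICC (ICC(A,1)), computed from the
  repeated-measures mean squares with the F-based confidence interval.
* Within-patient correlation between multiple nodules of one patient is
  deliberately ignored: synchronous GGNs are treated as independent
  lesions, as is conventional for this cohort type.

## What the phantom generator emulates

Each nodule is a smooth blob (a sphere with a low-order radial
perturbation) of ground-glass attenuation on a uniform aerated-lung
background near $-900$ HU, rendered at $0.7 \times 0.7 \times 1.25$ mm
voxels (slice thickness is the stated acquisition condition; the in-plane
pixel is a typical chest-CT value). HU are integers. The in-mask HU
distribution is a mixture of:

* a **bulk matrix** with one to three partially separated sub-modes
  (single-, flat- and double-peaked GGN histograms all occur in practice)
  and a mild right skew;
* a **partial-volume left component** near $-855$ HU — boundary voxels
  resemble aerated lung whatever the tumour class, which anchors the low
  percentiles (the 2.5th percentile is nearly class-independent, as
  reported cohorts show);
* a **narrow spike** sub-population of near-identical voxels (collapsed or
  homogeneous alveolar regions) whose weight and width vary per nodule;
  the spike dominates uniformity while barely moving entropy, which keeps
  the two texture measures from being mere transforms of each other;
* an optional **denser right-tail component** and an optional
  **solid core** below 5 mm diameter with HU $\ge -160$; outside the core
  the matrix is truncated below $-160$ HU, so a nodule without a core has
  no solid-range voxel by construction.

Class identity enters through a per-nodule **heterogeneity intensity**
$\lambda$ (a class-ordered truncated normal) that each nodule expresses
through a random split across three channels: more right-tail mass, more
bulk multi-modality, or a wider core. This reflects how invasive tumours
are heterogeneous in *different* ways — some grow a dense focus, some turn
architecturally complex, some densify throughout. Entropy integrates over
the whole histogram and responds to every channel, while any single
percentile responds to only a subset; that is what makes entropy the
robust independent predictor in the fitted models, rather than an artifact
of one tuned parameter. Class means of size, density, mid/high percentiles
and entropy increase with invasiveness and uniformity decreases, with
within-class dispersion comparable to published cohort tables; low
percentiles and skewness/kurtosis carry essentially no class signal.

Pathologic ground truth is sampled per class: AIS has invasion extent 0,
MIA uniform in (0.5, 5] mm, invasive log-normal with median 9.8 mm
truncated to [5.1, 19.7] mm. Cohort defaults are 38/61/92 nodules and all
generated solid cores are below 5 mm, so a default cohort passes the
$\ge 5$ mm solid-component exclusion filter unchanged.

**Observer simulation.** Two observers are simulated by independently
flipping boundary-shell voxels (probability 0.5 per unit of boundary
noise, default one voxel), keeping the largest connected component. A
one-voxel rim of partial-volume attenuation just outside the true boundary
ensures an over-inclusive ROI samples transition voxels rather than pure
lung. With noise 0 both observers reproduce the input mask exactly and all
downstream ICCs are exactly 1. Per-feature working values are the
arithmetic mean of the two observers, as in reader studies.

**What the generator does not emulate**: lung anatomy, vessels and airways
(masks are vessel-free by construction rather than by editing), scanner
noise texture and reconstruction kernels, DICOM series structure, and
spatial correlation of HU noise. Passing tests on phantoms therefore
demonstrate the *pipeline's* correctness and the qualitative
cohort-level behaviour, not clinical performance on real scans.

## Determinism and seeds

Cohort generation is a pure function of its specification: per-nodule
seeds derive deterministically from the master seed
(`derive_seed(master, index)`, a linear-congruential hash kept below
$2^{31}$), every stochastic step inside one nodule consumes only that
nodule's seeded stream, and bootstrap CIs take explicit seeds. Running the
pipeline twice with the same configuration produces byte-identical report
bundles.

## Problem sizes used by the test-suite

The packaged checks run the full default cohort (191 nodules) for trend
recovery, twenty master seeds for the selection-stability check, one
thousand small-diameter phantoms (6–11 mm) for the feature-invariance
sweep, and two hundred replicates at $n = 200$ for the stepwise
calibration study. These sizes were chosen to give stable Monte-Carlo
answers while keeping a complete run of the suite on a single CPU within
a coffee break.

## Design choices that were genuinely open

* **Entropy estimator**: the plug-in estimator is used without small-sample
  bias correction, because the published texture identities (uniform
  256-level histogram → exactly 8 bits) hold only for the plug-in form.
  The estimator's downward bias in small nodules is real and is part of
  the size–entropy covariance the cohort analysis sees.
* **Stepwise candidate entry** uses raw ANOVA P values; **post hoc P**
  values are pairwise-Bonferroni only (×3), with the family factor applied
  to the overall P — the published table format is ambiguous on whether
  post hoc values were additionally family-corrected, and the selection
  trace in the report makes this package's choice auditable.
* **Mediastinal size** re-uses the in-plane Feret convention on the
  thresholded solid component; published measurement protocols for the
  mediastinal window are not described precisely enough to copy.
* **ROC confidence intervals** are bootstrap rather than the Hanley–McNeil
  normal approximation: at 191 nodules both are adequate, but the
  bootstrap extends unchanged to the binary-rule ROC with ties.
* **Voxel HU are integers** end-to-end (CT convention); this makes the
  1-HU texture binning exact and every texture identity reproducible to
  the last bit.

## Known limitations

Phantom realism is deliberately limited (see above). The two-threshold
rule's published cutoffs are applied as given rather than re-derived; on
synthetic cohorts the rule's operating point sits in the same region of
feature space but its exact PPV depends on preset calibration. The
stepwise procedure inherits the known instability of backward selection
near the removal level, which is why the package reports the full
selection trace instead of only the final model.
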