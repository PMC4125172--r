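# ggnquant

Quantitative CT analysis of pulmonary ground-glass nodules (GGNs) in R:
first-order radiomics of the voxel HU histogram inside a segmented nodule,
and the statistical chain used to separate **invasive adenocarcinoma** from
**adenocarcinoma in situ (AIS)** and **minimally invasive adenocarcinoma
(MIA)** — three entities that can all present as a hazy GGN with little or
no solid component on CT.

The package is aimed at imaging researchers who want a tested, fully
reproducible implementation of this analysis to run on their own volumes
and masks (NIfTI), or on the built-in synthetic cohort generator when no
image data are at hand.

## What it computes

**Features** (per nodule, from a `ct_volume` + `nodule_mask` pair):
size in the lung window (in-plane Feret diameter) and in the mediastinal
window (Feret diameter of the largest 26-connected component with
HU ≥ −160), volume (cm³), density ((mean HU + 1000)/1000), mass (g),
skewness, kurtosis (non-excess), HU percentiles
p2.5/p25/p50/p75/p97.5 (linear interpolation), and first-order texture
over 1-HU bins:

- uniformity  U = Σᵢ pᵢ²
- entropy   H = −Σᵢ pᵢ log₂ pᵢ  (bits)

Higher entropy and lower uniformity mean a more heterogeneous nodule.

**Statistics** (per cohort): one-way ANOVA with Bonferroni post hoc tests
and family-level correction; Spearman correlation of every feature with
the pathologic invasion extent; two-observer ICC (two-way random effects,
absolute agreement, single measure); variance-inflation-factor screening
(iterative removal above VIF 10); backward-stepwise logistic regression of
invasive vs. AIS-or-MIA (likelihood-ratio removal at P > 0.10); ROC with a
seeded stratified-bootstrap CI; and the fixed two-threshold rule

```
predicted invasive  ⇔  p75 ≥ −470 HU  AND  entropy ≥ 7.90 bits
```

with cohort-level PPV, sensitivity and specificity.

**Phantoms**: `generate_cohort()` builds a deterministic synthetic
three-class GGN cohort (default 38 AIS / 61 MIA / 92 invasive at
0.7 × 0.7 × 1.25 mm voxels) whose per-class feature distributions follow
the ordering and dispersion seen in real cohorts; `simulate_observers()`
perturbs masks to emulate two readers. See the vignette
(`vignettes/ggn-quantitative-ct.Rmd`) for the generative model.

## Worked example

```r
library(ggnquant)

# one synthetic invasive nodule
spec <- phantom_spec("INV", diameter_mm = 15, ggo_mean_hu = -600,
                     ggo_sd_hu = 48, right_tail_weight = 0.2,
                     solid_focus_mm = 3, invasion_extent_mm = 9.8, seed = 42L)
nod <- generate_nodule(spec)
extract_features(nod$volume, nod$mask)

# full synthetic-cohort analysis, written to disk
out <- run_pipeline(pipeline_config(
  cohort = cohort_spec(master_seed = 57290L),
  out_dir = "ggn-report"
))
out$report
```

The report prints, for the default seed:

```
GGN cohort analysis (n = 191)
  logistic model retains: size_mediastinal_mm, p50_hu, p75_hu, uniformity, entropy_bits
  fitted-probability ROC AUC = 0.869 (95% CI 0.817-0.913)
  rule (p75 >= -470 HU AND entropy >= 7.9): PPV 87.5% (14/16)
```

meaning: after ANOVA screening (P < 0.10) and VIF screening, backward
selection kept the mediastinal size, the 50th/75th-percentile attenuation
and both texture measures as independent predictors of invasiveness; the
fitted model separates invasive from AIS/MIA nodules with AUC 0.869 on
this synthetic cohort; and of the 16 nodules meeting both fixed
thresholds, 14 were truly invasive. `ggn-report/` contains the feature
table, the ANOVA / Spearman / ICC tables, the VIF and stepwise traces,
ROC operating points and a run manifest; identical configuration gives a
byte-identical bundle.

NIfTI volumes and masks from real studies enter the same way:

```r
vol  <- load_volume("nodule_007.nii.gz")
mask <- load_mask("nodule_007_mask.nii.gz", vol)   # vessels excluded upstream
extract_features(vol, mask)
```

A thin command-line front end over the same functions lives in
`inst/scripts/ggnquant-cli.R` (`generate`, `extract`, `analyze`, `run`).

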