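---
title: "Opportunistic QCT screening: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic QCT screening: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctscreen)
```

`qctscreen` turns routine CT of the thoracolumbar spine into quantitative
bone measures and fracture-association statistics. This vignette explains
the science the package implements, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the numerical and design decisions that were genuinely open.

## From attenuation to density

CT voxels carry attenuation in Hounsfield units (HU). Asynchronous QCT
calibration maps HU to volumetric bone mineral density by a linear
relation estimated from phantom scans of known hydroxyapatite density,
specific to each scanner and protocol:

$$\mathrm{vBMD} \;=\; a \cdot \mathrm{HU} + b \qquad [\mathrm{mg/cm^3}].$$

Intravenous contrast medium inflates attenuation, so scans acquired in an
arterial or portal-venous phase receive a second linear map on the
calibrated density. Both maps are applied to the whole volume *before*
any measure is extracted; because the two affine maps do not commute, the
order is part of the contract and is asserted by a test. Calibration is
voltage-specific: the package models 120-kVp protocols only and rejects
other tube voltages rather than extrapolating. Coefficients live in a
YAML/JSON config, not in code — published conversion equations are
scanner-specific, and the shipped defaults are synthetic placeholders.

## Volumetric bone measures

A vertebral segmentation mask labels each level and, when available, the
body and posterior-elements subregions. The measurement chain per level
is:

1. **Body separation.** Explicit subregion labels pass through. For an
   unpartitioned vertebra a geometric heuristic is applied: the
   voxel-count profile along the anterior–posterior axis has a bulky
   anterior mode (the body) and a narrower posterior plateau (the
   arch); the vertebra is cut at the deepest valley behind the body
   peak. On labelled phantoms the heuristic reaches Dice ≥ 0.95 against
   the true body; its provenance is recorded on the output. The
   template-registration approach used with clinical masks is out of
   scope here — the heuristic keeps the measure arithmetic faithful
   without a registration pipeline.
2. **Metric erosion.** The trabecular compartment is the set of body
   voxels lying strictly deeper than 5 mm from the body surface,
   computed with an exact Euclidean distance transform that honours
   anisotropic voxel spacing (separable lower-envelope algorithm, one
   parabola pass per axis). "5 mm" is a physical distance: on a
   1×1×3 mm grid the margin is 5 mm in every direction, not 5 voxels.
   The erosion is three-dimensional rather than slice-wise — with
   near-isotropic modern reconstructions the two differ mainly at the
   endplates, and the 3-D form is the natural reading of a single
   distance. Erosion that empties a small vertebra marks the level
   non-evaluable instead of failing; the patient aggregate simply loses
   that level.
3. **Measures.** Trabecular vBMD and integral vBMD are arithmetic means
   of calibrated density over the trabecular and body masks; BMC is the
   summed mass (voxel volume × density, converted to grams). The
   identity BMC = integral vBMD × volume / 1000 holds to machine
   precision and is asserted on every phantom. Voxel volume is the
   product of the spacing components; no partial-volume model is applied
   at mask boundaries.
4. **Aggregation.** Patient-level values are unweighted means over the
   evaluable, non-excluded levels within T12–L4 (levels may be excluded
   for fracture, degeneration, or other focal abnormality). Unweighted
   averaging mirrors standard practice when multiple levels are
   evaluable.

## Virtual DXA

CT-based areal BMD is obtained by parallel projection of the masked,
calibrated volume along the anterior–posterior axis: each projection
pixel accumulates `density × Δy` through the body mask
(mg/cm³·mm → g/cm², factor 10⁻⁴), and aBMD is the mean over the
footprint — the pixels that received at least one body voxel. Because
only body masks are projected, lateral processes are excluded by
construction. Parallel (rather than divergent-beam) geometry was chosen
because it conserves mass exactly — the areal integral equals the
projected BMC, a property the suite asserts — and no acquisition geometry
is modelled anyway; the projection is monoenergetic areal mass, not a
dual-energy simulation. Patient aBMD averages per-level aBMD over L1–L4
(per-level-then-average, rather than pooling all footprint pixels, so
that levels contribute equally as in the volumetric aggregate). T-scores
standardize aBMD against a young-adult reference mean/SD; the shipped
reference is a configurable placeholder since vendor reference data are
proprietary. Osteoporosis is T ≤ −2.5 (boundary inclusive), low bone
mass −2.5 < T ≤ −1.

## Fracture-association statistics

All bone measures are *risk-oriented* before modelling: values are
standardized by the whole-cohort SD and negated, so odds ratios and AUCs
read "per SD decrease" and exceed 1 (or 0.5) for protective measures.
Whole-cohort rather than group-pooled SD is used for standardization —
the cohort is the sampling unit a screening tool sees.

- **Odds ratios.** Logistic regression by maximum likelihood; Wald 95%
  CIs on the log scale (the standard for the reported format); optional
  age/sex adjustment. Perfect separation is detected and flagged rather
  than reported as a huge finite OR.
- **ROC/AUC.** The AUC is the Mann–Whitney concordance probability with
  ties counted ½; thresholds sit at midpoints of adjacent distinct
  values. The variance is the DeLong structural-components estimator,
  and two measures on the same subjects are compared with the paired
  DeLong test (two-sided normal). Self-comparison returns difference 0
  and p = 1 by convention. The implementation is cross-checked in the
  suite against exhaustive pair counting, a 10⁴-replicate bootstrap, and
  pROC.
- **Group comparisons.** Welch t tests for continuous variables,
  chi-squared for sex; a summary-statistic Welch t test is provided for
  printed group summaries. Significance is two-sided at 0.05 with no
  multiplicity correction.

## Threshold transfer

Reference diagnostic bands exist for trabecular vBMD (ACR: osteoporosis
< 80 mg/cm³; low bone mass 80 ≤ BMD ≤ 120, upper bound inclusive). To
derive analogous cutoffs for another measure on the same subjects, the
package computes the reference cutoff's (sensitivity, specificity)
point, scans every candidate threshold of the target measure's ROC
curve, and selects the point minimizing the Euclidean distance in
(sensitivity, specificity) space — equivalent to (FPR, TPR) space up to
reflection. The result is rounded half-away-from-zero to the nearest
5 mg/cm³. Two conventions were genuinely open and are fixed as follows:
ties among equidistant candidates break toward higher specificity
(screening favours fewer false positives; configurable by the tie-break
being deterministic and documented), and rounding happens after
matching, so the reported operating point belongs to the unrounded
optimum. Transferred bands are half-open (`[low, high)`), while the ACR
trabecular band keeps its inclusive upper bound; `classify_band()`
preserves each convention per measure. Identity transfers recover the
reference cutoffs exactly, and affine targets map the cutoff through the
affine relation — both are asserted against exhaustive scans.

## What the synthetic generators emulate

**Phantoms** are vertebra-like objects: a superellipsoid-section body
(exponent 4, a rounded box), a cortical shell of configurable thickness
around a trabecular core, a posterior-elements block, soft-tissue
background, optional anterior wedge deformity (graded semiquantitatively:
20–25% height loss grade 1, 25–40% grade 2, > 40% grade 3; the technique
is cited without printed bands, so the conventional bands are adopted),
Gaussian HU noise, and optional contrast offsets. Attenuation is
synthesized by *inverting* the calibration chain, so calibration recovery
is exact in the noiseless case — a deliberate design choice that turns
calibration and erosion into exactly testable operations. The shell is
defined metrically with the same distance transform used for
measurement, so any erosion distance larger than the shell thickness
lands strictly inside the core. Default geometry (34×28×26 mm body, 3-mm
shell, 1-mm isotropic spacing, 10-HU noise, trabecular 100 / cortical
400 mg/cm³) is a plausible lumbar vertebra at clinical reconstruction
resolution. Phantoms exercise the erosion, projection and calibration
mathematics; they are *not* anatomically realistic CT — no beam
hardening, scatter, endplate curvature or trabecular microstructure — so
passing tests demonstrate correctness of the measurement pipeline, not
clinical segmentation performance.

**Cohorts** are two-group Gaussian samples: each measure gets its group
mean/SD (defaults are the reference study-group characteristics, 44
non-fractured / 148 fractured), and all measures share a single latent
factor giving every pair a within-group correlation of `correlation`
(default 0.5 — moderate dependence typical of correlated bone measures;
the true inter-measure correlations of the source cohort are unknown, so
this is a free simulation parameter, not an estimate). Marginal AUCs are
unaffected by it. Gaussian marginals are the natural model when only
means and SDs are reported; real cohorts have skewness, floor effects
and measure-specific tails the generator does not emulate.

The exclusion cascade (metastasis/hematologic disease, no assessable
DXA, no assessable CT, age < 50, insufficient coverage in non-fractured
patients: 360 − 18 − 34 − 15 − 35 − 66 = 192) is modelled as an ordered
roster filter with an audit trail; criteria are applied in the narrated
order even where they commute.

## Numerical choices and problem sizes

- Distance transforms treat everything outside the array as background
  (one padded layer suffices for exactness) and are validated against an
  all-pairs oracle on grids up to 16×12×10 with anisotropic spacings.
- The erosion threshold is strictly greater-than, so `erode(d = 0)` is
  the identity and nesting `E(d₂) ⊆ E(d₁)` for `d₂ > d₁` holds.
- AUC/DeLong use exact tie handling; degenerate variances (identical
  scores) return p = 1 rather than 0/0.
- The test suite works at deliberately small scale: phantoms of ~26×22×20
  mm at 1–2 mm spacing, 100-seed noise-recovery loops, 200-cohort AUC
  averages, 500-replicate CI-coverage simulations and 10⁴-replicate
  bootstraps — sizes chosen so each oracle comparison stays exact or
  statistically decisive while the whole suite runs in about a minute.
- `run_pipeline()` is deterministic given its config; result files from
  identical configs are byte-identical, and the statistics stage rerun on
  saved measures reproduces identical numbers.

## Limitations

The package measures what masks delimit: segmentation itself (the CNN
labelling used clinically) is an input, not a component. The virtual DXA
is monoenergetic areal mass and cannot reproduce DXA's two-energy soft
tissue compensation; agreement with real DXA is a property of real data
the synthetic suite cannot certify. Odds ratios and AUCs computed on
synthetic cohorts characterize the estimators under the stated Gaussian
model, not any particular clinical population; the transferred integral
vBMD cutoffs, like their clinical counterparts, would need validation
against incident fractures before diagnostic use.
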