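---
title: "Quantifying oncogenic activity from nuclear translocation reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oncogenic activity from nuclear translocation reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncrscreen)
```

## The assay model

A pathway reporter is a fluorescently tagged signalling protein that moves
from the cytoplasm into the nucleus when its pathway is activated. When a
candidate variant is co-transfected with such a reporter, the per-cell
nuclear-to-cytoplasmic ratio (NCR) — mean reporter fluorescence over the
nucleus divided by the mean over the cytoplasm — measures how strongly the
variant activates the pathway. The analysis chain in this package follows
the assay's aggregation scheme exactly:

1. per cell: NCR from segmented nucleus and cytoplasm compartments;
2. per well: the **median** NCR over the well's transfected cells;
3. per condition: the **mean** of six replicate-well medians.

Condition NCRs are rescaled against a wild-type (WT) anchor and a known
activating mutation (MT) anchor,

$$\mathrm{score} = 100\cdot\frac{\mathrm{NCR}_{VUS}-\mathrm{NCR}_{WT}}
{\mathrm{NCR}_{MT}-\mathrm{NCR}_{WT}},$$

so the score is a percentage of the known mutation's activity. The score is
invariant under positive affine transforms of the NCRs, may legitimately
fall below 0% or above 100%, and is never clamped. A variant is **active**
when its score is at least 20% (boundary inclusive). A two-sided t-test of
the variant's six well medians against the wild-type wells accompanies each
score; we use Welch's unequal-variance form by default (the classic pooled
form is a switch) and report the p-value without letting it gate the
activity call — the activity rule is the 20% cutoff alone.

Active variants are challenged with a 6-point log-spaced dose series of the
clinically assigned drug (both printed endpoints included). The drug
**inhibits** the variant when the activity falls *strictly below* the same
20-point cutoff at any dose. We read the inhibition threshold as 20 points
on the WT/MT scale — the activation cutoff — rather than 20% of the
untreated activity; the relative reading is available as
`call_inhibition(mode = "relative")`. An alternative reading of the
activation rule ("a 20% variation of the NCR compared to wild-type")
circulates in figure legends of assays of this type; we follow the
normalized-score definition because it is the one stated with the formula.

## Survival prediction rules

Patient-level predictions use a strict precedence:

1. **Amplification-based treatment.** When the drug was assigned on the
   basis of a gene amplification rather than an assayed variant, the assay
   is silent; a literature table keyed by (alteration, therapy) decides. The
   packaged table contains the single supported case (ERBB2 amplification,
   lapatinib + trastuzumab → positive); anything unmatched is negative. We
   deliberately did not invent further literature entries.
2. **No active targeted variant → negative.** "Targeted" is resolved through
   a packaged drug→gene map (sorafenib → FLT3/PDGFRA/KIT/RAF; imatinib →
   KIT/PDGFRA; vemurafenib → BRAF; lapatinib, trastuzumab → ERBB2/EGFR;
   erlotinib → EGFR). An active variant that the given drug does not target
   cannot rescue the prediction.
3. **Otherwise the dose-response assay of the patient's co-transfected
   variant combination decides.** Resistance co-mutations are not
   special-cased: a KRAS co-mutation defeats ERBB2 inhibition inside the
   assay itself, which is where the information belongs.

The example cohort's four positive predictions (patients 3, 4, 5, 9) and
eight negative ones follow from these three rules with no per-patient
exceptions.

## The synthetic-imaging generator

No raw images are distributed with the assay results, so the package ships
a ground-truthed simulator and validates the image chain against it. It
emulates what matters to segmentation and quantification:

- **Geometry.** Cells are discs with concentric nuclear discs (nucleus
  radius 0.55 of the cell radius, cell radius 10 ± 1 px). Centres keep a
  minimum separation of 1.3 cell radii: neighbouring cell bodies overlap
  (touching-cell segmentation is exercised) while nuclei stay separable.
  Circularity is a deliberate simplification — no published morphometry
  constrains the cell shape here, and discs are the simplest geometry that
  still forces watershed splits.
- **Signal.** The nuclear stain occupies the nucleus only. A transfected
  cell's reporter is partitioned so that nuclear mean / cytoplasmic mean
  equals the cell's sampled true NCR exactly before degradation. Per-cell
  NCRs are log-normal with configurable median and dispersion (default
  dispersion 0.1 on the log scale, a tight but realistic well-to-well
  spread); the transfection fraction defaults to 0.5 so the transfection
  gate is always exercised.
- **Degradation.** Signal plus constant background (100 counts) is blurred
  with a Gaussian PSF (σ = 1 px), then additive Gaussian read noise
  (σ = 5 counts) is applied and intensities are clipped to 16 bits. We
  apply blur before read noise because read noise arises at the detector,
  after the optics; this is the standard fluorescence approximation. No
  photobleaching, vignetting, texture, or 3-D optics.
- **Defaults as study conditions.** 640×640 px wells with 400 planted cells
  (≈200 transfected) and six replicate wells per condition mirror the
  replication scheme of the assay. Magnification, exposure and cell counts
  are not published for the original assay; the defaults above were chosen
  once as plausible high-content-screening values and are all exposed in
  `sim_config()`.

Passing the recovery tests on this simulator shows the chain is correct
*under the simulator's assumptions*; it does not certify performance on real
HeLa images, where shape irregularity, uneven illumination and focal drift
would stress the morphology rules and the background model.

## Segmentation chain and its numerical choices

1. **Enhancement**: a large-window median filter (radius 25 px, well above
   the cell diameter) estimates background; subtraction is clamped at zero.
2. **Foreground detection**: a Gaussian mixture (default 3 components:
   background, dim debris, bright cells) is fitted by EM to per-pixel
   multichannel log-intensities on a deterministic 20 000-pixel subsample
   and then classifies every pixel. A conjugate prior regularises the
   covariances so point masses (e.g. a constant region) cannot produce
   singular components. The lowest-mean component — merged with any
   component within 3 background SDs of it in every channel — is
   background; the rest is foreground. Detection runs on the *raw* channels:
   after background subtraction the background collapses onto a point mass
   at zero, which distorts the mixture, whereas the raw background is a
   clean Gaussian.
3. **Seeds and watershed**: nuclei are local maxima of the smoothed nuclear
   channel (minimum separation 7 px) grown over the Otsu-thresholded
   nuclear mask; cells are grown from the nucleus seeds over the foreground
   mask by seeded region growing on an inverted sum of min-max-normalised
   smoothed channels — both channels jointly shape the topography, so
   boundaries between touching cells fall along the joint intensity
   valleys. Region growing uses a deterministic propagation order, making
   the whole chain reproducible from the seed.
4. **Refinement**: objects violating any morphology bound (cell/nucleus
   area, eccentricity, solidity, nucleus-to-cell area ratio) are removed,
   cell and nucleus together, and labels are renumbered consecutively. The
   bounds are configuration values calibrated on the simulator defaults —
   the original assay's software publishes none. The solidity floor is 0.4:
   watershed fragments of touching cells are legitimately non-convex, and a
   stricter floor discards real cells.

A cell whose reporter is absent (non-transfected) is still detected through
its nucleus, but its "cell" region is essentially the nucleus; such cells
are excluded from NCR statistics by the empty-cytoplasm guard and by the
transfection gate (whole-cell mean reporter above background mean + 3 SD).

## Compartment guards

Compartment means at boundaries carry partial-volume error: blur mixes
nucleus with cytoplasm at the nuclear rim and cytoplasm with background at
the cell edge, and the detected nucleus overshoots the true one by roughly
the PSF width. `quantify_cells()` therefore erodes the nucleus by 2 px for
the nuclear mean and excludes from the cytoplasm a 1-px ring around the
nucleus plus a 2-px ring along the cell/background edge. Each guard falls
back to the unguarded region when it would empty a compartment, so tiny
hand-built objects are measured exactly. With the guards, simulated
condition NCRs are recovered well within the 10% tolerance across the
1.0–3.0 range; without them the wild-type condition is biased upward by
tens of percent.

Cells with cytoplasmic mean at or below ε = 1 intensity unit are excluded
with a reason code rather than capped — unbounded ratios would otherwise
dominate well medians. Wells need 50 usable transfected cells by default
(no published minimum exists); conditions need at least 3 of their 6 wells.

## Clinical statistics

PFS is compared between prediction groups with the Kruskal–Wallis test on
mid-ranks with tie correction, using the chi-square approximation for the
p-value even at n = 12 — what standard software does; an exact Monte Carlo
permutation p-value is one argument away and agrees at this sample size.
Kaplan–Meier curves use the product-limit estimator; the packaged cohort has
no censoring (every patient progressed) but the implementation supports it.
Reported medians are rounded half-up to one decimal. On the packaged cohort
the positive group's median is 5.8 months; the negative group's computed
median is 1.75 (1.8 rounded). A published figure of 1.7 for this group is
not reproducible from the printed one-decimal PFS values — the original
computation presumably used unrounded dates — and we report the computed
value rather than forcing agreement.

```{r cohort}
cohort <- load_cohort()
fit <- survival_by_prediction(cohort, predict_cohort(cohort))
tidy(fit)
glance(fit)
```

## Problem sizes

The recovery tests run the full image chain on 256×256 px wells with 60
cells for unit-level checks, and on the default 640×640 px, 400-cell wells
(six per condition, seven conditions) for the end-to-end recovery check —
sizes at which the per-condition NCR estimate is already dominated by
systematic rasterisation/blur effects rather than sampling noise, so larger
plates would not change the conclusions.

## Known limitations

- Circular-cell geometry; morphology rules calibrated to it.
- The transfection gate is intensity-based; very weakly expressing cells
  fall below it and dim debris above it, which is why counts recover to
  within a few percent rather than exactly.
- In crowded wells, watershed occasionally assigns fragments of a
  transfected neighbour's cytoplasm to a non-transfected cell, letting it
  pass the gate with a near-zero NCR; the per-well median absorbs this.
- Dose-response activity values for the cohort are synthetic encodings with
  the correct qualitative outcomes; only the inhibition calls, not the
  curve shapes, are meaningful.
- Predictions outside the four assayed reporter pathways, and any learning
  from outcomes, are out of scope.
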