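---
title: "astromigr: models, synthetic worlds, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{astromigr: models, synthetic worlds, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromigr)
```

`astromigr` quantifies assays of astrocyte progenitor migration from the
neonatal subventricular zone (SVZ) into the cortex: per-cell marker
colocalization on fluorescence images, implant-centered migration geometry
in organotypic explant cultures, automated migrated-cell counting, a gated
mixed-model inference procedure, and the single-cell RNA-seq QC rules used
alongside the imaging. This vignette explains the models and assumptions,
the synthetic worlds the package tests itself against, and the numerical
decisions a careful user should know about.

## 1. Colocalization scoring

The pipeline ingests a *label mask* (one positive integer per segmented
reporter-positive cell; segmentation itself is out of scope) and a raw
marker channel with a known pixel size. Scoring proceeds in three steps:

1. **Binarize** the marker channel. Default is Otsu's method on a 256-bin
   histogram; a fixed threshold is available for strict reproducibility. A
   constant image has no Otsu threshold: the result is an all-negative mask
   with a warning rather than an error, because an empty channel is a valid
   (if disappointing) observation.
2. **Choose the scored region** by the marker's biology: the whole cell
   (cytoplasmic markers such as BLBP), a membrane ring (glutamate
   transporters GLT1/GLAST, which live on the plasma membrane), or the
   nucleus via a separately segmented DAPI mask (NFIA, Olig2).
3. **Score** each region by its overlap fraction with the binarized marker
   and call it positive iff the fraction is *strictly* greater than the
   threshold (default 0.6). The percentage positive uses reporter-positive
   cells as denominator.

**Donut geometry.** The ring for membrane markers is
`dilate(cell, r_out) \ erode(cell, r_in)` with a disk structuring element
and `r_in = r_out = 2` px by default: a symmetric band around the cell
boundary wide enough to capture membrane staining at typical 40x confocal
sampling (~0.5 um/px), narrow enough not to swallow neighbors. The field
does not standardize this construction, so it is configurable (including a
square element). Two deliberate choices: rings never intrude into *any*
cell's eroded interior (membrane signal over another cell's cytoplasm is
ambiguous and excluded), and ring pixels claimed by several cells go to the
nearest cell by Euclidean distance to the cell's own pixels, ties to the
smaller label. The overlap denominator is the scored region's own area
(ring area for membrane markers) — an interpretation, since "area overlap"
does not name its denominator; it keeps fractions in [0, 1] for every
region kind.

**Alignment.** When the DAPI channel is acquired separately, alignment is
rigid integer translation estimated by FFT cross-correlation
(`register_translation()`), not elastic warping: same-stage acquisitions
differ by a shift to good approximation, and a rigid estimator is exactly
testable (a constructed shift must be recovered identically). The returned
offset is the displacement of `moving` relative to `fixed`; apply its
negation to align.

## 2. Migration geometry

All geometry lives in micrometers with X lateral (parallel to the corpus
callosum) and Y radial (toward the cortex); slices are imaged cortex-up, and
an orientation flag flips the sign convention if not. Displacements are
`d = sqrt((x2-x1)^2 + (y2-y1)^2)` from the implant-site center, with
lateral/radial components as *absolute* axis differences — the printed
formulas square and root each coordinate difference, so direction along an
axis is deliberately not preserved, and `d^2 = lateral^2 + radial^2` holds
to machine precision. Speed is `v = d/t` over the experiment duration.

**White-matter curve.** CC-to-CTX distances are measured from a smooth
curve through operator-marked points along the white matter. The curve is a
cubic smoothing spline parameterized by x (tracts are graph-like in coronal
sections); `smoothing = 0` (or fewer than 4 points) interpolates exactly,
two points give a straight segment. The curve is sampled as a polyline with
vertex spacing at most 1 um (refined by halving until the bound holds), and
distances are exact point-to-segment minima over that polyline, so the
sampling error is bounded by the spacing. The sign is positive on the
cortex side; only positive distances count as CC-to-CTX migration, because
cells still in the white matter have not entered the cortex.

**Counting.** Migrated cells are counted as 8-connected components of the
binarized reporter channel with area at least `min_area_px` (default 20 px
at 1 um/px — a conservative debris filter; no size filter is standardized),
excluding components whose centroid falls inside the implant ROI (default
radius 500 um: half the 1 mm explant punch). Counts are reported per brain
section without area normalization. Components are found via the pixel
adjacency graph (`igraph`); all pixel-level operations are verified against
independent per-pixel brute-force oracles in the test suite.

## 3. Gated statistics

Displacement outcomes are log-transformed (they are positive and
right-skewed) and modelled as

    log(y) ~ treatment + (1 | litter) + (1 | litter:slice)

with control as reference level: litters induce correlation between animals
of the same birth cohort, slices within litter between cells of the same
culture. Per-slice migrated-cell counts use `log(count + 1)` (counts can be
zero) with litter as the sole random effect, since slices are the rows.

**Gatekeeping.** To limit multiplicity, inhibitors are grouped into four
families (NMDAR; AMPAR/KAR; combinations; transporter) that partition the
non-control arms. Each family is tested by a joint F-test of its member
coefficients in the full model (a joint contrast, not a subset refit — both
readings of "compare control to the family" are defensible; the contrast
keeps one model and one error estimate). Only when the family p-value is
below alpha (0.05) are member-level Wald tests reported. No further
multiplicity correction is applied beyond the gate. Under a global null the
per-family gate-open rate is calibrated at ~alpha, and gating can only
remove member-level false positives (the gated rejections are a subset of
the ungated ones) — both properties are verified by simulation in the test
suite.

**Degrees of freedom.** Denominator df use a Satterthwaite-type
approximation implemented in-package: the REML criterion is profiled as a
function of the variance parameters (theta, sigma); their asymptotic
covariance is twice the inverse finite-difference Hessian; for a contrast
`c`, df = 2 (c'Vc)^2 / Var(c'Vc) by the delta method, and multi-df
contrasts combine eigen-contrast dfs. On a balanced paired design this
reproduces the paired t-test (t, df = n-1, p) to numerical precision, which
the tests assert. If the approximation fails numerically (e.g. variance
components at the boundary), the family test falls back to a
likelihood-ratio chi-square from ML refits with the family collapsed into
control, and the method used is recorded per family.

**Singular fits.** If the full random-effects structure is singular or
inadmissible (one observation per slice), the slice effect is dropped
first — slice variance is the least identifiable at small n — then litter
(plain linear model with residual df). Every fallback is recorded on the
fit object.

**Power.** `paired_t_power()` is exact noncentral-t power
(ncp = d*sqrt(n), df = n-1); `paired_t_detectable_effect()` inverts it by
root finding. At alpha 0.05 two-sided and 80% power this gives d = 1.68 at
n = 5 and d = 3.26 at n = 3 pairs.

## 4. Expression QC

Cells are excluded when they express fewer than 200 or more than 5000
unique features or more than 25% mitochondrial counts. All three rules are
strict as worded, so boundary cells (exactly 200, exactly 5000, exactly
25%) are *kept*. Mitochondrial genes are identified by a configurable name
prefix (default `mt-`, the mouse convention). Normalization is
`ln(1 + count/total * 10000)`; per cell `sum(exp(x) - 1) = 10000` exactly,
an identity the tests check to 1e-8 relative error. Cluster markers use a
two-sided Wilcoxon rank-sum test (exact for small tie-free groups, checked
against full enumeration) with Bonferroni adjustment `min(1, p * n_genes)`.
The log2 fold-difference is `log2((mean(expm1(in)) + 1) /
(mean(expm1(out)) + 1))` and the expression fractions are proportions of
cells with nonzero counts — stated conventions, since the upstream suites
do not print their formulas. Clustering, embedding and integration are out
of scope (published tools).

## 5. The synthetic worlds

Each generator emulates the statistical structure the analysis assumes —
not the optics or the biology beyond it.

**Colocalization images** place non-overlapping axis-aligned ellipses
(semi-axes 3-6 px on a 384x384 grid at 0.5 um/px) by rejection sampling
with bounded retries, draw per-cell truth flags Bernoulli(fraction), and
paint marker signal on the flagged cells' ring, interior, or nucleus plus
Gaussian background noise. There is no point-spread function, no 3-D, no
intensity gradient: a green recovery test establishes that the scoring
logic is correct, not that segmentation or optics are handled.

**Time-lapse tracks** draw per-cell speeds Normal(39, 10) um/h truncated at
zero (truncation, not resampling, preserves seed determinism) and move each
cell along a straight line, sampled every 30 min for 2 h. Real progenitors
migrate erratically; the straight-line world makes `v = d/t` recover the
drawn speed exactly, isolating the estimator from path-shape questions.

**Explant experiments** generate log-normal displacements:
`log y = log(baseline) + log(multiplier) + litter + slice + cell` with
independent Gaussian effects per outcome axis. The displacement
distribution shape is not reported anywhere; log-normal is assumed because
the analysis log-transforms — an assumption of this package, not a claim
about the data. Defaults are the reported effects (transporter blocker:
lateral x1.62, counts x10 outside / x6 in cortex; AMPAR blockade: radial
x0.5, x0.6 in combination) on top of chosen-once baselines: lateral 156 um
(a 162% effect reported alongside a 97 um absolute increase implies a
control baseline of 97/0.62), radial 200 um, counts 60/35 per slice. Variances (log-scale SDs 0.15
litter, 0.10 slice, 0.35 cell; 0.25 slice-level count overdispersion) are
typical biological CVs for explant cultures. `slices_per_litter` counts
slices *per treatment arm* within each litter, mirroring the within-litter
design. Counts are Poisson (no count distribution is reported) with
log-normal overdispersion; note that the `log(count+1)` model estimates
`(mu_t + 1)/(mu_c + 1)`, slightly below the true fold at small baselines —
visible as a ~1-2% shrinkage at the default baselines.

**QC matrices** plant cells that violate exactly one rule (features drawn
below 200, above 5000, or mitochondrial fraction lifted to 30-60%) among
cells that pass comfortably, and record who must survive. The matrices test
the QC gate; they do not model expression biology.

All generators are driven by a single explicit integer seed per call with
no global RNG state leakage, and identical seeds give byte-identical
outputs.

## 6. Numerical choices and degenerate inputs

* Coordinates are 0-based (row = Y, column = X); component centroids map
  pixel (1,1) to (0,0) um.
* Otsu on a constant image: all-negative mask + warning. Registration of
  constant images: zero offset + warning.
* `classify_positive` is strict (`>`), so fraction 0.6 is negative.
* Duplicate x in curve points are averaged with a warning; smoothing with
  fewer than 4 points falls back to interpolation.
* A label erased by erosion still gets a ring (dilation minus nothing);
  labels with no pixels in a scored region are dropped with a warning.
* Zero-radius implant ROI warns and excludes nothing.
* Ties in Wilcoxon fall back to the normal approximation; constant genes
  get p = 1 rather than an error.
* Finite-difference steps for the Satterthwaite Hessian/gradients are
  relative (1e-4 of each parameter, floored at 1e-6); failures at variance
  boundaries trigger the recorded LRT fallback.

## 7. Known limitations

* No segmentation, no elastic registration, no 3-D stacks, no PSF: masks
  are inputs and alignment is rigid.
* Lateral/radial distances are absolute values; direction along an axis is
  lost by construction.
* The count model is a log-linear LMM, not a GLMM; at very small baseline
  counts the `+1` pseudocount biases fold estimates toward 1.
* The synthetic explant world is balanced; heavily unbalanced real designs
  will rely more on the Satterthwaite approximation, and at very few
  litters the litter variance is weakly identified (the fallback chain
  then applies).
* Image I/O is plain-text TSV (+JSON sidecar); the in-memory structures,
  not the file format, are the contract.
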