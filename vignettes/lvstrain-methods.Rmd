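---
title: "Perimeter-based circumferential strain analysis: models, phantom and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perimeter-based circumferential strain analysis: models, phantom and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvstrain)
```

## The measurement model

`lvstrain` analyses stacks of closed endocardial contours extracted from
short-axis cine cardiac MR. For a slice with end-diastolic perimeter
$L_0$ and perimeter $L_n$ at frame $n$, the endocardial circumferential
strain is

$$\varepsilon_n = \frac{L_n - L_0}{L_0},$$

a dimensionless quantity that is negative during systole. Perimeters are
polygonal: the contour is an ordered point list in mm and the perimeter is
the sum of segment lengths including the implicit closing segment
(`contour_perimeter()`). Areas are absolute shoelace areas
(`contour_area()`). Both are invariant under rigid motions; perimeter
scales linearly and area quadratically under uniform scaling, which is
what makes the strain metric shape-agnostic: scaling any contour by $k$
yields $\varepsilon = k - 1$ regardless of its shape.

Slices, ordered base to apex, are split into three vertical regions by
`allocate_regions()`: each region receives $\lfloor n/3 \rfloor$ slices
and remainder slices go to the base first, then the mid-ventricle. For
the admissible 6–10 slice stacks every region then holds 2–4 slices. Any
remainder rule satisfying those bounds would be admissible; base-first
was chosen because basal slices are the largest and least affected by
apical truncation, and the rule is deterministic.

Regional strains (BCS, MCS, ACS) are the *peak of the region-averaged
curve*: the per-slice strain curves are averaged frame-wise within the
region, and the minimum (most negative) value of that mean curve is
reported, multiplied by 100. Global strain (GCS) does the same over all
slices. The alternative reading — mean of per-slice peaks — coincides
with ours for synchronous contraction; for dyssynchronous slices the
averaged-curve peak is attenuated towards zero, which we consider the
more physiological summary of a region's net circumferential shortening.
Whether the reported strain should be the temporal peak or the
end-systolic value is a second open choice; we use the peak, and for the
phantom's synchronous motion the two coincide exactly.

Frame 1 is treated as end diastole (cine acquisitions are ECG-gated from
ED). The strain at frame 1 is exactly zero by construction.

## Volumetrics

Cavity volumes are computed from the contours by slice summation:
each slice's enclosed area is extruded over the full inter-slice spacing
(8 mm thickness + 2 mm gap = 10 mm) and summed, `slice_stack_volume()`.
EDV is taken at frame 1 and ESV at the frame with the smallest stack
volume. Derived indices follow their standard definitions:
LVEF $= 100\,(EDV - ESV)/EDV$, ESVi $= ESV/BSA$, BMI $= W/H^2$. BSA
defaults to Du Bois ($0.007184\,W^{0.425}H^{0.725}$) — the dominant
convention for indexing cardiac volumes — with Mosteller
($\sqrt{HW/3600}$) available, since the upstream registries do not state
their formula.

Note that a mean of ratios is not a ratio of means: the LVEF evaluated at
cohort-mean volumes (e.g. `lvef(151.6, 58.7)` $= 61.3$) deliberately does
not match a cohort-mean LVEF near 56; the package always computes LVEF
per subject before averaging.

## The beating-LV phantom

Restricted registry imaging data cannot be redistributed, so validation
uses a parametric phantom, `synthesize_cine()`. It is first-class,
tested code, not a fixture.

* **Geometry.** The cavity is a truncated prolate half-ellipsoid sampled
  at slice mid-planes $z_i = (i - \tfrac12)\Delta$, $\Delta = 10$ mm,
  with the ellipsoid apex at $L = n_\text{slices}\Delta$; the
  cross-sectional radius profile is
  $r(z) = r_0\sqrt{1 - (z/L)^2}$. $r_0$ is sized so that the
  slice-summation volume of the *polygonal* contours equals the
  subject's drawn EDV exactly — so the volume pipeline recovers the EDV
  draw to machine precision when jitter is off.
* **Motion.** Each slice contracts as
  $R_s(t) = R_s(0)\,[1 - c_s\,w(t)]$ where $w$ is a raised-cosine
  activation rising from 0 at ED to 1 at end systole and back to 0 at the
  last frame. End systole sits at 40% of the cycle (a typical systolic
  interval; the acquisition protocol states only the 31.56 ms temporal
  resolution), and 25 frames cover one cycle at roughly 60 bpm. Because
  perimeters scale linearly with radius, the measured peak slice strain
  is exactly $-c_s$ with jitter off — the phantom's ground truth is
  analytic, not simulated.
* **Regions.** $c_s$ is constant within each of the three regions; the
  per-region contraction fractions are drawn per subject from the
  configured regional strain distributions ($c = -\text{strain}/100$).
* **Noise.** Optional iid zero-mean Gaussian jitter (default SD 0.2 mm)
  on every contour point emulates segmentation noise. Jitter inflates
  polyline length slightly (the inflation grows with point count and
  shrinks with segment length), biasing measured strain a few tenths of
  a percentage point towards zero — a real property of polygonal
  perimeters under point noise, visible in feature-tracking pipelines
  too. The default 50 points per contour corresponds to typical clinical
  contour densities (one point per ~3–4 mm of circumference). Jitter
  leaves areas unbiased (the shoelace sum is bilinear in the
  coordinates), so volume recovery is unaffected in expectation.
* **Disease effects.** Unhealthy cells carry their own distribution
  parameters, so disease enters primarily through the configured means
  and SDs (larger EDV, weaker strain). Two explicit modifiers remain
  available for mechanistic experiments: a dilatation factor multiplying
  all ED radii and a regional contraction deficit multiplying one
  region's $c$; both default to no effect.
* **Not modelled.** Through-plane motion (slices are material rings —
  this is what makes the ground truth exact), papillary muscles,
  cross-sectional eccentricity (configurable but defaulting to circular,
  since the strain metric is shape-agnostic), the right ventricle, and
  any joint correlation between EDV, strain and body size (the
  generator defaults to independence; the true joint structure is not
  published). Passing tests therefore demonstrate correctness of the
  *measurement pipeline*, not realism of cardiac mechanics: real data
  add through-plane motion, shape irregularity and spatially correlated
  segmentation error that the phantom deliberately omits.

Subject attributes (age, heart rate, BMI, weight, EDV, regional strains)
are drawn from per-cell normal distributions; the packaged defaults
(`default_distributions()`) reproduce the published cohort
characteristics table for healthy/unhealthy × three age bands. Draws are
truncated to the inclusion ranges (BMI 18.5–30 kg/m², age within its
band) plus wide physiological guards; height is derived from the weight
and BMI draws so the three are exactly consistent.

## Cohort construction

`apply_inclusion_filters()` applies the study's eligibility rules (BMI
18.5–30 kg/m², age 45–74, no diabetes, never-smokers, white British or
Irish background), tagging every exclusion with its first failing rule.
`stratify()` partitions records into the 12 sex × age band × health
cells, where unhealthy means any of the STEMI/NSTEMI/HF flags; age bands
are closed and fractional ages fall in the band containing
$\lfloor\text{age}\rfloor$, matching integer-year reporting.
`select_study_cohort()` randomly samples a fixed number per healthy cell
(default 100) and passes small unhealthy cells through untruncated.

Outlier removal (`remove_outliers()`) uses the ±2.7 SD rule per variable
*within each group*, in a single pass, removing the whole individual.
The within-group scope was chosen because group summaries are the
analysis unit (the pooled-cohort alternative is a one-line config
change); SDs use the $n-1$ denominator throughout. Before the SD rule,
volumes more than 4× their group median are flagged as unphysical
data-entry errors. Zero-SD variables remove nobody and groups under 3
records are skipped with a warning.

## The statistical battery

`run_battery()` reproduces the full inferential procedure:

1. pooled-variance Student's t-tests (not Welch) of all-healthy vs
   all-unhealthy and all-male vs all-female for each of the nine
   variables, at α = 0.05;
2. a one-way ANOVA per variable over the 12 cells, gating the contrasts
   at p ≤ 0.05;
3. the 17 planned contrasts per gated variable. A contrast with weights
   $w$ is tested as $t = \sum_i w_i\bar y_i \big/
   \sqrt{MSE\sum_i w_i^2/n_i}$ with the omnibus pooled MSE and
   within-group df — the classical ANOVA-contrast definition. Lumped
   sides ("all healthy males", …) use equal weights of 1/3 per
   constituent cell, the standard planned-contrast convention (per-cell-n
   weighting is a config option). Significance is judged against the
   *rounded* Bonferroni threshold, $\text{round}(0.05/17, 3) = 0.003$,
   reproducing the study's operational decision rule rather than the
   unrounded quotient (both are available from `bonferroni_alpha()`);
4. Pearson correlations of each variable with age and BSA within the
   four lumped groups, with two-sided t-transform p-values.

Every test also carries a seeded percentile bootstrap 95% CI (1000 case
resamples by default, seeds recorded in the output); parametric p-values
and bootstrap CIs are both emitted, and `pearson_cor()` flags the case
where they disagree. Degenerate inputs are handled explicitly: zero
pooled variance gives $t = 0, p = 1$ (equal means) or an infinite,
flagged statistic (unequal means); constant bootstrap data give a
zero-width CI; per-test errors are recorded per row and never abort the
batch.

## Numerical and design notes

* Contours are stored open (first point not repeated); closure is
  implicit, avoiding double-counting the seam segment. Coordinates live
  in a per-slice 2-D frame — strain and area need no world registration.
* All randomness flows from one master seed through deterministically
  derived per-subject and per-stage substreams; a run is reproducible
  from config + seed alone, and the CLI writes an audit log of seeds and
  counts (including the contour-correction rate, `audit_rate()`).
* Polygonal circle approximations converge to $2\pi r$/$\pi r^2$ from
  below; the slice-summation volume of the midpoint-sampled ellipsoid
  profile is within 2% of the closed form $\tfrac23\pi r_0^2 L$ at
  8 slices and converges as the slice count grows.
* Test problem sizes were chosen to make Monte-Carlo error small
  relative to the asserted bands while keeping the default suite quick:
  parameter recovery uses cohorts of ~190–200 subjects (3-standard-error
  bands), the familywise type-I simulation uses 2000 replicates of a
  12 × 20 null layout, and bootstrap coverage uses 150–200 outer
  replicates at 1000 resamples.

## Known limitations

The phantom's synchronous, through-plane-free motion means dyssynchrony
attenuation and slice-misregistration effects are only exercised by
constructed curve fixtures, not end-to-end. The unhealthy cells' small
sizes (as in the source registry) leave the corresponding contrasts
underpowered — a property of the design, not a defect of the
implementation. Infarct localisation is out of scope: the phantom can
weaken one region, but no claim is made about detecting *which* region
from real data.
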