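# lvstrain

Layer-specific endocardial circumferential strain analysis of short-axis
cardiac cine contours, with a parametric beating left-ventricle phantom,
cohort stratification and the full planned-contrast statistical battery.

## What it is for

Left-ventricular strain complements ejection fraction when assessing
function after myocardial infarction and other cardiovascular disease. This
package implements a perimeter-based, endocardium-specific circumferential
strain metric for short-axis cine contour stacks and everything needed to
study it at cohort scale: for each slice with end-diastolic perimeter
*L₀* and perimeter *Lₙ* at frame *n*,

    εₙ = (Lₙ − L₀) / L₀

Slices (base → apex) are split into base / mid-ventricle / apex regions
(2–4 slices each for 6–10 slice stacks); the regional strains **BCS, MCS,
ACS** are the peaks (most negative values) of the region-averaged strain
curves, and **GCS** averages all slices, all reported in %. Cavity volumes
(EDV, ESV), LVEF, ESVi = ESV/BSA and BMI come from slice-summation of the
contour areas over the 10 mm slice spacing.

Since the clinical imaging data such analyses are built on are
access-restricted, the package ships a tested phantom generator:
truncated-ellipsoid stacks of polygonal contours contracting with a
raised-cosine activation, whose ground-truth strain and volume are known
analytically, plus per-cell attribute distributions for 12 cohort cells
(sex × age band 45–54/55–64/65–74 × healthy/unhealthy). On top sit the
study-style inclusion filters, random cell selection, a ±2.7 SD outlier
rule, and the inferential battery: pooled-variance Student's t-tests,
per-variable one-way ANOVA over the 12 cells gating 17 planned contrasts at
the rounded Bonferroni threshold (0.05/17 → 0.003), percentile bootstrap
CIs, and Pearson correlations with age and BSA.

Intended users: researchers developing or validating strain pipelines,
and anyone needing a reproducible synthetic cohort with known ground truth
for power or methods studies.

## Worked example

```r
library(lvstrain)

# one synthetic subject from the healthy 65-74 female cell
subj  <- sample_subject(all_groups()[5, ], seed = 42)
stack <- synthesize_cine(subj, acquisition_params(n_slices = 8), seed = 7)

strain_analysis(stack)
#> <strain_fit> subject S0001: BCS -32.0%, MCS -22.9%, ACS -40.6%, GCS -30.8%

vol <- volume_indices(stack, height_cm = subj$height, weight_kg = subj$weight)
sprintf("EDV %.1f ml, ESV %.1f ml, LVEF %.1f%%, ESVi %.1f ml/m2",
        vol$EDV, vol$ESV, vol$LVEF, vol$ESVi)
#> "EDV 148.8 ml, ESV 73.8 ml, LVEF 50.4%, ESVi 37.9 ml/m2"
```

The measured MCS of −22.9% sits a few tenths above this subject's
ground-truth mid-region contraction of −23.3% — the expected small
attenuation from the default 0.2 mm segmentation jitter; with
`jitter_sd = 0` the recovery is exact to machine precision, and the
measured EDV matches the subject's 148.8 ml draw exactly.

A whole cohort, end to end (generation → measurement → selection →
outlier removal → statistics):

```r
pipe <- run_pipeline(list(default_n = 20, bootstrap_reps = 200,
                          n_healthy = 15), master_seed = 11)
pipe
#> <lv_pipeline> 240 generated, 210 selected, 4 outliers removed
#> <strain_battery> 18 t-tests, 9 ANOVAs (6 gated in), 102 contrast rows
#> Bonferroni threshold 0.003; 9 contrasts significant:
#>            contrast variable        p
#>    All FH vs All FU      ESV 5.41e-04
#>    All MH vs All MU      EDV 2.06e-03
#>    ...
```

The significant contrasts are where the generator's defaults differ
between cells: unhealthy cells are configured with larger volumes and
weaker strains, so healthy-vs-unhealthy volume and LVEF contrasts light
up, exactly as they should.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/lvstrain.R all --seed 7 --out results_dir
Rscript inst/cli/lvstrain.R stats --in results_dir/subjects.csv --out stats_dir
```

## Package layout

| file | contents |
| --- | --- |
| `R/geometry.R` | contour container, perimeter/area, circle fixtures |
| `R/strain.R` | strain curves, region allocation, BCS/MCS/ACS/GCS |
| `R/volumetrics.R` | slice-summation volumes, LVEF, BSA, ESVi, BMI |
| `R/synthetic.R` | phantom generator and cohort sampling |
| `R/cohort.R` | inclusion filters, stratification, outlier rule, summaries |
| `R/stats.R` | t-tests, ANOVA, 17 planned contrasts, bootstrap, correlations |
| `R/io.R` | JSON-lines contour stacks, CSV tables, config, CLI, pipeline |
| `vignettes/lvstrain-methods.Rmd` | full methods account and design choices |
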