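Package: lvstrain
Title: Layer-Specific Circumferential Strain Analysis of Short-Axis Cardiac Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for endocardial circumferential strain analysis of
    short-axis cardiac cine contour stacks: perimeter-based strain curves,
    apex/mid/base regional decomposition (ACS, MCS, BCS) and global
    circumferential strain, slice-summation ventricular volumetrics (EDV,
    ESV, LVEF, ESVi) with body-size indexing, cohort stratification by sex,
    age band and cardiovascular health status, and the full planned-contrast
    statistical battery (Student's t-tests, one-way ANOVA,
    Bonferroni-corrected planned contrasts with bootstrap confidence
    intervals, Pearson correlations). Includes a parametric beating
    left-ventricle phantom generator producing synthetic cohorts with
    configurable group-level distributions for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
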