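Package: t1gad
Title: Early-Phase Gadolinium Enhancement Analysis with Quantitative T1 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify early-phase gadolinium-based contrast agent
    uptake in the brain from pre- and post-contrast quantitative T1 maps.
    Provides a synthetic cohort generator with a linear generative model of
    regional T1 shortening (delta-T1), a deterministic 3-D brain phantom
    (parcellation labels plus rendered T1 maps and T1-weighted images),
    six-degree-of-freedom rigid registration with a least-squares cost,
    multiscale Frangi vesselness filtering, rule-based segmentation of
    basal-ganglia perivascular spaces and Gaussian-mixture refinement of the
    choroid plexus, regional delta-T1 median summaries, and the statistical
    battery for day/night contrasts (covariate-adjusted ANCOVA, stratified
    age-slope regressions, age-by-scan-time interactions, Mann-Whitney,
    chi-square and pairwise Fisher tests). Volumes are read and written as
    uncompressed NIfTI-1 files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
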