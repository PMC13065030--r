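# t1gad

Early-phase gadolinium enhancement analysis with quantitative T1 mapping.

Within minutes of intravenous injection, gadolinium-based contrast agents
(GBCAs) cross the blood–CSF barrier at the choroid plexus, spread along
perivascular spaces, and exchange with brain interstitial fluid — the influx
limb of the glymphatic system. Because gadolinium shortens T1, the voxelwise
difference of an early post-contrast and a pre-contrast quantitative T1 map,

```
ΔT1 = T1_post − T1_pre   [ms]   (more negative = stronger enhancement)
```

quantifies this uptake. Summarized as per-subject regional medians and
modelled against scan time (day 06:00–17:59 vs night 18:00–05:59) and age,
ΔT1 probes circadian and age-related variation in brain fluid clearance.

`t1gad` is for researchers who want that analysis chain as tested,
reusable R code:

* **synthetic cohort generator** — subject covariates with a realistic
  movement-disorders cohort structure (447 subjects, 307 day / 140 night,
  age ~ truncated N(63, 13.3²)) and a linear generative model of regional
  ΔT1: `ΔT1 = μ_r(period) + β_r(period)·(age − 63) + offsets + N(0, σ_r²)`;
* **3-D brain phantom** — a deterministic parcellation (lobar cortex per
  hemisphere, white matter, cerebellum, basal ganglia with ground-truth
  perivascular tubes, ventricle, choroid plexus) rendered into pre/post
  T1 maps and T1-weighted images, written as NIfTI-1;
* **rigid registration** — 6-DOF least-squares alignment (multi-resolution
  coordinate descent plus simplex polish);
* **Frangi vesselness** — multiscale Hessian tubularity filter for dark
  tubes, scales 1–2 voxels;
* **rule-based segmentation** — histogram standardization → vesselness →
  morphological basal-ganglia mask refinement → mean+1SD threshold →
  hemispheric PVS labels; Gaussian-mixture (EM) refinement of the choroid
  plexus on post-contrast intensities;
* **quantification and statistics** — regional median/IQR summaries;
  covariate-adjusted day/night ANCOVA, period-stratified age slopes,
  age × scan-time interaction, Mann–Whitney, chi-square, and pairwise
  Fisher tests with Bonferroni adjustment.

## Worked example

Simulate the default cohort and test the day/night contrast and age slope
for the cerebral cortex:

```r
library(t1gad)

coh <- simulate_cohort(seed = 1)
nrow(coh)                                   # 447
table(coh$scan_period)                      # day 307, night 140

grp <- ancova_group_pvalue(coh, "cerebral_cortex")
day <- age_slope_by_period(coh, "cerebral_cortex", "day")
round(c(gap = grp$estimate, p = grp$p_value, beta = day$beta), 3)
```

The night-minus-day `gap` estimate fluctuates around the generative +5.5 ms
(daytime enhancement is stronger, i.e. more negative), and `beta` around
the generative −0.47 ms per year of age.

Render a noiseless 64³ phantom and push it through quantification:

```r
lab  <- build_label_volume(phantom_geometry(64))
imgs <- render_t1_pair(lab, default_enhancement("day"), noise_sd = 0)
delta <- compute_delta_t1(imgs$t1_pre, imgs$t1_post)
regional_medians(delta, lab)[c(1, 7, 10), c("region", "n_voxels", "median")]
#>                   region n_voxels median
#> 1        cerebral_cortex    29166 -166.4
#> 7  cerebral_white_matter    27766  -39.3
#> 10        choroid_plexus      200 -869.7
```

The medians reproduce the configured enhancement magnitudes exactly; with
noise and registration in the loop they agree to well under 1 ms. An
end-to-end run (cohort + phantom + registration + segmentation +
quantification + statistics, with a JSON manifest of checksummed
artifacts) is one call:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "run1", phantom_n = 64))
```

## Acceptance script

`scripts/acceptance.R` regenerates the headline numbers from scratch with
your package build: the default cohort's mean age and median contrast
delay; cerebral-cortex, white-matter and choroid-plexus median ΔT1 from
96³ phantom pipelines (day and night conditions, rendering noise 20 ms,
registration and GMM CP segmentation included); and the mean recovered age
slopes over 20 replicate cohorts for four region/period strata.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a `value` and problem size `n` per
quantity and prints a summary to stderr.
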