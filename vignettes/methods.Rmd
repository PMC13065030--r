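---
title: "Quantifying early-phase gadolinium enhancement with t1gad: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early-phase gadolinium enhancement with t1gad: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1gad)
```

## The scientific problem

Gadolinium-based contrast agents (GBCAs) do not cross an intact blood-brain
barrier, but within minutes of intravenous injection they enter the
cerebrospinal fluid at the choroid plexus, distribute along perivascular
spaces, and exchange with interstitial fluid — the influx limb of the
glymphatic clearance system. Because gadolinium shortens the longitudinal
relaxation time T1, a pre-contrast and an early post-contrast quantitative
T1 map measure this uptake voxelwise:

\[
\Delta T_1 = T_1^{\text{post}} - T_1^{\text{pre}} \quad [\text{ms}],
\]

with more negative values indicating stronger enhancement. Summarized as
per-subject regional medians and modelled against scan time (day vs night)
and age, ΔT1 becomes a practical probe of circadian and age-related
variation in brain fluid dynamics.

`t1gad` implements that full analysis chain — rigid pre/post alignment,
rule-based segmentation of basal-ganglia perivascular spaces (PVS) and
choroid plexus (CP), regional ΔT1 quantification, and the statistical
battery — together with two synthetic data generators that make every stage
testable without access to patient data (none are publicly deposited for
this design): a tabular cohort simulator and a deterministic 3-D brain
phantom.

## Tier 1: the synthetic cohort

`sample_cohort()` draws subject covariates with the study's demographic
structure; `simulate_regional_delta_t1()` adds one ΔT1 column (ms) per
analyzed region from a linear generative model:

\[
\Delta T_1^{(r)} = \mu_r(\text{period}) +
\beta_r(\text{period}) \cdot (\text{age} - a_0) +
\text{sex/diagnosis offsets} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_r^2).
\]

Defaults (see `default_generative_params()`) encode the published cohort:

* **Sizes.** 447 subjects: 307 daytime, 140 nighttime. Daytime is
  06:00–17:59 and nighttime 18:00–05:59 (minutes since midnight 360–1079
  vs the complement), the clinical-shift definition used operationally;
  `assign_scan_period()` is a pure function of clock time and partitions
  the day into exactly 720 + 720 minutes.
* **Age.** Truncated normal, mean 63.0 y, SD 13.3 y, support [18, 95].
  Only the mean/SD and median/IQR are reported for the cohort; a truncated
  normal is the least-structured choice matching them while excluding
  implausible ages.
* **Sex and diagnosis.** Sampled per period with the observed
  period-stratified proportions (six diagnosis classes: idiopathic
  Parkinson's disease, essential tremor, multiple system atrophy,
  progressive supranuclear palsy, vascular parkinsonism, other).
* **Scan clock time.** Uniform within each period's window — the
  acquisition-time distribution is unreported, and the analysis only
  consumes the binary period label.
* **Contrast delay.** Lognormal with `meanlog = log(5.9)` and
  `sdlog = (log 6.5 − log 5.5) / (2 z_{0.75}) ≈ 0.124`, matching the
  reported median 5.9 min and IQR 5.5–6.5. It is metadata only, not a
  model covariate.
* **Levels and slopes.** Per region, `mu_day`/`mu_night` are the published
  period-specific medians and `beta_age_day`/`beta_age_night` the published
  per-year regression coefficients, both at reference age `a_0 = 63`.
  Day/night differences enter as period-specific levels, *additive* with
  the age effect: the published interaction tests are all null, so the
  generative default carries no age-by-period product term (slopes may
  still differ by period, which reproduces the reported stratified
  estimates). Whether the true generative form is additive is unknowable
  from the source; this is the parsimonious reading of the null
  interactions.
* **Noise.** `subject_sd` defaults to 22 ms for cortical regions,
  back-derived from the ≈ 29 ms cortical IQR width under normality
  (IQR = 1.349 σ); other regions are scaled the same way from their
  daytime IQR widths (occipital 33, cerebral WM 9, cerebellar WM 11,
  BG PVS 20, CP 108 ms).
* **Sex/diagnosis offsets.** Zero by default — no effect sizes are
  published for them. They exist so that covariate adjustment is genuinely
  exercised when tests set them nonzero.

With `subject_sd = 0` the simulator returns the deterministic linear
predictor exactly, which pins down the estimators: the stratified
regression recovers `beta_age` to machine precision on noiseless cohorts.

## Tier 2: the brain phantom

`build_label_volume()` constructs a deterministic parcellation on a cubic
grid (default 128³ at 1.5 mm; tests use 64³–96³; below 48³ thin structures
no longer fit and the constructor refuses): a cerebral ellipsoid whose
outer 20 % radial shell is cortex, subdivided into four lobes per
hemisphere by angular sectors and split left/right at the mid-sagittal
grid midplane; interior cerebral white matter; a cerebellar ellipsoid
(shell cortex, core white matter); a midline ventricle; choroid-plexus
blobs straddling the posterior ventricle wall; and one basal-ganglia blob
per hemisphere, each containing three tubes of ≈ 1 voxel radius in varied
orientations labelled as ground-truth PVS. The geometry is exactly
mirror-symmetric, so reflecting the volume and swapping left/right codes
reproduces it bit-identically — a free oracle for the hemispheric
bookkeeping.

`render_t1_pair()` assigns plausible 3T pre-contrast T1 values per tissue
(cortex 1400 ms, white matter 850 ms, basal ganglia 1300 ms, CSF 4000 ms,
CP 2200 ms, cerebellar cortex 1350 ms) and renders the post-contrast map as

\[
T_1^{\text{post}} = T_1^{\text{pre}} - m(\text{label}) + N(0, \sigma_n^2),
\]

where `m` is the per-label enhancement magnitude. The default magnitudes
are the period-specific regional medians of the generative model, with the
global cortical magnitude applied to all lobar labels; the basal-ganglia
parenchyma gets a small white-matter-like value and the ventricle none
(neither is a reported region). T1-weighted images are produced by a fixed
monotone decreasing map of T1 (intensity ∝ 1/T1 scaled to [0, 1000] a.u.
between anchors at 600 and 4500 ms), so CSF-filled spaces — ventricle and
PVS tubes — are hypointense, which is the only property the downstream
filters consume. The pre-contrast T1 values are placeholders: nothing
downstream depends on them except through ΔT1, and they must not be read
as acquisition values.

The phantom deliberately omits gyrification, bias fields, partial-volume
averaging, and motion. Two consequences matter for interpreting green
tests. First, tissue boundaries are step edges, so any resampling blurs
them more than it would blur real (band-limited) images; known-transform
registration tests therefore pre-smooth the phantom with a 1–1.5 voxel
Gaussian as a stand-in for partial volume, and at 48³ the least-squares
optimum itself sits up to ≈ 0.2° away from the generating transform — a
property of the data, not the optimizer, which is why recovery properties
are asserted at 64³. Second, the pipeline's default is *not* to inject a
synthetic misalignment before registration: same-session pre/post pairs
are nominally aligned (gross motion was an exclusion criterion in the
emulated study), registration then correctly estimates ≈ identity, and the
sharp-edged thin structures (2-voxel PVS tubes) are not destroyed by an
avoidable double interpolation. Registration *performance* is established
separately by known-transform recovery. Setting
`pipeline_config(misalign_rot=, misalign_trans=)` nonzero exercises the
full displace-and-recover path.

## Rigid registration

`register_rigid()` estimates the 6-parameter rigid-body transform (3
intrinsic x-y-z Euler rotations about the volume center, 3 translations,
all in world mm/degrees) minimizing the mean squared intensity difference
over in-field voxels — the least-squares cost named by the source pipeline,
whose optimizer is unspecified. We use cyclic coordinate descent with
golden-section line searches on a 3-level Gaussian pyramid (smooth σ = 1
voxel, decimate by 2), brackets shrinking from ±10 mm/±10° at the coarsest
level, followed by a short Nelder–Mead polish at full resolution because
coordinate descent converges slowly along coupled rotation–translation
directions. Initialization is the identity; the capture range is
accordingly ±10 mm/±10°, appropriate for same-session pairs. If the final
cost does not improve on the identity the function warns and returns the
identity with status `"no_improvement"` — which is also the expected,
benign outcome when the inputs are already aligned (the identity *is* the
minimum; a pre/post pair differs by contrast, so the floor cost is far
from zero). Transforms serialize as plain-text 4×4 homogeneous matrices;
trilinear interpolation is used for maps and nearest-neighbour is enforced
for label volumes.

## Vesselness and PVS segmentation

`frangi_vesselness()` is the classical Hessian-eigenvalue tubularity
filter. At scale σ the image is convolved with Gaussian-derivative kernels
(reflective boundaries; the sampled kernels are moment-corrected so
polynomials differentiate exactly), the Hessian is scale-normalized by σ²,
and its eigenvalues sorted by magnitude \(|\lambda_1| \le |\lambda_2| \le
|\lambda_3|\) feed

\[
V_\sigma = \left(1 - e^{-R_A^2/2\alpha^2}\right)
e^{-R_B^2/2\beta^2} \left(1 - e^{-S^2/2c^2}\right),
\]

with \(R_A = |\lambda_2|/|\lambda_3|\) (plate vs line),
\(R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}\) (blob),
\(S = \sqrt{\sum \lambda_i^2}\) (structureness), and the output the
voxelwise maximum over scales. Defaults: scales {1, 1.5, 2} voxels — the
stated 1–2 scale range, interpreted in voxels since the phantom is
isotropic and the source does not say otherwise — α = β = 0.5, and `c` per
scale set to half the maximal Frobenius norm over the volume (standard
practice where no constant is given). PVS are *dark* tubes on T1-weighted
images, so the sign condition is the flipped one, λ2 > 0 and λ3 > 0;
inverting the image recovers the classical bright-vessel filter.

`segment_pvs()` chains the published rule-based recipe: histogram
standardization of the T1-weighted image (within-mask empirical CDF to
[0, 1] — bin counts and scope are unspecified in the source, and the exact
CDF is the bin-free limit), vesselness filtering, refinement of the
basal-ganglia mask by binary closing then dilation with a spherical
structuring element (radius 2 voxels by default; unspecified, exposed as a
parameter), thresholding at τ = mean + 1 SD of the in-mask vesselness, and
left/right splitting at the grid midplane (the phantom is
midplane-symmetric; real data would need an anatomical midline, out of
scope). Two conventions are fixed deliberately: the SD is the population
SD (divide by n), and the comparison is strict (`> τ`), which makes the
zero-variance case well defined — constant vesselness yields τ = mean and
an empty mask, with a warning rather than an arbitrary split. τ is
returned alongside the vesselness volume so it is exactly recomputable
from the outputs.

## Choroid plexus refinement

`segment_cp()` refines an initial CP + ventricle mask by a univariate
Gaussian mixture on post-contrast T1-weighted intensities, fitted by EM
(`fit_gmm_1d()`). Initialization is deterministic and quantile-based
(component means at the (k−½)/K quantiles), avoiding seed sensitivity;
variances are floored at 10⁻⁶ of the sample variance with a flag rather
than allowed to collapse; the log-likelihood trace is monotone
non-decreasing up to 10⁻⁹. K = 2 with the higher-mean component returned
as CP is an assumption (the source does not state K or the assignment
rule): early after injection the CP enhances strongly while ventricular
CSF stays dark, so on the post-contrast image the bright component is CP.
If the top-two means are separated by less than half the pooled SD the
function warns but still returns the maximum-posterior assignment.

## Quantification and statistics

`compute_delta_t1()` subtracts registered pre from post, masking voxels
nonpositive in either input. `regional_medians()` reports median and IQR
(linear-interpolation quantiles, a fixed deterministic convention) over
the parcellation regions — cerebral cortex as the union of the eight lobar
labels, each lobe, cerebellar cortex, both white matters — plus the
*segmented* PVS and CP masks in the main path (truth-mask summaries are
available for validation); empty regions are flagged missing, never
reported as zero. Per-subject medians feed the group statistics, the
reading implied by the published tables.

The statistical battery mirrors the published analysis on a
`fit_linear_model()` backbone (QR least squares with Wald t tests;
rank-deficient designs are rejected naming the aliased columns):

* `ancova_group_pvalue()` — ΔT1 ~ period + age + sex + diagnosis,
  treatment coding with day/female/"Other" references (the coding is
  unstated in the source; the period contrast is unaffected), reporting
  the Wald p of the night coefficient, equivalent to a type-III F for a
  two-level factor.
* `age_slope_by_period()` — ΔT1 ~ age + sex + diagnosis within one
  period stratum; β is ms per year of age.
* `interaction_pvalue()` — ΔT1 ~ age × period + sex + diagnosis; Wald p
  of the product term.
* `mann_whitney_u()` — exact enumeration of all rank assignments when
  both samples have ≤ 8 observations, otherwise the normal approximation
  with tie-corrected variance (no continuity correction; the convention is
  unstated in the source and the exact path is oracle-checked).
* `chi_square_pvalue()` — Pearson statistic; the Yates continuity
  correction defaults to on for 2×2 tables, which reproduces the published
  sex comparison (whether the source used it is unstated).
* `fisher_exact_2x2()` / `pairwise_fisher_bonferroni()` — two-sided
  Fisher p by the point-probability method (summing all tables no more
  probable than the observed one, computed via log-factorials), with
  pairwise row comparisons multiplied by the number of pairs. For six
  diagnosis classes that multiplier is 15, which reproduces the published
  post-hoc value ≈ 0.013; the source does not state its multiplier, so
  this reproduction is consistent rather than confirmed.

No multiplicity correction is applied across regions, mirroring the
source, which reports unadjusted and covariate-adjusted p-values only.

## Numerical choices and degenerate inputs

* Gaussian-derivative kernels are truncated at 3.5 σ and moment-corrected;
  eigenvalues of the symmetric 3×3 Hessian come from the closed-form
  trigonometric solver, whose degenerate (repeated-eigenvalue) branch is
  accurate to about √machine-epsilon — tests on separable quadratics
  assert the null eigenvalues at 10⁻⁵, not machine precision.
* Vesselness is forced to zero where the structureness S vanishes
  (including the all-constant volume, where the data-driven `c` would
  otherwise be degenerate).
* Trilinear resampling treats any point inside the voxel-center hull as
  in-field (boundary-inclusive), so an identity transform is an exact
  pass-through; out-of-field voxels become background 0.
* The registration cost is `Inf` if fewer than 10 % of voxels map
  in-field, preventing the optimizer from "improving" the cost by pushing
  the volume out of view.
* CSV/JSON outputs of the pipeline are bit-reproducible given the seed;
  every artifact is checksummed in a JSON manifest.

## Known limitations

The phantom's sharp edges make it *harder* than real data for any
resampling step and *easier* for intensity clustering (CP vs CSF is
cleanly bimodal); Dice thresholds met here do not certify performance on
clinical images. The cohort generator is additive and Gaussian between
subjects — it contains no medication, sleep, or circadian-phase structure
beyond the binary day/night label, so a green parameter-recovery test
establishes estimator correctness, not the biology. Whether the Frangi
scales of the source are voxels or millimetres, and whether its filter ran
on pre- or post-contrast images, are unstated; this implementation assumes
voxels and pre-contrast. Registration here is strictly rigid with a
least-squares cost; affine or mutual-information alignment, brain
extraction, and deep-learning segmentation (the source's nnU-Net stage,
which requires trained weights and GPUs) are out of scope — the classical
rule-based algorithms implemented here are the procedures that *generated*
that model's training labels.
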