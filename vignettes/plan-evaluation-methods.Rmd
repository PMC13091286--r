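---
title: "Methods: DVH goal scoring, radiobiological models and workflow simulation for DL breast radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plan evaluation and workflow simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breastplanr)
```

# The problem

Deep-learning (DL) segmentation and DL dose-prediction models can produce a
left-sided breast treatment plan with essentially no human interaction. The
clinical question is not whether such a plan *can* be made, but how often it
is acceptable without manual edits, and how much staff time an automated
workflow saves when the plans that do need edits are routed through
increasingly expensive correction branches. `breastplanr` implements the
full evaluation chain for that question: dose/structure containers, DVH
clinical-goal scoring, an EUD-based tumour control probability (TCP), a
panel of linear excess-risk estimates for late effects, contour-similarity
metrics between clinical and DL segmentations, the route-decision rules and
workflow time model, and a paired nonparametric comparison chain — plus a
synthetic-cohort generator so every stage is testable without patient data.

Four plan setups per patient are compared throughout, named by their
structure source and plan source: `CS_CP` (clinical structures, clinically
approved plan — the gold standard), `DLS_DLP` (fully automated), `CS_DLP`
(DL plan on clinical structures) and `PS_DLP` (DL plan after correcting
only the DL target contour). All DVH metrics are always evaluated on the
*reference* structures regardless of which structures fed planning; the
planning structures influence only the dose.

# Dose model and DVH metrics

A `dose_grid` is an axis-aligned voxel field of absorbed dose (Gy) with
per-axis spacing in mm; a `struct_mask` is a boolean field on the same
geometry. A voxel belongs to a structure iff its centre is inside it, and
all metrics are voxel-centre based. Cross-volume operations require
alignment of shape, spacing and origin to within $10^{-6}$ mm; resampling
between mismatched grids is deliberately an error, never silent
interpolation. Volumes read and write as NIfTI (`.nii`, `.nii.gz`) or
uncompressed MetaImage (`.mha`/`.mhd`), masks as 8-bit 0/1.

The cumulative DVH is computed on uniform bin edges (default width
0.01 Gy = 1 cGy, matching treatment-planning-system reporting precision):
`cum_volume(d)` is the fraction of structure voxels with dose $\ge d$.
`d_mean()` is always the exact voxel mean, never re-derived from the
binned curve; `d_percent(curve, p)` (e.g. D98, D2) interpolates linearly
between the bracketing bin edges. Both conventions agree with voxel
percentiles to within one bin width, which is also the guarantee the test
suite enforces against a sort-based oracle.

The six clinical goals of the 40.05 Gy / 15-fraction protocol are, with
inclusive comparisons at every threshold:

| structure   | metric  | goal                                  |
|-------------|---------|---------------------------------------|
| PTVp-Skin05 | D_mean  | 39.65 Gy (99%) – 40.45 Gy (101%)      |
| PTVp-Skin05 | D_98    | ≥ 38.05 Gy (95%)                      |
| PTVp-Skin05 | D_2     | ≤ 42.85 Gy (107%)                     |
| Lungs       | D_mean  | ≤ 6 Gy                                |
| Heart       | D_mean  | ≤ 3 Gy                                |
| Breast CL   | D_mean  | ≤ 1 Gy                                |

The goal count (0–6) per plan is the plan-performance indicator and the
sole input to workflow routing.

# Radiobiological models

## TCP

The TCP uses the equivalent-uniform-dose (EUD) logistic model
$$\mathrm{TCP} = \frac{1}{1 + (\mathrm{TCD}_{50}/\mathrm{EUD})^{4\gamma_{50}}},
\qquad \mathrm{EUD} = \Big(\sum_i v_i D_i^a\Big)^{1/a},$$
with the differential DVH $(v_i, D_i)$ taken at bin midpoints. For
negative $a$ (tumours), bin doses below $\varepsilon = 10^{-3}$ Gy are
clamped to $\varepsilon$, so any cold volume drives the EUD — and hence
the TCP — towards zero without a division by zero.

Default parameters (`tcp_params()`): $a = -7.2$, $\mathrm{TCD}_{50} =
28.3$ Gy, $\gamma_{50} = 2.0$, $\alpha/\beta = 10$ Gy. These are
representative breast-adenocarcinoma values from the EUD-TCP literature,
referenced to 2 Gy per fraction; they are configuration entries, not
constants, and should be treated as reference-derived defaults rather than
clinically validated numbers. Because the protocol delivers 15 × 2.67 Gy,
the default parameter set enables the per-bin linear-quadratic conversion
to 2-Gy-equivalent dose before the EUD is formed,
$$\mathrm{EQD2}(D) = D\,\frac{D/n + \alpha/\beta}{2 + \alpha/\beta},$$
which leaves 2 Gy-per-fraction doses untouched and is required for the
absolute TCP scale to be meaningful under hypofractionation. The flag
`eqd2_enabled` exposes the choice; with it off, the same physical dose is
scored against the 2-Gy-referenced response curve directly. Either way the
same model is applied to all four setups, so relative comparisons are
unaffected by the choice — only the absolute scale moves.

## Excess-risk panel

Late effects are scored with linear no-threshold excess-risk models:
$$\mathrm{risk}\,[\%] = \mathrm{baseline}\,[\%] \times
\mathrm{ERR/Gy} \times \bar{D}_{\mathrm{organ}}\,[\mathrm{Gy}].$$
Three endpoints are evaluated, each for patients with and without the
relevant risk factor (pre-existing cardiac risk factors for the coronary
endpoint, smoking for the mortality endpoints) — six estimates per plan:

| endpoint                        | organ | ERR/Gy | baseline with / without RF |
|---------------------------------|-------|--------|----------------------------|
| acute coronary events           | heart | 0.074  | 8.6% / 4.9%                |
| cardiac-disease mortality       | heart | 0.041  | 8.9% / 2.2%                |
| secondary lung-cancer mortality | lungs | 0.110  | 9.1% / 0.4%                |

The ERR coefficients are the published epidemiological slopes per Gy of
mean organ dose; the baseline lifetime risks are representative population
values chosen once so the model reproduces published excess-risk
magnitudes at typical breast-plan organ doses. All five numbers per
endpoint live in the configuration (`risk_model()`) and are echoed into
every report. Risk estimates are linear and zero-anchored by construction;
they never enter route decisions.

# Contour-similarity metrics

Comparisons between clinical and DL segmentations use three metrics with
one consistent surface convention: a member voxel is a *surface voxel* iff
at least one of its six face-neighbours is a non-member or lies outside
the array (so array-edge members count as surface; masks are expected
padded), and surfaces are represented by voxel centres with anisotropic
spacing respected in mm.

* **VDSC** — volumetric Dice, $2|A \cap B|/(|A|+|B|)$ over voxel counts.
* **SDSC(τ)** — surface Dice: the fraction of both surfaces lying within
  τ mm (default 3) of the other surface.
* **HD95** — the maximum of the two directed 95th-percentile
  nearest-surface distances, percentiles by linear interpolation between
  order statistics. The max-of-directed form (rather than pooling all
  distances) is the package's convention; it is symmetric and never
  smaller than the pooled variant.

The implementation uses vectorised nearest-neighbour search; the test
suite verifies it against an explicit $O(n^2)$ pairwise brute force to
$10^{-9}$ mm on randomly generated mask pairs.

# Workflow routing and the time model

Route decision rules, applied per patient from goal counts only:
route **A** if the fully automated plan meets all six goals; otherwise
**B** if the target-corrected plan meets all six; otherwise **C**. Route
D (unedited structures, manually optimised plan) cannot be distinguished
from C retrospectively, so C's times are used as the worst case and D
exists only in the time table for what-if reporting.

Per-plan time estimates (minutes of hands-on time, hours of between-steps
working time): current workflow 85 min / 37 h; A 20 / 16; B 25 / 24;
C 75 / 36; D 70 / 36. The average saving per patient is the difference
between the current workflow's times and the route-count-weighted mean.
With the route split 43/26/32 over 101 patients this gives 46.3 min and
12.6 h exactly (the package reports the exact rational values; rounded
figures in clinical summaries are 45 min and 12 h).

## Statistics

Differences between setups are tested per metric with a fixed chain:
Shapiro–Wilk on all pairwise differences (reported descriptively — the
chain always proceeds nonparametrically, mirroring the practice for these
heavily tied, skewed metrics), then the Friedman omnibus over the four
paired columns, then — only if the omnibus p < α (default 0.05) — all six
pairwise Wilcoxon signed-rank tests with Bonferroni correction
$p_{\mathrm{adj}} = \min(1, 6p)$. The Bonferroni family is the six setup
pairs within one metric; the family size is configurable.

Both tests are implemented in-package with explicit conventions: Friedman
uses per-block mid-ranks and the statistic
$\frac{12n}{k(k+1)}\sum_j(\bar R_j - \frac{k+1}{2})^2$ with the χ²(k−1)
approximation, switching to the exact permutation null (dynamic
programming over column rank-sum vectors) for n ≤ 8 tie-free blocks;
Wilcoxon drops zero differences, mid-ranks ties, and uses the exact
sign-flip null (a generating-function convolution over doubled ranks,
valid with ties) for n ≤ 25, else the normal approximation with
tie-corrected variance and no continuity correction. The exact nulls are
verified in the tests against full enumeration ($24^3$ orderings, $2^n$
sign flips); the χ² approximation deviates from the exact Friedman null
by up to a few hundredths at n = 8 — a property of the approximation's
discreteness, worth knowing when n is small.

# The synthetic cohort generator

No patient data ship with the package; the generator produces virtual
patients with the statistical structure of a clinical left-breast cohort
so that every downstream stage can be exercised and calibrated. It is a
statistical emulator, not a physics simulation.

## DVH-level mode (default, fast)

Each of the six goal metrics per setup has a configured
(Q1, median, Q3) triple. Draws use a quantile-kink ("split normal")
family — $Q(u) = m + \sigma_{\mathrm{lo}}\Phi^{-1}(u)$ below the median
and $\sigma_{\mathrm{hi}}$ above, log-space for the strictly positive OAR
mean doses — so the configured median and quartiles are matched *exactly*
by construction; recovery at n = 2000 is part of the acceptance suite.
Cohort tables print at 0.1 Gy, which would make some PTV triples
degenerate; the defaults therefore use sub-rounding widths consistent
with the printed cells (e.g. 40.40 (40.37–40.43) for the DL plans' PTV
mean dose).

Correlation uses a Gaussian copula with a product structure: the same
metric in two setups of one patient correlates at `rho_setup` (default
0.9 — the four plans share one anatomy), two different metrics of one
plan at `rho_metric` (default 0.4 — plan quality is shared across
metrics), and cross terms at their product. Marginals are unaffected by
the copula, so calibration and correlation can be chosen independently.

A configurable fraction (default 0.23) of patients carries a *clinically
relevant DL target defect*: their fully automated plan receives a
cold-spot mixture component (volume fraction U(0.03, 0.18) at a dose
U(14, 28) Gy below the plateau), which is absent again in `PS_DLP` —
correcting the target contour removes the defect. The severity range was
fixed once so that the emergent automated-setup TCP panel shows the
intended clinical picture (roughly a quarter of plans below 95% TCP and
a setup mean TCP near 82% despite a high median); it also drags D98 below
its goal for most defect plans. PTV DVH curves are reconstructed from the
sampled (D_mean, D98, D2) — a split-normal bulk whose mode is solved so
the mean matches, plus the cold component — and TCP, goals and risks are
then evaluated from those curves, so every reported number is internally
consistent with the curve the TCP sees.

## Voxel-level mode (slow, small n)

A voxel phantom of left-breast anatomy is built from ellipsoids: torso,
both breast bulges (body = union), carved lungs and heart, CTV = whole
ipsilateral breast, and PTV = CTV expanded 5 mm, kept strictly more than
5 mm from non-body voxels and carved off the OARs. Doses are painted as a
plateau inside the PTV with band-limited multiplicative Gaussian
heterogeneity and exponential distance falloff (decay length 12 mm)
outside, then calibrated exactly: a global scale fixes the PTV mean, and
per-organ scales fix each requested OAR mean (this per-organ scaling is a
deliberate emulator shortcut — a single physical field cannot hit
arbitrary independent organ means). Cold spots are spheres sized from the
requested volume fraction with a 5 mm edge ramp.

DL-vs-clinical contour differences are emulated by `perturb_mask()`: the
perturbed mask is the sublevel set $\mathrm{sdf}(x) \le A\,\eta(x)$ of
the signed distance field, with band-limited unit-variance noise η
(coarse-lattice white noise, trilinearly interpolated; correlation length
tied to the HD95 target) and amplitude A solved by bisection on the
measured VDSC (tolerance 0.005). VDSC targets are therefore hit to well
within ±0.02; HD95 emerges approximately and *floors at about one voxel
pitch* — a 1.2 mm HD95 target is unreachable on a 5 mm grid, which the
per-structure results table makes visible rather than hiding.

## What the generator does not emulate

No beam/fluence physics, no realistic CT anatomy or inter-patient shape
variation beyond a global scale factor, no DL-model behaviour beyond
statistical mimicry, and no joint distribution of goal failures beyond
the copula above. Passing tests demonstrate that the *evaluation chain*
is correct and that the generator is calibrated to its configured
targets; they are not evidence about any real patient cohort.

# Numerical choices and problem sizes

* DVH bin width: 0.01 Gy for voxel DVHs, 0.02 Gy for reconstructed
  curves (narrow CS-CP goal margins sit ~0.05 Gy from thresholds, so
  coarser bins would blur goal decisions).
* EUD cold clamp $10^{-3}$ Gy; EUD computed in log space for stability at
  large |a|.
* Alignment tolerance $10^{-6}$ mm; surface-Dice tolerance comparisons
  absorb $10^{-9}$ mm of floating-point noise.
* Euclidean distance transforms use the exact separable parabola-envelope
  algorithm with anisotropic spacing, in plain R; a 65×52×77 grid (5 mm
  phantom) transforms in under a second.
* Tests run phantoms at 5–8 mm spacing and the sampler at n ≤ 2000;
  voxel-level cohort tests use n = 2. These sizes were chosen as the
  smallest that exercise every code path with stable statistics.
* Ties in the Friedman exact path fall back to the χ² approximation
  (mid-rank permutation nulls are not exchangeable block-wise);
  quantile interpolation is type 7 everywhere.

# Known limitations

* TCP/NTCP parameter defaults are reference-derived, not fitted to any
  cohort; absolute TCP values should be read comparatively.
* The DICOM-RT import adapter is out of scope; convert RTDOSE/RTSTRUCT
  to NIfTI or MetaImage upstream.
* Differential DVHs, absolute-volume goals, mesh-based surfaces,
  added-path-length and mean-surface-distance metrics are not
  implemented.
* Route D is never auto-assigned; retrospective goal counts cannot
  distinguish it from C.
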