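# breastplanr

Plan evaluation and workflow simulation for deep-learning (DL) breast
radiotherapy.

For left-sided breast cancer, DL segmentation plus DL dose prediction can
produce a treatment plan with almost no human interaction. The question a
physics group then faces is operational: **how often is the automated plan
clinically acceptable as-is, which patients need which kind of manual
correction, and how much staff time does the automated workflow save?**
`breastplanr` implements the evaluation chain for that question:

* **Dose/structure containers and IO** — axis-aligned dose grids and binary
  structure masks (NIfTI and uncompressed MetaImage), strict geometric
  alignment checks.
* **DVH goal scoring** — cumulative DVHs, exact `D_mean`, interpolated
  `D_98`/`D_2`, and the six clinical goals of the 40.05 Gy / 15-fraction
  protocol (PTV 39.65 ≤ D_mean ≤ 40.45 Gy, D_98 ≥ 38.05 Gy,
  D_2 ≤ 42.85 Gy; mean dose ≤ 6 / 3 / 1 Gy for lungs, heart,
  contralateral breast).
* **Radiobiology** — EUD-based TCP,
  `TCP = 1 / (1 + (TCD50/EUD)^(4·γ50))` with
  `EUD = (Σ v_i D_i^a)^(1/a)` and optional per-bin EQD2 conversion, and a
  six-entry linear excess-risk panel
  (`risk % = baseline % × ERR/Gy × mean organ dose`) for acute coronary
  events, cardiac mortality and secondary lung-cancer mortality, each
  with/without risk factor.
* **Contour similarity** — volumetric Dice, surface Dice at 3 mm and HD95
  between clinical and DL segmentations, voxel-centre surfaces under
  6-connectivity, verified against pairwise brute force.
* **Workflow routing** — the decision rules (route A if the fully
  automated plan meets all six goals, B if correcting only the target
  contour suffices, C/D otherwise), per-route time estimates, and the
  average per-patient time saving.
* **Statistics** — Shapiro-Wilk gate, Friedman omnibus (exact permutation
  null for small tie-free samples), pairwise Wilcoxon signed-rank with
  Bonferroni correction.
* **Synthetic cohort** — a generator of virtual patients (voxel phantoms,
  plan-like dose fields, contour perturbations, or a fast DVH-level
  sampler with quantile-matched marginals and a configurable
  "clinically relevant DL target defect" subpopulation) so the whole
  pipeline runs and calibrates without any patient data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
101-patient cohort; each is a thin driver over the package functions.

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_goal_scoring.R
Rscript analysis/04_routes_and_times.R
```

`02_goal_scoring.R` prints the cohort audit table (medians with
quartiles, and goal-pass rates per setup):

```
patients meeting at least k of the six goals [%]:
      goals CS_CP DLS_DLP CS_DLP PS_DLP
 ≥6/6 goals    91      40     67     63
 ≥5/6 goals    99      69     94     97
```

i.e. the fully automated setup (DLS-DLP) met all six clinical goals in
40% of the simulated patients against 91% for the clinically approved
gold standard — the automated plans that fail do so almost always on the
target-coverage goal (D_98), driven by the simulated DL target-contour
defects. `03_radbio_panel.R` shows the radiobiological consequence: 25%
of automated plans fall below 95% TCP (mean TCP 81.7% against a 96.3%
median), while excess-risk differences between setups stay at the 0.1%
level. `04_routes_and_times.R` turns goal counts into workflow routes and
time savings:

```
clinical route split 43/26/32 of 101:
  active-time saving 46.3 min/patient, inter-step saving 12.6 h/patient

simulated cohort routes: A=40, B=28, C/D=33 (n=101)
  active-time saving 45.6 min/patient, inter-step saving 12.2 h/patient
```

The first block is the exact arithmetic for a clinically observed route
split (85 min / 37 h current workflow versus 20/16, 25/24 and 75/36 for
routes A, B and C); the second is the same computation on the simulated
cohort's own routing.

Programmatic use mirrors the scripts:

```r
library(breastplanr)
co <- generate_cohort(cohort_config(n_patients = 101, seed = 1))
s  <- summarize_cohort(co$evals)
render_summary(s)$dvh          # median (Q1-Q3) table per setup
s$route_counts                 # A / B / C
s$time_saving                  # minutes and hours saved per patient
```

Volumetric workflows use the same functions on real data: read a dose and
masks with `read_volume()`, evaluate with `plan_metrics()`, compare
contours with `compare_masks()`.

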