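---
title: "Evaluating online-adaptive versus scheduled radiotherapy plans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating online-adaptive versus scheduled radiotherapy plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In online-adaptive radiotherapy (ART) the treatment plan is re-optimized on
each day's imaged anatomy before delivery; in image-guided radiotherapy
(IGRT) the original ("scheduled") plan is delivered after positioning only.
For pelvic targets — cervix and uterus in particular — the clinical target
volume (CTV) deforms substantially between fractions, so the scheduled plan
may underdose the target of the day while the adapted plan, by
construction, conforms to it. Adaptation is expensive (machine time, an
interprofessional team online for every fraction), so two questions matter:

1. How much target coverage does the scheduled plan actually lose per
   fraction and over an accumulated series, as a function of the PTV
   margin?
2. Can a patient who needs adaptation be identified *offline*, from the
   scheduled plan's daily dosimetry, early in the course?

`adaptidose` implements the full evaluation chain for these questions and a
seeded simulator that generates treatment series with the relevant
statistical structure, so every stage is testable without clinical data.

## Dosimetric model

Coverage of a structure with voxel doses $d_i$ and volume fractions $v_i$
is summarized by dose-volume histogram (DVH) endpoints — D95/D98/D99
(dose covering x% of the volume), V95/V100 (volume receiving at least x%
of the prescription), the minimum dose — and by the generalized equivalent
uniform dose

$$\mathrm{gEUD}(a) = \Big(\sum_i v_i\, d_i^{\,a}\Big)^{1/a},$$

with exponent $a = -20$ for targets: large negative $a$ makes the gEUD
track cold spots, the clinically limiting feature of target coverage. For
serial organs at risk a positive exponent (hot-spot weighting) is
conventional; the bladder/rectum exponent here defaults to $a = +8$ as a
configurable assumption, not an established value.

Per-fraction metrics are expressed as percentage deviations from the
planning reference: the same metric evaluated for the undeformed CTV under
the reference plan,

$$\%X_i = 100\,\frac{X(\text{plan}_i,\ \mathrm{iCTV}_i) - X(\text{ref},\ \mathrm{CTV})}{X(\text{ref},\ \mathrm{CTV})},$$

where iCTV is the deformed CTV of fraction $i$. The *adaptation gain* of a
fraction is the difference of the adapted-plan and scheduled-plan
deviations. Series-level coverage uses deformable dose accumulation: each
fraction's dose is pulled back to the reference frame through the
fraction's displacement field and summed voxel-wise.

The offline switching rule monitors scheduled-plan target gEUD deviations
sequentially: a fraction with a deviation strictly below −7% is a
violation; the series is flagged for a switch from IGRT to ART when the
second violation occurs within the first 9 fractions, or when violations
thereafter exceed 20% of fractions.

## Numerical choices

* **Grids.** Arrays are stored `[x, y, z]` with x fastest (the same
  fastest-axis-first order as the NRRD files) and 1-based voxel indices;
  voxel centers sit at `origin + (index - 1) * spacing` in mm. Grid
  geometry equality is tested at 1e-6 mm to absorb float round-trips.
  Fractions are numbered from 1, following clinical usage.
* **DVH.** Uniform bins of width 0.1% of the prescription cover
  `[0, max dose]`; the differential histogram assigns voxels to bins, but
  the cumulative curve is evaluated *exactly* from the voxel doses at
  every bin edge, so Dx%/Vx% queries interpolate a curve with no in-bin
  placement error at the edges. Dx% is the largest dose whose cumulative
  volume fraction is at least x/100, linearly interpolated and clamped
  into the realized dose range (the interpolation inside the hottest and
  coldest bins can otherwise overshoot by up to one bin width). For the
  same reason `endpoints()` clamps Dx values from below at the exact voxel
  minimum, keeping `min_dose <= d99 <= d98 <= d95` exactly.
* **gEUD.** Computed from the differential DVH with bin-midpoint doses
  (midpoints of the extreme occupied bins clamped into
  `[min_dose, max_dose]`); a voxel-exact mode (`geud(list(d=, v=), a)`)
  exists for analytic tests. The dominant dose is factored out before
  exponentiation, so exponents down to −200 and beyond are stable. The
  limit conventions: `a = 0` is an error (the geometric-mean limit is not
  used anywhere in this analysis), and a zero-dose voxel with `a < 0`
  returns the mathematical limit 0 with a warning rather than an error,
  which keeps the function total on degenerate synthetic inputs.
* **Margin expansion.** A voxel joins the expanded structure iff its
  center lies within the margin of some source-voxel center. This is
  evaluated through an exact anisotropic Euclidean distance transform
  (separable squared-distance minimisation with a cap radius), written
  in-package because no installed R package provides a 3D anisotropic
  EDT.
* **Dose mapping.** Pull-back only: `dose_ref(x) = dose_fx(x + v(x))`
  with trilinear interpolation; the displacement field lives on the
  reference grid and points from reference to fraction frame. Mapped
  points outside the fraction grid contribute 0 Gy and are counted, never
  silently extrapolated. Accumulation resamples the reference frame to
  1 mm by default (configurable; the package's own cohort runs use the
  native simulation spacing).
* **Percentiles.** Deviation spreads are reported as the empirical
  5th–95th percentile interval with linear interpolation between order
  statistics (R quantile type 7). The reported "90% interval" is a
  percentile range of the per-fraction distribution, *not* a confidence
  interval of the median; a bootstrap CI of the median is available as an
  option. The percentile reading was chosen because such intervals track
  the spread of the per-fraction ECDF, which is the quantity the
  monitoring rule consumes.
* **Switching rule.** Violation comparison is strict (`< cutpoint`).
  "Violations in more than 20% of fractions thereafter" is read as a
  running proportion over *all* fractions observed so far, re-tested
  after each fraction beyond the early window — the simplest auditable
  reading; the alternative scope (violations among post-window fractions
  only) is exposed as `late_scope = "post_window"`. If both triggers
  would fire at the same fraction, the early-violation trigger is
  reported.
* **Statistics.** Paired comparisons use the Wilcoxon signed rank test
  (zero differences discarded; exact null distribution for n ≤ 25
  computed by convolution over doubled ranks, which stays exact under
  tied magnitudes; normal approximation with continuity and tie
  correction otherwise), independent comparisons the Mann-Whitney test,
  multi-group comparisons the Kruskal-Wallis test, association the
  Pearson correlation with t-based p-values, and trend displays ordinary
  least squares with 95% confidence and prediction bands. Two-sided
  p-values double the smaller tail, capped at 1.

## What the simulator emulates — and what it does not

`sim_config()`/`simulate_series()` generate: a reference dose equal to the
fraction prescription inside the PTV with a sigmoidal penumbra
$Rx/(1+\exp(d/s - 3))$ in the Euclidean distance $d$ outside (truncated to
zero beyond $15s$); per-fraction anatomy displaced by a rigid translation
(per-axis normal, SD `drift_sd_mm`) plus a smooth single-mode sinusoidal
elastic field of amplitude `deform_amp_mm`; a scheduled dose fixed in the
reference frame; and an adapted dose *recomputed* conformally to the
deformed target's PTV. Organ-at-risk surrogates (a bladder-like ellipsoid
anterior, an elongated rectum-like ellipsoid posterior) move coherently
with the target.

Defaults are fixed once: 64^3 voxels at 2 mm (series generation and
cohort evaluation; the standalone accumulation API defaults to 1 mm
resampling), CTV semi-axes (25, 20, 20) mm, 6 fractions of 2 Gy (series
of at least 5 fractions at 1.8–2 Gy per fraction are the relevant
regime), penumbra scale 4 mm (≈5%/mm falloff), drift SD 5 mm and elastic
amplitude 3 mm (the scale of reported cervix/uterus interfractional
motion; no authoritative value exists for this setting), PTV margin 5 mm
with 0 mm as the studied limit, edit-class sampling weights 25/22/11/2
and adaptive-delivery probability 45/61 mirroring a realistic cohort mix.

The simulator is *not* a treatment planning system: the adapted plan is a
re-conformation surrogate, not a re-optimization, so adapted-plan
deviations are exactly zero up to grid effects rather than scattered
within a few percent of zero; there is no imaging noise, no
segmentation/contouring error, no intrafraction motion, no dose
calculation heterogeneity, and the elastic model is a smooth global mode,
not biomechanics. Passing tests therefore demonstrate the *machinery*
(metrics, normalization, accumulation, rule logic) and the *direction* of
the margin-dependence effects, not clinical effect sizes. The inverse of
the forward deformation is approximated to first order when warping masks
(`x - t - e(x)`), which is accurate for the small, smooth fields used
here but would bias strongly curved fields.

## Design decisions that were genuinely open

* **Adapted dose as re-conformation.** Re-optimizing a plan per fraction
  is out of scope; recomputing the conformal dose around the deformed
  target preserves the property that matters for the analysis — the
  adapted dose conforms to the anatomy of the day.
* **Margin comparisons on matched draws.** A series' deformation sequence
  depends only on the seed and fraction count, not on the margin, so
  cohorts with 5 mm and 0 mm margins can be compared fraction by fraction
  on identical anatomies.
* **V95/V100 thresholds** use the fraction prescription for per-fraction
  plans (plans are normalized per fraction); accumulated doses use the
  series-total prescription.
* **Absent adapted doses** (IGRT-only fractions) are represented as
  missing, not as zero grids — zero dose is a legal value; deviation
  tables carry `NA` for those fractions.
* **Edit-class tallies** accept an explicit denominator because graded
  series can contain fractions without a grading; percentages are
  reported at 1 decimal.

## Problem sizes

Unit tests run on 8^3–48^3 grids; cohort-level checks use 10 series of 6
fractions on 64^3 grids at 2 mm with accumulation at the native 2 mm
(about 4 minutes on one core), which is where the directional effects are
comfortably resolved. The bundled acceptance script
(`scripts/acceptance.R`) uses the same cohort sizes.

## Known limitations

DICOM-RT import is not implemented (NRRD + JSON manifests only; a future
adapter could map RTDOSE/RTSTRUCT onto the same containers). Grids must
be axis-aligned and regular. Displacement fields are inputs (or
synthetic); no deformable registration is performed. OAR gEUD exponents
default to an assumed value. The statistics module reports unadjusted
p-values; no multiplicity correction is applied.
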