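---
title: "Exemplar-based nodule characterization and inter-observer agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exemplar-based nodule characterization and inter-observer agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulesig)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic
phantoms do and do not emulate, and the numerical and design choices made
where the design was genuinely open.

## The pipeline

A nodule is characterized in four stages.

**Segmentation.** Semi-automatic segmentation is modelled as dual-threshold
seed-voxel region growing: the maximal connected component (6- or
26-connectivity, default 26) of voxels with attenuation in
`[hu_low, hu_high]` that contains the seed, clipped to an axis-aligned
volume-of-interest box around the seed. The published workflow this
emulates names the mechanism but not the growing criterion, so the fixed
dual threshold is an explicit assumption; the defaults (−750 HU, 200 HU)
bracket ground-glass through solid soft tissue while excluding aerated
lung and bone. Manual border adjustment is modelled by two scripted
primitives — an eraser sphere (closed ball on voxel centres; radius 0
removes at most one voxel) and an exclusion half-space (strict side of a
plane; voxels on the plane survive) — applied in order, each only
removing voxels. A `segmentation_session` records seed, parameters, and
edits; replay must reproduce the stored mask bit-identically or it raises
a reproducibility error, which gives exact inter-observer auditability.

**Exemplar model.** Each voxel is described by its 9×9 in-plane
neighbourhood (the centre plus 80 surrounding voxels; windows are 2-D
because slice thickness is typically 2–3× the in-plane spacing, making
3-D windows anisotropic). Features are a 16-bin normalized HU histogram
over [−1024, 200] (half-open bins, last bin closed, values clamped to the
range ends), the patch mean, the patch SD, and the histogram entropy.
Training samples patches uniformly without replacement from nodule voxels
with full window support (774 by default), standardizes features
column-wise, and clusters them with affinity propagation on
`s(i,k) = −‖f_i − f_k‖²`. The shared diagonal preference is calibrated by
bisection between `min(S)` and the saturation end (zero for this metric)
until exactly nine exemplars emerge; the exemplar count is
non-decreasing in the preference up to rare message-passing flips, which
makes the bisection well-posed. The feature set and metric are package
choices — the original system's features are not published — so both are
configurable, and no claim is made that the learned exemplars match any
previously trained ones.

**Class labels.** The nine exemplars are ranked by mean HU: the four
densest receive the VIRO labels (descending R, O, V, I), the three
lightest the lepidic labels (ascending G, C, B), the middle two P (below)
and Y (above). The within-group sub-order is an arbitrary but frozen
convention; only the group membership (VIRO vs lepidic vs intermediate)
carries meaning downstream.

**Classification and risk.** Every mask voxel with full window support is
assigned the label of the nearest exemplar in standardized feature space
(exact ties go to the lowest exemplar index). Mask voxels lacking support
are reported as *unclassified* rather than padded — padding would
fabricate attenuation — and the signature's denominator uses classified
voxels only. The signature's VIRO fraction drives the
Good/Intermediate/Poor call: Poor at `viro ≥ t_poor`, Good below
`t_good`, Intermediate between, with boundary values going to the more
severe category. The published cut-points for this characterization come
from survival work that is out of scope here, so the defaults
(`t_good = 0.10`, `t_poor = 0.45`) are explicit assumptions; every
`risk_call` records the thresholds and the VIRO fraction it used, so the
rule can be swapped without invalidating stored results. Whether the
original characterization uses the VIRO fraction alone or the full
nine-class composition is not derivable from our sources; the rule is
isolated behind `risk_rule` so either can be substituted.

## Agreement statistics

The observer table holds one percent-scale fraction per
(nodule, observer, class); fractions are analyzed untransformed (a logit
analysis was considered and rejected as the default because the source
analysis reports none). For each class the balanced two-way crossing
yields method-of-moments variance components:
σ²_residual = MSE, σ²_observer = (MS_obs − MSE)/n, σ²_nodule =
(MS_nod − MSE)/k. Negative estimates are truncated to zero *and flagged*
for the decomposition report, but the ICC uses the untruncated mean
squares:

ICC(A,1) = (MS_nod − MSE) / (MS_nod + (k−1)·MSE + (k/n)(MS_obs − MSE)),

the two-way random-effects, absolute-agreement, single-measurement form —
the only form matching a decomposition into nodule, observer, and
unexplained variance. Estimation is ANOVA moments rather than REML for
closed-form testability; REML would differ slightly in unbalanced or
truncated settings. The 95% interval is the McGraw–Wong F-based interval
with Satterthwaite degrees of freedom; the lower bound is deliberately
not truncated at zero, so near-null classes can print negative lower
bounds. The panel reports one ICC per class, one for VIRO computed on the
*summed* V+I+R+O fractions (not an average of ICCs), and an "Avg." row
that is the arithmetic mean of the nine per-class ICCs — whether a
pooled-data ICC was meant instead is ambiguous in our sources; the
mean-of-ICCs reading is adopted and flagged here.

Dice is 2|A∩B|/(|A|+|B|) with a strong-overlap flag above 0.7. Fleiss
kappa uses the standard multi-rater formulation with the large-sample
null standard error for its interval and the conventional interpretation
bands (0.61–0.8 substantial, 0.81–1.0 almost perfect). With two raters it
reduces exactly to Scott's pi (pooled marginals) — not to Cohen's kappa,
which weights chance agreement by each rater's own marginals; the test
suite asserts the Scott identity. Kruskal–Wallis delegates to
`stats::kruskal.test` (tie-corrected H, chi-square reference); how the
original analysis formed its per-scan observations for this test is not
derivable from our sources, so the operation accepts generic grouped
values. No multiple-testing correction is applied anywhere, matching the
source analysis.

## The phantom generator

Phantoms are spheres of ground-glass attenuation (−550 HU) with an
optional concentric solid core (40 HU) in lung background (−850 HU),
optionally with a vessel cylinder tangent to the nodule surface and a
chest-wall slab, plus additive i.i.d. Gaussian noise (default SD 20 HU,
a typical lung-window noise level). The default grid is 36×48×48 voxels
at 1.25×0.7×0.7 mm, echoing thin-slice chest CT anisotropy. The default
cohort sampler draws radius uniformly on 4–8 mm and solid-core fraction
uniformly on [0, 1] — the spectrum from pure ground-glass to fully solid
nodules — with a vessel on 30% of phantoms.

Simulated observers perturb the true border with a smooth Gaussian random
field: the field (3 mm correlation length, marginal SD `boundary_sd`,
clamped at 3.5 SD) is compared against the signed distance to the mask
boundary, computed by band-limited 26-neighbour chamfer propagation (an
approximation to the Euclidean distance, adequate within the narrow
displacement band). The result is restricted to the 26-connected
component meeting the true nodule, and an abutting vessel segment is
retained with probability `vessel_inclusion_prob`. Nothing is known about
the distribution of real observers' edits, so these are free knobs, not
estimates; expected Dice against truth decreases monotonically in
`boundary_sd`, which the suite verifies at three jitter levels with 50
replicates each.

What the phantoms do *not* emulate: reconstruction texture and streak
artifacts, lobar anatomy, spiculation and irregular margins, partial
volume at the slice level beyond what the grid induces, and real
histology-to-attenuation mappings. Passing tests therefore demonstrate
the pipeline's internal consistency and statistical machinery, not
clinical performance on patient scans — the published headline agreement
values come from patient cohorts that are not deposited and are not
reproducible here.

## Numerical choices

- Coordinates are 1-based (slice, row, col) with world position
  `origin + (index − 1) · spacing` mm; grids align when shapes match and
  spacing/origin agree within 1e-6 mm.
- Affinity propagation adds a deterministic, vanishing jitter
  (`eps·|S|`-scale, zero-mean, fixed seed) before message passing:
  exactly symmetric inputs (duplicate points) otherwise oscillate into
  degenerate all-self-exemplar states. After convergence the standard
  within-cluster refinement replaces each exemplar by the member
  maximizing the within-cluster similarity sum, iterated to a fixed
  point. Net similarity is always reported on the unjittered matrix, and
  non-convergence is flagged with a warning, never silent.
- On small random instances (n ≤ 10) the refined message passing attains
  the exhaustive-search optimum roughly 9 times in 10 — the same rate a
  widely used reference implementation achieves on identical instances —
  so the oracle suite's 90% bar sits exactly at the algorithm's intrinsic
  optimality rate and individual seeds can land on either side.
- The ICC interval's coverage is a known weak point when the rater
  variance is carried by few raters: with k = 3 observers the observer
  mean square has 2 degrees of freedom, and simulated coverage of the
  nominal 95% interval falls to roughly 80% at high ICC with a
  non-negligible observer component (verified against an independent
  implementation), while staying at ~95% when the observer share is
  small. The recovery simulations in the suite use n = 200 nodules ×
  3 observers with variance components (10·ICC, 0.5, 9.5 − 10·ICC).
- Model JSON is written with 17 significant digits so serialization
  round-trips doubles exactly; session masks are stored run-length
  encoded in plain-text JSON.
- Degenerate inputs raise typed errors rather than returning silently:
  seeds outside the thresholds, edits that empty a mask, perturbations
  that empty an observer mask, flat tables (zero total variance),
  single-category kappa tables, and all-tied Kruskal–Wallis data.

## Problem sizes

The test suite trains fixture models on eight 3–4.2 mm phantoms with 250
VOIs; the end-to-end checks use a 30-phantom cohort at the default
sampler settings with 774 training VOIs and three simulated observers,
and the ICC recovery and coverage simulations use 200-nodule tables
(20 seeds per target ICC) and 200-table coverage runs. These sizes keep
the full suite and the acceptance script to a few minutes each on one
CPU while leaving every statistical check adequately powered.

## Known limitations

Beyond the phantom realism and interval-coverage caveats above: the
region-growing criterion, feature set, similarity metric, and risk
cut-points are explicit package assumptions wherever the published
workflow leaves them unstated; the chamfer distance over-estimates true
Euclidean distance by up to ~8% along diagonal directions; and freehand
2-D lasso edits are not implemented (the eraser and half-space primitives
cover the documented adjustment tools).
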