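# nodulesig

Exemplar-based CT characterization of lung adenocarcinoma (ADC) nodules,
with a full inter-observer agreement analysis, exercised end to end on
synthetic CT phantoms with simulated observers.

## The problem

Early lung adenocarcinomas span a spectrum from indolent, lepidic-growth
tumors (ground-glass opacity on CT) to aggressive invasive tumors (solid
attenuation). A non-invasive way to place a nodule on that spectrum is to
classify every voxel of a segmented nodule into one of nine learned
density classes and summarize the nodule by its class composition. This
package implements that pipeline for researchers studying radiomic
characterization and, in particular, its *reproducibility across
observers*, since semi-automatic segmentation leaves room for
border-adjustment differences between users.

## The method

1. **Segmentation** — seed-voxel region growing: the maximal connected
   component of voxels with HU in `[hu_low, hu_high]` (defaults −750 to
   200) containing the seed, clipped to a volume-of-interest box, plus
   scripted manual edits (eraser spheres, exclusion planes) recorded in a
   replayable session.
2. **Exemplar model** — 9×9 in-plane voxel patches are sampled from
   training nodules (774 by default) and described by a 16-bin HU
   histogram plus first-order statistics (mean, SD, entropy). Pairwise
   similarity `s(i,k) = −‖f_i − f_k‖²` on standardized features feeds
   affinity propagation (responsibility/availability message passing with
   damping); the shared diagonal preference is calibrated by bisection
   until exactly nine exemplars emerge. Exemplars are labelled along the
   attenuation spectrum with the palette V, I, B, G, Y, O, R, C, P, where
   {V, I, R, O} ("VIRO") mark solid, invasion-associated density,
   {B, C, G} ground-glass/lepidic density, and {P, Y} sit between.
3. **Classification** — every mask voxel with a full 9×9 window is
   assigned its nearest exemplar's class. The per-class fractions form the
   nodule's *parametric signature*; the VIRO fraction drives a
   Good/Intermediate/Poor risk call (configurable cut-points, default
   0.10/0.45, every call carries its rule trace).
4. **Agreement statistics** — for nodules segmented by several observers:
   per-class two-way random-effects variance components
   (σ²_nodule, σ²_observer, σ²_residual), the intraclass correlation
   ICC(A,1) = σ²_nodule / (σ²_nodule + σ²_observer + σ²_residual) with the
   McGraw–Wong F-based 95% interval, pairwise Dice overlap
   2|A∩B|/(|A|+|B|), Fleiss kappa on the risk calls, and Kruskal–Wallis
   comparisons of grouped agreement values.

A phantom generator supplies the inputs: spherical nodules with a
configurable solid core inside lung-attenuation background, optional
abutting vessels and chest wall, Gaussian noise, and simulated observers
that perturb the true border with a smooth random displacement field.

## Worked example

```r
library(nodulesig)

cohort <- generate_cohort(12, seed = 42)          # phantoms + manifest
model  <- train_exemplar_model(cohort$phantoms, n_vois = 400, seed = 7)
model
#> <exemplar_model> 9 exemplars (OVRPBYIGC), 19 features, preference -150.5

gt      <- cohort$phantoms[[1]]
session <- segment_nodule(gt$volume, gt$spec$nodule_center)
cls     <- classify_nodule(gt$volume, session$result, model)
cls$signature
#> <parametric_signature> 559 voxels classified, 0 unclassified
#>    V    I    B    G    Y    O    R    C    P
#>  0.2 14.3  5.5 39.0 27.0  0.0  0.0 14.0  0.0
#> VIRO 14.5%  lepidic 58.5%  intermediate 27.0%
risk_characterize(cls$signature)
#> <risk_call> Intermediate (VIRO 14.5%; cuts 10%/45%)

study <- observer_study(cohort$phantoms, model,
                        list(observer_jitter(0.5, 0.2, 1),
                             observer_jitter(0.5, 0.2, 2),
                             observer_jitter(0.5, 0.2, 3)))
study
#> <observer_study> 12 nodules x 3 observers
#>   class-average ICC 0.999; mean DSC 0.989 (sd 0.014); Fleiss kappa 0.898
```

Reading the numbers: this nodule is mostly ground-glass (58.5% lepidic
classes) with a 14.5% VIRO burden, so it lands between the Good (<10%)
and Poor (≥45%) cut-points. Across twelve phantoms segmented by three
simulated observers with 0.5 mm border jitter, between-nodule differences
dwarf observer differences (class-average ICC 0.999), segmentations
overlap strongly (mean Dice 0.989), and the three observers' risk calls
agree almost perfectly (kappa 0.898).

A command-line front end for shell use lives at
`system.file("cli", "nodulesig", package = "nodulesig")` with subcommands
`simulate`, `segment`, `train`, `classify`, and `agree` (volumes and
masks as NIfTI or NRRD, tables as CSV, models and sessions as JSON).

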