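# labyrinthSeg

Shape-model level-set segmentation of the inner-ear labyrinth in 3D MRI,
with a synthetic phantom test bed.

The fluid-filled inner-ear labyrinth — cochlea, vestibule and the three
semicircular canals — is bright on heavily T2-weighted MRI and is the
structure radiologists delineate when working up Meniere's disease.
`labyrinthSeg` implements a complete, tested pipeline for that task, aimed
at medical-image-analysis researchers who need a reproducible reference
implementation:

1. **Statistical shape model.** Corresponding landmark sets are aligned by
   generalized Procrustes analysis: every shape is centered and scaled to
   unit centroid size *S* = sqrt(Σ<sub>m</sub> ‖x<sub>m</sub> − x̄‖²), rotated to the
   running mean by the Kabsch SVD solution minimizing the Procrustes
   distance P<sub>d</sub>(A, B) = Σ<sub>m</sub> ‖a<sub>m</sub> − b<sub>m</sub>‖², and the mean shape is
   re-estimated until convergence (the objective is provably
   non-increasing).
2. **Automatic ROI localization.** A rigid transform x ↦ **A**x + **b**
   (**A**ᵀ**A** = I, det **A** = 1) is found by maximizing mutual
   information MI(X,Y) = H(X) + H(Y) − H(X,Y) over a 32×32 joint
   histogram, with tricubic (local cubic Lagrange) resampling and
   coordinate-wise hill climbing on a two-level pyramid; the atlas ROI box
   is mapped through the result.
3. **Level-set segmentation.** The registered mean shape, weighted by the
   bright intensity class, initializes a distance-regularized level-set
   evolution (DRLSE): ∂φ/∂t = μ div(d<sub>p</sub>(|∇φ|)∇φ) +
   λ δ<sub>ε</sub>(φ) div(g∇φ/|∇φ|) + α g δ<sub>ε</sub>(φ), with
   edge indicator g = 1/(1 + |∇(G<sub>σ</sub> ∗ I)|²).
4. **Baseline and metrics.** A seeded region-growing comparator (flood
   fill + adaptive curvature-threshold repair + DRLSE) and the full
   evaluation panel: MCC, Dice, FPR/FNR (normalized by reference size),
   TP%/FP%, average minimum Euclidean distance and Hausdorff distance.

Because no public labelled cohort of inner-ear MRI exists, the package
includes a first-class synthetic phantom generator (spiral cochlear duct,
ellipsoidal vestibule, three partial-torus canals; random pose, per-subject
shape jitter, bias field, noise) that provides exact ground truth masks and
corresponding landmarks for every downstream stage.

## Worked example

Simulate a small cohort, build the shape model, segment a held-out subject
and score it against the ground truth:

```r
library(labyrinthSeg)

sp     <- phantom_spec()                       # 64^3 voxels, 0.4 mm
cohort <- generate_cohort(6, sp, seed = 1)

ssm   <- build_shape_model(lapply(cohort, function(s) s$landmarks))
atlas <- cohort[[1]]
model <- attach_atlas(ssm, atlas$landmarks, atlas$volume,
                      mask_roi(atlas$truth_mask))

res    <- segment_is3dls(cohort[[2]]$volume, model)
report <- evaluate_segmentation(res$mask, cohort[[2]]$truth_mask)
report
#> <evaluation_report>
#>   MCC 0.9361  DSC 0.9373  FPR 0.0632  FNR 0.0623
#>   TP 93.77%  FP 6.32%  AMED 0.0956 mm  HD 1.2000 mm
```

A Dice coefficient of 0.94 means 94% overlap agreement with the ground
truth; FPR and FNR say that over- and under-segmentation each amount to
about 6% of the reference volume; the mean surface error is 0.1 mm (a
quarter voxel) with a worst-case deviation of 1.2 mm. The provenance record
(`res$provenance`) stores the recovered atlas transform, the localized ROI
box and all parameters.

The region-growing comparator runs with an automatically chosen seed and
tolerance:

```r
base <- segment_region_growing_baseline(
  cohort[[2]]$volume, auto_region_grow_config(cohort[[2]]$volume))
evaluate_segmentation(base, cohort[[2]]$truth_mask)
```

A command-line front end covers the same stages
(`simulate`, `build-ssm`, `segment`, `evaluate`, `all`, `show-config`):

```sh
exec/labyrinthseg all --out runs/demo --seed 1 --verbose
```

which leaves NIfTI volumes and masks, landmark CSVs, the serialized shape
model, per-subject segmentations by both methods, an `evaluation.csv`
comparing them and a JSON run manifest in `runs/demo/`.

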