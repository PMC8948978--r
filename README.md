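# neckssm

Statistical shape modelling of the infrarenal abdominal aortic aneurysm
neck — the stent-graft sealing zone between the lowest renal artery (LRA)
and the aneurysm onset.

Hostile-neck scalars (length, diameter, angulation, conicity) reduce a
complex 3D anatomy to a few numbers. A statistical shape model (SSM)
instead learns the full morphological variation of a population: every
neck is parametrized as 360 corresponded surface points (10 cross-sectional
rings × 36 rays around the center lumen line), translated to a common LRA
anchor, and decomposed by PCA so that

```
x  =  x̄  +  Σᵢ bᵢ √λᵢ vᵢ
```

with mean shape `x̄`, orthonormal modes `vᵢ`, mode variances `λᵢ`
(eigenvalues, mm²), and per-patient scores `bᵢ` in SD units. An n-patient
cohort yields n − 1 modes; the leading ones correspond to interpretable
anatomy (length, left/right and anterior deflection, diameter, distal-end
deflection). Model quality is assessed by the standard triple:
**compactness** (cumulative variance per mode count), **generalization**
(leave-one-out reconstruction RMSE, mm), and **specificity** (RMSE from
randomly synthesized shapes to their nearest training shape, mm).

The package is aimed at vascular-imaging researchers with per-patient
exports from a vascular workstation: a triangular lumen mesh (STL/PLY/OBJ),
a center lumen line (CSV/JSON), and landmark coordinates (JSON/CSV). CT
segmentation itself is out of scope. Because such patient data are not
public, the package includes a parametric synthetic-neck generator with
five controllable deformation modes and calibrated noise, providing
closed-form ground truth for every pipeline stage.

## Worked example

```r
library(neckssm)

# synthesize a 97-patient cohort whose five generative modes carry
# variance in proportion 51/30/12/2/2 plus 5% residual noise
spec   <- spectrum_cohort_spec(n = 97, seed = 1)
cohort <- generate_cohort(spec)

# per patient: parametrize -> rearrange -> align -> flatten
vectors <- lapply(cohort$shapes, function(s)
  process_neck(s$mesh, s$cll, s$landmarks))
model <- fit_ssm(shape_cohort(vectors))
print(model)
#> neck_ssm: 96 components from 97 training shapes (10 x 36 grid)
#>   first 5 variance fractions: 51.7%, 24.0%, 13.8%, 2.6%, 2.0%

report <- evaluate_all(shape_cohort(vectors), k_values = c(5, 9),
                       n_samples = 200, seed = 1)
print(report)
#> SSM quality report
#>   compactness at 5 PCs: 94.1%
#>   generalization, 5 PCs: 0.79 mm (95% CI 0.78-0.80)
#>   generalization, 9 PCs: 0.77 mm (95% CI 0.76-0.77)
#>   specificity,    5 PCs: 1.35 mm (95% CI 1.30-1.40)
#>   specificity,    9 PCs: 1.37 mm (95% CI 1.32-1.42)
```

The model print shows the explained-variance fractions of the leading
modes (the fitted spectrum recovers the generative 51/30/12/2/2 pattern up
to the sampling scatter of 97 draws). The report reads: five modes carry
94.1% of the cohort's shape variance; an unseen neck is reconstructed to
within ≈0.8 mm RMS by its first five scores; and random shapes drawn from
the model lie within ≈1.4 mm RMS of a real training shape.

Mode-shape meshes for visualization (e.g. mean ± 3 SD along mode 1, or the
empirical bound from `score_range()` for skewed modes):

```r
write_mesh(mode_mesh(model, 1, +3), "pc1_plus3.ply")
score_range(model)[1:5, ]
```

`run_pipeline()` performs all of the above plus artifact export
(per-patient grids, cohort matrix, model container, mode meshes, quality
report, JSON-lines log) in one call; `inst/cli/neckssm.R` wraps it for the
shell. Real cohorts are ingested from a directory with one subdirectory
per patient (`mesh.ply`, `cll.csv`, `landmarks.json`).

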