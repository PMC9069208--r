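# sprct

Stopping-power-ratio (SPR) prediction and validation for CT-based
particle-therapy treatment planning, in R.

Ion beam ranges are computed from voxel maps of the stopping-power ratio —
each tissue's stopping power relative to water. This package implements and
compares the two clinical routes from CT images to SPR:

* **DLCT (dual-layer spectral CT)**: relative electron density ρe and
  effective atomic number Z_eff are measured directly; SPR follows from the
  Bethe equation (higher-order corrections neglected),

  ```
  SPR = ρe · [ln(2 me c² β²/(1−β²)) − ln I − β²] / [ln(2 me c² β²/(1−β²)) − ln I_w − β²]
  ```

  at 100 MeV/u with I_w = 78.73 eV, where the mean excitation energy I comes
  from a piecewise log-linear mapping of Z_eff calibrated on reference human
  tissues. A dual-energy quadratic model
  `ρ = ρe (1 + Σ e_n x^n)`, `x = (Z_eff/Z_eff,w)^3.3 − 1`, estimates mass
  density from the same inputs.

* **SECT (single-energy CT)**: CT numbers are modeled with the two-parameter
  stoichiometric parametrization
  `u = ρe (k1 Z̃^3.62 + k2 Ẑ^1.86 + 1) / (water term)`, `CTN = 1000(u − 1)`,
  and converted to SPR through a piecewise-linear Hounsfield look-up table
  (HLUT) fitted on reference tissues.

Because no public scan data accompany the methodology, the package ships a
synthetic phantom generator: voxelized cylindrical PMMA phantoms (one- and
nine-bore, matching the published geometries) with tissue-surrogate and
implant inserts, exact composition-based ground truth, per-channel Gaussian
noise, and paired analytic dose grids. On top sit the evaluation tools: ~70%
diameter ROI extraction, the five accuracy statistics (mean overall relative
residual, RMSE, Pearson r, regression slope/intercept), water-equivalent
path length and distal-range shift along rays, and a local-normalization 3-D
gamma-index engine (3%/1.5 mm, 5% low-dose cutoff) with a compiled
sub-voxel search.

Intended users: medical-physics researchers who want a reproducible,
self-contained bench for comparing CT-to-SPR calibration strategies, and
developers of DECT analysis pipelines who need a tested reference
implementation of the component algorithms.

## Worked example

Nine-insert phantom, realistic noise, DLCT route calibrated on reference
human tissues:

```r
library(sprct)
db  <- load_material_tables()
ph  <- rasterize(builtin_geometries()$SC, spacing = c(2, 2, 2), db = db)
dl  <- render_dlct(ph, noise_model(sigma_ed = 0.01, sigma_ean = 0.1, seed = 1))
map <- fit_ivalue_mapping(db, anchor_water = FALSE)
roi <- extract_roi_means(predict_spr_volume(dl$ed, dl$ean, map), ph)
ref <- ph$truth$spr[match(roi$material, ph$truth$material)]
summarize_residuals(roi$mean, ref, roi$material)
```

```
SPR accuracy report (n = 9 inserts)
          name spr_pre spr_ref residual_pct
    true_water  1.0176  1.0169      0.06477
       adipose  0.9541  0.9484      0.60645
    inner_bone  1.0822  1.0914     -0.84213
        muscle  1.0350  1.0415     -0.62370
        cb2_30  1.2773  1.2910     -1.05817
         brain  1.0786  1.0790     -0.03400
 cortical_bone  1.6572  1.6519      0.31921
         liver  1.0800  1.0866     -0.60983
        breast  0.9803  0.9797      0.06309
  mean overall relative residual: 0.469 %
  RMSE:  0.0068
  r:     0.9995
  alpha: 1.002
  delta: -0.005
```

Each row is one insert: the ROI-mean predicted SPR, the composition-derived
reference, and their relative residual in percent. The summary lines are the
accuracy statistics used to compare prediction routes; running the same
phantom through the SECT route (`render_sect()`, `build_hlut()`,
`convert_ctn_volume()`) gives a mean overall relative residual about four
times larger, which is the core DLCT-vs-SECT contrast the package
demonstrates.

A command-line surface over the same pipeline lives in
`inst/cli/sprct.R` (subcommands `synth`, `predict-dlct`, `calibrate-hlut`,
`predict-sect`, `massdensity`, `evaluate`, `wepl`, `gamma`; volumes are
NIfTI or MetaImage with JSON sidecars).

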