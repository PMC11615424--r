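# canalssm

Statistical shape modeling (SSM) of the proximal femoral intramedullary
canal — the cavity an uncemented hip stem is fixed into. The canal's
internal geometry, not the femur's external landmarks, largely dictates the
achieved stem version, so quantifying how canal shape varies between
subjects matters for arthroplasty planning. `canalssm` is aimed at
researchers in orthopedic morphometry and biomedical image analysis who
need a tested, fully synthetic-data-validated pipeline from (phantom) CT
segmentation to interpreted PCA shape modes.

## What it does

Each canal is represented as a point distribution model: a fixed-length
ordered point set `x_i ∈ R^(3N)`, index-matched across the population. PCA
on the centered shape matrix yields orthonormal modes `φ_k` with
eigenvalues `λ_k` (sample covariance, `n−1` normalization), and shapes are
synthesized as

    x(w) = x̄ + Σ_k w_k √λ_k φ_k ,

with weights in SD units (±3 SD is the standard perturbation for
visualizing a mode). Explained-variance fractions `λ_k / Σλ` and their
cumulative sum rank the modes; the *size* mode is identified objectively as
the mode with the steepest least-squares slope of enclosed volume versus
weight over −3…+3 SD.

Around that core the package provides:

* **geometry**: triangle meshes, watertight volume, symmetric surface RMSE,
  voxelization + volumetric IoU, rigid ICP with a Kabsch/SVD step (Rcpp
  closest-point kernel with a uniform-grid index); STL/PLY/MetaImage IO.
* **synthetic population generator**: a 150 mm canal template (1002 points,
  elliptical cross-sections, proximal flare) with five planted orthonormal
  modes — size, proximal torsion, anteversion, varus/valgus, distal twist —
  known variance spectrum, surface noise, scanner pose jitter, and CT-like
  three-label phantoms.
* **preprocessing**: bone-window threshold segmentation with Boolean cavity
  extraction (flood fill), exact separable Gaussian mask smoothing with
  RMSE/IoU validation (pass rule: RMSE < 1 mm, IoU > 0.5), cropping to the
  standard 15 cm length with exclusion of shorter inputs.
* **correspondence**: landmark-based anatomical frames (posterior condylar
  line + intertrochanteric crest), population alignment, template-to-target
  point mapping by ICP + nearest-point projection, iterative mean shape,
  and the axial-plane version angle (anteversion positive).
* **pipeline**: validated nested configuration, on-disk population
  generation with manifests/checksums, end-to-end model building with CSV
  reports and perturbation meshes, and a human-readable summary.

## Worked example

Build a model of a synthetic 64-subject population (vector fidelity: exact
correspondences, no imaging stages) and print the report:

```r
library(canalssm)

cfg <- pipeline_config(population = list(n_samples = 64), seed = 2024)
res <- run_build_model(cfg, out_dir = "demo_model")
run_report("demo_model")
```

```
Shape model summary
  seed: 2024  config: 6b220ad8c8fe8b1d51636bbcbf623c3f
  samples: 64  points: 1002  modes: 63
  mode 1: eigenvalue 1065 mm^2,  39.0% (cumulative  39.0%)
  mode 2: eigenvalue 550.5 mm^2,  20.2% (cumulative  59.1%)
  mode 3: eigenvalue 371.9 mm^2,  13.6% (cumulative  72.7%)
  mode 4: eigenvalue 213 mm^2,   7.8% (cumulative  80.5%)
  mode 5: eigenvalue 129.4 mm^2,   4.7% (cumulative  85.3%)
  size mode (steepest volume trace): mode 1
    mode 1 volume slope: 7257 mm^3/SD
    mode 2 volume slope: -594.4 mm^3/SD
    mode 3 volume slope: -223.5 mm^3/SD
    mode 4 volume slope: 347.4 mm^3/SD
    mode 5 volume slope: 12.62 mm^3/SD
```

The five planted modes dominate the spectrum (the generator's default
variances are in the proportions 3.8 : 1.9 : 1.5 : 0.89 : 0.61 with a
small isotropic residual); the five-mode cumulative fraction sits around
85%, and the volume-trace procedure attributes mode 1 to size — its slope
is an order of magnitude steeper than any other mode's. `demo_model/`
additionally holds the model container (`model.json`), the scree table,
volume traces, smoothing-validation rows (mesh runs) and ±3 SD
perturbation meshes (`perturbations/mode{k}_w{±d}.ply`).

Mesh fidelity runs the full imaging chain per case — phantom
rasterization, segmentation, smoothing + validation, anatomical-frame
alignment, cropping, correspondence:

```r
cfg <- pipeline_config(population = list(n_samples = 64, fidelity = "mesh"),
                       seed = 1)
res <- run_build_model(cfg, out_dir = "mesh_model")
res$size_mode$mode      # 1
all(res$validation$pass) # TRUE (RMSE < 1 mm, IoU > 0.5 for every case)
```

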