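---
title: "Statistical shape modeling of the femoral intramedullary canal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modeling of the femoral intramedullary canal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Uncemented hip stems are fixed inside the intramedullary canal of the
proximal femur, and the achieved (prosthetic) femoral version is largely
dictated by the canal's internal geometry rather than by the bone's external
landmarks. `canalssm` builds point-distribution statistical shape models
(SSM) of canal-like tubular anatomy so that the main modes of inter-subject
variation — size, proximal torsion, version, varus/valgus, distal shaft
twist — can be quantified and ranked by explained variance.

Because patient CT data cannot be shipped, every stage is validated against
a synthetic population generator with *planted*, orthonormal modes of
variation and a known variance spectrum. The generator is first-class,
tested code: its output is the ground truth against which segmentation,
correspondence and PCA recovery are judged.

# The model

Each shape is a fixed-length ordered point set ("equal number of nodes"),
flattened to a row vector $x_i \in \mathbb{R}^{3N}$ (layout
$x_0,y_0,z_0,x_1,\dots$). With mean $\bar{x}$, PCA factorizes the centered
data matrix by a thin SVD; eigenvalues are
$\lambda_k = d_k^2/(n-1)$ — the unbiased sample covariance spectrum — and
modes $\phi_k$ are orthonormal. A shape is synthesized as

$$x(w) = \bar{x} + \sum_k w_k \sqrt{\lambda_k}\,\phi_k,$$

with weights in SD units, so $w_k = \pm 3$ is the standard ±3 SD
perturbation. Explained-variance fractions are $\lambda_k / \sum_j
\lambda_j$; the scree table also reports the smallest mode count reaching a
configurable cumulative threshold (default 80%).

The $3N \times 3N$ covariance matrix is never formed ($n \ll 3N$); an
explicit covariance eigendecomposition is retained in the test suite as the
independent oracle for the SVD path. Mode signs are fixed by making each
mode's largest-magnitude entry positive, so ± SD exports are reproducible.

## Mode interpretation by volume traces

The size mode is identified quantitatively, not visually: the mean is
deformed along one mode at weights $-3,-2,\dots,+3$ SD, the enclosed volume
is measured at each weight (open, cropped surfaces are capped first), and
the closed-form least-squares slope of volume against weight is attached.
The mode with the steepest trace is the size mode; ties break toward the
lower index and are flagged. Rotation-like modes change volume only at
second order, so their traces are flat by symmetry.

# Canonical frame and landmarks

The package fixes one anatomical frame and uses it everywhere: **+x** along
the posterior condylar line from medial to lateral, **+z** from the
condylar midpoint toward the intertrochanteric crest (orthogonalized
against x), **+y = z × x** (anterior), origin at the intertrochanteric
crest. The canal template occupies $z \in [-150, 0]$ mm, i.e. the crest
sits at the level of the proximal crop plane and the distal crop plane
center is $(0,0,-150)$. Version is the signed axial-plane angle between
the neck axis (base → head) and the (undirected) condylar line, positive
anterior; it is computed in the frame derived from the same landmarks and
is therefore rigid-invariant.

# The synthetic population generator

`canal_template()` builds a deterministic tubular surface, 150 mm long,
with 1002 surface points arranged as 40 rings × 25 points plus two pole
vertices, triangulated into a closed mesh. Cross-sections are ellipses
(semi-axes 1.20 and 0.85 of the base radius, medial-lateral wide as in the
metaphysis) with a smoothstep proximal flare over the top third (default
flare ratio 2.5 on a 6 mm distal radius). The marked ellipticity is
deliberate: on a circular tube an axial rotation leaves the surface
invariant, so torsion would be unobservable to any surface-based
correspondence; real canals are strongly non-circular, and the generator
must emulate that or the torsion/version modes could not exist as
detectable surface modes.

`canal_mode_basis()` constructs five raw displacement fields — (1) radial
scaling about the axis, (2) axial rotation ramping from the proximal end to
zero at the calcar level, (3) rigid axial rotation of all points,
(4) coronal tilt about the canal midpoint, (5) axial rotation ramping from
mid-shaft to the distal end — then Gram–Schmidt orthonormalizes them in
this order, so "size" stays the dominant interpretable direction.

`sample_population()` draws mode coefficients from zero-mean normals with
the configured variances and adds an isotropic residual confined to the
orthogonal complement of the five fields, so the planted variances are
*exactly* the top five population eigenvalues — the analytic ground truth
for PCA recovery. Mesh fidelity additionally adds Gaussian surface noise
along vertex normals and a random rigid scanner pose (applied to surface
and landmarks alike).

## Default study conditions

The defaults are the emulated study conditions: 64 subjects; variance
spectrum in the proportions 3.8 : 1.9 : 1.5 : 0.89 : 0.61 with a residual
of 1.66/8.7 of the planted total; 0.3 mm surface noise; pose jitter up to
10° and 5 mm. The absolute scale (mode 1 = 1000 mm², about 1 mm radial SD
per point, ±3 mm at 3 SD on a 6 mm radius) is chosen from template
geometry so that ±3 SD shapes remain valid closed surfaces; the
literature's absolute eigenvalues are not portable because they scale with
the (unreported) node count. The spectrum-recovery simulations configure
the literal values 3.8e5 … 6.1e4 mm² with an isotropic residual of
1.66e5 mm² in *vector* fidelity, where only the linear algebra matters.
With $n = 64$ and $p = 3006$, the expected sample spectrum is mildly
inflated (≈ $p\sigma^2_{\mathrm{res}}/n \approx 2.6\times10^3$ mm² per
mode), which the reported fractions reflect; averaged over ten seeds the
five fractions land within a point or two of 37/19/14/8.5/5.8% with a
five-mode cumulative near 85%.

# Phantom, segmentation and smoothing

`make_ct_phantom()` rasterizes a sample into a three-label CT-like image:
canal interior 80 HU, a dilated cortical shell (default 3 mm) at 1200 HU,
background −1000 HU — so the standard bone window [230, 3020] HU selects
exactly the cortex. `segment_canal()` reproduces the Boolean-subtraction
workflow: threshold the bone, flood-fill the complement from the image
border (6-connected, so the fill cannot leak diagonally through the
shell), and take the unreached cavity as the canal ("filled" minus bone).

Surfaces are extracted as the exact 0.5 level set of nearest-neighbour
interpolation (boundary voxel faces). This "cuberille" surface is
watertight, consistently oriented and exactly volume-consistent with the
mask. Masks are first cleaned of edge-diagonal voxel contacts (filling one
in-plane neighbour, iterated to a fixed point) so the surface is a closed
2-manifold; the change is sub-voxel. Marching cubes would give smoother
normals but is not needed: smoothing happens in mask space.

"Gaussian recursive filter" smoothing is implemented as exact separable
Gaussian convolution (σ in mm, converted per axis by the spacing),
re-thresholded at 0.5; at desk-scale grids the exact form is affordable
and the contract is the Gaussian response, not the recursion. σ defaults
to 1.5 mm — a config choice, not a literature value (the original kernel
size is unreported). Smoothing fidelity is validated by the symmetric
surface RMSE and the voxel IoU on a shared grid, with the acceptance rule
RMSE < 1 mm and IoU > 0.5; at default noise the pipeline typically
measures RMSE ≈ 0.3 mm and IoU ≈ 0.96.

Cropping standardizes the axial extent to 150 mm from the proximal
extreme, re-triangulating faces cut by the crop plane and capping the cut
loop; shorter inputs are rejected, mirroring the exclusion of scans with
insufficient field of view.

# Correspondence

`map_points()` carries the template into each (anatomically aligned)
target pose by rigid ICP — point-to-nearest-triangle correspondences with
a Kabsch SVD fit per iteration, terminating on the change of mean
correspondence distance — and then projects each registered template point
onto its nearest point on the target surface. The output lives in the
canonical frame: pose standardization is the job of the landmark frame,
and rotational anatomy (version, varus/valgus, torsion) must remain in the
coordinates or the model could never capture it. Removing the ICP pose
from the output ("pull-back") was considered and rejected for exactly this
reason: it silently deletes every rigid-like mode of variation. As a
consequence the mapped coordinates are *equivariant* with the target's
pose (exactly, inside the ICP convergence basin), not invariant.

`compute_mean_shape()` alternates mapping all targets with index-wise
averaging (default 5 outer rounds, 0.1 mm tolerance, history logged so
non-convergence is visible). The initial template is a configurable
reference case by default; the pipeline passes the canonical template so
recovered modes are directly comparable with the planted fields. The
result depends weakly on the initialization, which is documented rather
than hidden.

## Known limitation: tangential sliding

Nearest-point projection records only the locally surface-normal component
of a displacement field; tangential components slide along the surface.
Radial (size) displacements are nearly normal and survive with mild
attenuation (flare slope, ellipse obliquity); fully rigid modes
(varus/valgus tilt, global version) are carried intact by the ICP pose.
Ramped axial twists, however, are largely tangential on a tubular surface:
after the ICP absorbs their best global-rotation part, the remainder is
visible only through the elliptical cross-section signature (~0.5 mm at
the default amplitudes), which voxel rasterization plus 1.5 mm smoothing
largely erases. In end-to-end runs at the default conditions the dominant
recovered modes align with the planted fields at best-match |cos| ≈ 0.7
(size), 0.99 (varus/valgus tilt), 0.7 (version), but the ramped torsion
and distal-twist fields are only partially recovered. This is a property
of nearest-point correspondence at CT-like resolution — group-wise or
feature-aware correspondence would be required to do better and is out of
scope — and it is why passing tests on synthetic data should not be read
as a claim that torsional modes of real canals are recovered without
attenuation. The size-mode identification and the variance-ranking
machinery are unaffected: the end-to-end pipeline ranks size first and
passes the smoothing-fidelity thresholds at the default noise.

# Numerical choices

* Covariance normalized by $n-1$; modes retained while
  $\lambda > 10^{-9}\lambda_1$ (reporting defaults to five).
* Rigid transforms validated to orthonormality and det +1 within 1e-9;
  Kabsch uses a determinant correction, never a reflection.
* Voxelization marks voxel centers strictly inside the surface by +z
  ray-casting parity; the grid adds a one-voxel margin and centers sit at
  half-spacing offsets from the minimum vertex coordinate, so
  lattice-aligned geometry cannot tie; coincident crossings from coplanar
  triangle pairs are collapsed. Default IoU/voxelization spacing is 1 mm —
  sub-millimetre detail is below CT segmentation fidelity.
* Closest-point queries prune through a uniform centroid grid (expanding
  ring search with a two-ring safety margin); meshes under 2048 faces are
  searched exhaustively, and `k_candidates = 0` forces the exhaustive path
  (used by the oracles).
* ICP requires ≥ 3 non-collinear source points and errors otherwise;
  `map_points` flags cases whose final mean distance exceeds a divergence
  cap (default 25 mm).
* Degenerate inputs error early with informative messages: open meshes for
  volume/voxelization (listing boundary edges), empty canal masks, crest
  collinear with the condylar line, neck axis without axial projection.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: spectrum recovery uses $n = 64$ subjects × 3006
coordinates averaged over ten seeds; generator calibration checks use
populations up to $n = 10{,}000$ (coefficients) and $n = 5{,}000$
(spectrum); the end-to-end mesh run uses 64 phantoms at 1 mm spacing with
1002-point correspondence, completing in a couple of minutes.

# What the synthetic data does not emulate

Real canals have irregular, subject-specific cross-sections, cortical
thickness variation, trabecular texture, metal artifacts and field-of-view
truncation; landmarks on real scans carry digitization error, while the
generator's landmarks are exact (so anatomical frames are recovered
exactly). Passing the planted-truth tests therefore validates the
machinery — segmentation accuracy, correspondence plumbing, PCA recovery,
variance accounting — not clinical performance on patient CTs.
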