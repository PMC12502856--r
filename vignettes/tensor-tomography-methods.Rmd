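---
title: "Reconstructing voxel-resolved reciprocal-space maps from scanning SAXS/WAXS data"
author: "tensortomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing voxel-resolved reciprocal-space maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensortomo)
```

## The problem

Scanning small- and wide-angle X-ray scattering tomography raster-scans a
sample through a focused beam while rotating it on a two-axis goniometer
(an inner rotation stage carried by an outer tilt stage).  Instead of a
single transmission value, every scan point records an azimuthally
regrouped diffraction pattern: the scattered intensity in C azimuthal
detector segments at a fixed scattering angle 2θ.  The measurements
therefore form a five-dimensional array D[s, j, k, c] over goniometer
settings s, raster positions (j, k) and detector segments c.

The object of reconstruction is a *tensor field*: in every voxel a function
W(q̂) on the unit sphere — one fixed-|q| shell of the local 3D
reciprocal-space map (RSM) — describing how strongly that voxel scatters in
each direction.  Scattering intensities obey Friedel symmetry,
W(q̂) = W(−q̂), which is why a half-circle detector suffices for SAXS and
why even spherical-harmonic degrees carry all the signal.

## Forward model

Three linear maps compose the forward model:

1. **Basis expansion.**  W(q̂) = Σᵢ cᵢ fᵢ(q̂) with basis functions fᵢ on the
   sphere.  Three linear basis families are provided:
   real orthonormal spherical harmonics up to a band limit
   (`SphericalHarmonicsBasis`; even degrees only under Friedel symmetry;
   coefficient order is degree-ascending, order m = −l…l),
   nearest-neighbor indicator functions on an orientation grid
   (`NearestNeighborBasis`), and antipodally symmetrized spherical Gaussian
   kernels exp(−d²/2σ²) in the geodesic angle d with peak value 1
   (`GaussianKernelBasis`, unnormalized — any scale is absorbed by the
   coefficients).
2. **Detector-segment response.**  Segment c at goniometer setting s probes
   the *average* of W over its arc, with the probed direction
   q̂(φ) = cos θ (cos φ q̂₀ + sin φ q̂₉₀) − sin θ p̂ rotated into the sample
   frame by the transpose of the goniometer rotation
   R_s = R(β_s, outer axis) · R(α_s, inner axis).  `segmentIntegrals`
   evaluates the arc averages B[s, c, i] by adaptive Simpson (Newton–Cotes)
   quadrature to an absolute tolerance of 1e−6, or — the documented fast
   path — by a single evaluation at the central angle of each segment.  The
   sign of the out-of-plane −sin θ p̂ term is exposed as an argument
   (`tiltSign`) because conventions differ between beamlines; the default
   tilts the scattering vector against the beam.  At 2θ = 0 (the
   small-angle limit) the term vanishes.
3. **John transform.**  The beam at scan position (j, k) integrates the
   field along its path.  The projector implements Joseph's interpolating
   method: rays march in unit steps along the dominant component of the
   rotated beam direction and the field is bilinearly interpolated in the
   transverse plane.  The interpolation weights are the beam–voxel overlap
   coefficients; each lies in [0, 1] and is exactly zero for voxels the ray
   does not touch.  We deliberately do not rescale the per-step weights by
   the inverse dominant beam component: that factor (up to √3 for oblique
   rays) would push individual matrix entries above 1, breaking the overlap
   interpretation and the unit bound on the system-matrix entries.  Because
   the same discretization is used for data simulation and reconstruction,
   this convention is self-consistent; only when comparing absolute
   intensities across very different beam obliquities would the ≤15% path
   under-counting of oblique rays matter.  Per-projection offsets Δj, Δk
   (from parasitic stage movement) are applied as sub-pixel shifts of the
   ray origins, never by resampling data.  The adjoint uses identical
   weights, so `forwardProject`/`adjointProject` are an exact matrix
   transpose pair — gradient-based optimization gets a true gradient, and
   the dot-product identity ⟨Ax, y⟩ = ⟨x, Aᵀy⟩ holds to round-off (this is
   the module's central tested contract).  The compiled implementation is
   verified entry-by-entry against a dense ray tracer written independently
   in plain R.

Voxel and scan grids are both centered: voxel x has center coordinate
(x − (N−1)/2)·a, ray (j, k) has transverse origin
((j − (J−1)/2) + Δj)·b, with voxel size a and scan step b equal by default.

## Inversion

Reconstruction minimizes a weighted residual norm plus optional penalties,

loss(c) = Σ ρ( w · (A c − D) ) + Σ μ · reg(D c),

where the per-measurement weights w multiply residuals (weight 0 excludes a
measurement entirely — the masking convention used for dead pixels and
degenerate transmission values) and ρ is either the squared loss or the
Huber loss (quadratic inside δ, linear outside; default δ = 1).

Regularizers (`regularizerValueGrad`): squared norm of the 6-neighbor
finite-difference Laplacian with reflective boundaries (so constant fields
are unpenalized and the operator is symmetric), total variation as the
Huber norm of forward spatial differences (no difference is taken across
the far boundary — differencing against padded zeros would spuriously
penalize constant fields; smoothing default δ = 1e−2 in coefficient
units), plus plain L2, L1 and elementwise-Huber norms of the field.  With a
spherical-harmonics basis the L1 and Huber norms are not rotational
invariants and can bias solutions toward particular directions; the package
warns when this combination is used.

Pipelines:

* **SIRT** — the classical preconditioned Landweber iteration
  x ← x + C Aᵀ R (b − A x), with R and C the inverse row and column sums of
  |A| computed matrix-free (absolute values keep the weights well defined
  for signed harmonic responses; for nonnegative responses they equal the
  plain sums).  Sums below 1e−12 of the maximum are masked out.  Iteration
  count is the regularization knob (semi-convergence); the default cap is
  20 iterations.
* **MITRA** — the same preconditioned gradient step generalized to
  arbitrary regularizers and optional Nesterov momentum
  (γₜ = (t−1)/(t+2)).  With no regularizers and no momentum it reproduces
  SIRT exactly (tested to 1e−12).  Note that the fixed preconditioned step
  combined with nonsmooth penalties (L1) is only stable for moderate
  weights; large weights make the subgradient step oscillate, which the
  pipeline detects (loss growth guard) and reports rather than returning a
  meaningless iterate.  The Huber-smoothed norm converges more easily and
  is the recommended sparsity penalty.
* **SIGTT** — spherical harmonics, squared loss, Laplacian regularization,
  minimized by L-BFGS-B (`stats::optim`) from a zero start with a relative
  loss-change stop (default 1e−4, mapped to the optimizer's `factr`);
  deterministic given the data.
* **DD** (discrete directions) — splits the tensor problem into independent
  scalar tomograms, one per orientation-grid direction of a
  nearest-neighbor basis: measurements whose segment arc responds to
  direction m (positive arc-averaged indicator, which also weights the
  sub-problem so total signal is conserved) are reconstructed by scalar
  SIRT and become channel m.  A direction with no assigned measurements
  yields a zeroed channel and a warning.

All pipelines are pure functions of the input stack, start from zero (the
models are convex) and record their loss trace in the provenance.

## Alignment

Parasitic sample motion during rotation misaligns projections by offsets
Δj, Δk that must be estimated before reconstruction.  `phaseMatchingAlign`
iterates: scalar SIRT reconstruction of an isotropic signal (transmission
or azimuthally averaged intensity) with the current offsets → forward
re-projection → per-projection sub-pixel cross-correlation of measured
versus synthetic images → damped offset update (damping 0.8, chosen to
stabilize the reconstruct–reproject loop).  The correlation peak is
localized by the center of mass of a 5×5 window around the argmax and then
refined on a 10× Fourier-upsampled grid (matrix-multiply DFT evaluation in
a ±1.5 px neighborhood), giving ≈0.1 px resolution.

A rigid translation t of the object changes every projection's offsets by
(ĵ_s·t, k̂_s·t) and is unobservable from projection consistency.  Simply
constraining the mean offset to zero does not remove this 3-parameter
family, and the reconstruct–reproject loop will happily drift along it; the
loop therefore projects the offsets onto the orthogonal complement of the
translation gauge after every update (`removeTranslationGauge`).  Recovered
offsets and ground-truth shifts must be compared after applying the same
projection to both.  A common shift of *all* projections, by contrast, is
pure gauge only when the scan axis is rotation-invariant (the k axis of an
untilted single-axis scan); with tilts it is genuine signal and is
recovered as such.

## Derived quantities

From a coefficient field the package computes per voxel: the spherical mean
intensity (analytic for harmonics, c₀₀/√(4π)); the second-moment tensor
T = ∮ W(q̂) q̂ q̂ᵀ dΩ (closed form from the degree-0/2 coefficients for
harmonics — only those degrees contribute — or by sphere quadrature); its
eigensystem; the fractional anisotropy
FA = √(3/2) · ‖λ − λ̄‖ / ‖λ‖ ∈ [0, 1]; the main orientation (largest
eigenvector for polar-cap scattering, smallest for an equatorial band, sign
fixed so the first nonvanishing component is positive, degenerate pairs
flagged); and the relative anisotropy (spherical standard deviation over
mean).  T is left unnormalized by the spherical mean — FA and the
orientation are invariant to that choice.  Sphere integrals use a
Gauss–Legendre × uniform-azimuth product rule, which is exact for the
polynomial integrands involved; the default 1000-node rule is already far
beyond the accuracy of any reconstruction.

## The synthetic-data generator

`makePhantom` builds a spherical (or concentric-shell) support carrying a
smoothly bending orientation field u(x) and per-voxel maps
W(q̂) = (1 − A) + A·g(q̂·u), with g either a Gaussian equatorial band
(width 0.35 in q̂·u — the fiber-scattering archetype, scattering
perpendicular to the axis) or Gaussian polar caps, expanded in the
requested basis by weighted least squares on a quadrature mesh (an
orthonormal projection for harmonics).  The ground truth returned is the
*band-limited* field, so recovery tests compare against what the basis can
represent.  `simulateExperiment` runs the exact forward model, injects
per-projection shifts as ray-origin offsets (recording zeros in the output
stack, as a misaligned experiment would), adds Gaussian noise (sd relative
to the mean model intensity) or scaled Poisson counts, and simulates the
transmission diode as a Beer–Lambert signal of the mean-intensity map with
unit maximum optical depth — enough absorption contrast for alignment to
work with.  The default acquisition crosses full inner rotations with
outer tilts of 0°, 20° and 40°, mimicking a typical rotation-plus-tilt
acquisition.

What the generator does *not* emulate: detector solid-angle/polarization
corrections (assumed already applied upstream), beam profiles wider than
one voxel, multi-q shells, q-dependent geometry, and detector noise
correlations.  Passing recovery tests therefore demonstrates correctness
of the model and solvers, not robustness to every artifact of real
beamline data.

## Validation problem sizes and numerical choices

The validation suite uses 16³-voxel phantoms with 60 projections
(20 rotations × 3 tilts), 8 half-circle segments and a degree-4 harmonic
basis for recovery tests, 8³ grids for dense-oracle comparisons, and a 32³
phantom with 24 projections for alignment; these sizes keep the full suite
around two minutes while leaving every contract sharply testable.  For the
convergence-quality checks SIGTT is run with `maxIter = 200, tol = 0` — the
pipeline default of 20 iterations matches common practice for routine
reconstructions, but quality bars (coefficient correlation ≥ 0.95,
orientation error ≤ 5°) are properties of the converged estimator.
Other fixed numerical choices: quadrature tolerance 1e−6 (absolute) for
segment responses; preconditioner masking at 1e−12 of the maximum sum;
degenerate-eigenpair threshold 1e−9 of the tensor trace with a
deterministic index tie-break; divergence guard at 10× initial loss.

## Limitations

The zonal-harmonics (symmetric-RSM) nonlinear workflow, optical-flow
alignment, GPU execution and fused sparse projector–basis kernels are out
of scope.  Only one q shell is handled per reconstruction; multi-q joint
reconstruction and azimuthal regrouping of raw frames belong upstream.
The projector models the beam footprint with bilinear interpolation only —
finite beam width beyond one voxel is not represented.
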