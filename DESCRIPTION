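Package: tensortomo
Title: Tensor Tomography of Small- and Wide-Angle X-Ray Scattering Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of voxel-resolved reciprocal-space maps from
    azimuthally regrouped small- and wide-angle X-ray scattering tensor
    tomography (SAXS-TT/WAXS-TT) data. Provides the experimental geometry
    model, an HDF5 projection-stack reader and writer, a matched
    forward/adjoint John-transform projector based on Joseph's
    interpolating method, spherical-harmonic, nearest-neighbor and
    Gaussian-kernel basis sets on the unit sphere, weighted least-squares
    and Huber losses with Laplacian, total-variation, L1, L2 and Huber
    regularizers, SIRT, MITRA, SIGTT and discrete-directions
    reconstruction pipelines, iterative phase-matching projection
    alignment by sub-pixel cross-correlation, derived per-voxel
    orientation and fractional-anisotropy maps, and a synthetic phantom
    generator for validation and experiment planning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    pracma,
    rhdf5
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
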