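make_stack <- function(S = 3L, J = 4L, K = 5L, C = 4L, seed = 30L) {
    set.seed(seed)
    g <- TTGeometry(innerAngles = runif(S, 0, 2 * pi),
                    outerAngles = runif(S, 0, 0.5),
                    jOffsets = rnorm(S, sd = 0.5), kOffsets = rnorm(S, sd = 0.5),
                    volumeShape = c(4L, 4L, 4L))
    new("ProjectionStack",
        data = array(abs(rnorm(S * J * K * C)), c(S, J, K, C)),
        diode = array(runif(S * J * K, 0.5, 1), c(S, J, K)),
        weights = array(as.numeric(rbinom(S * J * K * C, 1, 0.9)),
                        c(S, J, K, C)),
        geometry = g, segments = DetectorSegments(C, "half"))
}

test_that("projection stacks round-trip through HDF5 bit-exactly", {
    stack <- make_stack()
    path <- tempfile(fileext = ".h5")
    on.exit(unlink(path))
    saveProjectionStack(stack, path)
    back <- loadProjectionStack(path)
    expect_identical(projectionData(back), projectionData(stack))
    expect_identical(diodeData(back), diodeData(stack))
    expect_identical(measurementWeights(back), measurementWeights(stack))
    g1 <- geometry(stack); g2 <- geometry(back)
    for (nm in c("pDirection", "innerAxis", "outerAxis", "innerAngles",
                 "outerAngles", "jOffsets", "kOffsets"))
        expect_identical(slot(g2, nm), slot(g1, nm))
    expect_identical(g2@volumeShape, g1@volumeShape)
    expect_identical(detectorSegments(back)@boundaries,
                     detectorSegments(stack)@boundaries)
})

test_that("missing optional datasets default to ones and gaps are rejected", {
    stack <- make_stack(S = 2L)
    path <- tempfile(fileext = ".h5")
    on.exit(unlink(path))
    saveProjectionStack(stack, path)
    # strip the optional weights of projection 0 and reload
    rhdf5::h5delete(path, "projections/0/weights")
    back <- loadProjectionStack(path)
    expect_equal(measurementWeights(back)[1, , , ],
                 array(1, dim(projectionData(stack))[2:4]))
    expect_identical(measurementWeights(back)[2, , , ],
                     measurementWeights(stack)[2, , , ])
    # renaming projection 1 to 2 leaves a gap, which must be named
    file.rename(path, path)  # no-op, keep handle clear
    rhdf5::h5closeAll()
    fid <- rhdf5::H5Fopen(path)
    rhdf5::H5Lmove(fid, "projections/1", fid, "projections/2")
    rhdf5::H5Fclose(fid)
    expect_error(loadProjectionStack(path), "\"1\"")
})

test_that("geometry defaults and overrides control missing file fields", {
    stack <- make_stack(S = 2L)
    path <- tempfile(fileext = ".h5")
    on.exit(unlink(path))
    saveProjectionStack(stack, path)
    rhdf5::h5delete(path, "inner_axis")
    back <- loadProjectionStack(path, defaults = list(innerAxis = c(1, 0, 0)))
    expect_equal(geometry(back)@innerAxis, c(1, 0, 0))
    back2 <- loadProjectionStack(path,
                                 defaults = list(innerAxis = c(1, 0, 0)),
                                 override = list(jOffsets = c(0.25, -0.25)))
    expect_equal(geometry(back2)@jOffsets, c(0.25, -0.25))
})

test_that("segment centers are converted to boundaries on request", {
    stack <- make_stack(C = 4L)
    path <- tempfile(fileext = ".h5")
    on.exit(unlink(path))
    saveProjectionStack(stack, path)
    centers <- (stack@segments@boundaries[-1] + stack@segments@boundaries[-5]) / 2
    rhdf5::h5delete(path, "detector_angles")
    rhdf5::h5write(centers, path, "detector_angles")
    back <- loadProjectionStack(path, centers = TRUE)
    expect_equal(detectorSegments(back)@boundaries,
                 stack@segments@boundaries, tolerance = 1e-12)
})

test_that("transmission normalization divides data and masks dead pixels", {
    stack <- make_stack()
    # identity when the diode is 1
    s1 <- stack; s1@diode[] <- 1
    expect_equal(projectionData(normalizeByTransmission(s1)),
                 projectionData(stack))
    # plain division
    s2 <- stack; s2@diode[] <- 2; s2@data[] <- 6
    expect_equal(as.numeric(projectionData(normalizeByTransmission(s2))),
                 rep(3, length(s2@data)))
    # a dead diode pixel masks all its segments
    s3 <- stack; s3@diode[2, 1, 3] <- 0
    n3 <- normalizeByTransmission(s3)
    expect_equal(as.numeric(measurementWeights(n3)[2, 1, 3, ]),
                 rep(0, dim(s3@data)[4]))
    expect_equal(measurementWeights(n3)[1, , , ], measurementWeights(s3)[1, , , ])
})

test_that("reconstructions round-trip with basis descriptor and maps", {
    sh <- SphericalHarmonicsBasis(2)
    set.seed(31)
    co <- array(rnorm(2 * 3 * 2 * 6), c(2, 3, 2, 6))
    rec <- new("TTReconstruction", field = TensorField(co, sh),
               maps = list(), provenance = list(pipeline = "SIGTT",
                                                lossTrace = c(3, 2, 1)))
    path <- tempfile(fileext = ".h5")
    on.exit(unlink(path))
    saveReconstruction(rec, path)
    back <- loadReconstruction(path)
    expect_equal(coefficients4D(back), co)
    expect_true(is(basisSet(back), "SphericalHarmonicsBasis"))
    expect_equal(provenance(back)$pipeline, "SIGTT")
    # without maps the file advertises their absence
    expect_equal(as.integer(rhdf5::h5read(path, "has_derived_maps")), 0L)
    # with maps, the derived datasets are present and identical after reload
    rec2 <- deriveMaps(rec)
    saveReconstruction(rec2, path)
    back2 <- loadReconstruction(path)
    expect_equal(back2@maps$fractional_anisotropy,
                 rec2@maps$fractional_anisotropy)
    expect_true(all(c("mean_intensity", "second_moment", "eigenvalues",
                      "eigenvectors", "main_orientation") %in%
                    names(back2@maps)))
    # a mismatched coefficient/basis combination cannot be constructed
    expect_error(TensorField(co, SphericalHarmonicsBasis(4)), "match")
    # a Gaussian-kernel basis descriptor round-trips too
    gk <- GaussianKernelBasis(fibonacciGrid(5), sigma = 0.25)
    recG <- new("TTReconstruction",
                field = TensorField(array(rnorm(8 * 5), c(2, 2, 2, 5)), gk),
                maps = list(), provenance = list())
    saveReconstruction(recG, path)
    backG <- loadReconstruction(path)
    expect_equal(basisSet(backG)@sigma, 0.25)
    expect_equal(basisSet(backG)@directions, gk@directions)
})
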