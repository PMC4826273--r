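test_that("generators are pure functions of their seed", {
    d1 <- makeTemplateEGF(seed = 4L)
    d2 <- makeTemplateEGF(seed = 4L)
    expect_identical(atoms(d1$structure), atoms(d2$structure))
    d3 <- makeTemplateEGF(seed = 5L)
    expect_false(identical(atoms(d1$structure)$x, atoms(d3$structure)$x))
    r1 <- simulateRDCs(fxModel4()$model, fxTensorA(), noise = 2, seed = 6L)
    r2 <- simulateRDCs(fxModel4()$model, fxTensorA(), noise = 2, seed = 6L)
    expect_identical(r1, r2)
})

test_that("generated domains satisfy the consuming invariants", {
    d <- makeTemplateEGF(seed = 1L)
    expect_true(validObject(d$structure))
    expect_true(validObject(d$definition))
    expect_true(validObject(d$sequence))
    ## classifier as oracle for the cb request
    expect_true(classifyCaBinding(d$sequence)$isCb)
    expect_false(classifyCaBinding(
        makeTemplateEGF(seed = 1L, cb = FALSE)$sequence,
        allowDAtThird = TRUE)$isCb)
    expect_error(makeTemplateEGF(nResidues = 20L), "at least 25")
})

test_that("multidomain construction records retrievable ground truth", {
    tilts <- c(45, 33, 15)
    m <- makeMultidomain(4L, lapply(tilts, InterdomainGeometry,
                                    twist = 120), seed = 12L)
    got <- vapply(measureGeometries(m), tiltAngle, numeric(1L))
    expect_equal(got, tilts, tolerance = 1e-6)
    expect_error(makeMultidomain(4L, list(InterdomainGeometry(0, 0))),
                 "nDomains - 1")
})

test_that("simulated RDC noise is recovered in the refit residuals", {
    fx <- fxModel4()
    rdc <- simulateRDCs(fx$model, fxTensorA(), noise = 2, seed = 9L)
    fit <- fitTensorSVD(fx$vectors, rdc)
    expect_equal(fit@rmsDev, 2, tolerance = 0.25)
})

test_that("the flexible-construct generator defeats the joint fit", {
    fx <- fxModel4()
    rdc <- simulateRDCs(fx$model, fxTensorA(), noise = 2, seed = 10L,
                        flexibleLinkerIndex = 2L, tensorB = fxTensorB())
    fits <- fitSegments(fx$vectors, rdc,
                        list(c("EGF1", "EGF2"), c("EGF3", "EGF4")))
    expect_gt(qFactor(fits$joint),
              max(qFactor(fits$segments[[1L]]),
                  qFactor(fits$segments[[2L]])))
    expect_identical(verdict(flexibilityTest(fits$segments, fits$joint)),
                     "flexible")
})

test_that("hetNOE simulation drives the full flagging pipeline", {
    ## no flexible regions: nothing flagged, linkers rigid
    p0 <- simulateHetNOE(1:40, list(), seed = 13L)
    f0 <- flagFlexible(computeHetNOE(p0, seed = 1L),
                       linkers = list(l = c(35, 40)))
    expect_false(any(f0$residues$flexible))
    expect_identical(f0$linkers$verdict, "rigid")
    ## mobile N terminus: exactly those four residues
    p4 <- simulateHetNOE(1:40, list(c(1, 4)), seed = 14L)
    f4 <- flagFlexible(computeHetNOE(p4, seed = 1L),
                       linkers = list(l = c(35, 40)))
    expect_identical(f4$residues$residue[f4$residues$flexible], 1:4)
    expect_identical(f4$linkers$verdict, "rigid")
})

test_that("titration simulators close the loop with the fitters", {
    tc <- simulateCompetition(4e-6, noise = 0, seed = 1L)
    expect_true(validObject(tc))
    expect_equal(kdValues(fitCompetition(tc, 1L)), 4e-6,
                 tolerance = 1e-6)
    cv <- simulateNMRTitration(170e-6, noise = 0, seed = 1L)
    expect_true(validObject(cv))
    expect_equal(kdValues(fitNMRTitration(cv)), 170e-6,
                 tolerance = 1e-6)
})

test_that("competition Kd recovery stays accurate under noise", {
    relErr <- vapply(1:40, function(i) {
        t <- simulateCompetition(10e-6, noise = 0.005, seed = 500L + i)
        abs(kdValues(fitCompetition(t, 1L)) - 10e-6) / 10e-6
    }, numeric(1L))
    expect_lt(median(relErr), 0.05)
})
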