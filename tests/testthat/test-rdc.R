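test_that("the two back-calculation routes agree to 1e-10", {
    set.seed(100)
    for (i in 1:10) {
        t0 <- makeTensor(runif(1, -20, 20), runif(1, 0, 2 / 3),
                         runif(3, -180, 180))
        v <- randomUnitVectors(25, seed = 100 + i)
        expect_lt(max(abs(backCalculate(t0, v) -
                          backCalculate(t0, v, method = "angles"))), 1e-10)
    }
})

test_that("back-calculation limits match the dipolar equation", {
    t0 <- makeTensor(7, 0.3)
    ## bond along the principal z axis: D = 2 Da
    expect_equal(backCalculate(t0, c(0, 0, 1)), 14)
    ## theta = 90, phi = 0: D = Da (-1 + 1.5 R)
    expect_equal(backCalculate(t0, c(1, 0, 0)), 7 * (-1 + 0.45))
    ## Da = 0: identically zero
    tz <- makeTensor(0, 0)
    expect_equal(backCalculate(tz, randomUnitVectors(5, 1)),
                 rep(0, 5))
})

test_that("Q factor follows its definition", {
    expect_equal(rdcQ(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(rdcQ(c(1, 2, 3), c(0, 0, 0)), 1)
    expect_equal(rdcQ(c(10, -5, 3), c(8, -4, 2)), sqrt(6 / 134))
    expect_error(rdcQ(c(0, 0), c(1, 1)), "all observed")
})

test_that("noiseless RDCs invert to the exact tensor", {
    fx <- fxModel4()
    t0 <- fxTensorA()
    rdc <- simulateRDCs(fx$model, t0, noise = 0, seed = 5L)
    fit <- fitTensorSVD(fx$vectors, rdc)
    expect_lt(qFactor(fit), 1e-9)
    expect_lt(max(abs(saupeMatrix(alignmentTensor(fit)) -
                      saupeMatrix(t0))), 1e-9)
    expect_equal(daValue(fit), 14.9, tolerance = 1e-9)
    expect_equal(rhombicity(alignmentTensor(fit)), 0.25,
                 tolerance = 1e-9)
})

test_that("underdetermined and degenerate geometries are refused", {
    fx <- fxModel4()
    rdc <- simulateRDCs(fx$model, fxTensorA(), noise = 0, seed = 5L)
    expect_error(fitTensorSVD(fx$vectors[1:4, ], rdc), "at least 5")
    ## all vectors parallel: rank deficient
    vpar <- data.frame(residue = rdc$residue[1:20],
                       domain = rdc$domain[1:20],
                       vx = 0, vy = 0, vz = 1)
    expect_error(fitTensorSVD(vpar, rdc[1:20, ]), "rank deficient")
})

test_that("noisy fits recover Da within the propagated uncertainty", {
    fx <- fxModel4()
    t0 <- fxTensorA()
    hits <- 0L
    for (i in 1:25) {
        rdc <- simulateRDCs(fx$model, t0, noise = 2, seed = 200L + i)
        fit <- fitTensorSVD(fx$vectors, rdc)
        if (abs(daValue(fit) - 14.9) < 3 * daError(fit)) hits <- hits + 1L
    }
    expect_gte(hits, 23L)
})

test_that("Q and Da are invariant under global rotation", {
    fx <- fxModel4()
    t0 <- fxTensorA()
    rdc <- simulateRDCs(fx$model, t0, noise = 1, seed = 77L)
    fit0 <- fitTensorSVD(fx$vectors, rdc)
    R <- egfarch:::rotationAboutAxis(c(1, 1, 2), 1.1)
    vrot <- fx$vectors
    vrot[, c("vx", "vy", "vz")] <-
        as.matrix(fx$vectors[, c("vx", "vy", "vz")]) %*% t(R)
    fitR <- fitTensorSVD(vrot, rdc)
    expect_equal(qFactor(fitR), qFactor(fit0), tolerance = 1e-9)
    expect_equal(daValue(fitR), daValue(fit0), tolerance = 1e-9)
    expect_equal(rhombicity(alignmentTensor(fitR)),
                 rhombicity(alignmentTensor(fit0)), tolerance = 1e-9)
})

test_that("segment fits: a single segment equals the joint fit", {
    fx <- fxModel4()
    rdc <- simulateRDCs(fx$model, fxTensorA(), noise = 1, seed = 31L)
    r <- fitSegments(fx$vectors, rdc,
                     list(c("EGF1", "EGF2", "EGF3", "EGF4")))
    expect_equal(qFactor(r$segments[[1L]]), qFactor(r$joint))
    expect_equal(daValue(r$segments[[1L]]), daValue(r$joint))
})

test_that("flexibility verdict clauses fire as specified", {
    mkFit <- function(da, daSe, q)
        new("TensorFit", tensor = makeTensor(da, 0.2), q = q,
            rmsDev = 1, daSe = daSe, nUsed = 30L, condition = 3)
    ## opposite Da signs: flexible regardless of Q
    v1 <- flexibilityTest(list(`EGF8+EGF9` = mkFit(14.9, 0.5, 0.15),
                               `EGF10+EGF11` = mkFit(-8.5, 0.3, 0.2)),
                          mkFit(5, 1, 0.21))
    expect_identical(verdict(v1), "flexible")
    expect_match(v1@rationale, "signs differ")
    ## identical tensors and consistent joint Q: rigid
    v2 <- flexibilityTest(list(a = mkFit(10, 0.5, 0.2),
                               b = mkFit(10, 0.5, 0.2)),
                          mkFit(10, 0.4, 0.21))
    expect_identical(verdict(v2), "rigid")
    ## overlapping Da within errors, consistent Q: rigid
    v3 <- flexibilityTest(list(a = mkFit(10, 3, 0.2),
                               b = mkFit(8, 3, 0.22)),
                          mkFit(9, 2, 0.23))
    expect_identical(verdict(v3), "rigid")
    ## same-sign but hugely different Da: flexible via the sigma clause
    v4 <- flexibilityTest(list(a = mkFit(14.9, 0.5, 0.15),
                               b = mkFit(5, 0.3, 0.2)),
                          mkFit(9, 1, 0.22))
    expect_identical(verdict(v4), "flexible")
    expect_match(v4@rationale, "combined sigma")
})

test_that("Monte Carlo tensor uncertainty behaves physically", {
    fx <- fxModel4()
    t0 <- fxTensorA()
    rdc <- simulateRDCs(fx$model, t0, noise = 0, seed = 5L)
    ## zero error: zero spread
    mc0 <- mcTensorUncertainty(fx$vectors, rdc, errorHz = 0, nMc = 10L,
                               seed = 1L)
    expect_lt(mc0$sd["da"], 1e-12)
    ## 2 Hz on a well-conditioned set: spread near the linearized value
    big <- rdc; big$sigma_hz <- 2
    mc2 <- mcTensorUncertainty(fx$vectors, big, errorHz = 2, nMc = 120L,
                               seed = 2L)
    analytic <- daError(fitTensorSVD(fx$vectors, big))
    expect_equal(unname(mc2$sd["da"]), analytic, tolerance = 0.25)
    ## a minimal 6-RDC set is less informative
    idx <- seq_len(6L)
    mc6 <- mcTensorUncertainty(fx$vectors[fx$vectors$residue %in%
                                          rdc$residue[idx], ],
                               big[idx, ], errorHz = 2, nMc = 120L,
                               seed = 3L)
    expect_gt(mc6$sd["da"], mc2$sd["da"])
})
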