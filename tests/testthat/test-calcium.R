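test_that("free-calcium solver matches an independent bisection oracle", {
    ## no binding sites: identity
    expect_equal(solveFreeCa(10e-6), 10e-6)
    ## single site: closed-form quadratic oracle
    ## f^2 + (T + K - Ca) f - K Ca = 0
    T <- 20e-6; K <- 1.6e-6; Ca <- 10e-6
    fQuad <- (-(T + K - Ca) + sqrt((T + K - Ca)^2 + 4 * K * Ca)) / 2
    expect_equal(solveFreeCa(Ca, T, K), fQuad, tolerance = 1e-12)
    expect_equal(fQuad * 1e6, 1.2456, tolerance = 1e-4)
    ## multi-site: bisection oracle
    totals <- c(25e-6, 25e-6, 25e-6); kds <- c(1.6e-6, 4e-6, 60e-6)
    for (ca in c(1e-6, 2e-5, 5e-5, 2e-4))
        expect_equal(solveFreeCa(ca, totals, kds),
                     oracleFreeCa(ca, totals, kds), tolerance = 1e-10)
    ## weak-site limit: free approaches total
    expect_equal(solveFreeCa(10e-6, 20e-6, 1), 10e-6, tolerance = 1e-4)
})

test_that("competition signal has the right endpoints and is decreasing", {
    t0 <- CompetitionTitration(
        points = data.frame(ca_total = c(0, 1e-5), signal = c(1, 0.5)),
        chelatorTotal = 20e-6, proteinTotal = 20e-6, chelatorKd = 1.6e-6)
    expect_equal(competitionSignal(0, t0, 4e-6), 1)
    expect_lt(competitionSignal(5e-3, t0, 4e-6), 0.01)
    grid <- seq(0, 1e-4, length.out = 40)
    sig <- competitionSignal(grid, t0, 4e-6)
    expect_true(all(diff(sig) < 0))
    ## mid-curve value against the oracle solver
    ca <- 3e-5
    f <- oracleFreeCa(ca, c(20e-6, 20e-6), c(1.6e-6, 4e-6))
    expect_equal(competitionSignal(ca, t0, 4e-6), 1.6e-6 / (f + 1.6e-6),
                 tolerance = 1e-9)
})

test_that("competition fitting recovers noiseless Kds exactly", {
    t4 <- simulateCompetition(4e-6, noise = 0, seed = 1L)
    fit <- fitCompetition(t4, 1L)
    expect_true(isConverged(fit))
    expect_equal(kdValues(fit), 4e-6, tolerance = 1e-6)
    expect_lt(sseValue(fit), 1e-12)
})

test_that("Kds far outside the chelation range are flagged", {
    tw <- simulateCompetition(10e-3, noise = 0.002, seed = 2L)
    fit <- fitCompetition(tw, 1L)
    expect_true(isIllDetermined(fit))
})

test_that("a two-site curve prefers the two-site model", {
    t2 <- simulateCompetition(c(2e-6, 15e-6), noise = 0, seed = 3L)
    f1 <- fitCompetition(t2, 1L)
    f2 <- fitCompetition(t2, 2L)
    expect_lt(sseValue(f2), sseValue(f1))
    expect_equal(kdValues(f2), c(2e-6, 15e-6), tolerance = 1e-4)
})

test_that("fitCompetition refuses sparse titrations", {
    t4 <- simulateCompetition(4e-6, noise = 0, seed = 1L, nPoints = 9L)
    short <- CompetitionTitration(titrationPoints(t4)[1:6, ],
                                  25e-6, 25e-6, 1.6e-6)
    expect_error(fitCompetition(short, 1L), "at least 8")
})

test_that("the F test follows its definition and degenerate rules", {
    mkFit <- function(sse, nPar, n = 25L)
        new("BindingFit", nSites = nPar, kd = rep(1e-6, nPar),
            kdSe = rep(1e-7, nPar), amplitude = NA_real_, sse = sse,
            nPoints = n, nPar = nPar, converged = TRUE,
            illDetermined = FALSE)
    ## equal sse: F = 0, keep the simpler model
    r <- fTestSelect(mkFit(0.5, 1L), mkFit(0.5, 2L))
    expect_equal(r$F, 0)
    expect_identical(r$selected, 1L)
    ## formula check against direct arithmetic
    r2 <- fTestSelect(mkFit(0.8, 1L), mkFit(0.3, 2L))
    Fexp <- ((0.8 - 0.3) / 1) / (0.3 / (25 - 2))
    expect_equal(r2$F, Fexp)
    expect_equal(r2$p, pf(Fexp, 1, 23, lower.tail = FALSE))
    expect_identical(r2$selected, 2L)
    ## perfect richer fit
    r3 <- fTestSelect(mkFit(0.1, 1L), mkFit(0, 2L))
    expect_identical(r3$selected, 2L)
    expect_equal(r3$p, 0)
    expect_error(fTestSelect(mkFit(0.1, 2L), mkFit(0.2, 1L)), "nested")
    expect_error(fTestSelect(mkFit(0.1, 1L), mkFit(0.1, 2L, n = 20L)),
                 "same data")
})

test_that("NMR titration fitting recovers low- and medium-affinity Kds", {
    for (kd in c(170e-6, 19e-3)) {
        cv <- simulateNMRTitration(kd, noise = 0, seed = 1L)
        fit <- fitNMRTitration(cv)
        expect_equal(kdValues(fit), kd, tolerance = 1e-6)
        expect_equal(fit@amplitude, 1, tolerance = 1e-6)
        expect_false(isIllDetermined(fit))
    }
    ## the contextual affinity enhancement reproduced from the two fits
    kHi <- kdValues(fitNMRTitration(simulateNMRTitration(19e-3,
                                                         seed = 1L)))
    kLo <- kdValues(fitNMRTitration(simulateNMRTitration(170e-6,
                                                         seed = 1L)))
    expect_equal(kHi / kLo, 19e-3 / 170e-6, tolerance = 1e-5)
})

test_that("a featureless titration is flagged, not silently fitted", {
    flat <- NMRTitrationCurve(
        points = data.frame(ca_total = seq(0, 1e-3, length.out = 8),
                            observed = rep(0.4, 8)),
        proteinTotal = 100e-6)
    fit <- fitNMRTitration(flat)
    expect_true(isIllDetermined(fit))
    expect_equal(fit@amplitude, 0)
})

test_that("occupancy arithmetic matches the saturation statements", {
    expect_equal(occupancy(170e-6, 1.4e-3)$fractionBound, 0.8917,
                 tolerance = 1e-4)
    expect_equal(occupancy(60e-6, 1.4e-3)$fractionBound, 0.9589,
                 tolerance = 1e-4)
    expect_equal(occupancy(3.7e-5, 3.7e-5)$fractionBound, 0.5)
    o <- occupancy(2e-6, 8e-6)
    expect_identical(o$fractionBound, o$freeCa / (o$freeCa + o$kd))
})
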