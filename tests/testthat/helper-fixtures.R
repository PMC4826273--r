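## Shared fixtures, built once per test run. Everything is generated in
## code from fixed seeds; nothing is loaded from outside the package.

.fx <- new.env(parent = emptyenv())

fxPair <- function() {
    if (is.null(.fx$pair))
        .fx$pair <- list(
            a = makeTemplateEGF(seed = 1L, domainId = "EGF5"),
            b = makeTemplateEGF(seed = 2L, domainId = "EGF6",
                                startResidue = 42L))
    .fx$pair
}

## Rigid four-domain model with its definitions and N-H vectors.
fxModel4 <- function() {
    if (is.null(.fx$model4)) {
        m <- makeMultidomain(
            4L, list(InterdomainGeometry(20, 100),
                     InterdomainGeometry(30, -120),
                     InterdomainGeometry(15, 130)), seed = 3L)
        defs <- lapply(modelFragments(m), `[[`, "definition")
        .fx$model4 <- list(
            model = m, defs = defs,
            vectors = extractNHVectors(modelStructure(m), defs))
    }
    .fx$model4
}

fxTensorA <- function() makeTensor(14.9, 0.25, c(20, 40, 60))
fxTensorB <- function() makeTensor(-8.5, 0.2, c(-50, 70, 10))

## Independent oracle: bisection on the calcium mass balance, written
## without reference to the package's solver.
oracleFreeCa <- function(caTotal, totals, kds, iter = 200L) {
    g <- function(f) f + sum(totals * f / (f + kds)) - caTotal
    lo <- 0; hi <- caTotal
    for (i in seq_len(iter)) {
        mid <- (lo + hi) / 2
        if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
}

## Smallest difference between two angles in degrees (handles the
## -180/+180 wrap).
angDiff <- function(a, b) {
    d <- (a - b + 180) %% 360 - 180
    abs(d)
}

randomUnitVectors <- function(n, seed) {
    set.seed(seed)
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
}
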