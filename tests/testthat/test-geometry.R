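test_that("domain frames are orthonormal and rotation-equivariant", {
    fx <- fxPair()
    f <- domainFrame(fx$a$structure, fx$a$definition)
    expect_equal(sum(f@longAxis^2), 1, tolerance = 1e-9)
    expect_equal(sum(f@longAxis * f@twistRef), 0, tolerance = 1e-9)
    R <- egfarch:::rotationAboutAxis(c(2, -1, 1), 0.8)
    tr <- new("RigidTransform", rotation = R, translation = c(3, 4, -5))
    f2 <- domainFrame(applyTransform(fx$a$structure, tr),
                      fx$a$definition)
    expect_equal(f2@longAxis, drop(R %*% f@longAxis), tolerance = 1e-9)
    expect_equal(f2@twistRef, drop(R %*% f@twistRef), tolerance = 1e-9)
})

test_that("template-based frames agree with direct frames", {
    fx <- fxPair()
    ## template onto itself: identical frame
    fDirect <- domainFrame(fx$a$structure, fx$a$definition)
    fTempl <- domainFrame(fx$a$structure, fx$a$definition, template = fx$a)
    expect_equal(fTempl@longAxis, fDirect@longAxis, tolerance = 1e-9)
    expect_equal(fTempl@twistRef, fDirect@twistRef, tolerance = 1e-9)
    ## template carried onto a rotated copy rotates with it
    R <- egfarch:::rotationAboutAxis(c(0, 1, 1), 1.2)
    tr <- new("RigidTransform", rotation = R, translation = c(1, 2, 3))
    rot <- list(structure = applyTransform(fx$a$structure, tr),
                definition = fx$a$definition)
    fCarried <- domainFrame(rot$structure, rot$definition, template = fx$a)
    expect_equal(fCarried@longAxis, drop(R %*% fDirect@longAxis),
                 tolerance = 1e-6)
})

test_that("frames from incomplete domains are flagged", {
    fx <- fxPair()
    a <- atoms(fx$a$structure)
    keep <- !(a$atom == "CA" & a$resno %in% c(7, 9, 13, 20, 22, 25, 31, 33,
                                              35, 36, 37, 38))
    f <- domainFrame(Structure(a[keep, ]), fx$a$definition)
    expect_true(attr(f, "incomplete"))
    ## too few atoms is an error
    few <- !(a$atom == "CA" & a$resno %in% 6:35)
    expect_error(domainFrame(Structure(a[few, ]), fx$a$definition),
                 "fewer than 10")
})

test_that("identical frames give zero tilt and twist", {
    fx <- fxPair()
    f <- domainFrame(fx$a$structure, fx$a$definition)
    g <- tiltTwist(f, f)
    expect_equal(tiltAngle(g), 0, tolerance = 1e-9)
    expect_equal(twistAngle(g), 0, tolerance = 1e-9)
})

test_that("a pure tilt rotation is read back as that tilt", {
    fx <- fxPair()
    f <- domainFrame(fx$a$structure, fx$a$definition)
    n <- egfarch:::pracmaCross(f@longAxis, f@twistRef)
    R <- egfarch:::rotationAboutAxis(n, egfarch:::deg2rad(70))
    f2 <- new("DomainFrame", origin = f@origin,
              longAxis = drop(R %*% f@longAxis),
              twistRef = drop(R %*% f@twistRef))
    expect_equal(tiltAngle(tiltTwist(f, f2)), 70, tolerance = 1e-9)
})

test_that("buildPair/tiltTwist round-trips across the angle ranges", {
    fx <- fxPair()
    for (tilt in c(0, 45, 90, 135, 180))
        for (twist in c(-150, -60, 0, 90, 180)) {
            sB <- buildPair(fx$a, fx$b,
                            InterdomainGeometry(tilt, twist))
            g <- tiltTwist(domainFrame(fx$a$structure, fx$a$definition),
                           domainFrame(sB, fx$b$definition))
            expect_equal(tiltAngle(g), tilt, tolerance = 1e-6)
            if (tilt %in% c(0, 180)) next  # twist defined up to convention
            expect_lt(angDiff(twistAngle(g), twist), 1e-6)
        }
})

test_that("geometry measurements are invariant under global motion", {
    fx <- fxPair()
    sB <- buildPair(fx$a, fx$b, InterdomainGeometry(33, 140))
    R <- egfarch:::rotationAboutAxis(c(1, 0, 2), -0.9)
    tr <- new("RigidTransform", rotation = R, translation = c(10, -20, 5))
    g1 <- tiltTwist(domainFrame(fx$a$structure, fx$a$definition),
                    domainFrame(sB, fx$b$definition))
    g2 <- tiltTwist(domainFrame(applyTransform(fx$a$structure, tr),
                                fx$a$definition),
                    domainFrame(applyTransform(sB, tr),
                                fx$b$definition))
    expect_equal(tiltAngle(g2), tiltAngle(g1), tolerance = 1e-8)
    expect_equal(twistAngle(g2), twistAngle(g1), tolerance = 1e-8)
})

test_that("collinear placement and linker limits behave", {
    fx <- fxPair()
    s0 <- buildPair(fx$a, fx$b, InterdomainGeometry(0, 0))
    fa <- domainFrame(fx$a$structure, fx$a$definition)
    fb <- domainFrame(s0, fx$b$definition)
    expect_equal(sum(fa@longAxis * fb@longAxis), 1, tolerance = 1e-9)
    expect_error(buildPair(fx$a, fx$b, InterdomainGeometry(0, 0),
                           linkerResidues = 0L, gap = 40),
                 "span limit")
})

test_that("assembled models reproduce their input geometries", {
    geoms <- list(InterdomainGeometry(33, 179),
                  InterdomainGeometry(87, 117),
                  InterdomainGeometry(30, 150),
                  InterdomainGeometry(16, 130),
                  InterdomainGeometry(17, 136))
    m <- makeMultidomain(6L, geoms, seed = 21L)
    got <- measureGeometries(m)
    for (i in seq_along(geoms)) {
        expect_equal(tiltAngle(got[[i]]), tiltAngle(geoms[[i]]),
                     tolerance = 1e-6)
        expect_equal(twistAngle(got[[i]]), twistAngle(geoms[[i]]),
                     tolerance = 1e-6)
    }
    expect_error(assembleModel(modelFragments(m)[1:3], geoms),
                 "geometries")
})

test_that("clash detection separates extended from folded conformers", {
    fx <- fxPair()
    ## extended tandem: clean
    m <- assembleModel(list(fx$a, fx$b),
                       list(InterdomainGeometry(15, 130)))
    expect_identical(nClashes(clashCheck(m)), 0L)
    expect_true(all(linkerFeasible(clashCheck(m))))
    ## U-shaped fold-back on a short linker: steric violations
    mU <- assembleModel(list(fx$a, fx$b),
                        list(InterdomainGeometry(178, 20)),
                        linkerResidues = 5L, gap = 6)
    expect_gt(nClashes(clashCheck(mU)), 0L)
    ## duplicated, nearly coincident domain clashes massively
    shift <- new("RigidTransform", rotation = diag(3),
                 translation = c(0.5, 0, 0))
    dup <- new("AssemblyModel",
               fragments = list(fx$a,
                                list(structure = applyTransform(
                                         fx$a$structure, shift),
                                     definition = fx$a$definition)),
               transforms = list(shift, shift),
               geometries = list(InterdomainGeometry(0, 0)),
               linkerResidues = 6L, structure = fx$a$structure)
    expect_gt(nClashes(clashCheck(dup)), 50L)
})

test_that("superposition recovers exact transforms and noise floors", {
    fx <- fxPair()
    s <- fx$a$structure
    sel <- data.frame(mobileChain = "A", mobileResno = 1:40,
                      refChain = "A", refResno = 1:40)
    ## identity
    expect_equal(superpose(s, s, sel)$rmsd, 0, tolerance = 1e-9)
    ## known transform is inverted exactly
    R <- egfarch:::rotationAboutAxis(c(1, 2, 3), 0.7)
    tr <- new("RigidTransform", rotation = R, translation = c(5, -3, 2))
    s2 <- applyTransform(s, tr)
    sp <- superpose(s2, s, sel)
    expect_equal(sp$rmsd, 0, tolerance = 1e-9)
    expect_equal(sp$transform@rotation, t(R), tolerance = 1e-9)
    ## Gaussian perturbation: rmsd near sigma * sqrt(3 - 6/n)
    a <- atoms(s)
    ca <- a$atom == "CA"
    n <- 40L
    rmsds <- vapply(1:30, function(i) {
        set.seed(400 + i)
        a2 <- a
        a2[ca, c("x", "y", "z")] <- a2[ca, c("x", "y", "z")] +
            matrix(rnorm(3 * n, 0, 0.5), n, 3)
        superpose(Structure(a2), s, sel)$rmsd
    }, numeric(1L))
    expect_equal(mean(rmsds), 0.5 * sqrt(3 - 6 / n), tolerance = 0.2)
    ## degenerate (collinear) selections are refused
    aLin <- a[ca, ]
    aLin$x <- seq_len(n); aLin$y <- 0; aLin$z <- 0
    expect_error(superpose(Structure(aLin), Structure(aLin), sel),
                 "collinear")
})

test_that("superposition against an independent reference fit", {
    ## cross-check the Kabsch route against bio3d's least-squares fit
    fx <- fxPair()
    X <- as.matrix(atoms(fx$a$structure)[1:60, c("x", "y", "z")])
    set.seed(9)
    R <- egfarch:::rotationAboutAxis(rnorm(3), 0.6)
    Y <- X %*% t(R) + matrix(c(4, -1, 2), nrow(X), 3, byrow = TRUE) +
        matrix(rnorm(length(X), 0, 0.2), nrow(X), 3)
    bioFit <- matrix(bio3d::rot.lsq(xx = as.numeric(t(X)),
                                    yy = as.numeric(t(Y))),
                     ncol = 3, byrow = TRUE)
    k <- egfarch:::.kabsch(X, Y)
    ours <- X %*% t(k$R) + matrix(k$t, nrow(X), 3, byrow = TRUE)
    expect_equal(abs(det(k$R)), 1, tolerance = 1e-9)
    expect_lt(max(abs(ours - bioFit)), 1e-6)
})

test_that("orientation search finds the generating geometry", {
    fx <- fxPair()
    sB <- buildPair(fx$a, fx$b, InterdomainGeometry(70, 115))
    m <- assembleModel(
        list(fx$a, list(structure = sB, definition = fx$b$definition)),
        list(InterdomainGeometry(70, 115)))
    rdc <- simulateRDCs(m, makeTensor(12, 0.3, c(25, 55, -40)),
                        noise = 0, seed = 4L)
    res <- orientationSearch(fx$a, fx$b, rdc)
    expect_equal(tiltAngle(res$geometry), 70, tolerance = 0.5)
    expect_equal(twistAngle(res$geometry), 115, tolerance = 0.5)
    expect_lt(res$q, 1e-6)
    expect_false(res$illDetermined)
    ## the Q landscape decreases from a 90-degree start toward 70
    prof <- res$profile
    q90 <- prof$q[prof$tilt == 90 & prof$twist == 120]
    q70 <- prof$q[prof$tilt == 70 & prof$twist == 120]
    expect_gt(q90, q70)
})

test_that("RDCs covering one domain leave the search ill-determined", {
    fx <- fxPair()
    sB <- buildPair(fx$a, fx$b, InterdomainGeometry(70, 115))
    m <- assembleModel(
        list(fx$a, list(structure = sB, definition = fx$b$definition)),
        list(InterdomainGeometry(70, 115)))
    rdc <- simulateRDCs(m, makeTensor(12, 0.3), noise = 0, seed = 4L)
    rdcA <- rdc[rdc$domain == "EGF5", ]
    res <- orientationSearch(fx$a, fx$b, rdcA)
    expect_true(res$illDetermined)
})
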