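## Interdomain tilt/twist geometry, rigid-body pair construction,
## multidomain assembly, steric/linker feasibility and superposition.
##
## Frame convention (applied uniformly; absolute angles from other
## conventions may differ by a fixed offset): a domain's long axis is the
## principal inertia axis of its Cys1-Cys6 C-alpha span, oriented N to C;
## the twist reference is the Cys3 to Cys4 C-alpha direction orthogonalized
## against the long axis; the origin is the span centroid.
##
## Tilt is the angle between consecutive long axes. Twist is the signed
## rotation about the N-terminal domain's long axis that aligns the twist
## references after removing the tilt. The forward construction
## (buildPair) and the measurement (tiltTwist) are exact inverses.

#' Construct an InterdomainGeometry
#'
#' @param tilt degrees in [0, 180].
#' @param twist degrees in (-180, 180].
#' @return An \linkS4class{InterdomainGeometry}.
#' @export
InterdomainGeometry <- function(tilt, twist) {
    new("InterdomainGeometry", tilt = tilt, twist = wrapAngle(twist))
}

.caSpan <- function(s, d) {
    a <- atoms(s)
    sel <- a$chain == d@chainId & a$atom == "CA" &
        a$resno >= d@cysPositions[1L] & a$resno <= d@cysPositions[6L]
    a[sel, , drop = FALSE]
}

#' Reference frame of an EGF domain
#'
#' Computes the domain frame either directly from the domain's own
#' coordinates (default), or by least-squares superposition of a template
#' fragment's core C-alpha atoms onto the domain, carrying the template's
#' stored frame into the domain's coordinates. The direct route and the
#' template route agree when the template is the domain itself.
#'
#' @param s a \linkS4class{Structure} containing the domain.
#' @param d the domain's \linkS4class{DomainDefinition}.
#' @param template optional list(structure, definition) of a reference
#'   fragment whose frame is transferred by superposition.
#' @return A \linkS4class{DomainFrame}. If C-alpha atoms are missing from
#'   the Cys1-Cys6 span, the frame is computed from the remaining atoms and
#'   carries attribute \code{incomplete = TRUE}.
#' @export
domainFrame <- function(s, d, template = NULL) {
    ca <- .caSpan(s, d)
    nExpected <- d@cysPositions[6L] - d@cysPositions[1L] + 1L
    if (nrow(ca) < 10L)
        stop("fewer than 10 C-alpha atoms in the Cys1-Cys6 span of ",
             d@domainId)
    if (!is.null(template)) {
        tf <- domainFrame(template$structure, template$definition)
        tca <- .caSpan(template$structure, template$definition)
        common <- intersect(
            tca$resno - template$definition@cysPositions[1L],
            ca$resno - d@cysPositions[1L])
        if (length(common) < 10L)
            stop("fewer than 10 matchable C-alpha atoms between template ",
                 "and domain")
        X <- as.matrix(tca[match(common,
            tca$resno - template$definition@cysPositions[1L]),
            c("x", "y", "z")])
        Y <- as.matrix(ca[match(common, ca$resno - d@cysPositions[1L]),
            c("x", "y", "z")])
        k <- .kabsch(X, Y)
        frame <- new("DomainFrame",
                     origin = drop(k$R %*% tf@origin) + k$t,
                     longAxis = drop(k$R %*% tf@longAxis),
                     twistRef = drop(k$R %*% tf@twistRef))
        attr(frame, "incomplete") <- nrow(ca) < nExpected
        return(frame)
    }
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    cen <- sweep(xyz, 2L, ctr)
    ev <- eigen(crossprod(cen), symmetric = TRUE)
    axis <- ev$vectors[, 1L]
    nc <- xyz[nrow(xyz), ] - xyz[1L, ]      # orient N -> C
    if (sum(axis * nc) < 0) axis <- -axis
    c3 <- atomCoord(s, d@chainId, d@cysPositions[3L], "CA")
    c4 <- atomCoord(s, d@chainId, d@cysPositions[4L], "CA")
    if (is.null(c3) || is.null(c4))
        stop("C-alpha of Cys3/Cys4 required for the twist reference of ",
             d@domainId)
    tw <- (c4 - c3) - sum((c4 - c3) * axis) * axis
    frame <- new("DomainFrame", origin = ctr, longAxis = unitize(axis),
                 twistRef = unitize(tw))
    attr(frame, "incomplete") <- nrow(ca) < nExpected
    frame
}

#' Tilt and twist between two domain frames
#'
#' Tilt is the angle between the long axes. Twist is the signed rotation
#' about the N-terminal frame's long axis that maps its twist reference
#' onto the C-terminal frame's twist reference after the tilt has been
#' removed (rotation about the mutual perpendicular). Identical frames
#' give (0, 0).
#'
#' @param a,b \linkS4class{DomainFrame} objects (a is N-terminal).
#' @return An \linkS4class{InterdomainGeometry}.
#' @export
tiltTwist <- function(a, b) {
    za <- a@longAxis; zb <- b@longAxis
    ct <- max(-1, min(1, sum(za * zb)))
    cr <- pracmaCross(za, zb)
    tilt <- atan2(vnorm(cr), ct)   # accurate near 0 and 180 degrees
    xb <- b@twistRef
    if (vnorm(cr) > 1e-8) {
        n <- unitize(cr)
        xUntilted <- drop(rotationAboutAxis(n, -tilt) %*% xb)
    } else if (ct > 0) {
        xUntilted <- xb                      # tilt ~ 0
    } else {
        xUntilted <- -xb                     # tilt ~ 180: mirror convention
    }
    xUntilted <- unitize(xUntilted - sum(xUntilted * za) * za)
    twist <- signedAngleAbout(a@twistRef, xUntilted, za)
    InterdomainGeometry(rad2deg(tilt), rad2deg(twist))
}

## Kabsch: optimal proper rotation R and translation t with Y ~ X %*% t(R) + t
.kabsch <- function(X, Y) {
    cx <- colMeans(X); cy <- colMeans(Y)
    Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
    sv <- svd(crossprod(Xc, Yc))
    if (nrow(X) >= 3L && sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-300))
        stop("degenerate (collinear) atom selection for superposition")
    dsign <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, dsign))
    R <- sv$v %*% D %*% t(sv$u)
    list(R = R, t = drop(cy - R %*% cx))
}

#' Least-squares superposition of matched C-alpha atoms
#'
#' Optimal proper rotation (reflections excluded) and translation mapping
#' the mobile selection onto the reference, with the post-fit RMSD.
#'
#' @param mobile,reference \linkS4class{Structure} objects.
#' @param selection data.frame with columns \code{mobileChain},
#'   \code{mobileResno}, \code{refChain}, \code{refResno}; C-alpha atoms of
#'   these residues are matched pairwise. At least 3 pairs.
#' @return list(transform = \linkS4class{RigidTransform}, rmsd).
#' @export
superpose <- function(mobile, reference, selection) {
    stopifnot(nrow(selection) >= 3L)
    X <- t(vapply(seq_len(nrow(selection)), function(i)
        atomCoord(mobile, selection$mobileChain[i],
                  selection$mobileResno[i], "CA"), numeric(3L)))
    Y <- t(vapply(seq_len(nrow(selection)), function(i)
        atomCoord(reference, selection$refChain[i],
                  selection$refResno[i], "CA"), numeric(3L)))
    k <- .kabsch(X, Y)
    fitted <- X %*% t(k$R) + matrix(k$t, nrow(X), 3L, byrow = TRUE)
    rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
    list(transform = new("RigidTransform", rotation = k$R,
                         translation = k$t),
         rmsd = rmsd)
}

#' Apply a rigid transform to a structure
#'
#' @param s a \linkS4class{Structure}.
#' @param tr a \linkS4class{RigidTransform}.
#' @return the transformed \linkS4class{Structure}.
#' @export
applyTransform <- function(s, tr) {
    a <- atoms(s)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(tr@rotation) +
        matrix(tr@translation, nrow(a), 3L, byrow = TRUE)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
    Structure(a)
}

#' Linker span limit
#'
#' Maximal feasible C-alpha distance between Cys6 of one domain and Cys1
#' of the next: 3.5 Angstrom per linker residue plus 5 Angstrom slack.
#'
#' @param linkerResidues number of residues strictly between Cys6 and Cys1.
#' @return distance limit, Angstrom.
#' @export
linkerSpanLimit <- function(linkerResidues) 3.5 * linkerResidues + 5

## Rotation carrying frame b onto the target frame implied by tilt/twist
## relative to frame a: twist about a's long axis first, then tilt about
## the twisted y axis.
.pairRotation <- function(fa, fb, g) {
    za <- fa@longAxis; xa <- fa@twistRef
    ya <- pracmaCross(za, xa)
    twistRot <- rotationAboutAxis(za, deg2rad(g@twist))
    xTw <- drop(twistRot %*% xa)
    yTw <- drop(twistRot %*% ya)
    tiltRot <- rotationAboutAxis(yTw, deg2rad(g@tilt))
    zTarget <- drop(tiltRot %*% za)
    xTarget <- drop(tiltRot %*% xTw)
    Bcur <- cbind(fb@twistRef, pracmaCross(fb@longAxis, fb@twistRef),
                  fb@longAxis)
    Btar <- cbind(xTarget, pracmaCross(zTarget, xTarget), zTarget)
    list(R = Btar %*% t(Bcur), zTarget = zTarget)
}

#' Place a C-terminal domain at a specified tilt/twist
#'
#' Rigidly rotates and translates domain b so that
#' \code{tiltTwist(frame(a), frame(b))} equals \code{g} (to 1e-6 degrees)
#' and the Cys6(a)-Cys1(b) C-alpha gap equals \code{gap} (default: a
#' typical extended-linker spacing, capped at the linker span limit).
#'
#' @param a,b list(structure, definition) for the N- and C-terminal
#'   domains.
#' @param g target \linkS4class{InterdomainGeometry}.
#' @param linkerResidues residues between Cys6(a) and Cys1(b).
#' @param gap optional target Cys6-Cys1 C-alpha distance (Angstrom); an
#'   error is raised if it exceeds the linker span limit.
#' @return the repositioned \linkS4class{Structure} of domain b.
#' @export
buildPair <- function(a, b, g, linkerResidues = 6L, gap = NULL) {
    stopifnot(is(g, "InterdomainGeometry"), linkerResidues >= 0L)
    fa <- domainFrame(a$structure, a$definition)
    fb <- domainFrame(b$structure, b$definition)
    limit <- linkerSpanLimit(linkerResidues)
    if (is.null(gap)) gap <- min(3.8 + 3.5 * linkerResidues, limit)
    if (gap > limit)
        stop(sprintf(
            "target Cys6-Cys1 gap %.1f A exceeds the %d-residue linker span limit %.1f A (violation %.1f A)",
            gap, linkerResidues, limit, gap - limit))
    pr <- .pairRotation(fa, fb, g)
    R <- pr$R; za <- fa@longAxis; zTarget <- pr$zTarget
    ## rotate b about its own origin, then translate its Cys1 CA to sit at
    ## the requested gap from Cys6(a), along the mean of the two long axes
    bRot <- applyTransform(b$structure,
                           new("RigidTransform", rotation = R,
                               translation = drop(fb@origin - R %*% fb@origin)))
    cys6a <- atomCoord(a$structure, a$definition@chainId,
                       a$definition@cysPositions[6L], "CA")
    cys1b <- atomCoord(bRot, b$definition@chainId,
                       b$definition@cysPositions[1L], "CA")
    if (is.null(cys6a) || is.null(cys1b))
        stop("C-alpha atoms of Cys6(a)/Cys1(b) are required for placement")
    dirSum <- za + zTarget
    u <- if (vnorm(dirSum) > 1e-8) unitize(dirSum) else za
    target <- cys6a + gap * u
    applyTransform(bRot, new("RigidTransform", rotation = diag(3),
                             translation = target - cys1b))
}

#' Assemble a multidomain model from fragments and geometries
#'
#' Sequentially applies \code{\link{buildPair}}; the recomputed pairwise
#' geometries of the result match the inputs.
#'
#' @param fragments list of list(structure, definition), N- to C-terminal.
#'   Residue numbering must not overlap between fragments.
#' @param geometries list of \linkS4class{InterdomainGeometry}, one per
#'   consecutive pair.
#' @param linkerResidues integer vector (recycled) of linker lengths.
#' @param gap optional Cys6-Cys1 target gap(s), Angstrom (recycled); see
#'   \code{\link{buildPair}}.
#' @return An \linkS4class{AssemblyModel}.
#' @export
assembleModel <- function(fragments, geometries, linkerResidues = 6L,
                          gap = NULL) {
    if (length(geometries) != length(fragments) - 1L)
        stop("need exactly length(fragments) - 1 geometries, got ",
             length(geometries))
    linkerResidues <- as.integer(rep(linkerResidues,
                                     length.out = length(geometries)))
    gaps <- if (is.null(gap)) vector("list", length(geometries)) else
        as.list(rep(gap, length.out = length(geometries)))
    placed <- list(fragments[[1L]])
    transforms <- list(new("RigidTransform", rotation = diag(3),
                           translation = c(0, 0, 0)))
    for (i in seq_along(geometries)) {
        prev <- placed[[i]]
        nxt <- fragments[[i + 1L]]
        sNew <- buildPair(prev, nxt, geometries[[i]],
                          linkerResidues = linkerResidues[i],
                          gap = gaps[[i]])
        old <- as.matrix(atoms(nxt$structure)[, c("x", "y", "z")])
        newm <- as.matrix(atoms(sNew)[, c("x", "y", "z")])
        k <- .kabsch(old, newm)
        transforms[[i + 1L]] <- new("RigidTransform", rotation = k$R,
                                    translation = k$t)
        placed[[i + 1L]] <- list(structure = sNew,
                                 definition = nxt$definition)
    }
    merged <- do.call(rbind, lapply(placed, function(f) atoms(f$structure)))
    merged$serial <- seq_len(nrow(merged))
    new("AssemblyModel",
        fragments = placed, transforms = transforms,
        geometries = geometries, linkerResidues = linkerResidues,
        structure = Structure(merged))
}

#' Recompute interdomain geometries of an assembled model
#'
#' @param m an \linkS4class{AssemblyModel}.
#' @return list of \linkS4class{InterdomainGeometry} measured from the
#'   assembled coordinates.
#' @export
measureGeometries <- function(m) {
    frames <- lapply(m@fragments, function(f)
        domainFrame(f$structure, f$definition))
    lapply(seq_len(length(frames) - 1L), function(i)
        tiltTwist(frames[[i]], frames[[i + 1L]]))
}

#' Steric clash and linker feasibility check
#'
#' Counts inter-domain heavy-atom pairs closer than the cutoff and checks
#' each linker's Cys6-Cys1 C-alpha distance against the span limit.
#'
#' @param m an \linkS4class{AssemblyModel}.
#' @param cutoff heavy-atom clash distance (Angstrom).
#' @param excludeLinkerNeighbors skip atom pairs involving the two
#'   terminal residues on either side of a shared linker (their proximity
#'   is imposed by the covalent connection).
#' @return A \linkS4class{ClashReport}.
#' @export
clashCheck <- function(m, cutoff = 2.5, excludeLinkerNeighbors = TRUE) {
    frs <- m@fragments
    nd <- length(frs)
    pairs <- list()
    for (i in seq_len(nd - 1L)) for (j in seq(i + 1L, nd)) {
        ai <- atoms(frs[[i]]$structure)
        aj <- atoms(frs[[j]]$structure)
        ai <- ai[ai$element != "H", , drop = FALSE]
        aj <- aj[aj$element != "H", , drop = FALSE]
        if (excludeLinkerNeighbors && j == i + 1L) {
            ai <- ai[ai$resno < frs[[i]]$definition@residueRange[2L] - 1L, ,
                     drop = FALSE]
            aj <- aj[aj$resno > frs[[j]]$definition@residueRange[1L] + 1L, ,
                     drop = FALSE]
        }
        if (nrow(ai) == 0L || nrow(aj) == 0L) next
        Xi <- as.matrix(ai[, c("x", "y", "z")])
        Xj <- as.matrix(aj[, c("x", "y", "z")])
        d2 <- outer(rowSums(Xi^2), rowSums(Xj^2), "+") -
            2 * Xi %*% t(Xj)
        hit <- which(d2 < cutoff^2, arr.ind = TRUE)
        if (nrow(hit) > 0L)
            pairs[[length(pairs) + 1L]] <- data.frame(
                domainA = frs[[i]]$definition@domainId,
                resnoA = ai$resno[hit[, 1L]], atomA = ai$atom[hit[, 1L]],
                domainB = frs[[j]]$definition@domainId,
                resnoB = aj$resno[hit[, 2L]], atomB = aj$atom[hit[, 2L]],
                distance = sqrt(pmax(d2[hit], 0)))
    }
    pairDf <- if (length(pairs) > 0L) do.call(rbind, pairs) else
        data.frame(domainA = character(), resnoA = integer(),
                   atomA = character(), domainB = character(),
                   resnoB = integer(), atomB = character(),
                   distance = numeric())
    feasible <- vapply(seq_len(nd - 1L), function(i) {
        c6 <- atomCoord(frs[[i]]$structure, frs[[i]]$definition@chainId,
                        frs[[i]]$definition@cysPositions[6L], "CA")
        c1 <- atomCoord(frs[[i + 1L]]$structure,
                        frs[[i + 1L]]$definition@chainId,
                        frs[[i + 1L]]$definition@cysPositions[1L], "CA")
        vnorm(c1 - c6) <= linkerSpanLimit(m@linkerResidues[i])
    }, logical(1L))
    new("ClashReport", nClashes = nrow(pairDf), pairs = pairDf,
        linkerFeasible = feasible)
}

#' Grid-plus-refinement search for the interdomain orientation
#'
#' Scans tilt/twist placements of the C-terminal domain, fitting a single
#' joint alignment tensor to the RDCs of both domains at each geometry, and
#' returns the geometry minimizing the joint Q together with the
#' Q-versus-angle profile. A Nelder-Mead refinement follows the coarse
#' grid; grid ties are broken toward smaller tilt.
#'
#' @param a,b list(structure, definition) for the two domains (b is
#'   repositioned).
#' @param rdcs RDC data.frame covering residues of both domains.
#' @param gridStep coarse grid step, degrees.
#' @param linkerResidues linker length used for placement.
#' @return list(geometry = \linkS4class{InterdomainGeometry},
#'   q = minimized Q, profile = data.frame(tilt, twist, q),
#'   illDetermined = TRUE when the Q range across the grid is < 0.01).
#' @export
orientationSearch <- function(a, b, rdcs, gridStep = 10,
                              linkerResidues = 6L) {
    vecA <- extractNHVectors(a$structure, list(a$definition))
    vecB0 <- extractNHVectors(b$structure, list(b$definition))
    fa <- domainFrame(a$structure, a$definition)
    fb <- domainFrame(b$structure, b$definition)
    ## RDCs depend only on bond-vector orientation, so the trial geometry
    ## acts on b's vectors directly; no structure rebuild per grid point.
    matched <- .matchVectorsRdcs(rbind(vecA, vecB0), rdcs)
    vmat <- as.matrix(matched[, c("vx", "vy", "vz")])
    isB <- matched$domain %in% b$definition@domainId
    dObs <- matched$d_obs_hz
    sig <- if ("sigma_hz" %in% names(matched)) matched$sigma_hz else
        rep(1, nrow(matched))
    qAt <- function(tilt, twist) {
        R <- .pairRotation(fa, fb, InterdomainGeometry(tilt, twist))$R
        v <- vmat
        v[isB, ] <- v[isB, , drop = FALSE] %*% t(R)
        qFactor(.fitTensorCore(v, dObs, sig))
    }
    tilts <- seq(0, 180, by = gridStep)
    twists <- seq(-180 + gridStep, 180, by = gridStep)
    profile <- expand.grid(tilt = tilts, twist = twists)
    profile$q <- mapply(qAt, profile$tilt, profile$twist)
    ord <- order(profile$q, profile$tilt)
    best <- profile[ord[1L], ]
    opt <- stats::optim(c(best$tilt, best$twist),
                        function(p) qAt(min(max(p[1L], 0), 180),
                                        wrapAngle(p[2L])),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 300))
    g <- InterdomainGeometry(min(max(opt$par[1L], 0), 180),
                             wrapAngle(opt$par[2L]))
    list(geometry = g, q = opt$value, profile = profile,
         illDetermined = diff(range(profile$q)) < 0.01)
}
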