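## Residual dipolar coupling analysis: SVD alignment-tensor fitting,
## back-calculation, Q factors, per-segment tensor comparison for
## interdomain-flexibility detection, and Monte Carlo error propagation.
##
## Conventions, applied uniformly: the Saupe order matrix is symmetric and
## traceless; eigenvalues are assigned to principal axes by
## |Szz| >= |Syy| >= |Sxx|; Da = Szz/2 (so an N-H vector along the
## principal z axis back-calculates to 2*Da) and rhombicity
## R = 2*(Sxx - Syy)/(3*Szz), which lies in [0, 2/3].

.tensorFromMatrix <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)
    lam <- e$values[ord]            # (Szz, Syy, Sxx)
    V <- e$vectors[, rev(ord)]      # columns: x, y, z principal axes
    if (det(V) < 0) V[, 1L] <- -V[, 1L]
    szz <- lam[1L]; syy <- lam[2L]; sxx <- lam[3L]
    da <- szz / 2
    rh <- if (abs(szz) < 1e-300) 0 else 2 * (sxx - syy) / (3 * szz)
    rh <- min(max(rh, 0), 2 / 3)
    new("AlignmentTensor",
        saupe = c(S[2L, 2L], S[3L, 3L], S[1L, 2L], S[1L, 3L], S[2L, 3L]),
        da = da, rhombicity = rh, eulerAngles = eulerZYZ(V))
}

#' Construct an alignment tensor from Da, rhombicity and orientation
#'
#' @param da axial component (Hz); the coupling of a bond along the
#'   principal z axis is 2*da.
#' @param rhombicity dimensionless, in [0, 2/3].
#' @param eulerAngles z-y-z Euler angles (degrees) of the principal frame
#'   relative to the structure frame.
#' @return An \linkS4class{AlignmentTensor}.
#' @export
makeTensor <- function(da, rhombicity = 0, eulerAngles = c(0, 0, 0)) {
    stopifnot(rhombicity >= 0, rhombicity <= 2 / 3)
    sxx <- -da * (1 - 1.5 * rhombicity)
    syy <- -da * (1 + 1.5 * rhombicity)
    szz <- 2 * da
    ang <- deg2rad(eulerAngles)
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3L, 3L)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3L, 3L)
    V <- Rz(ang[1L]) %*% Ry(ang[2L]) %*% Rz(ang[3L])
    S <- V %*% diag(c(sxx, syy, szz)) %*% t(V)
    .tensorFromMatrix(S)
}

#' Extract amide N-H bond unit vectors
#'
#' One unit vector per residue carrying both amide atoms. When the amide
#' hydrogen is absent (X-ray inputs lack protons) it is rebuilt along the
#' bisector geometry from N, CA and the preceding residue's C at 1.02
#' Angstrom. Prolines and residues where neither route works are skipped
#' with a warning.
#'
#' @param s a \linkS4class{Structure}.
#' @param domains list of \linkS4class{DomainDefinition}.
#' @return data.frame(residue, domain, vx, vy, vz) of unit N-H vectors.
#' @export
extractNHVectors <- function(s, domains) {
    if (is(domains, "DomainDefinition")) domains <- list(domains)
    out <- list()
    skipped <- 0L
    for (d in domains) {
        rng <- d@residueRange
        a <- atoms(s)
        for (res in seq(rng[1L], rng[2L])) {
            rows <- a[a$chain == d@chainId & a$resno == res, , drop = FALSE]
            if (nrow(rows) == 0L) next
            if (rows$resid[1L] == "PRO") next
            N <- atomCoord(s, d@chainId, res, "N")
            if (is.null(N)) next
            H <- atomCoord(s, d@chainId, res, "H")
            if (is.null(H)) H <- atomCoord(s, d@chainId, res, "HN")
            if (is.null(H)) {
                CA <- atomCoord(s, d@chainId, res, "CA")
                Cp <- atomCoord(s, d@chainId, res - 1L, "C")
                if (is.null(CA) || is.null(Cp)) { skipped <- skipped + 1L
                                                  next }
                u <- -(unitize(CA - N) + unitize(Cp - N))
                H <- N + 1.02 * unitize(u)
            }
            v <- unitize(H - N)
            out[[length(out) + 1L]] <- data.frame(
                residue = res, domain = d@domainId,
                vx = v[1L], vy = v[2L], vz = v[3L])
        }
    }
    if (skipped > 0L)
        warning(skipped, " residue(s) skipped: no amide H and no geometry ",
                "to rebuild it")
    do.call(rbind, out)
}

.designMatrix <- function(v) {
    ## v: n x 3 unit vectors; parameters (Syy, Szz, Sxy, Sxz, Syz)
    cbind(v[, 2L]^2 - v[, 1L]^2,
          v[, 3L]^2 - v[, 1L]^2,
          2 * v[, 1L] * v[, 2L],
          2 * v[, 1L] * v[, 3L],
          2 * v[, 2L] * v[, 3L])
}

#' Back-calculate an RDC from a tensor and a bond vector
#'
#' Two algebraically equivalent routes are provided: contraction of the
#' Saupe matrix with the bond vector (default), and the polar-angle form
#' Da*[(3*cos^2(theta) - 1) + 1.5*R*sin^2(theta)*cos(2*phi)] in the tensor
#' principal frame. They agree to numerical precision.
#'
#' @param t an \linkS4class{AlignmentTensor}.
#' @param v unit 3-vector, or an n x 3 matrix of unit vectors, or a
#'   data.frame with columns vx, vy, vz.
#' @param method "saupe" or "angles".
#' @return back-calculated coupling(s), Hz.
#' @export
backCalculate <- function(t, v, method = c("saupe", "angles")) {
    method <- match.arg(method)
    if (is.data.frame(v)) v <- as.matrix(v[, c("vx", "vy", "vz")])
    if (is.null(dim(v))) v <- matrix(v, 1L, 3L)
    if (method == "saupe") {
        S <- saupeMatrix(t)
        return(rowSums((v %*% S) * v))
    }
    ang <- deg2rad(t@eulerAngles)
    Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3L, 3L)
    Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3L, 3L)
    V <- Rz(ang[1L]) %*% Ry(ang[2L]) %*% Rz(ang[3L])
    vp <- v %*% V                      # components in the principal frame
    ct <- vp[, 3L]
    st2 <- pmax(1 - ct^2, 0)
    phi <- atan2(vp[, 2L], vp[, 1L])
    t@da * ((3 * ct^2 - 1) + 1.5 * t@rhombicity * st2 * cos(2 * phi))
}

#' RDC quality (Q) factor
#'
#' Q = sqrt(sum((obs - calc)^2)) / sqrt(sum(obs^2)).
#'
#' @param obs,calc observed and back-calculated couplings (Hz), equal
#'   length.
#' @return dimensionless Q.
#' @export
rdcQ <- function(obs, calc) {
    stopifnot(length(obs) == length(calc), length(obs) >= 1L)
    denom <- sqrt(sum(obs^2))
    if (denom == 0) stop("Q undefined: all observed couplings are zero")
    sqrt(sum((obs - calc)^2)) / denom
}

.matchVectorsRdcs <- function(vectors, rdcs) {
    key <- if ("domain" %in% names(rdcs) && "domain" %in% names(vectors))
        c("residue", "domain") else "residue"
    merged <- merge(vectors, rdcs, by = key, sort = FALSE)
    if (nrow(merged) < 5L)
        stop("need at least 5 matched residue/RDC pairs; got ",
             nrow(merged))
    merged
}

#' Fit an alignment tensor to RDCs by SVD
#'
#' Least-squares Saupe elements from singular-value decomposition of the
#' five-column design matrix; Da, rhombicity and orientation follow from
#' eigen-decomposition under the fixed |Szz| >= |Syy| >= |Sxx| convention.
#' The linearized standard error of Da is propagated from the measurement
#' uncertainties through the design-matrix pseudoinverse.
#'
#' @param vectors data.frame(residue, domain, vx, vy, vz) of unit N-H
#'   vectors (see \code{\link{extractNHVectors}}).
#' @param rdcs data.frame with columns \code{residue}, optionally
#'   \code{domain}, \code{d_obs_hz}, \code{sigma_hz}.
#' @param weighted logical; weight rows by 1/sigma (default unweighted:
#'   the experimental error is uniform).
#' @return A \linkS4class{TensorFit}.
#' @export
fitTensorSVD <- function(vectors, rdcs, weighted = FALSE) {
    m <- .matchVectorsRdcs(vectors, rdcs)
    v <- as.matrix(m[, c("vx", "vy", "vz")])
    d <- m$d_obs_hz
    sig <- if ("sigma_hz" %in% names(m)) m$sigma_hz else rep(1, nrow(m))
    .fitTensorCore(v, d, sig, weighted)
}

.fitTensorCore <- function(v, d, sig, weighted = FALSE) {
    A <- .designMatrix(v)
    b <- d
    if (weighted) {
        A <- A / sig
        b <- d / sig
    }
    sv <- svd(A)
    if (min(sv$d) < 1e-8 * max(sv$d))
        stop("design matrix is rank deficient: the bond-vector geometry ",
             "does not determine all 5 Saupe elements (singular values ",
             paste(signif(sv$d, 3), collapse = ", "), ")")
    p <- sv$v %*% (crossprod(sv$u, b) / sv$d)
    S <- matrix(c(-p[1L] - p[2L], p[3L], p[4L],
                  p[3L], p[1L], p[5L],
                  p[4L], p[5L], p[2L]), 3L, 3L)
    tensor <- .tensorFromMatrix(S)
    calc <- backCalculate(tensor, v)
    resid <- d - calc
    rms <- sqrt(mean(resid^2))
    q <- rdcQ(d, calc)
    ## Da = 0.5 * z'Sz with z the principal axis; linear in the parameters.
    ang <- deg2rad(tensor@eulerAngles)
    Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3L, 3L)
    Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3L, 3L)
    z <- (Rz(ang[1L]) %*% Ry(ang[2L]) %*% Rz(ang[3L]))[, 3L]
    g <- c(0.5 * (z[2L]^2 - z[1L]^2), 0.5 * (z[3L]^2 - z[1L]^2),
           z[1L] * z[2L], z[1L] * z[3L], z[2L] * z[3L])
    sigma2 <- mean(sig^2)
    covp <- sv$v %*% diag(1 / sv$d^2, 5L) %*% t(sv$v) * sigma2
    daSe <- sqrt(max(drop(t(g) %*% covp %*% g), 0))
    new("TensorFit", tensor = tensor, q = q, rmsDev = rms, daSe = daSe,
        nUsed = nrow(v), condition = max(sv$d) / min(sv$d))
}

#' Fit alignment tensors per segment and jointly
#'
#' Fits one tensor independently to each group of domains and one joint
#' tensor to all residues on the same coordinates. Segments of a rigidly
#' tumbling molecule yield consistent tensors and a joint Q close to the
#' segment Qs; independently aligning segments do not.
#'
#' @param vectors,rdcs as for \code{\link{fitTensorSVD}}.
#' @param segmentation list of character vectors of domain ids, e.g.
#'   \code{list(c("EGF8", "EGF9"), c("EGF10", "EGF11"))}.
#' @param weighted see \code{\link{fitTensorSVD}}.
#' @return list(segments = named list of \linkS4class{TensorFit},
#'   joint = \linkS4class{TensorFit}).
#' @export
fitSegments <- function(vectors, rdcs, segmentation, weighted = FALSE) {
    stopifnot(length(segmentation) >= 1L)
    segFits <- list()
    for (seg in segmentation) {
        nm <- paste(seg, collapse = "+")
        vs <- vectors[vectors$domain %in% seg, , drop = FALSE]
        rs <- rdcs[rdcs$domain %in% seg, , drop = FALSE]
        segFits[[nm]] <- fitTensorSVD(vs, rs, weighted = weighted)
    }
    allDoms <- unique(unlist(segmentation))
    joint <- fitTensorSVD(vectors[vectors$domain %in% allDoms, , drop = FALSE],
                          rdcs[rdcs$domain %in% allDoms, , drop = FALSE],
                          weighted = weighted)
    list(segments = segFits, joint = joint)
}

#' Interdomain flexibility test from per-segment alignment tensors
#'
#' Two rigidly connected segments must share one alignment tensor. The
#' verdict is "flexible" when the segment Da values differ in sign, or
#' differ by more than \code{daSigmaMult} combined standard errors, or the
#' joint-fit Q exceeds the worst segment Q by more than \code{qExcess};
#' "rigid" when none of those hold and the joint Q is within
#' \code{qExcess/2} of the worst segment Q; otherwise "indeterminate".
#'
#' @param segFits list of two \linkS4class{TensorFit} objects (or the
#'   \code{segments} element returned by \code{\link{fitSegments}}).
#' @param jointFit joint \linkS4class{TensorFit}.
#' @param daSigmaMult multiplier on the combined Da standard error.
#' @param qExcess Q-excess threshold.
#' @return A \linkS4class{FlexibilityVerdict}.
#' @export
flexibilityTest <- function(segFits, jointFit, daSigmaMult = 5,
                            qExcess = 0.1) {
    stopifnot(length(segFits) >= 2L)
    a <- segFits[[1L]]; b <- segFits[[2L]]
    nms <- names(segFits)
    if (is.null(nms)) nms <- c("segment1", "segment2")
    daA <- daValue(a); daB <- daValue(b)
    seA <- daError(a); seB <- daError(b)
    qA <- qFactor(a); qB <- qFactor(b); qJ <- qFactor(jointFit)
    combined <- sqrt(seA^2 + seB^2)
    clauses <- character()
    if (sign(daA) != sign(daB))
        clauses <- c(clauses, sprintf(
            "Da signs differ (%.2f vs %.2f Hz)", daA, daB))
    if (combined > 0 && abs(daA - daB) > daSigmaMult * combined)
        clauses <- c(clauses, sprintf(
            "|dDa| = %.2f Hz exceeds %g x combined sigma (%.2f Hz)",
            abs(daA - daB), daSigmaMult, combined))
    if (qJ - max(qA, qB) > qExcess)
        clauses <- c(clauses, sprintf(
            "joint Q %.3f exceeds max segment Q %.3f by > %g",
            qJ, max(qA, qB), qExcess))
    if (length(clauses) > 0L) {
        verdict <- "flexible"
        rationale <- paste(clauses, collapse = "; ")
    } else if (qJ <= max(qA, qB) + qExcess / 2) {
        verdict <- "rigid"
        rationale <- sprintf(
            "consistent tensors (Da %.2f vs %.2f Hz) and joint Q %.3f within %g of segment Qs",
            daA, daB, qJ, qExcess / 2)
    } else {
        verdict <- "indeterminate"
        rationale <- sprintf(
            "no flexibility clause fired but joint Q %.3f is not within %g of max segment Q %.3f",
            qJ, qExcess / 2, max(qA, qB))
    }
    new("FlexibilityVerdict", segmentA = nms[1L], segmentB = nms[2L],
        daA = daA, daB = daB, daSeA = seA, daSeB = seB,
        qJoint = qJ, qA = qA, qB = qB, verdict = verdict,
        rationale = rationale)
}

#' Monte Carlo uncertainty of a tensor fit
#'
#' Refits the tensor \code{nMc} times with independent Gaussian noise of
#' standard deviation \code{errorHz} added to the observed couplings.
#'
#' @param vectors,rdcs as for \code{\link{fitTensorSVD}}.
#' @param errorHz experimental error (Hz).
#' @param nMc number of resamples.
#' @param seed RNG seed.
#' @return list(samples = data.frame(da, rhombicity, axisDev) where
#'   axisDev is the deviation (degrees) of the refit principal z axis from
#'   the base fit, and sd = named numeric of parameter spreads).
#' @export
mcTensorUncertainty <- function(vectors, rdcs, errorHz = 2, nMc = 100L,
                                seed = 1L) {
    base <- fitTensorSVD(vectors, rdcs)
    ang <- deg2rad(eulerAngles(alignmentTensor(base)))
    Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3L, 3L)
    Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3L, 3L)
    z0 <- (Rz(ang[1L]) %*% Ry(ang[2L]) %*% Rz(ang[3L]))[, 3L]
    withLocalSeed(seed, {
        res <- lapply(seq_len(nMc), function(i) {
            noisy <- rdcs
            noisy$d_obs_hz <- noisy$d_obs_hz +
                stats::rnorm(nrow(noisy), 0, errorHz)
            f <- fitTensorSVD(vectors, noisy)
            angi <- deg2rad(eulerAngles(alignmentTensor(f)))
            zi <- (Rz(angi[1L]) %*% Ry(angi[2L]) %*% Rz(angi[3L]))[, 3L]
            c(daValue(f), rhombicity(alignmentTensor(f)),
              rad2deg(acos(min(1, abs(sum(z0 * zi))))))
        })
        m <- do.call(rbind, res)
        samples <- data.frame(da = m[, 1L], rhombicity = m[, 2L],
                              axisDev = m[, 3L])
        list(samples = samples,
             sd = c(da = stats::sd(samples$da),
                    rhombicity = stats::sd(samples$rhombicity),
                    axisDev = stats::sd(samples$axisDev)))
    })
}
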