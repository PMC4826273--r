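## Ground-truth generators: idealized EGF-like domain scaffolds, rigid-body
## multidomain models, RDCs from a known tensor, hetNOE peak-height pairs,
## and chelator-competition / NMR titration curves from known Kds.
##
## The scaffold is an idealized compact elongated backbone, not a folded
## EGF domain; it exists so every analysis stage can be exercised against
## known ground truth. Every generator is a pure function of its seed.

.fillResidues <- c("G", "S", "A", "T", "L", "V", "K", "R", "I", "M")

## Canonical six-cysteine spacing scaled to the requested length, with the
## consensus slots the classifier needs kept open.
.cysLayout <- function(nResidues) {
    cys <- round(c(5, 11, 17, 28, 30, 39) / 40 * nResidues)
    cys[1L] <- max(cys[1L], 2L)
    for (i in 2:6) cys[i] <- max(cys[i], cys[i - 1L] + 1L)
    if (cys[5L] - cys[4L] < 2L) cys[5L] <- cys[4L] + 2L
    for (i in 5:6) cys[i] <- max(cys[i], cys[i - 1L] + 1L)
    if (cys[6L] > nResidues)
        stop("nResidues too small to host six cysteines at canonical ",
             "spacing")
    as.integer(cys)
}

.egfSequenceString <- function(nResidues, cys, cb = TRUE,
                               thirdSiteD = FALSE, packing = "Y") {
    s <- rep(.fillResidues, length.out = nResidues)
    s[cys] <- "C"
    if (cb) {
        p <- cys[1L] - 1L
        if (p < 1L) stop("no room for the consensus before Cys1")
        s[p] <- "D"
        s[cys[1L] + 1L] <- "D"
        s[cys[1L] + 2L] <- if (thirdSiteD) "D" else "E"
        q <- max(cys[3L] + 1L, min(cys[4L] - 1L, cys[1L] + 2L + 13L))
        s[q] <- "D"
        s[cys[4L] + 1L] <- "Y"
    }
    pk <- cys[5L] + 4L
    if (!is.null(packing) && pk <= nResidues && !(pk %in% cys))
        s[pk] <- packing
    paste(s, collapse = "")
}

#' Generate an idealized EGF-like domain scaffold
#'
#' Deterministic-per-seed backbone (N, CA, C and amide H) along a compact
#' elongated curve with small coordinate jitter, six cysteines at canonical
#' spacing, and (on request) the calcium-binding consensus residues placed
#' so the sequence classifier sees a cb or non-cb domain.
#'
#' @param nResidues number of residues (>= 25).
#' @param seed RNG seed for the coordinate jitter.
#' @param cb place the calcium-binding consensus.
#' @param thirdSiteD use D instead of E at the third consensus site.
#' @param packing residue at the packing position four after Cys5
#'   ("Y", "F", "W", "H", or NULL for none).
#' @param domainId,chainId,startResidue identity and author numbering.
#' @return list(structure = \linkS4class{Structure},
#'   definition = \linkS4class{DomainDefinition},
#'   sequence = \linkS4class{EGFSequence}).
#' @examples
#' d <- makeTemplateEGF(seed = 1)
#' classifyCaBinding(d$sequence)$isCb
#' @export
makeTemplateEGF <- function(nResidues = 40L, seed = 1L, cb = TRUE,
                            thirdSiteD = FALSE, packing = "Y",
                            domainId = "EGF", chainId = "A",
                            startResidue = 1L) {
    if (nResidues < 25L) stop("nResidues must be at least 25")
    cys <- .cysLayout(nResidues)
    seqStr <- .egfSequenceString(nResidues, cys, cb = cb,
                                 thirdSiteD = thirdSiteD, packing = packing)
    aa3 <- c(G = "GLY", S = "SER", A = "ALA", T = "THR", L = "LEU",
             V = "VAL", K = "LYS", R = "ARG", I = "ILE", M = "MET",
             C = "CYS", D = "ASP", E = "GLU", Y = "TYR", W = "TRP",
             H = "HIS", N = "ASN", Q = "GLN", F = "PHE")
    withLocalSeed(seed, {
        i <- seq_len(nResidues)
        omega <- deg2rad(100)
        r <- 2.45; rise <- 0.6
        ca <- cbind(r * cos(omega * i), r * sin(omega * i), rise * i) +
            matrix(stats::rnorm(3L * nResidues, 0, 0.3), nResidues, 3L)
        radial <- cbind(cos(omega * i), sin(omega * i), 0)
        rows <- list()
        serial <- 0L
        addAtom <- function(name, pos, res, elem) {
            serial <<- serial + 1L
            data.frame(serial = serial, atom = name,
                       resid = aa3[[substr(seqStr, res, res)]],
                       chain = chainId,
                       resno = startResidue + res - 1L,
                       x = pos[1L], y = pos[2L], z = pos[3L],
                       element = elem, b = 0,
                       stringsAsFactors = FALSE)
        }
        Cpos <- matrix(NA_real_, nResidues, 3L)
        Npos <- matrix(NA_real_, nResidues, 3L)
        for (res in i) {
            prevDir <- if (res > 1L) unitize(ca[res - 1L, ] - ca[res, ])
                       else -unitize(ca[2L, ] - ca[1L, ])
            nextDir <- if (res < nResidues)
                unitize(ca[res + 1L, ] - ca[res, ]) else
                -unitize(ca[res - 1L, ] - ca[res, ])
            Npos[res, ] <- ca[res, ] +
                1.46 * unitize(prevDir + 0.5 * radial[res, ])
            Cpos[res, ] <- ca[res, ] +
                1.52 * unitize(nextDir + 0.5 * radial[res, ])
        }
        for (res in i) {
            N <- Npos[res, ]
            rows[[length(rows) + 1L]] <- addAtom("N", N, res, "N")
            rows[[length(rows) + 1L]] <- addAtom("CA", ca[res, ], res, "C")
            rows[[length(rows) + 1L]] <- addAtom("C", Cpos[res, ], res, "C")
            hDir <- if (res > 1L)
                -(unitize(ca[res, ] - N) + unitize(Cpos[res - 1L, ] - N))
            else radial[res, ]
            rows[[length(rows) + 1L]] <-
                addAtom("H", N + 1.02 * unitize(hDir), res, "H")
        }
        s <- Structure(do.call(rbind, rows))
        def <- new("DomainDefinition", domainId = domainId,
                   chainId = chainId,
                   residueRange = c(startResidue,
                                    startResidue + nResidues - 1L),
                   cysPositions = cys + startResidue - 1L)
        list(structure = s, definition = def,
             sequence = EGFSequence(domainId, seqStr,
                                    startResidue = startResidue))
    })
}

#' Synthetic EGF4-13 sequence set
#'
#' Ten curated synthetic domain sequences (not the real receptor sequence,
#' which ships with no external data) engineered to display the reported
#' consensus features of the human Notch1 EGF4-13 region: full consensus
#' in EGF4, 5, 8, 11, 12 and 13; the D-at-third-site variant in EGF7 and
#' EGF9; no consensus in EGF6 and EGF10; a tryptophan packing residue in
#' EGF7, a histidine in EGF5, and no packing aromatic in EGF9; a
#' five-residue linker between EGF9 and EGF10 and six residues in all
#' other linkers.
#'
#' @return named list of \linkS4class{EGFSequence}, EGF4 to EGF13.
#' @export
syntheticNotchSequences <- function() {
    feat <- list(
        EGF4  = list(cb = TRUE,  d3 = FALSE, pk = "Y"),
        EGF5  = list(cb = TRUE,  d3 = FALSE, pk = "H"),
        EGF6  = list(cb = FALSE, d3 = FALSE, pk = "Y"),
        EGF7  = list(cb = TRUE,  d3 = TRUE,  pk = "W"),
        EGF8  = list(cb = TRUE,  d3 = FALSE, pk = "Y"),
        EGF9  = list(cb = TRUE,  d3 = TRUE,  pk = NULL),
        EGF10 = list(cb = FALSE, d3 = FALSE, pk = "Y"),
        EGF11 = list(cb = TRUE,  d3 = FALSE, pk = "Y"),
        EGF12 = list(cb = TRUE,  d3 = FALSE, pk = "Y"),
        EGF13 = list(cb = TRUE,  d3 = FALSE, pk = "Y"))
    ## EGF9-10 linker is five residues; all others six
    starts <- cumsum(c(139, 41, 41, 41, 41, 41, 40, 41, 41, 41))
    cys <- .cysLayout(40L)
    out <- list()
    for (i in seq_along(feat)) {
        id <- names(feat)[i]
        f <- feat[[i]]
        seqStr <- .egfSequenceString(40L, cys, cb = f$cb,
                                     thirdSiteD = f$d3, packing = f$pk)
        out[[id]] <- EGFSequence(id, seqStr, startResidue = starts[i])
    }
    out
}

#' Assemble a synthetic multidomain model with known geometry
#'
#' @param nDomains number of domains.
#' @param geometries list of \linkS4class{InterdomainGeometry} (length
#'   nDomains - 1).
#' @param seed RNG seed (per-domain scaffolds use seed, seed+1, ...).
#' @param nResidues residues per domain.
#' @param linkerResidues linker lengths (recycled).
#' @param domainIds optional domain labels; default EGF1, EGF2, ...
#' @return An \linkS4class{AssemblyModel}; ground-truth geometries are
#'   retrievable via \code{modelGeometries}.
#' @export
makeMultidomain <- function(nDomains, geometries, seed = 1L,
                            nResidues = 40L, linkerResidues = 6L,
                            domainIds = NULL) {
    if (length(geometries) != nDomains - 1L)
        stop("need exactly nDomains - 1 geometries, got ",
             length(geometries))
    if (is.null(domainIds)) domainIds <- paste0("EGF", seq_len(nDomains))
    linkers <- rep(linkerResidues, length.out = max(nDomains - 1L, 1L))
    cys <- .cysLayout(nResidues)
    spacing <- linkers + cys[6L] - cys[1L] + 1L
    starts <- cumsum(c(1L, spacing))
    fragments <- lapply(seq_len(nDomains), function(i)
        makeTemplateEGF(nResidues = nResidues, seed = seed + i - 1L,
                        domainId = domainIds[i],
                        startResidue = starts[i]))
    assembleModel(fragments, geometries, linkerResidues = linkers)
}

#' Simulate RDC measurements from an assembled model
#'
#' Back-calculates couplings for every amide N-H vector of the model under
#' a known alignment tensor and adds Gaussian noise. When
#' \code{flexibleLinkerIndex} is set, domains after that linker use the
#' second tensor, emulating segments that align independently because of
#' interdomain motion.
#'
#' @param m an \linkS4class{AssemblyModel}.
#' @param tensor \linkS4class{AlignmentTensor} for (the first segment of)
#'   the model.
#' @param noise Gaussian noise sd (Hz).
#' @param seed RNG seed.
#' @param flexibleLinkerIndex optional index i: domains i+1, ... use
#'   \code{tensorB}.
#' @param tensorB second \linkS4class{AlignmentTensor}; required with
#'   \code{flexibleLinkerIndex}.
#' @return data.frame(residue, domain, d_obs_hz, sigma_hz).
#' @export
simulateRDCs <- function(m, tensor, noise = 0, seed = 1L,
                         flexibleLinkerIndex = NULL, tensorB = NULL) {
    stopifnot(is(m, "AssemblyModel"), is(tensor, "AlignmentTensor"))
    if (!is.null(flexibleLinkerIndex) && is.null(tensorB))
        stop("tensorB is required when flexibleLinkerIndex is set")
    defs <- lapply(m@fragments, `[[`, "definition")
    vecs <- extractNHVectors(m@structure, defs)
    tensorOf <- function(domIdx)
        if (!is.null(flexibleLinkerIndex) && domIdx > flexibleLinkerIndex)
            tensorB else tensor
    ids <- vapply(defs, function(d) d@domainId, "")
    withLocalSeed(seed, {
        d <- numeric(nrow(vecs))
        for (dom in unique(vecs$domain)) {
            sel <- vecs$domain == dom
            d[sel] <- backCalculate(tensorOf(match(dom, ids)),
                                    vecs[sel, , drop = FALSE])
        }
        data.frame(residue = vecs$residue, domain = vecs$domain,
                   d_obs_hz = d + stats::rnorm(length(d), 0, noise),
                   sigma_hz = rep(max(noise, 1e-3), length(d)))
    })
}

#' Simulate heteronuclear NOE peak-height pairs
#'
#' Rigid residues sit near the rigid-limit plateau and flexible residues
#' near the mobile level, with Gaussian spread; both peak heights then get
#' baseline noise.
#'
#' @param residues integer vector of residue numbers.
#' @param flexibleRegions list of integer(2) residue ranges that are
#'   mobile.
#' @param noise baseline noise on the peak heights (reference height 1).
#' @param seed RNG seed.
#' @param rigidMean,flexMean NOE ratio means of the two classes.
#' @param spread residue-to-residue sd of the true ratio.
#' @return data.frame(residue, i_sat, i_ref, noise).
#' @export
simulateHetNOE <- function(residues, flexibleRegions = list(),
                           noise = 0.02, seed = 1L, rigidMean = 0.78,
                           flexMean = 0.3, spread = 0.02) {
    withLocalSeed(seed, {
        flex <- rep(FALSE, length(residues))
        for (rng in flexibleRegions)
            flex <- flex | (residues >= rng[1L] & residues <= rng[2L])
        trueRatio <- ifelse(flex, flexMean, rigidMean) +
            stats::rnorm(length(residues), 0, spread)
        iRef <- 1 + stats::rnorm(length(residues), 0, noise)
        iSat <- trueRatio + stats::rnorm(length(residues), 0, noise)
        data.frame(residue = residues, i_sat = iSat, i_ref = iRef,
                   noise = rep(noise, length(residues)))
    })
}

#' Simulate a chelator-competition titration
#'
#' Forward competition model under the standard working conditions of the
#' chromophoric-chelator method (chelator Kd 1.6 uM; 20-30 uM chelator and
#' protein), with Gaussian signal noise.
#'
#' @param kds protein site Kd(s), molar.
#' @param noise signal noise sd (normalized absorbance units).
#' @param seed RNG seed.
#' @param chelatorKd,chelatorTotal,proteinTotal molar conditions.
#' @param nPoints titration points (calcium from 0 to twice the total site
#'   capacity).
#' @return A \linkS4class{CompetitionTitration}.
#' @export
simulateCompetition <- function(kds, noise = 0.005, seed = 1L,
                                chelatorKd = 1.6e-6,
                                chelatorTotal = 25e-6,
                                proteinTotal = 25e-6, nPoints = 25L) {
    stopifnot(all(kds > 0), nPoints >= 8L)
    caMax <- 2 * (chelatorTotal + length(kds) * proteinTotal)
    ca <- seq(0, caMax, length.out = nPoints)
    t0 <- CompetitionTitration(
        points = data.frame(ca_total = ca, signal = 1),
        chelatorTotal = chelatorTotal, proteinTotal = proteinTotal,
        chelatorKd = chelatorKd)
    sig <- competitionSignal(ca, t0, kds)
    withLocalSeed(seed, {
        sig <- sig + stats::rnorm(length(sig), 0, noise)
        CompetitionTitration(
            points = data.frame(ca_total = ca, signal = sig),
            chelatorTotal = chelatorTotal, proteinTotal = proteinTotal,
            chelatorKd = chelatorKd)
    })
}

#' Simulate a single-site NMR titration
#'
#' Fast-exchange observable proportional to the bound fraction with ligand
#' depletion, plus Gaussian noise. Sampling is quadratic (dense at low
#' calcium) up to well past the Kd.
#'
#' @param kd site dissociation constant (M).
#' @param noise observation noise sd.
#' @param seed RNG seed.
#' @param proteinTotal protein concentration (M).
#' @param amplitude saturating observable value.
#' @param nPoints number of titration points.
#' @return An \linkS4class{NMRTitrationCurve}.
#' @export
simulateNMRTitration <- function(kd, noise = 0, seed = 1L,
                                 proteinTotal = 100e-6, amplitude = 1,
                                 nPoints = 15L) {
    stopifnot(kd > 0, nPoints >= 5L)
    caMax <- max(25e-3, 10 * kd)
    ca <- caMax * seq(0, 1, length.out = nPoints)^2
    obs <- amplitude * .boundFraction(ca, proteinTotal, kd)
    withLocalSeed(seed, {
        obs <- obs + stats::rnorm(length(obs), 0, noise)
        NMRTitrationCurve(points = data.frame(ca_total = ca,
                                              observed = obs),
                          proteinTotal = proteinTotal)
    })
}
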