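## Calcium-binding consensus classification for EGF-like domains.
##
## The predictive consensus at the N terminus of a Ca2+-binding EGF domain
## is D/N-x-D/N-E/Q-x(m)-D/N*-x(n)-Y/F, where * marks the possibly
## beta-hydroxylated residue and m/n are variable spacings. Some domains
## carry an aspartate in place of the expected E/Q at the third consensus
## site and still bind calcium with high affinity; that variant is accepted
## on request and flagged.

#' Construct an EGFSequence
#'
#' @param domainId domain label, e.g. "EGF5".
#' @param sequence one-letter amino-acid string containing six cysteines.
#' @param cysIndex optional integer(6) 1-based cysteine positions; located
#'   automatically when the sequence contains exactly six cysteines.
#' @param startResidue author residue number of the first position.
#' @return An \linkS4class{EGFSequence}.
#' @export
EGFSequence <- function(domainId, sequence, cysIndex = NULL,
                        startResidue = 1L) {
    if (is.null(cysIndex)) {
        cysIndex <- which(strsplit(sequence, "")[[1L]] == "C")
        if (length(cysIndex) != 6L)
            stop("sequence of ", domainId, " has ", length(cysIndex),
                 " cysteines; supply cysIndex explicitly")
    }
    new("EGFSequence", domainId = domainId, sequence = sequence,
        cysIndex = as.integer(cysIndex),
        startResidue = as.integer(startResidue))
}

#' Read per-domain EGF sequences from FASTA
#'
#' Headers must carry the domain id as the record name; an optional
#' \code{start=<n>} token in the description sets the author numbering
#' offset.
#'
#' @param path FASTA file.
#' @return list of \linkS4class{EGFSequence}, named by domain id.
#' @export
readEGFFasta <- function(path) {
    aa <- Biostrings::readAAStringSet(path)
    out <- list()
    for (i in seq_along(aa)) {
        hdr <- names(aa)[i]
        toks <- strsplit(hdr, "\\s+")[[1L]]
        id <- toks[1L]
        start <- 1L
        st <- grep("^start=", toks, value = TRUE)
        if (length(st) == 1L) start <- as.integer(sub("^start=", "", st))
        out[[id]] <- EGFSequence(id, as.character(aa[[i]]),
                                 startResidue = start)
    }
    out
}

#' Derive EGF domain definitions from a structure's cysteine pattern
#'
#' Groups the chain's cysteine residues, in sequence order, into
#' consecutive sets of six (the canonical EGF disulfide complement) and
#' builds one \linkS4class{DomainDefinition} per set, with the residue
#' range extended a few residues beyond the Cys1-Cys6 span.
#'
#' @param s a \linkS4class{Structure}.
#' @param chain chain identifier.
#' @param ids optional domain labels, one per group of six cysteines.
#' @return list of \linkS4class{DomainDefinition}.
#' @export
deriveDomainDefinitions <- function(s, chain, ids = NULL) {
    a <- atoms(s)
    cys <- sort(unique(a$resno[a$chain == chain & a$resid == "CYS"]))
    if (length(cys) %% 6L != 0L)
        stop("chain ", chain, " has ", length(cys),
             " cysteines; not a multiple of six")
    nDom <- length(cys) %/% 6L
    if (is.null(ids)) ids <- paste0("EGF", seq_len(nDom))
    lapply(seq_len(nDom), function(i) {
        cp <- cys[(6L * (i - 1L) + 1L):(6L * i)]
        new("DomainDefinition", domainId = ids[i], chainId = chain,
            residueRange = c(cp[1L] - 4L, cp[6L] + 1L),
            cysPositions = as.integer(cp))
    })
}

.matchClass <- function(ch, class) {
    switch(class,
           DN = ch %in% c("D", "N"),
           EQ = ch %in% c("E", "Q"),
           EQD = ch %in% c("E", "Q", "D"),
           YF = ch %in% c("Y", "F"),
           TRUE)
}

#' Classify an EGF domain as calcium binding from its sequence
#'
#' Searches the N-terminal region for the calcium-binding consensus
#' D/N-x-D/N-E/Q-x(m)-D/N*-x(n)-Y/F. The match must start at or before the
#' residue preceding the first cysteine, the D/N* site must fall strictly
#' between Cys3 and Cys4, and the Y/F site strictly between Cys4 and Cys5 -
#' the positions the calcium ligands occupy in canonical cbEGF folds.
#'
#' @param d an \linkS4class{EGFSequence}.
#' @param allowDAtThird accept D at the E/Q (third) consensus site; matches
#'   made through this variant are flagged via \code{thirdSiteIsD}.
#' @param mRange,nRange allowed spacings (inclusive) between the E/Q site
#'   and D/N*, and between D/N* and Y/F.
#' @return list with elements \code{isCb}, \code{sitePositions} (named
#'   integer vector, 1-based within the sequence), \code{m}, \code{n},
#'   \code{thirdSiteIsD} and \code{packingAromatic} (position four after the
#'   fifth cysteine if aromatic, see \code{\link{findPackingAromatic}}).
#' @examples
#' seqs <- syntheticNotchSequences()
#' classifyCaBinding(seqs[["EGF12"]])$isCb
#' @export
classifyCaBinding <- function(d, allowDAtThird = FALSE,
                              mRange = c(0L, 12L), nRange = c(0L, 12L)) {
    stopifnot(is(d, "EGFSequence"))
    s <- strsplit(d@sequence, "")[[1L]]
    ci <- d@cysIndex
    if (length(s) < ci[6L]) stop("sequence shorter than its six cysteines")
    third <- if (allowDAtThird) "EQD" else "EQ"
    noMatch <- list(isCb = FALSE, sitePositions = NULL, m = NA_integer_,
                    n = NA_integer_, thirdSiteIsD = FALSE,
                    packingAromatic = tryCatch(findPackingAromatic(d),
                                               error = function(e) NULL))
    for (p in seq_len(max(ci[1L] - 1L, 0L))) {
        if (p + 3L > length(s)) break
        if (!(.matchClass(s[p], "DN") && .matchClass(s[p + 2L], "DN") &&
              .matchClass(s[p + 3L], third))) next
        qs <- if (ci[4L] - ci[3L] >= 2L) seq(ci[3L] + 1L, ci[4L] - 1L)
              else integer(0)
        rs <- if (ci[5L] - ci[4L] >= 2L) seq(ci[4L] + 1L, ci[5L] - 1L)
              else integer(0)
        for (q in qs) {
            m <- q - (p + 3L) - 1L
            if (m < mRange[1L] || m > mRange[2L]) next
            if (!.matchClass(s[q], "DN")) next
            for (r in rs) {
                n <- r - q - 1L
                if (n < nRange[1L] || n > nRange[2L]) next
                if (!.matchClass(s[r], "YF")) next
                sites <- c(site1 = p, x = p + 1L, site2 = p + 2L,
                           site3 = p + 3L, siteHydroxy = q, siteArom = r)
                return(list(isCb = TRUE, sitePositions = sites,
                            m = m, n = n,
                            thirdSiteIsD = s[p + 3L] == "D",
                            packingAromatic = noMatch$packingAromatic))
            }
        }
    }
    noMatch
}

#' Locate the interdomain packing aromatic of an EGF domain
#'
#' The residue four positions after the fifth cysteine packs against the
#' major beta-hairpin of the following domain in rod-like tandem cbEGF
#' pairs. Returns that position if it holds an aromatic (Y/F/W, or H which
#' occurs as a non-standard packing residue), otherwise NULL.
#'
#' @param d an \linkS4class{EGFSequence}.
#' @return 1-based position within the sequence, or NULL.
#' @export
findPackingAromatic <- function(d) {
    stopifnot(is(d, "EGFSequence"))
    s <- strsplit(d@sequence, "")[[1L]]
    pos <- d@cysIndex[5L] + 4L
    if (pos > length(s))
        stop("sequence of ", d@domainId,
             " ends before position four after the fifth cysteine")
    if (s[pos] %in% c("Y", "F", "W", "H")) pos else NULL
}

#' Interdomain linker length
#'
#' Number of residues strictly between the sixth cysteine of the N-terminal
#' domain and the first cysteine of the following domain.
#'
#' @param a,b consecutive \linkS4class{EGFSequence} or
#'   \linkS4class{DomainDefinition} objects (a precedes b).
#' @return integer linker length.
#' @examples
#' seqs <- syntheticNotchSequences()
#' linkerLength(seqs[["EGF9"]], seqs[["EGF10"]])  # 5
#' @export
linkerLength <- function(a, b) {
    cys6a <- if (is(a, "DomainDefinition")) a@cysPositions[6L] else
        cysPositions(a)[6L]
    cys1b <- if (is(b, "DomainDefinition")) b@cysPositions[1L] else
        cysPositions(b)[1L]
    n <- cys1b - cys6a - 1L
    if (n < 0L)
        stop("domains overlap or are misordered (Cys6 of ", domainId(a),
             " at ", cys6a, ", Cys1 of ", domainId(b), " at ", cys1b, ")")
    as.integer(n)
}
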