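#' @import methods
NULL

## ---------------------------------------------------------------------------
## Coordinates and domains
## ---------------------------------------------------------------------------

#' Protein structure container
#'
#' Holds atomic coordinates in Angstrom with author residue numbering
#' preserved exactly as read. The \code{atoms} slot is a data.frame with
#' columns \code{serial}, \code{atom}, \code{resid}, \code{chain},
#' \code{resno}, \code{x}, \code{y}, \code{z}, \code{element}, \code{b}.
#'
#' @slot atoms data.frame of atom records, one row per atom, file order.
#' @exportClass Structure
setClass("Structure", representation(atoms = "data.frame"))

setValidity("Structure", function(object) {
    a <- object@atoms
    need <- c("serial", "atom", "resid", "chain", "resno",
              "x", "y", "z", "element", "b")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) > 0L && !all(is.finite(c(a$x, a$y, a$z))))
        return("atom coordinates must be finite")
    TRUE
})

#' EGF domain definition
#'
#' A domain is an inclusive author-numbered residue range on one chain,
#' together with the six canonical cysteine positions in ascending order.
#'
#' @slot domainId single string, e.g. "EGF5".
#' @slot chainId single string.
#' @slot residueRange integer(2), inclusive.
#' @slot cysPositions integer(6), strictly increasing, inside residueRange.
#' @exportClass DomainDefinition
setClass("DomainDefinition",
    representation(domainId = "character", chainId = "character",
                   residueRange = "integer", cysPositions = "integer"))

setValidity("DomainDefinition", function(object) {
    if (length(object@residueRange) != 2L)
        return("residueRange must have length 2")
    cp <- object@cysPositions
    if (length(cp) != 6L) return("exactly six cysteine positions required")
    if (any(diff(cp) <= 0L)) return("cysteine positions must strictly increase")
    if (cp[1L] < object@residueRange[1L] || cp[6L] > object@residueRange[2L])
        return("cysteine positions must lie inside residueRange")
    TRUE
})

#' EGF domain sequence
#'
#' One-letter amino-acid sequence of a single EGF-like domain with the six
#' canonical cysteines located. Positions are 1-based within the sequence;
#' \code{startResidue} gives the author residue number of position 1 so that
#' linker lengths between consecutive domains can be computed.
#'
#' @slot domainId single string.
#' @slot sequence amino-acid string.
#' @slot cysIndex integer(6), 1-based positions of the six cysteines.
#' @slot startResidue author residue number of the first sequence position.
#' @exportClass EGFSequence
setClass("EGFSequence",
    representation(domainId = "character", sequence = "character",
                   cysIndex = "integer", startResidue = "integer"))

setValidity("EGFSequence", function(object) {
    s <- strsplit(object@sequence, "")[[1L]]
    ci <- object@cysIndex
    if (length(ci) != 6L) return("exactly six cysteine indices required")
    if (any(diff(ci) <= 0L)) return("cysteine indices must strictly increase")
    if (ci[6L] > length(s)) return("cysteine index beyond sequence end")
    if (!all(s[ci] == "C")) return("all cysteine indices must hold 'C'")
    TRUE
})

## ---------------------------------------------------------------------------
## Calcium binding
## ---------------------------------------------------------------------------

#' Chelator competition titration
#'
#' Normalized chromophoric-chelator competition curve. \code{points} is a
#' data.frame with columns \code{ca_total} (M, strictly increasing) and
#' \code{signal} (fraction of chelator in the Ca-free state, 1 at zero Ca).
#'
#' @slot points data.frame(ca_total, signal).
#' @slot chelatorTotal total chelator concentration (M).
#' @slot proteinTotal total protein concentration (M).
#' @slot chelatorKd chelator Ca2+ dissociation constant (M).
#' @exportClass CompetitionTitration
setClass("CompetitionTitration",
    representation(points = "data.frame", chelatorTotal = "numeric",
                   proteinTotal = "numeric", chelatorKd = "numeric"))

setValidity("CompetitionTitration", function(object) {
    p <- object@points
    if (!all(c("ca_total", "signal") %in% names(p)))
        return("points needs columns ca_total, signal")
    if (any(p$ca_total < 0)) return("ca_total must be non-negative")
    if (nrow(p) > 1L && any(diff(p$ca_total) <= 0))
        return("ca_total must strictly increase")
    if (object@chelatorKd <= 0) return("chelatorKd must be positive")
    TRUE
})

#' NMR calcium titration curve
#'
#' Fast-exchange single-site titration: a dimensionless observable (chemical
#' shift change or normalized intensity) versus total Ca2+.
#'
#' @slot points data.frame(ca_total, observed).
#' @slot proteinTotal protein concentration (M).
#' @exportClass NMRTitrationCurve
setClass("NMRTitrationCurve",
    representation(points = "data.frame", proteinTotal = "numeric"))

setValidity("NMRTitrationCurve", function(object) {
    p <- object@points
    if (!all(c("ca_total", "observed") %in% names(p)))
        return("points needs columns ca_total, observed")
    if (nrow(p) < 5L) return("at least 5 titration points required")
    if (!all(is.finite(p$observed))) return("observed values must be finite")
    TRUE
})

#' Fitted calcium-binding model
#'
#' @slot nSites 1 or 2.
#' @slot kd fitted dissociation constants (M), ascending.
#' @slot kdSe standard errors of the kd estimates (M).
#' @slot amplitude fitted amplitude (NMR titration fits; NA otherwise).
#' @slot sse residual sum of squares.
#' @slot nPoints number of data points fitted.
#' @slot nPar number of fitted parameters.
#' @slot converged logical; optimizer convergence.
#' @slot illDetermined logical; TRUE when a kd standard error exceeds the
#'   estimate or the curve carries no information about the parameter.
#' @exportClass BindingFit
setClass("BindingFit",
    representation(nSites = "integer", kd = "numeric", kdSe = "numeric",
                   amplitude = "numeric", sse = "numeric", nPoints = "integer",
                   nPar = "integer", converged = "logical",
                   illDetermined = "logical"))

setValidity("BindingFit", function(object) {
    if (length(object@kd) != object@nSites)
        return("length of kd must equal nSites")
    if (any(object@kd <= 0)) return("kd must be positive")
    if (object@sse < 0) return("sse must be non-negative")
    TRUE
})

## ---------------------------------------------------------------------------
## RDC analysis
## ---------------------------------------------------------------------------

#' Molecular alignment (Saupe) tensor
#'
#' Symmetric traceless order matrix characterised by the axial magnitude
#' \code{da} (Hz), rhombicity in [0, 2/3], and the principal-frame
#' orientation. Eigenvalues are assigned to axes by the convention
#' |Szz| >= |Syy| >= |Sxx| with Da = Szz/2.
#'
#' @slot saupe numeric(5): (Syy, Szz, Sxy, Sxz, Syz); Sxx = -Syy - Szz.
#' @slot da axial component (Hz).
#' @slot rhombicity dimensionless, in [0, 2/3].
#' @slot eulerAngles z-y-z Euler angles (degrees) rotating the structure
#'   frame onto the principal frame.
#' @exportClass AlignmentTensor
setClass("AlignmentTensor",
    representation(saupe = "numeric", da = "numeric", rhombicity = "numeric",
                   eulerAngles = "numeric"))

setValidity("AlignmentTensor", function(object) {
    if (length(object@saupe) != 5L) return("saupe must have 5 elements")
    if (object@rhombicity < -1e-9 || object@rhombicity > 2 / 3 + 1e-9)
        return("rhombicity must lie in [0, 2/3]")
    S <- saupeMatrix(object)
    if (abs(sum(diag(S))) > 1e-8 * max(1, max(abs(S))))
        return("saupe matrix must be traceless")
    TRUE
})

#' Alignment-tensor fit result
#'
#' @slot tensor fitted AlignmentTensor.
#' @slot q Q factor, sqrt(sum((obs-calc)^2)) / sqrt(sum(obs^2)).
#' @slot rmsDev rms deviation of observed minus back-calculated RDCs (Hz).
#' @slot daSe linearized standard error of da (Hz).
#' @slot nUsed number of RDCs used.
#' @slot condition design-matrix condition number.
#' @exportClass TensorFit
setClass("TensorFit",
    representation(tensor = "AlignmentTensor", q = "numeric",
                   rmsDev = "numeric", daSe = "numeric", nUsed = "integer",
                   condition = "numeric"))

setValidity("TensorFit", function(object) {
    if (object@q < 0) return("q must be non-negative")
    if (object@nUsed < 5L) return("at least 5 RDCs are required for a fit")
    TRUE
})

#' Interdomain flexibility verdict
#'
#' Decision from comparing per-segment alignment tensors with a joint
#' single-tensor fit. Segments that align independently (different Da sign
#' or magnitude, or a joint Q well above the segment Qs) indicate
#' medium-to-large-scale interdomain motion.
#'
#' @slot segmentA,segmentB segment labels.
#' @slot daA,daB per-segment axial components (Hz).
#' @slot daSeA,daSeB their standard errors (Hz).
#' @slot qJoint,qA,qB Q factors of the joint and per-segment fits.
#' @slot verdict one of "rigid", "flexible", "indeterminate".
#' @slot rationale which decision clauses fired.
#' @exportClass FlexibilityVerdict
setClass("FlexibilityVerdict",
    representation(segmentA = "character", segmentB = "character",
                   daA = "numeric", daB = "numeric",
                   daSeA = "numeric", daSeB = "numeric",
                   qJoint = "numeric", qA = "numeric", qB = "numeric",
                   verdict = "character", rationale = "character"))

setValidity("FlexibilityVerdict", function(object) {
    if (!object@verdict %in% c("rigid", "flexible", "indeterminate"))
        return("verdict must be rigid, flexible or indeterminate")
    TRUE
})

## ---------------------------------------------------------------------------
## Geometry and assembly
## ---------------------------------------------------------------------------

#' Domain reference frame
#'
#' Orthonormal frame attached to an EGF domain: centroid origin, long axis
#' (principal inertia axis of the Cys1-Cys6 C-alpha span, oriented N to C)
#' and a twist reference perpendicular to it (orthogonalized Cys3 to Cys4
#' direction).
#'
#' @slot origin numeric(3), Angstrom.
#' @slot longAxis unit numeric(3).
#' @slot twistRef unit numeric(3), orthogonal to longAxis.
#' @exportClass DomainFrame
setClass("DomainFrame",
    representation(origin = "numeric", longAxis = "numeric",
                   twistRef = "numeric"))

setValidity("DomainFrame", function(object) {
    if (abs(sqrt(sum(object@longAxis^2)) - 1) > 1e-9)
        return("longAxis must be a unit vector")
    if (abs(sqrt(sum(object@twistRef^2)) - 1) > 1e-9)
        return("twistRef must be a unit vector")
    if (abs(sum(object@longAxis * object@twistRef)) > 1e-9)
        return("twistRef must be orthogonal to longAxis")
    TRUE
})

#' Interdomain tilt/twist geometry
#'
#' @slot tilt inclination between domain long axes, degrees in [0, 180].
#' @slot twist rotation about the N-terminal domain's long axis after
#'   removing tilt, degrees in (-180, 180].
#' @exportClass InterdomainGeometry
setClass("InterdomainGeometry",
    representation(tilt = "numeric", twist = "numeric"))

setValidity("InterdomainGeometry", function(object) {
    if (object@tilt < 0 || object@tilt > 180)
        return("tilt must lie in [0, 180] degrees")
    if (object@twist <= -180 || object@twist > 180)
        return("twist must lie in (-180, 180] degrees")
    TRUE
})

#' Proper rigid-body transform
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation numeric(3), Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
    representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
        return("rotation must be orthogonal")
    if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
    TRUE
})

#' Assembled multidomain model
#'
#' Rigid-body assembly of EGF domain fragments at specified interdomain
#' geometries. \code{structure} holds the merged coordinates; per-domain
#' definitions and the transforms applied to each fragment are retained.
#'
#' @slot fragments list of list(structure = Structure,
#'   definition = DomainDefinition), in N-to-C order.
#' @slot transforms list of RigidTransform, one per fragment.
#' @slot geometries list of InterdomainGeometry between consecutive domains.
#' @slot linkerResidues integer vector of linker lengths between
#'   consecutive domains.
#' @slot structure merged Structure.
#' @exportClass AssemblyModel
setClass("AssemblyModel",
    representation(fragments = "list", transforms = "list",
                   geometries = "list", linkerResidues = "integer",
                   structure = "Structure"))

setValidity("AssemblyModel", function(object) {
    if (length(object@geometries) != length(object@fragments) - 1L)
        return("need exactly one geometry per consecutive domain pair")
    TRUE
})

#' Steric clash and linker feasibility report
#'
#' @slot nClashes number of inter-domain heavy-atom pairs below the cutoff.
#' @slot pairs data.frame of clashing atom pairs with distances (Angstrom).
#' @slot linkerFeasible logical, one per linker: Cys6-Cys1 C-alpha span
#'   within the per-residue extension limit.
#' @exportClass ClashReport
setClass("ClashReport",
    representation(nClashes = "integer", pairs = "data.frame",
                   linkerFeasible = "logical"))

setValidity("ClashReport", function(object) {
    if (object@nClashes != nrow(object@pairs))
        return("nClashes must equal the number of reported pairs")
    TRUE
})
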