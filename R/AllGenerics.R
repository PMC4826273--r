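## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))
#' @export
setGeneric("cysPositions", function(x) standardGeneric("cysPositions"))
#' @export
setGeneric("residueRange", function(x) standardGeneric("residueRange"))
#' @export
setGeneric("domainSequence", function(x) standardGeneric("domainSequence"))
#' @export
setGeneric("titrationPoints", function(x) standardGeneric("titrationPoints"))
#' @export
setGeneric("kdValues", function(x) standardGeneric("kdValues"))
#' @export
setGeneric("kdErrors", function(x) standardGeneric("kdErrors"))
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @export
setGeneric("sseValue", function(x) standardGeneric("sseValue"))
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @export
setGeneric("isIllDetermined", function(x) standardGeneric("isIllDetermined"))
#' @export
setGeneric("saupeMatrix", function(x) standardGeneric("saupeMatrix"))
#' @export
setGeneric("daValue", function(x) standardGeneric("daValue"))
#' @export
setGeneric("daError", function(x) standardGeneric("daError"))
#' @export
setGeneric("rhombicity", function(x) standardGeneric("rhombicity"))
#' @export
setGeneric("eulerAngles", function(x) standardGeneric("eulerAngles"))
#' @export
setGeneric("qFactor", function(x) standardGeneric("qFactor"))
#' @export
setGeneric("alignmentTensor", function(x) standardGeneric("alignmentTensor"))
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @export
setGeneric("tiltAngle", function(x) standardGeneric("tiltAngle"))
#' @export
setGeneric("twistAngle", function(x) standardGeneric("twistAngle"))
#' @export
setGeneric("modelStructure", function(x) standardGeneric("modelStructure"))
#' @export
setGeneric("modelGeometries", function(x) standardGeneric("modelGeometries"))
#' @export
setGeneric("modelFragments", function(x) standardGeneric("modelFragments"))
#' @export
setGeneric("nClashes", function(x) standardGeneric("nClashes"))
#' @export
setGeneric("linkerFeasible", function(x) standardGeneric("linkerFeasible"))

#' @describeIn Structure-class atom table accessor
#' @param x object
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @export
setMethod("domainId", "DomainDefinition", function(x) x@domainId)
#' @export
setMethod("domainId", "EGFSequence", function(x) x@domainId)
#' @export
setMethod("cysPositions", "DomainDefinition", function(x) x@cysPositions)
#' @export
setMethod("cysPositions", "EGFSequence",
          function(x) x@cysIndex + x@startResidue - 1L)
#' @export
setMethod("residueRange", "DomainDefinition", function(x) x@residueRange)
#' @export
setMethod("domainSequence", "EGFSequence", function(x) x@sequence)

#' @export
setMethod("titrationPoints", "CompetitionTitration", function(x) x@points)
#' @export
setMethod("titrationPoints", "NMRTitrationCurve", function(x) x@points)

#' @export
setMethod("kdValues", "BindingFit", function(x) x@kd)
#' @export
setMethod("kdErrors", "BindingFit", function(x) x@kdSe)
#' @export
setMethod("nSites", "BindingFit", function(x) x@nSites)
#' @export
setMethod("sseValue", "BindingFit", function(x) x@sse)
#' @export
setMethod("isConverged", "BindingFit", function(x) x@converged)
#' @export
setMethod("isIllDetermined", "BindingFit", function(x) x@illDetermined)

#' @export
setMethod("saupeMatrix", "AlignmentTensor", function(x) {
    p <- x@saupe
    matrix(c(-p[1L] - p[2L], p[3L], p[4L],
             p[3L],          p[1L], p[5L],
             p[4L],          p[5L], p[2L]), 3L, 3L)
})
#' @export
setMethod("daValue", "AlignmentTensor", function(x) x@da)
#' @export
setMethod("rhombicity", "AlignmentTensor", function(x) x@rhombicity)
#' @export
setMethod("eulerAngles", "AlignmentTensor", function(x) x@eulerAngles)
#' @export
setMethod("daValue", "TensorFit", function(x) x@tensor@da)
#' @export
setMethod("daError", "TensorFit", function(x) x@daSe)
#' @export
setMethod("qFactor", "TensorFit", function(x) x@q)
#' @export
setMethod("alignmentTensor", "TensorFit", function(x) x@tensor)
#' @export
setMethod("verdict", "FlexibilityVerdict", function(x) x@verdict)

#' @export
setMethod("tiltAngle", "InterdomainGeometry", function(x) x@tilt)
#' @export
setMethod("twistAngle", "InterdomainGeometry", function(x) x@twist)

#' @export
setMethod("modelStructure", "AssemblyModel", function(x) x@structure)
#' @export
setMethod("modelGeometries", "AssemblyModel", function(x) x@geometries)
#' @export
setMethod("modelFragments", "AssemblyModel", function(x) x@fragments)
#' @export
setMethod("nClashes", "ClashReport", function(x) x@nClashes)
#' @export
setMethod("linkerFeasible", "ClashReport", function(x) x@linkerFeasible)

## show methods -------------------------------------------------------------

setMethod("show", "Structure", function(object) {
    a <- object@atoms
    cat("Structure with", nrow(a), "atoms,",
        length(unique(paste(a$chain, a$resno))), "residues,",
        length(unique(a$chain)), "chain(s)\n")
})

setMethod("show", "DomainDefinition", function(object) {
    cat(sprintf("DomainDefinition %s chain %s residues %d-%d, Cys at %s\n",
                object@domainId, object@chainId,
                object@residueRange[1L], object@residueRange[2L],
                paste(object@cysPositions, collapse = ",")))
})

setMethod("show", "EGFSequence", function(object) {
    cat(sprintf("EGFSequence %s (%d aa, start %d)\n  %s\n", object@domainId,
                nchar(object@sequence), object@startResidue, object@sequence))
})

setMethod("show", "BindingFit", function(object) {
    cat(sprintf("BindingFit: %d site(s), n = %d\n", object@nSites,
                object@nPoints))
    for (i in seq_len(object@nSites))
        cat(sprintf("  Kd%d = %.4g +/- %.2g uM\n", i, object@kd[i] * 1e6,
                    object@kdSe[i] * 1e6))
    cat(sprintf("  sse = %.4g; converged = %s; ill-determined = %s\n",
                object@sse, object@converged, object@illDetermined))
})

setMethod("show", "AlignmentTensor", function(object) {
    cat(sprintf(
        "AlignmentTensor: Da = %.3f Hz, R = %.3f, euler(zyz) = %s deg\n",
        object@da, object@rhombicity,
        paste(sprintf("%.1f", object@eulerAngles), collapse = ", ")))
})

setMethod("show", "TensorFit", function(object) {
    cat(sprintf(
        "TensorFit: Da = %.3f +/- %.3f Hz, R = %.3f, Q = %.4f (n = %d)\n",
        object@tensor@da, object@daSe, object@tensor@rhombicity, object@q,
        object@nUsed))
})

setMethod("show", "FlexibilityVerdict", function(object) {
    cat(sprintf("FlexibilityVerdict %s vs %s: %s\n", object@segmentA,
                object@segmentB, object@verdict))
    cat(sprintf("  Da = %.2f +/- %.2f vs %.2f +/- %.2f Hz; Q joint %.3f, segments %.3f/%.3f\n",
                object@daA, object@daSeA, object@daB, object@daSeB,
                object@qJoint, object@qA, object@qB))
    cat("  ", object@rationale, "\n")
})

setMethod("show", "InterdomainGeometry", function(object) {
    cat(sprintf("InterdomainGeometry: tilt %.2f deg, twist %.2f deg\n",
                object@tilt, object@twist))
})

setMethod("show", "AssemblyModel", function(object) {
    ids <- vapply(object@fragments, function(f) f$definition@domainId, "")
    cat("AssemblyModel:", paste(ids, collapse = "-"), "\n")
    for (i in seq_along(object@geometries))
        cat(sprintf("  %s/%s: tilt %.1f, twist %.1f deg\n", ids[i], ids[i + 1L],
                    object@geometries[[i]]@tilt, object@geometries[[i]]@twist))
})

setMethod("show", "ClashReport", function(object) {
    cat(sprintf("ClashReport: %d clash(es); linkers feasible: %s\n",
                object@nClashes,
                paste(object@linkerFeasible, collapse = ", ")))
})
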