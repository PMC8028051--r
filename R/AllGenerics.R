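#' @rdname ElectronicStateSet-class
#' @param object,x an object.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("stateEnergies", function(x) standardGeneric("stateEnergies"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("atomicCharges", function(x) standardGeneric("atomicCharges"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("transitionDipoles", function(x) standardGeneric("transitionDipoles"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("permanentDipoles", function(x) standardGeneric("permanentDipoles"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' @rdname ElectronicStateSet-class
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' Mass-weighted center of mass of a quantum center
#'
#' For an [ElectronicStateSet-class] the gas-phase geometry is used; for a
#' numeric coordinate matrix the masses must be supplied.  Translating every
#' coordinate by a vector t translates the result by exactly t.
#'
#' @param x an `ElectronicStateSet` or an `nAtoms x 3` coordinate matrix (nm).
#' @param ... for the matrix method, `masses`: positive numeric vector, u.
#' @return Numeric length-3 center of mass, nm.
#' @examples
#' centerOfMass(rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(1, 1))
#' @export
setGeneric("centerOfMass", function(x, ...) standardGeneric("centerOfMass"))

#' @rdname FrameEnsemble-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameEnsemble-class
#' @export
setGeneric("ensembleLabel", function(x) standardGeneric("ensembleLabel"))

#' @rdname FrameEnsemble-class
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' @rdname FrameEnsemble-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname GapSeries-class
#' @export
setGeneric("gapValues", function(x) standardGeneric("gapValues"))

#' @rdname GapSeries-class
#' @export
setGeneric("gapKind", function(x) standardGeneric("gapKind"))
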