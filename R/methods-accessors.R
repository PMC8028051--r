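#' @rdname ElectronicStateSet-class
setMethod("nStates", "ElectronicStateSet", function(x) length(x@energies))

#' @rdname ElectronicStateSet-class
setMethod("nAtoms", "ElectronicStateSet", function(x) nrow(x@geometry))

#' @rdname ElectronicStateSet-class
setMethod("stateEnergies", "ElectronicStateSet", function(x) x@energies)

#' @rdname ElectronicStateSet-class
setMethod("atomicCharges", "ElectronicStateSet", function(x) x@atomicCharges)

#' @rdname ElectronicStateSet-class
setMethod("transitionDipoles", "ElectronicStateSet",
  function(x) x@transitionDipoles)

#' @rdname ElectronicStateSet-class
setMethod("permanentDipoles", "ElectronicStateSet", function(x) {
  ns <- nStates(x)
  out <- matrix(NA_real_, ns, 3L)
  for (i in seq_len(ns)) out[i, ] <- x@transitionDipoles[i, i, ]
  out
})

#' @rdname ElectronicStateSet-class
setMethod("geometry", "ElectronicStateSet", function(x) x@geometry)

#' @rdname ElectronicStateSet-class
setMethod("totalCharge", "ElectronicStateSet", function(x) x@totalCharge)

#' @rdname ElectronicStateSet-class
setMethod("speciesLabel", "ElectronicStateSet", function(x) x@speciesLabel)

#' @rdname centerOfMass
setMethod("centerOfMass", "ElectronicStateSet", function(x, ...) {
  centerOfMass(as.matrix(x@geometry[, c("x", "y", "z")]),
    masses = x@geometry$mass)
})

#' @rdname centerOfMass
#' @param masses positive atomic masses, u, one per row of the matrix.
setMethod("centerOfMass", "matrix", function(x, masses, ...) {
  if (nrow(x) == 0L) .stopf("centerOfMass: empty geometry")
  if (length(masses) != nrow(x))
    .stopf("centerOfMass: %d masses for %d atoms", length(masses), nrow(x))
  if (any(!is.finite(masses)) || any(masses < 0))
    .stopf("centerOfMass: masses must be finite and non-negative")
  m <- sum(masses)
  if (m <= 0) .stopf("centerOfMass: total mass must be positive")
  as.numeric(crossprod(x, masses) / m)
})

#' @rdname FrameEnsemble-class
setMethod("nFrames", "FrameEnsemble", function(x) length(x@frames))

#' @rdname FrameEnsemble-class
setMethod("ensembleLabel", "FrameEnsemble", function(x) x@label)

#' @rdname FrameEnsemble-class
setMethod("temperature", "FrameEnsemble", function(x) x@temperature)

#' @rdname FrameEnsemble-class
setMethod("frames", "FrameEnsemble", function(x) x@frames)

#' @rdname FrameEnsemble-class
#' @param x a `FrameEnsemble`.
#' @param i frame index.
#' @export
setMethod("[[", "FrameEnsemble", function(x, i) x@frames[[i]])

#' @rdname GapSeries-class
setMethod("gapValues", "GapSeries", function(x) x@values)

#' @rdname GapSeries-class
setMethod("gapKind", "GapSeries", function(x) x@kind)

#' @rdname GapSeries-class
#' @param x a `GapSeries`.
#' @export
setMethod("length", "GapSeries", function(x) length(x@values))

## show methods -------------------------------------------------------------

setMethod("show", "ElectronicStateSet", function(object) {
  cat(sprintf("ElectronicStateSet '%s': %d atoms, %d states, charge %+d e\n",
    object@speciesLabel, nAtoms(object), nStates(object), object@totalCharge))
  e <- object@energies - object@energies[1L]
  cat(sprintf("  excitation energies (eV): %s\n",
    paste(sprintf("%.3f", utils::head(e, 7L)), collapse = ", ")))
})

setMethod("show", "RedoxSpeciesPair", function(object) {
  cat(sprintf("RedoxSpeciesPair '%s': %d atoms, %d states\n",
    object@red@speciesLabel, nAtoms(object@red), nStates(object@red)))
  cat(sprintf("  unperturbed VIE %.4f eV, AIE %.4f eV\n",
    object@oxVertical@energies[1L] - object@red@energies[1L],
    object@oxAdiabatic@energies[1L] - object@red@energies[1L]))
  if (is.finite(object@gasVieCalc))
    cat(sprintf("  gas VIE calc %.3f eV%s\n", object@gasVieCalc,
      if (is.finite(object@gasVieExp))
        sprintf(", exp %.3f eV", object@gasVieExp) else ""))
})

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame: %d QC atoms, %d environment points, box %.3f nm\n",
    nrow(object@qcCoords), nrow(object@envPoints), object@boxEdge))
})

setMethod("show", "FrameEnsemble", function(object) {
  cat(sprintf("FrameEnsemble '%s': %d frames, %d QC atoms, T = %g K\n",
    object@label, nFrames(object),
    if (nFrames(object)) nrow(object@frames[[1L]]@qcCoords) else 0L,
    object@temperature))
})

setMethod("show", "GapSeries", function(object) {
  cat(sprintf(
    "GapSeries (%s, %s): %d frames, mean %.4f eV, sd %.4f eV, %d skipped\n",
    object@label, object@kind, length(object@values), mean(object@values),
    stats::sd(object@values), object@nSkipped))
})

setMethod("show", "PerturbedState", function(object) {
  cat(sprintf("PerturbedState: ground %.6f eV, %d states\n",
    object@groundEnergy, length(object@eigenvalues)))
})

setMethod("show", "RedoxEstimate", function(object) {
  cat("RedoxEstimate (energies eV, potentials V vs SHE)\n")
  cat(sprintf("  VIE     %8.4f +/- %.4f\n", object@vie, object@errVie))
  cat(sprintf("  AIE     %8.4f\n", object@aie))
  cat(sprintf("  deltaA  %8.4f +/- %.4f\n", object@deltaA, object@errDeltaA))
  cat(sprintf("  V_red   %8.4f +/- %.4f\n", object@vRed, object@errVRed))
  cat(sprintf("  reorganization %.4f eV, gas shift applied %+.4f eV\n",
    object@reorganization, object@shiftApplied))
  cat(sprintf("  frames: %d red (%d skipped), %d ox (%d skipped); %s\n",
    object@nFramesRed, object@nSkippedRed, object@nFramesOx,
    object@nSkippedOx, object@ionicRelaxationAssumption))
})
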