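#' @import methods
NULL

## ---------------------------------------------------------------------------
## ElectronicStateSet: gas-phase (unperturbed) description of one species
## ---------------------------------------------------------------------------

#' ElectronicStateSet: unperturbed electronic states of a quantum center
#'
#' Holds the gas-phase description of one chemical species at one geometry, as
#' produced once by electronic-structure calculations and consumed by the
#' perturbed-matrix engine: state energies, per-state atomic partial charges,
#' the geometry of the quantum center (QC), and the full real symmetric
#' transition-dipole matrix whose diagonal carries the permanent dipoles.
#'
#' @slot speciesLabel character(1), free-text species name.
#' @slot totalCharge integer(1), total molecular charge in e.
#' @slot geometry data.frame with columns `atom` (label), `mass` (u) and
#'   `x`, `y`, `z` (nm).
#' @slot energies numeric, one unperturbed electronic energy per state in eV,
#'   ground state first.
#' @slot atomicCharges numeric matrix, `nStates x nAtoms`; each row sums to
#'   `totalCharge` (within 1e-6 e).
#' @slot transitionDipoles numeric array `nStates x nStates x 3`, e nm,
#'   symmetric in its first two indices; `[i, i, ]` is state i's permanent
#'   dipole.
#'
#' @seealso [ElectronicStateSet()] for the user constructor,
#'   [readStateSet()] / [writeStateSet()] for the on-disk schema.
#' @export
setClass("ElectronicStateSet",
  slots = c(
    speciesLabel = "character",
    totalCharge = "integer",
    geometry = "data.frame",
    energies = "numeric",
    atomicCharges = "matrix",
    transitionDipoles = "array"
  )
)

setValidity("ElectronicStateSet", function(object) {
  msg <- character()
  g <- object@geometry
  ns <- length(object@energies)
  na <- nrow(g)
  if (length(object@speciesLabel) != 1L || is.na(object@speciesLabel))
    msg <- c(msg, "speciesLabel must be a single non-NA string")
  if (length(object@totalCharge) != 1L || is.na(object@totalCharge))
    msg <- c(msg, "totalCharge must be a single integer")
  if (!all(c("atom", "mass", "x", "y", "z") %in% names(g)))
    msg <- c(msg, "geometry must have columns atom, mass, x, y, z")
  else {
    if (na < 1L) msg <- c(msg, "geometry must contain at least one atom")
    if (any(!is.finite(as.matrix(g[, c("x", "y", "z")]))))
      msg <- c(msg, "geometry coordinates must be finite")
    if (any(!is.finite(g$mass)) || any(g$mass <= 0))
      msg <- c(msg, "all atomic masses must be positive")
  }
  if (ns < 1L) msg <- c(msg, "at least one electronic state is required")
  if (any(!is.finite(object@energies)))
    msg <- c(msg, "state energies must be finite")
  if (ns >= 2L && any(object@energies[1L] > object@energies[-1L] + 1e-12))
    msg <- c(msg, "state 0 must have the lowest energy")
  if (!identical(dim(object@atomicCharges), c(ns, na)))
    msg <- c(msg, sprintf(
      "atomicCharges must be %d states x %d atoms (got %s)",
      ns, na, paste(dim(object@atomicCharges), collapse = " x ")))
  else {
    qs <- rowSums(object@atomicCharges)
    bad <- which(abs(qs - object@totalCharge) > 1e-6)
    if (length(bad))
      msg <- c(msg, sprintf(
        "atomic charges of state(s) %s sum to %s, expected total charge %d (tol 1e-6 e)",
        paste(bad - 1L, collapse = ", "),
        paste(signif(qs[bad], 8), collapse = ", "), object@totalCharge))
  }
  td <- object@transitionDipoles
  if (!identical(dim(td), c(ns, ns, 3L)))
    msg <- c(msg, sprintf("transitionDipoles must be %d x %d x 3", ns, ns))
  else {
    for (k in 1:3) {
      if (max(abs(td[, , k] - t(td[, , k]))) > 1e-9) {
        msg <- c(msg, "transitionDipoles must be componentwise symmetric")
        break
      }
    }
    if (any(!is.finite(td))) msg <- c(msg, "transition dipoles must be finite")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an ElectronicStateSet
#'
#' @param speciesLabel species name.
#' @param totalCharge total molecular charge, e.
#' @param geometry data.frame with columns `atom`, `mass` (u), `x`, `y`, `z`
#'   (nm).
#' @param energies numeric vector of state energies, eV, ground state first.
#' @param atomicCharges `nStates x nAtoms` matrix of per-state atomic partial
#'   charges, e.
#' @param transitionDipoles `nStates x nStates x 3` array, e nm; diagonal
#'   entries are the permanent dipoles.
#' @return A validated [ElectronicStateSet-class] object.
#' @examples
#' s <- ElectronicStateSet("toy", 0L,
#'   data.frame(atom = "X", mass = 12, x = 0, y = 0, z = 0),
#'   energies = 0, atomicCharges = matrix(0, 1, 1),
#'   transitionDipoles = array(0, c(1, 1, 3)))
#' nStates(s)
#' @export
ElectronicStateSet <- function(speciesLabel, totalCharge, geometry, energies,
                               atomicCharges, transitionDipoles) {
  if (is.vector(atomicCharges) && length(energies) == 1L)
    atomicCharges <- matrix(atomicCharges, nrow = 1L)
  new("ElectronicStateSet",
    speciesLabel = as.character(speciesLabel),
    totalCharge = as.integer(totalCharge),
    geometry = as.data.frame(geometry),
    energies = as.numeric(energies),
    atomicCharges = as.matrix(atomicCharges),
    transitionDipoles = array(as.numeric(transitionDipoles),
      dim = c(length(energies), length(energies), 3L)))
}

## ---------------------------------------------------------------------------
## RedoxSpeciesPair: reduced + oxidized (vertical and adiabatic) state sets
## ---------------------------------------------------------------------------

#' RedoxSpeciesPair: the reduced/oxidized state sets of one redox couple
#'
#' Bundles the three unperturbed descriptions needed for redox thermodynamics:
#' the neutral (reduced) species at its own geometry, the radical cation at the
#' *neutral* geometry (vertical ionization), and the cation at its own relaxed
#' geometry (adiabatic ionization), plus the gas-phase calculated and (if
#' available) experimental vertical ionization energies used for the
#' unperturbed-energy shift correction.
#'
#' @slot red [ElectronicStateSet-class], neutral species.
#' @slot oxVertical [ElectronicStateSet-class], cation at the neutral geometry.
#' @slot oxAdiabatic [ElectronicStateSet-class], cation at its own geometry.
#' @slot gasVieCalc numeric(1), calculated gas-phase VIE, eV.
#' @slot gasVieExp numeric(1), experimental gas-phase VIE, eV (NA if absent).
#' @export
setClass("RedoxSpeciesPair",
  slots = c(
    red = "ElectronicStateSet",
    oxVertical = "ElectronicStateSet",
    oxAdiabatic = "ElectronicStateSet",
    gasVieCalc = "numeric",
    gasVieExp = "numeric"
  )
)

setValidity("RedoxSpeciesPair", function(object) {
  msg <- character()
  gr <- object@red@geometry
  gv <- object@oxVertical@geometry
  if (!identical(gr$atom, gv$atom) ||
      max(abs(as.matrix(gr[, c("x", "y", "z")]) -
              as.matrix(gv[, c("x", "y", "z")]))) > 1e-12)
    msg <- c(msg, "oxVertical geometry must be identical to red geometry")
  if (object@oxVertical@totalCharge != object@red@totalCharge + 1L)
    msg <- c(msg, "oxVertical total charge must be red charge + 1")
  if (object@oxAdiabatic@totalCharge != object@red@totalCharge + 1L)
    msg <- c(msg, "oxAdiabatic total charge must be red charge + 1")
  if (length(object@gasVieCalc) != 1L)
    msg <- c(msg, "gasVieCalc must be a single number (may be NA)")
  if (length(object@gasVieExp) != 1L)
    msg <- c(msg, "gasVieExp must be a single number (may be NA)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a RedoxSpeciesPair
#'
#' @param red,oxVertical,oxAdiabatic see [RedoxSpeciesPair-class].
#' @param gasVieCalc,gasVieExp gas-phase vertical ionization energies, eV;
#'   `gasVieExp` may be `NA` when no experimental value exists.
#' @return A validated [RedoxSpeciesPair-class] object.
#' @export
RedoxSpeciesPair <- function(red, oxVertical, oxAdiabatic,
                             gasVieCalc = NA_real_, gasVieExp = NA_real_) {
  new("RedoxSpeciesPair", red = red, oxVertical = oxVertical,
    oxAdiabatic = oxAdiabatic, gasVieCalc = as.numeric(gasVieCalc),
    gasVieExp = as.numeric(gasVieExp))
}

## ---------------------------------------------------------------------------
## Frame / FrameEnsemble: classical configurations
## ---------------------------------------------------------------------------

#' Frame: one classical configuration of QC atoms plus environment charges
#'
#' @slot boxEdge numeric(1), cubic box side, nm.
#' @slot qcCoords numeric matrix `nAtoms x 3`, QC atom positions, nm, in the
#'   same atom order as the associated [ElectronicStateSet-class] geometry.
#' @slot envPoints data.frame with columns `x`, `y`, `z` (nm), `charge` (e)
#'   and `group` (charge-group id, e.g. one id per solvent molecule); zero
#'   rows for an empty environment.
#' @export
setClass("Frame",
  slots = c(boxEdge = "numeric", qcCoords = "matrix", envPoints = "data.frame"))

setValidity("Frame", function(object) {
  msg <- character()
  if (!.is_number(object@boxEdge) || object@boxEdge <= 0)
    msg <- c(msg, "boxEdge must be a single positive number")
  if (ncol(object@qcCoords) != 3L || nrow(object@qcCoords) < 1L)
    msg <- c(msg, "qcCoords must be an nAtoms x 3 matrix")
  if (any(!is.finite(object@qcCoords)))
    msg <- c(msg, "QC coordinates must be finite")
  ep <- object@envPoints
  if (!all(c("x", "y", "z", "charge", "group") %in% names(ep)))
    msg <- c(msg, "envPoints needs columns x, y, z, charge, group")
  else if (nrow(ep) &&
           any(!is.finite(as.matrix(ep[, c("x", "y", "z", "charge")]))))
    msg <- c(msg, "environment coordinates and charges must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a Frame
#'
#' @param boxEdge cubic box side, nm.
#' @param qcCoords `nAtoms x 3` matrix of QC positions, nm.
#' @param envPoints data.frame of environment point charges (`x`, `y`, `z`,
#'   `charge`, `group`); defaults to an empty environment.
#' @return A validated [Frame-class] object.
#' @export
Frame <- function(boxEdge, qcCoords, envPoints = emptyEnv()) {
  qcCoords <- as.matrix(qcCoords)
  if (is.null(dim(qcCoords)) || ncol(qcCoords) != 3L)
    qcCoords <- matrix(qcCoords, ncol = 3L, byrow = TRUE)
  storage.mode(qcCoords) <- "double"
  dimnames(qcCoords) <- NULL
  new("Frame", boxEdge = as.numeric(boxEdge), qcCoords = qcCoords,
    envPoints = as.data.frame(envPoints))
}

#' @rdname Frame
#' @export
emptyEnv <- function() {
  data.frame(x = numeric(), y = numeric(), z = numeric(),
    charge = numeric(), group = character())
}

#' FrameEnsemble: a labeled, ordered collection of frames
#'
#' One statistical ensemble of classical configurations, sampled with the
#' quantum center either in its reduced (neutral) or oxidized (radical-cation)
#' charge state, each with its own ionic conditions.
#'
#' @slot label character(1), `"reduced"` or `"oxidized"`.
#' @slot temperature numeric(1), K.
#' @slot frames list of [Frame-class] objects, time-ordered.
#' @slot chargeMapId character(1), provenance of the environment charges.
#' @slot variableComposition logical(1); when FALSE (default) every frame must
#'   carry the same multiset of environment group ids.
#' @export
setClass("FrameEnsemble",
  slots = c(label = "character", temperature = "numeric", frames = "list",
    chargeMapId = "character", variableComposition = "logical"))

setValidity("FrameEnsemble", function(object) {
  msg <- character()
  if (!object@label %in% c("reduced", "oxidized"))
    msg <- c(msg, "label must be 'reduced' or 'oxidized'")
  if (!.is_number(object@temperature) || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive number (K)")
  if (!length(object@frames))
    msg <- c(msg, "ensemble must contain at least one frame")
  else {
    if (!all(vapply(object@frames, is, logical(1), "Frame")))
      msg <- c(msg, "all frames must be Frame objects")
    else {
      nqc <- vapply(object@frames, function(f) nrow(f@qcCoords), integer(1))
      if (length(unique(nqc)) != 1L)
        msg <- c(msg, "all frames must share the same QC atom count")
      if (!object@variableComposition) {
        sig <- vapply(object@frames, function(f)
          paste(sort(as.character(f@envPoints$group)), collapse = "|"),
          character(1))
        if (length(unique(sig)) != 1L)
          msg <- c(msg, paste("frames differ in environment group composition;",
            "set variableComposition = TRUE if intended"))
      }
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a FrameEnsemble
#'
#' @param label `"reduced"` or `"oxidized"`.
#' @param frames list of [Frame-class] objects.
#' @param temperature K (default 300).
#' @param chargeMapId provenance string for the environment charges.
#' @param variableComposition allow frames with differing group compositions
#'   (e.g. grand-canonical-style inputs); default FALSE.
#' @return A validated [FrameEnsemble-class] object.
#' @export
FrameEnsemble <- function(label, frames, temperature = 300,
                          chargeMapId = "unspecified",
                          variableComposition = FALSE) {
  new("FrameEnsemble", label = as.character(label), frames = frames,
    temperature = as.numeric(temperature),
    chargeMapId = as.character(chargeMapId),
    variableComposition = isTRUE(variableComposition))
}

## ---------------------------------------------------------------------------
## PerturbationSample / PerturbedState / GapSeries / RedoxEstimate
## ---------------------------------------------------------------------------

#' PerturbationSample: the electrostatic perturbation felt by the QC
#'
#' The per-frame inputs to the perturbed Hamiltonian: the electrostatic
#' potential exerted by the environment at every QC atomic position (used for
#' the atom-based diagonal), and the electric field at the QC center of mass
#' (used for the dipolar off-diagonal coupling).
#'
#' @slot potentialsAtAtoms numeric, V, one per QC atom.
#' @slot fieldAtCom numeric(3), V/nm.
#' @slot com numeric(3), instantaneous QC center of mass, nm.
#' @export
setClass("PerturbationSample",
  slots = c(potentialsAtAtoms = "numeric", fieldAtCom = "numeric",
    com = "numeric"))

setValidity("PerturbationSample", function(object) {
  if (any(!is.finite(object@potentialsAtAtoms)) ||
      !all(is.finite(object@fieldAtCom)) || length(object@fieldAtCom) != 3L ||
      !all(is.finite(object@com)) || length(object@com) != 3L)
    "all perturbation-sample entries must be finite (field and com length 3)"
  else TRUE
})

#' PerturbedState: eigen-solution of one perturbed Hamiltonian
#'
#' @slot eigenvalues numeric, eV, ascending.
#' @slot groundEnergy numeric(1), eV, equal to `eigenvalues[1]`.
#' @slot groundVector numeric, unit-norm coefficients of the perturbed ground
#'   state over the unperturbed basis; sign fixed so the largest-magnitude
#'   coefficient is positive.
#' @slot frameIndex integer(1), originating frame (NA outside a trajectory).
#' @export
setClass("PerturbedState",
  slots = c(eigenvalues = "numeric", groundEnergy = "numeric",
    groundVector = "numeric", frameIndex = "integer"))

setValidity("PerturbedState", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (is.unsorted(ev)) msg <- c(msg, "eigenvalues must be ascending")
  if (abs(object@groundEnergy - ev[1L]) > 1e-12)
    msg <- c(msg, "groundEnergy must equal the lowest eigenvalue")
  if (abs(sqrt(sum(object@groundVector^2)) - 1) > 1e-10)
    msg <- c(msg, "groundVector must have unit norm (tol 1e-10)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GapSeries: per-frame oxidized-minus-reduced perturbed ground energies
#'
#' @slot label character(1), ensemble the frames came from (`"reduced"` or
#'   `"oxidized"`).
#' @slot kind character(1), `"vertical"` (cation at the neutral geometry) or
#'   `"adiabatic"` (cation at its own geometry).
#' @slot values numeric, eV, one per retained frame.
#' @slot frameIndex integer, original indices of the retained frames.
#' @slot nSkipped integer(1), frames dropped for near-singular contacts.
#' @export
setClass("GapSeries",
  slots = c(label = "character", kind = "character", values = "numeric",
    frameIndex = "integer", nSkipped = "integer"))

setValidity("GapSeries", function(object) {
  msg <- character()
  if (!object@label %in% c("reduced", "oxidized"))
    msg <- c(msg, "label must be 'reduced' or 'oxidized'")
  if (!object@kind %in% c("vertical", "adiabatic"))
    msg <- c(msg, "kind must be 'vertical' or 'adiabatic'")
  if (length(object@values) != length(object@frameIndex))
    msg <- c(msg, "values and frameIndex must have equal length")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "gap values must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

GapSeries <- function(label, kind, values, frameIndex = seq_along(values),
                      nSkipped = 0L) {
  new("GapSeries", label = as.character(label), kind = as.character(kind),
    values = as.numeric(values), frameIndex = as.integer(frameIndex),
    nSkipped = as.integer(nSkipped))
}

#' RedoxEstimate: the thermodynamic summary of one redox couple
#'
#' @slot deltaA numeric(1), oxidation free energy, eV (mean-of-bounds
#'   estimator over the adiabatic gap averages of the two ensembles).
#' @slot vRed numeric(1), standard reduction potential, V vs SHE.
#' @slot vie,aie numeric(1), vertical / adiabatic ionization energies, eV.
#' @slot reorganization numeric(1), eV, half the difference of the two
#'   ensemble-averaged adiabatic gaps; non-negative for equilibrium sampling.
#' @slot errVie,errDeltaA,errVRed numeric(1), block-averaging standard errors.
#' @slot shiftApplied numeric(1), gas-phase correction added to vie, aie,
#'   deltaA and vRed (0 when no correction was requested).
#' @slot nFramesRed,nFramesOx,nSkippedRed,nSkippedOx integer(1) frame counts.
#' @slot ionicRelaxationAssumption character(1), fixed record that the ionic
#'   relaxation free energies of the two ensembles are assumed to cancel.
#' @export
setClass("RedoxEstimate",
  slots = c(deltaA = "numeric", vRed = "numeric", vie = "numeric",
    aie = "numeric", reorganization = "numeric", errVie = "numeric",
    errDeltaA = "numeric", errVRed = "numeric", shiftApplied = "numeric",
    nFramesRed = "integer", nFramesOx = "integer", nSkippedRed = "integer",
    nSkippedOx = "integer", ionicRelaxationAssumption = "character"))
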