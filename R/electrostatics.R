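## Bare Coulomb electrostatics of environment point charges, evaluated at QC
## locations.  Minimum-image periodic wrapping is applied per displacement when
## requested; there is no Ewald summation, cutoff or reaction field.  A
## configurable near-contact guard (dMin) turns unphysical overlaps between a
## probe point and an environment charge into a classed error
## ("pmmNearSingularity") instead of silently huge energies.

.env_displacements <- function(point, frame, usePbc) {
  ep <- frame@envPoints
  d <- cbind(point[1] - ep$x, point[2] - ep$y, point[3] - ep$z)
  if (usePbc) d <- minimumImage(d, frame@boxEdge)
  d
}

.check_dmin <- function(d2, dMin, frameIndex) {
  if (length(d2) && min(d2) < dMin^2) {
    w <- which.min(d2)
    cond <- structure(class = c("pmmNearSingularity", "error", "condition"),
      list(message = sprintf(paste("environment charge %d within d_min = %g nm",
        "of the probe point (distance %.4g nm, frame %s)"), w, dMin,
        sqrt(d2[w]), as.character(frameIndex)), call = NULL))
    stop(cond)
  }
}

#' Electrostatic potential of a frame's environment at a point
#'
#' Bare Coulomb sum `k_e * sum(q_k / r_k)` with `k_e = 1.439964 eV nm / e^2`;
#' with `usePbc = TRUE` every point-charge displacement is wrapped by the
#' minimum-image convention first.
#'
#' @param point length-3 position, nm.
#' @param frame a [Frame-class].
#' @param usePbc apply the minimum-image convention (default TRUE).
#' @param dMin near-contact guard distance, nm: an environment charge closer
#'   than this raises a `pmmNearSingularity` error.
#' @param frameIndex optional index reported in error messages.
#' @return Potential, V.
#' @examples
#' f <- Frame(10, matrix(0, 1, 3),
#'   data.frame(x = 1, y = 0, z = 0, charge = 1, group = "w1"))
#' potentialAt(c(0, 0, 0), f, usePbc = FALSE)  # 1.439964 V
#' @export
potentialAt <- function(point, frame, usePbc = TRUE, dMin = 0.05,
                        frameIndex = NA_integer_) {
  stopifnot(.is_vec3(point), is(frame, "Frame"))
  if (!nrow(frame@envPoints)) return(0)
  d <- .env_displacements(point, frame, usePbc)
  d2 <- rowSums(d * d)
  .check_dmin(d2, dMin, frameIndex)
  .KE * sum(frame@envPoints$charge / sqrt(d2))
}

#' Electric field of a frame's environment at a point
#'
#' `k_e * sum(q_k * (point - r_k) / |point - r_k|^3)`, the negative gradient
#' of [potentialAt()].
#'
#' @inheritParams potentialAt
#' @return Length-3 field, V/nm.
#' @export
fieldAt <- function(point, frame, usePbc = TRUE, dMin = 0.05,
                    frameIndex = NA_integer_) {
  stopifnot(.is_vec3(point), is(frame, "Frame"))
  if (!nrow(frame@envPoints)) return(c(0, 0, 0))
  d <- .env_displacements(point, frame, usePbc)
  d2 <- rowSums(d * d)
  .check_dmin(d2, dMin, frameIndex)
  w <- frame@envPoints$charge / (d2 * sqrt(d2))
  .KE * as.numeric(crossprod(d, w))
}

#' Sample the electrostatic perturbation for one frame
#'
#' Evaluates the environment potential at every QC atomic position of the
#' frame (inputs to the atom-based Hamiltonian diagonal) and the electric
#' field at the frame-instantaneous QC center of mass (input to the dipolar
#' off-diagonal coupling).  QC positions are taken from the frame; the state
#' set supplies only the atom count and masses.
#'
#' @param frame a [Frame-class].
#' @param stateset the [ElectronicStateSet-class] describing the QC.
#' @inheritParams potentialAt
#' @return A [PerturbationSample-class].
#' @export
samplePerturbation <- function(frame, stateset, usePbc = TRUE, dMin = 0.05,
                               frameIndex = NA_integer_) {
  stopifnot(is(frame, "Frame"), is(stateset, "ElectronicStateSet"))
  nqc <- nrow(frame@qcCoords)
  if (nqc != nAtoms(stateset))
    .stopf("frame has %d QC atoms but the state set declares %d", nqc,
      nAtoms(stateset))
  com <- centerOfMass(frame@qcCoords, masses = geometry(stateset)$mass)
  pot <- vapply(seq_len(nqc), function(i)
    potentialAt(frame@qcCoords[i, ], frame, usePbc = usePbc, dMin = dMin,
      frameIndex = frameIndex), numeric(1))
  fld <- fieldAt(com, frame, usePbc = usePbc, dMin = dMin,
    frameIndex = frameIndex)
  new("PerturbationSample", potentialsAtAtoms = pot, fieldAtCom = fld,
    com = com)
}
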