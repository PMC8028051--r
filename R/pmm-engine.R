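## Perturbed matrix method engine.  Per frame the perturbed electronic
## Hamiltonian of the quantum center is assembled in the basis of its
## unperturbed states and diagonalized:
##
##   H[i,i] = E_i + sum_N q_{N,i} * V(R_N)     (atom-based monopole diagonal)
##   H[i,j] = -E(r_0) . mu_ij   for i != j     (QC dipolar approximation)
##
## with V the environment potential at atom N's instantaneous position, E the
## environment field at the instantaneous center of mass r_0, q_{N,i} state
## i's partial charge on atom N and mu_ij the transition dipoles.  The
## perturbed ground state is the lowest eigenvalue per frame; no adiabatic
## state tracking is attempted across frames, but the minimum ground/first-
## excited separation is reported as a crossing diagnostic.

#' Build the perturbed electronic Hamiltonian for one frame
#'
#' @param sample a [PerturbationSample-class] for the frame.
#' @param stateset the quantum center's [ElectronicStateSet-class].
#' @return `nStates x nStates` real symmetric matrix, eV.
#' @examples
#' # with a zero perturbation the Hamiltonian is diag(state energies)
#' @export
buildHamiltonian <- function(sample, stateset) {
  stopifnot(is(sample, "PerturbationSample"), is(stateset, "ElectronicStateSet"))
  if (length(sample@potentialsAtAtoms) != nAtoms(stateset))
    .stopf("perturbation sample has %d potentials for %d QC atoms",
      length(sample@potentialsAtAtoms), nAtoms(stateset))
  ns <- nStates(stateset)
  H <- matrix(0, ns, ns)
  td <- stateset@transitionDipoles
  f <- sample@fieldAtCom
  ## off-diagonal: -E . mu_ij (the charge x potential term of the QC-based
  ## expansion is diagonal-only because the unperturbed states are orthonormal)
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (i != j)
    H[i, j] <- -sum(f * td[i, j, ])
  H <- (H + t(H)) / 2                      # exact symmetry by construction
  diag(H) <- stateset@energies +
    as.numeric(stateset@atomicCharges %*% sample@potentialsAtAtoms)
  H
}

#' Diagonalize a perturbed Hamiltonian
#'
#' Symmetric eigen-decomposition with a deterministic sign convention: for
#' every eigenvector the coefficient of largest magnitude (lowest index on
#' ties) is made positive.  The perturbed ground state is the lowest
#' eigenvalue.
#'
#' @param H real symmetric matrix, eV (asymmetry beyond 1e-10 eV is an error).
#' @param frameIndex optional originating frame index.
#' @return A [PerturbedState-class].
#' @examples
#' diagonalizePMM(diag(c(0, 5)))
#' @export
diagonalizePMM <- function(H, frameIndex = NA_integer_) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H) || max(abs(H - t(H))) > 1e-10)
    .stopf("diagonalizePMM: matrix is not symmetric within 1e-10 eV")
  es <- eigen(H, symmetric = TRUE)
  ord <- seq(ncol(H), 1L)                  # eigen() returns descending order
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    i_max <- which.max(abs(vecs[, k]))     # first index on ties
    if (vecs[i_max, k] < 0) vecs[, k] <- -vecs[, k]
  }
  g <- vecs[, 1L]
  new("PerturbedState", eigenvalues = vals, groundEnergy = vals[1L],
    groundVector = g / sqrt(sum(g^2)), frameIndex = as.integer(frameIndex))
}

.frame_ground <- function(frame, stateset, usePbc, dMin, frameIndex,
                          sample = NULL) {
  if (is.null(sample))
    sample <- samplePerturbation(frame, stateset, usePbc = usePbc,
      dMin = dMin, frameIndex = frameIndex)
  ps <- diagonalizePMM(buildHamiltonian(sample, stateset), frameIndex)
  list(ground = ps@groundEnergy,
    gap01 = if (length(ps@eigenvalues) > 1L)
      ps@eigenvalues[2L] - ps@eigenvalues[1L] else Inf)
}

#' Perturbed ground-state energy along an ensemble
#'
#' Maps build-and-diagonalize over every frame, preserving order.  Frames in
#' which an environment charge overlaps a QC probe point within `dMin` are
#' either skipped with a log message (`onClash = "skip"`, default) or turned
#' into a hard error (`onClash = "error"`).
#'
#' @param ensemble a [FrameEnsemble-class].
#' @param stateset the QC's [ElectronicStateSet-class].
#' @param usePbc apply the minimum-image convention.
#' @param dMin near-contact guard, nm.
#' @param onClash `"skip"` or `"error"`.
#' @return data.frame with columns `frame`, `energy` (eV) and `min_gap_01`
#'   (eV, ground/first-excited separation), one row per retained frame, plus
#'   attribute `skipped` (integer vector of dropped frame indices).
#' @export
groundEnergySeries <- function(ensemble, stateset, usePbc = TRUE, dMin = 0.05,
                               onClash = c("skip", "error")) {
  stopifnot(is(ensemble, "FrameEnsemble"))
  onClash <- match.arg(onClash)
  n <- nFrames(ensemble)
  energy <- gap01 <- rep(NA_real_, n)
  for (fi in seq_len(n)) {
    res <- tryCatch(
      .frame_ground(ensemble@frames[[fi]], stateset, usePbc, dMin, fi),
      pmmNearSingularity = function(e) {
        if (onClash == "error") stop(e)
        message("skipping frame ", fi, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) { energy[fi] <- res$ground; gap01[fi] <- res$gap01 }
  }
  keep <- which(!is.na(energy))
  if (!length(keep))
    .stopf("all %d frames were skipped for near-singular contacts", n)
  out <- data.frame(frame = keep, energy = energy[keep],
    min_gap_01 = gap01[keep])
  attr(out, "skipped") <- setdiff(seq_len(n), keep)
  out
}

#' Per-frame red -> ox perturbed ground-energy gaps in one ensemble
#'
#' For every frame the perturbed ground energies of the reduced species and of
#' the oxidized species (`kind = "vertical"`: cation states at the neutral
#' geometry; `kind = "adiabatic"`: cation states at the relaxed cation
#' geometry) are evaluated on the *same* configuration and subtracted.  A
#' frame skipped for either species is skipped for both, so the series stays
#' paired.
#'
#' @param ensemble a [FrameEnsemble-class] (reduced or oxidized).
#' @param pair a [RedoxSpeciesPair-class].
#' @param kind `"vertical"` or `"adiabatic"`.
#' @inheritParams groundEnergySeries
#' @return A [GapSeries-class].
#' @export
gapSeries <- function(ensemble, pair, kind = c("vertical", "adiabatic"),
                      usePbc = TRUE, dMin = 0.05,
                      onClash = c("skip", "error")) {
  stopifnot(is(ensemble, "FrameEnsemble"), is(pair, "RedoxSpeciesPair"))
  kind <- match.arg(kind)
  onClash <- match.arg(onClash)
  ox <- if (kind == "vertical") pair@oxVertical else pair@oxAdiabatic
  red <- pair@red
  n <- nFrames(ensemble)
  vals <- rep(NA_real_, n)
  for (fi in seq_len(n)) {
    res <- tryCatch({
      ## red and ox share atom count and masses, so one perturbation sample
      ## (potentials at frame positions, field at frame COM) serves both
      smp <- samplePerturbation(ensemble@frames[[fi]], red, usePbc = usePbc,
        dMin = dMin, frameIndex = fi)
      e_red <- .frame_ground(ensemble@frames[[fi]], red, usePbc, dMin, fi,
        sample = smp)$ground
      e_ox <- .frame_ground(ensemble@frames[[fi]], ox, usePbc, dMin, fi,
        sample = smp)$ground
      e_ox - e_red
    }, pmmNearSingularity = function(e) {
      if (onClash == "error") stop(e)
      message("skipping frame ", fi, ": ", conditionMessage(e))
      NA_real_
    })
    vals[fi] <- res
  }
  keep <- which(!is.na(vals))
  if (!length(keep))
    .stopf("all %d frames were skipped for near-singular contacts", n)
  GapSeries(ensembleLabel(ensemble), kind, vals[keep], keep,
    nSkipped = n - length(keep))
}

#' Write a per-frame energy table as CSV
#'
#' Columns: `frame_index`, `E0_red`, `E0_ox`, `gap_eV`, `min_gap_01_eV`,
#' `skipped_flag`.
#'
#' @param ensemble,pair,kind,usePbc,dMin as in [gapSeries()].
#' @param path output CSV path.
#' @return The table, invisibly.
#' @export
writeFrameTable <- function(ensemble, pair, path,
                            kind = c("vertical", "adiabatic"), usePbc = TRUE,
                            dMin = 0.05) {
  kind <- match.arg(kind)
  ox <- if (kind == "vertical") pair@oxVertical else pair@oxAdiabatic
  red_s <- groundEnergySeries(ensemble, pair@red, usePbc, dMin, "skip")
  ox_s <- groundEnergySeries(ensemble, ox, usePbc, dMin, "skip")
  keep <- intersect(red_s$frame, ox_s$frame)
  n <- nFrames(ensemble)
  tab <- data.frame(frame_index = seq_len(n),
    E0_red = NA_real_, E0_ox = NA_real_, gap_eV = NA_real_,
    min_gap_01_eV = NA_real_, skipped_flag = !(seq_len(n) %in% keep))
  tab$E0_red[red_s$frame] <- red_s$energy
  tab$E0_ox[ox_s$frame] <- ox_s$energy
  tab$gap_eV <- tab$E0_ox - tab$E0_red
  tab$min_gap_01_eV[red_s$frame] <- red_s$min_gap_01
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
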