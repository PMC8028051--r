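## Redox thermodynamics from energy-gap ensembles.
##
## The oxidation free energy is estimated by the linear-response mean-of-
## bounds formula dA = (<dE>_red + <dE>_ox) / 2, where <dE> is the ensemble
## average of the perturbed ground-state energy change upon oxidation
## (adiabatic kind) evaluated in the reduced and in the oxidized ensemble.
## The two averages are rigorous upper and lower bounds of dA when the ionic
## relaxation free energies of the two ensembles cancel; their midpoint is
## exact for Gaussian gap statistics of equal variance.  The VIE is the
## average *vertical* gap in the reduced ensemble only.  Statistical errors
## come from block averaging over three contiguous sub-trajectories.

#' Vertical ionization energy from a gap series
#'
#' The ensemble average, in the reduced ensemble, of the per-frame vertical
#' oxidized-minus-reduced perturbed ground-state energy.
#'
#' @param gaps a [GapSeries-class] with `label = "reduced"` and
#'   `kind = "vertical"`; anything else is an error.
#' @return VIE, eV.
#' @export
verticalIonizationEnergy <- function(gaps) {
  stopifnot(is(gaps, "GapSeries"))
  if (gaps@label != "reduced" || gaps@kind != "vertical")
    .stopf("VIE requires vertical gaps from the reduced ensemble (got %s/%s)",
      gaps@label, gaps@kind)
  mean(gaps@values)
}

#' Adiabatic ionization energy from a gap series
#'
#' The ensemble average, in the reduced ensemble, of the adiabatic gap (cation
#' states at the relaxed cation geometry).
#'
#' @param gaps a [GapSeries-class] with `label = "reduced"`,
#'   `kind = "adiabatic"`.
#' @return AIE, eV.
#' @export
adiabaticIonizationEnergy <- function(gaps) {
  stopifnot(is(gaps, "GapSeries"))
  if (gaps@label != "reduced" || gaps@kind != "adiabatic")
    .stopf("AIE requires adiabatic gaps from the reduced ensemble (got %s/%s)",
      gaps@label, gaps@kind)
  mean(gaps@values)
}

#' Ensemble-averaged gaps of the two redox ensembles
#'
#' @param redGaps adiabatic (or vertical) [GapSeries-class] from the reduced
#'   ensemble.
#' @param oxGaps matching-kind [GapSeries-class] from the oxidized ensemble.
#' @return List with `mean_gap_red`, `mean_gap_ox` (eV), `kind`,
#'   `n_frames_red`, `n_frames_ox`.
#' @export
ensembleAverages <- function(redGaps, oxGaps) {
  stopifnot(is(redGaps, "GapSeries"), is(oxGaps, "GapSeries"))
  if (redGaps@label != "reduced" || oxGaps@label != "oxidized")
    .stopf("need one reduced-ensemble and one oxidized-ensemble gap series")
  if (redGaps@kind != oxGaps@kind)
    .stopf("gap kinds differ: %s vs %s", redGaps@kind, oxGaps@kind)
  list(mean_gap_red = mean(redGaps@values), mean_gap_ox = mean(oxGaps@values),
    kind = redGaps@kind, n_frames_red = length(redGaps@values),
    n_frames_ox = length(oxGaps@values))
}

#' Oxidation free energy: mean-of-bounds (linear-response) estimator
#'
#' `dA = (mean_gap_red + mean_gap_ox) / 2` over adiabatic gaps; the two
#' ensemble averages bound dA from above and below once the ionic relaxation
#' free energies of the two ensembles are assumed to cancel, and the midpoint
#' is exact for equal-variance Gaussian gap statistics.
#'
#' @param avg result of [ensembleAverages()]; must have `kind = "adiabatic"`
#'   (mixing kinds is refused).
#' @return Oxidation free energy dA, eV.
#' @export
oxidationFreeEnergy <- function(avg) {
  if (!identical(avg$kind, "adiabatic"))
    .stopf("oxidation free energy is defined on adiabatic gaps (got '%s')",
      avg$kind)
  (avg$mean_gap_red + avg$mean_gap_ox) / 2
}

#' Reorganization energy: half the gap-average difference
#'
#' Non-negative for equilibrium-sampled ensembles; a negative value beyond
#' `tol` triggers a warning (not an error) as a sampling diagnostic.
#'
#' @param avg result of [ensembleAverages()].
#' @param tol diagnostic tolerance, eV.
#' @return Reorganization energy, eV.
#' @export
reorganizationEnergy <- function(avg, tol = 1e-9) {
  lambda <- (avg$mean_gap_red - avg$mean_gap_ox) / 2
  if (lambda < -tol)
    warning(sprintf(paste("negative reorganization energy (%.4g eV):",
      "ensembles may not be equilibrium-sampled"), lambda), call. = FALSE)
  lambda
}

#' Standard reduction potential from the oxidation free energy
#'
#' `V_red = dA / n - V_SHE`.  With dA the per-molecule oxidation free energy
#' in eV and n the number of electrons, dA/n in eV is numerically the
#' potential in V (the Faraday constant cancels in these units); subtracting
#' the absolute standard-hydrogen-electrode potential places the result on
#' the SHE scale.  A larger oxidation free energy (harder to oxidize) gives a
#' larger reduction potential.
#'
#' @param deltaA oxidation free energy per molecule, eV.
#' @param nElectrons number of electrons transferred (>= 1).
#' @param vShe absolute SHE potential, V (default 4.281).
#' @return Reduction potential, V vs SHE.
#' @examples
#' reductionPotential(5.331)  # 1.05 V
#' @export
reductionPotential <- function(deltaA, nElectrons = 1L, vShe = .VSHE) {
  if (!.is_number(deltaA)) .stopf("deltaA must be a single finite number")
  if (!.is_number(nElectrons) || nElectrons < 1 ||
      nElectrons != round(nElectrons))
    .stopf("nElectrons must be an integer >= 1")
  deltaA / nElectrons - vShe
}

#' Gas-phase shift correction of an aqueous calculated energy
#'
#' Adds the discrepancy between the experimental and calculated gas-phase
#' (unperturbed) values to the corresponding aqueous calculated value:
#' `value + (gasExp - gasCalc)`.  Used to correct aqueous VIEs and, via the
#' same unperturbed shift, reduction free energies.
#'
#' @param valueAqCalc aqueous calculated value, eV.
#' @param gasCalc,gasExp gas-phase calculated and experimental values, eV.
#' @return Corrected value, eV.
#' @examples
#' gasShiftCorrection(7.66, 7.92, 8.24)  # 7.98
#' @export
gasShiftCorrection <- function(valueAqCalc, gasCalc, gasExp) {
  stopifnot(.is_number(valueAqCalc), .is_number(gasCalc), .is_number(gasExp))
  valueAqCalc + (gasExp - gasCalc)
}

#' Block-averaging standard error of a series mean
#'
#' Splits the series into `nBlocks` contiguous blocks of equal length
#' (remainder values at the end are dropped), takes the block means and
#' returns their sample standard deviation divided by `sqrt(nBlocks)` -- the
#' standard error of the mean over quasi-independent sub-trajectories.
#'
#' @param series numeric vector (or a [GapSeries-class]).
#' @param nBlocks number of contiguous blocks (default 3).
#' @return Standard error estimate.
#' @examples
#' blockError(rep(c(1, 2, 3), each = 10))  # sd(1,2,3)/sqrt(3)
#' @export
blockError <- function(series, nBlocks = 3L) {
  if (is(series, "GapSeries")) series <- series@values
  n <- length(series)
  if (!.is_number(nBlocks) || nBlocks < 2L)
    .stopf("nBlocks must be an integer >= 2")
  if (n < nBlocks)
    .stopf("series of length %d is shorter than %d blocks", n, nBlocks)
  len <- n %/% nBlocks
  bm <- vapply(seq_len(nBlocks), function(b)
    mean(series[((b - 1L) * len + 1L):(b * len)]), numeric(1))
  stats::sd(bm) / sqrt(nBlocks)
}

## ---------------------------------------------------------------------------
## solvent truncation convergence scan
## ---------------------------------------------------------------------------

.truncate_frame <- function(frame, nRemove, com, usePbc) {
  ep <- frame@envPoints
  if (!nRemove) return(frame)
  gids <- unique(ep$group)
  if (nRemove > length(gids))
    .stopf("cannot remove %d of %d environment groups", nRemove, length(gids))
  ## group centers = unweighted means of the group's sites
  cx <- tapply(ep$x, ep$group, mean)[gids]
  cy <- tapply(ep$y, ep$group, mean)[gids]
  cz <- tapply(ep$z, ep$group, mean)[gids]
  d <- cbind(cx - com[1], cy - com[2], cz - com[3])
  if (usePbc) d <- minimumImage(d, frame@boxEdge)
  dist <- sqrt(rowSums(d * d))
  drop_ids <- gids[order(-dist, gids)][seq_len(nRemove)]
  Frame(frame@boxEdge, frame@qcCoords, ep[!(ep$group %in% drop_ids), ])
}

#' Solvent-truncation convergence scan of the VIE
#'
#' For each requested removal level the `nRemove` solvent charge groups whose
#' centers lie farthest from the instantaneous QC center of mass are removed
#' frame by frame, the vertical gaps are recomputed on the truncated frames,
#' and the per-frame differences against the all-solvent reference are
#' summarized.  Removing more of the environment perturbs the gaps more, so
#' the difference distribution widens with the removal level -- the classic
#' convergence-with-system-size diagnostic.
#'
#' @param ensemble a reduced-ensemble [FrameEnsemble-class].
#' @param pair a [RedoxSpeciesPair-class].
#' @param removeCounts integer vector of group-removal levels (0 = reference).
#' @param usePbc,dMin as in [gapSeries()].
#' @return data.frame with one row per level: `removed`, `retained`, `vie`
#'   (eV), `mean_diff`, `sd_diff`, `max_abs_diff` (eV vs the all-solvent
#'   reference), plus attribute `differences` (frames x levels matrix).
#' @export
solventTruncationScan <- function(ensemble, pair, removeCounts,
                                  usePbc = TRUE, dMin = 0.05) {
  stopifnot(is(ensemble, "FrameEnsemble"), is(pair, "RedoxSpeciesPair"))
  removeCounts <- sort(unique(as.integer(removeCounts)))
  n <- nFrames(ensemble)
  red <- pair@red; ox <- pair@oxVertical
  n_groups <- length(unique(ensemble@frames[[1L]]@envPoints$group))
  if (any(removeCounts > n_groups))
    .stopf("requested removal of %d groups exceeds the %d available",
      max(removeCounts), n_groups)

  gap_one <- function(frame, fi) {
    smp <- samplePerturbation(frame, red, usePbc = usePbc, dMin = dMin,
      frameIndex = fi)
    diagonalizePMM(buildHamiltonian(smp, ox), fi)@groundEnergy -
      diagonalizePMM(buildHamiltonian(smp, red), fi)@groundEnergy
  }

  gaps <- matrix(NA_real_, n, length(removeCounts))
  for (fi in seq_len(n)) {
    fr <- ensemble@frames[[fi]]
    com <- centerOfMass(fr@qcCoords, masses = geometry(red)$mass)
    for (li in seq_along(removeCounts))
      gaps[fi, li] <- gap_one(
        .truncate_frame(fr, removeCounts[li], com, usePbc), fi)
  }
  ref <- if (0L %in% removeCounts) gaps[, which(removeCounts == 0L)]
    else vapply(seq_len(n), function(fi)
      gap_one(ensemble@frames[[fi]], fi), numeric(1))
  diffs <- gaps - ref
  out <- data.frame(removed = removeCounts,
    retained = n_groups - removeCounts,
    vie = colMeans(gaps),
    mean_diff = colMeans(diffs),
    sd_diff = apply(diffs, 2L, stats::sd),
    max_abs_diff = apply(abs(diffs), 2L, max))
  attr(out, "differences") <- diffs
  out
}

## ---------------------------------------------------------------------------
## full estimate
## ---------------------------------------------------------------------------

#' Full redox estimate from two frame ensembles
#'
#' Runs the perturbed-matrix engine over the reduced and oxidized ensembles
#' and assembles VIE, AIE, the mean-of-bounds oxidation free energy, the
#' reduction potential vs SHE, block-averaged errors, and the (optional)
#' gas-phase shift correction into a [RedoxEstimate-class].
#'
#' The ionic relaxation free energies of the two ensembles are assumed to
#' cancel (recorded in the result); the V_SHE reference is treated as exact
#' in the error propagation, so `errVRed = errDeltaA / nElectrons`.
#'
#' @param redEnsemble,oxEnsemble reduced/oxidized [FrameEnsemble-class]s.
#' @param pair a [RedoxSpeciesPair-class].
#' @param nElectrons electrons transferred (default 1).
#' @param vShe absolute SHE potential, V.
#' @param applyGasShift add `gasVieExp - gasVieCalc` from `pair` to the
#'   reported energies and potential (requires both values finite).
#' @param nBlocks blocks for the error estimate.
#' @inheritParams gapSeries
#' @return A [RedoxEstimate-class].
#' @export
estimateRedox <- function(redEnsemble, oxEnsemble, pair, nElectrons = 1L,
                          vShe = .VSHE, applyGasShift = FALSE, nBlocks = 3L,
                          usePbc = TRUE, dMin = 0.05,
                          onClash = c("skip", "error")) {
  onClash <- match.arg(onClash)
  g_vert <- gapSeries(redEnsemble, pair, "vertical", usePbc, dMin, onClash)
  g_ad_r <- gapSeries(redEnsemble, pair, "adiabatic", usePbc, dMin, onClash)
  g_ad_o <- gapSeries(oxEnsemble, pair, "adiabatic", usePbc, dMin, onClash)

  vie <- verticalIonizationEnergy(g_vert)
  aie <- adiabaticIonizationEnergy(g_ad_r)
  avg <- ensembleAverages(g_ad_r, g_ad_o)
  dA <- oxidationFreeEnergy(avg)
  lambda <- reorganizationEnergy(avg)

  err_vie <- blockError(g_vert, nBlocks)
  err_dA <- sqrt(blockError(g_ad_r, nBlocks)^2 +
                 blockError(g_ad_o, nBlocks)^2) / 2

  shift <- 0
  if (applyGasShift) {
    if (!is.finite(pair@gasVieCalc) || !is.finite(pair@gasVieExp))
      .stopf("gas-shift correction requested but pair lacks gas VIE values")
    shift <- pair@gasVieExp - pair@gasVieCalc
  }
  vred <- reductionPotential(dA + shift, nElectrons, vShe)

  new("RedoxEstimate",
    deltaA = dA + shift, vRed = vred, vie = vie + shift, aie = aie + shift,
    reorganization = lambda, errVie = err_vie, errDeltaA = err_dA,
    errVRed = err_dA / nElectrons, shiftApplied = shift,
    nFramesRed = length(g_ad_r@values), nFramesOx = length(g_ad_o@values),
    nSkippedRed = g_ad_r@nSkipped, nSkippedOx = g_ad_o@nSkipped,
    ionicRelaxationAssumption =
      "ionic relaxation free energies of the two ensembles assumed equal")
}
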