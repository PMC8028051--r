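## Synthetic inputs for the whole pipeline: rigid three-site water-like
## solvent boxes (iid or Metropolis-sampled point-charge ensembles), fully
## synthetic redox species pairs with known unperturbed gaps, and Gaussian
## gap series with an analytic free energy.  Everything is reproducible from
## an integer seed.
##
## The default solvent emulates the reference simulation conditions: a cubic
## box of 3.1 nm side with ~1050 three-site water-like groups (SPC charges
## -0.82 / +0.41 / +0.41 e, O-H 0.1 nm, H-O-H 109.47 deg) at 300 K.

.WATER_SITES <- local({
  a <- 109.47 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
    H1 = 0.1 * c(cos(a), sin(a), 0),
    H2 = 0.1 * c(cos(a), -sin(a), 0))
})
.WATER_CHARGES <- c(-0.82, 0.41, 0.41)
## intergroup hard-core distances, nm, indexed [site_i, site_j] with 1 = O,
## 2:3 = H; the O-H core is set so the closest-contact pair energy is
## hydrogen-bond-like (~ -0.25 eV) rather than divergent
.CORE <- matrix(c(0.26, 0.19, 0.19,
                  0.19, 0.15, 0.15,
                  0.19, 0.15, 0.15), 3, 3, byrow = TRUE)

#' Specification of a synthetic solvent box
#'
#' @param nGroups number of rigid charge groups (default 1050).
#' @param boxEdge cubic box side, nm (default 3.1).
#' @param temperature K (default 300).
#' @param exclusionRadius nm; solvent oxygens are kept at least this far from
#'   every QC atom (default 0.3).
#' @param siteCharges length-3 site charges (O, H, H), e; must sum to 0.
#' @param seed integer random seed.
#' @return A validated list of class `"SolventSpec"`.
#' @export
solventSpec <- function(nGroups = 1050L, boxEdge = 3.1, temperature = 300,
                        exclusionRadius = 0.3,
                        siteCharges = .WATER_CHARGES, seed = 1L) {
  if (nGroups < 0L) .stopf("nGroups must be >= 0")
  if (boxEdge <= 0) .stopf("boxEdge must be positive")
  if (abs(sum(siteCharges)) > 1e-9)
    .stopf("solvent group charges must sum to 0 (got %g)", sum(siteCharges))
  if (exclusionRadius >= boxEdge / 2)
    .stopf("exclusion sphere (radius %g nm) does not fit in a %g nm box",
      exclusionRadius, boxEdge)
  structure(list(nGroups = as.integer(nGroups), boxEdge = boxEdge,
    temperature = temperature, exclusionRadius = exclusionRadius,
    siteCharges = as.numeric(siteCharges), seed = as.integer(seed)),
    class = "SolventSpec")
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

## place group oxygens uniformly, rejecting inside the QC exclusion sphere
.place_oxygens <- function(spec, qc) {
  n <- spec$nGroups
  if (!n) return(matrix(numeric(), 0L, 3L))
  out <- matrix(NA_real_, n, 3L)
  have <- 0L
  tries <- 0L
  while (have < n) {
    tries <- tries + 1L
    if (tries > 1000L) .stopf("cannot place %d groups outside the exclusion sphere", n)
    m <- max(2L * (n - have), 16L)
    cand <- matrix(stats::runif(3L * m, 0, spec$boxEdge), m, 3L)
    ok <- rep(TRUE, m)
    if (nrow(qc)) {
      for (i in seq_len(nrow(qc))) {
        d <- minimumImage(cand - matrix(qc[i, ], m, 3L, byrow = TRUE),
          spec$boxEdge)
        ok <- ok & rowSums(d * d) > spec$exclusionRadius^2
      }
    }
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), n - have)
    if (take) out[(have + 1L):(have + take), ] <- cand[seq_len(take), ]
    have <- have + take
  }
  out
}

## sites array helpers: sites is a (3*nGroups) x 3 matrix, group g occupying
## rows 3g-2 .. 3g with site types O, H, H
.build_sites <- function(oxy) {
  n <- nrow(oxy)
  sites <- matrix(NA_real_, 3L * n, 3L)
  for (g in seq_len(n)) {
    R <- .random_rotation()
    sites[(3L * g - 2L):(3L * g), ] <-
      .WATER_SITES %*% t(R) + matrix(oxy[g, ], 3L, 3L, byrow = TRUE)
  }
  sites
}

.sites_frame <- function(sites, spec, qc) {
  n <- nrow(sites) %/% 3L
  env <- if (n) data.frame(
    x = sites[, 1L], y = sites[, 2L], z = sites[, 3L],
    charge = rep(spec$siteCharges, n),
    group = rep(sprintf("w%d", seq_len(n)), each = 3L))
  else emptyEnv()
  Frame(spec$boxEdge, qc, env)
}

## Coulomb energy of group g's 3 sites against all other solvent sites and
## the QC charges, with minimum-image wrapping; Inf on hard-core overlap or
## oxygen inside the QC exclusion sphere
.group_energy <- function(g, sites, spec, qc, qcCharges) {
  idx <- (3L * g - 2L):(3L * g)
  own <- sites[idx, , drop = FALSE]
  L <- spec$boxEdge
  n_other <- nrow(sites) - 3L
  e <- 0
  if (n_other > 0L) {
    other <- sites[-idx, , drop = FALSE]
    type_o <- rep(1:3, nrow(other) %/% 3L)
    q_o <- rep(spec$siteCharges, nrow(other) %/% 3L)
    for (s in 1:3) {
      d <- minimumImage(other - matrix(own[s, ], nrow(other), 3L,
        byrow = TRUE), L)
      dist <- sqrt(rowSums(d * d))
      if (any(dist < .CORE[s, type_o])) return(Inf)
      e <- e + .KE * spec$siteCharges[s] * sum(q_o / dist)
    }
  }
  if (nrow(qc)) {
    dO <- minimumImage(qc - matrix(own[1L, ], nrow(qc), 3L, byrow = TRUE), L)
    if (any(rowSums(dO * dO) < spec$exclusionRadius^2)) return(Inf)
    for (s in 1:3) {
      d <- minimumImage(qc - matrix(own[s, ], nrow(qc), 3L, byrow = TRUE), L)
      dist <- sqrt(rowSums(d * d))
      if (any(dist < 0.5 * spec$exclusionRadius)) return(Inf)
      e <- e + .KE * spec$siteCharges[s] * sum(qcCharges / dist)
    }
  }
  e
}

## solvent-QC interaction energy of a whole configuration (diagnostic)
.solvent_qc_energy <- function(sites, spec, qc, qcCharges) {
  if (!nrow(sites) || !nrow(qc)) return(0)
  q_s <- rep(spec$siteCharges, nrow(sites) %/% 3L)
  e <- 0
  for (i in seq_len(nrow(qc))) {
    d <- minimumImage(sites - matrix(qc[i, ], nrow(sites), 3L, byrow = TRUE),
      spec$boxEdge)
    e <- e + .KE * qcCharges[i] * sum(q_s / sqrt(rowSums(d * d)))
  }
  e
}

#' Generate a synthetic solvent-frame ensemble
#'
#' Two sampling modes around a fixed quantum center placed at the box center:
#'
#' * `"iid"`: every frame draws all groups independently -- uniform positions
#'   (rejected inside the QC exclusion sphere) and uniform orientations.
#'   Fast, with no configurational correlation to the QC charge state.
#' * `"metropolis"`: single-group translation+rotation proposals accepted by
#'   the Boltzmann criterion at the spec temperature, with point-charge
#'   Coulomb energy (solvent-solvent plus solvent-QC using the supplied
#'   per-atom QC charges) and site-type hard cores.  Frames are recorded
#'   every `stride` attempted moves after `burnin` moves.  This produces
#'   *distinct, physically responsive* reduced and oxidized ensembles -- the
#'   structure the mean-of-bounds free-energy estimator needs.
#'
#' @param spec a [solventSpec()].
#' @param qcGeometry data.frame with columns `x`, `y`, `z` (nm) -- typically
#'   `geometry(stateset)`; its centroid is moved to the box center.
#' @param nFrames number of frames to record.
#' @param mode `"iid"` or `"metropolis"`.
#' @param qcStateCharges per-QC-atom charges, e, defining the sampling charge
#'   state (required for `"metropolis"`; the ground-state row of
#'   [atomicCharges()]).
#' @param label ensemble label (`"reduced"` or `"oxidized"`).
#' @param burnin,stride Metropolis schedule in attempted moves; defaults
#'   `200 * nGroups` and `10 * nGroups`.
#' @param trStep,rotStep proposal widths: translation sd (nm) and rotation-
#'   angle sd (radians).
#' @return A [FrameEnsemble-class]; for Metropolis runs the attributes
#'   `acceptanceRate` and `solventQcEnergy` (per-frame diagnostic, eV) are
#'   attached.
#' @export
generateSolventFrames <- function(spec, qcGeometry, nFrames,
                                  mode = c("iid", "metropolis"),
                                  qcStateCharges = NULL, label = "reduced",
                                  burnin = NULL, stride = NULL,
                                  trStep = 0.012, rotStep = 0.35) {
  stopifnot(inherits(spec, "SolventSpec"))
  mode <- match.arg(mode)
  qc <- as.matrix(qcGeometry[, c("x", "y", "z")])
  ## center the QC in the box
  qc <- qc - matrix(colMeans(qc), nrow(qc), 3L, byrow = TRUE) +
    matrix(spec$boxEdge / 2, nrow(qc), 3L)
  set.seed(spec$seed)

  if (mode == "iid") {
    frames <- lapply(seq_len(nFrames), function(i)
      .sites_frame(.build_sites(.place_oxygens(spec, qc)), spec, qc))
    return(FrameEnsemble(label, frames, temperature = spec$temperature,
      chargeMapId = sprintf("synthetic-iid-seed%d", spec$seed)))
  }

  if (is.null(qcStateCharges))
    .stopf("metropolis mode needs qcStateCharges (the sampling charge state)")
  if (length(qcStateCharges) != nrow(qc))
    .stopf("qcStateCharges length %d does not match %d QC atoms",
      length(qcStateCharges), nrow(qc))
  n <- spec$nGroups
  if (is.null(burnin)) burnin <- 200L * max(n, 1L)
  if (is.null(stride)) stride <- 10L * max(n, 1L)
  beta <- 1 / (.KB * spec$temperature)

  ## start from a non-overlapping iid placement
  sites <- .build_sites(.place_oxygens(spec, qc))
  if (n) {
    one <- spec
    one$nGroups <- 1L
    for (g in seq_len(n)) {
      k <- 0L
      idx <- (3L * g - 2L):(3L * g)
      while (is.infinite(.group_energy(g, sites, spec, qc, qcStateCharges))) {
        sites[idx, ] <- .build_sites(.place_oxygens(one, qc))
        k <- k + 1L
        if (k > 500L) .stopf("infeasible initial packing for group %d", g)
      }
    }
  }

  frames <- vector("list", nFrames)
  e_qc <- numeric(nFrames)
  accepted <- 0L
  attempted <- 0L
  total_moves <- burnin + nFrames * stride
  next_record <- burnin + stride
  rec <- 0L
  move <- 0L
  while (rec < nFrames) {
    move <- move + 1L
    if (n) {
      g <- sample.int(n, 1L)
      idx <- (3L * g - 2L):(3L * g)
      old <- sites[idx, , drop = FALSE]
      e_old <- .group_energy(g, sites, spec, qc, qcStateCharges)
      shift <- stats::rnorm(3L, 0, trStep)
      R <- .small_rotation(rotStep)
      O <- old[1L, ]
      prop <- (old - matrix(O, 3L, 3L, byrow = TRUE)) %*% t(R) +
        matrix(O + shift, 3L, 3L, byrow = TRUE)
      ## wrap the oxygen back into the primary box, rigidly
      wrapO <- prop[1L, ] - (prop[1L, ] %% spec$boxEdge)
      prop <- prop - matrix(wrapO, 3L, 3L, byrow = TRUE)
      sites[idx, ] <- prop
      e_new <- .group_energy(g, sites, spec, qc, qcStateCharges)
      attempted <- attempted + 1L
      if (is.infinite(e_new) ||
          (e_new > e_old && stats::runif(1) > exp(-beta * (e_new - e_old)))) {
        sites[idx, ] <- old            # reject
      } else accepted <- accepted + 1L
    }
    if (move >= next_record) {
      rec <- rec + 1L
      frames[[rec]] <- .sites_frame(sites, spec, qc)
      e_qc[rec] <- .solvent_qc_energy(sites, spec, qc, qcStateCharges)
      next_record <- next_record + stride
    }
    if (move > total_moves + stride) break
  }
  ens <- FrameEnsemble(label, frames, temperature = spec$temperature,
    chargeMapId = sprintf("synthetic-metropolis-seed%d", spec$seed))
  attr(ens, "acceptanceRate") <- if (attempted) accepted / attempted else NA
  attr(ens, "solventQcEnergy") <- e_qc
  ens
}

.small_rotation <- function(rotStep) {
  axis <- stats::rnorm(3L)
  axis <- axis / sqrt(sum(axis^2))
  th <- stats::rnorm(1L, 0, rotStep)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
    -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Build a synthetic redox species pair with known unperturbed answers
#'
#' Fabricates a valid [RedoxSpeciesPair-class]: random compact geometry,
#' per-state charges normalized to the exact total charge, symmetric
#' transition dipoles, an unperturbed vertical gap of exactly `gap0`, and a
#' cation adiabatic surface sitting exactly `relaxation` below the vertical
#' one.  The `dipoleShift` knob (default 1.8 debye) increases the cation
#' ground-state permanent dipole relative to the neutral's along the neutral
#' dipole direction -- the mechanism by which polar solvents differentially
#' stabilize a radical cation.
#'
#' @param nAtoms atoms in the quantum center (default 12).
#' @param nStates electronic states per species (default 7: ground + six
#'   excited).
#' @param dipoleShift cation-minus-neutral ground-state dipole increase,
#'   e nm (default 1.8 D = 0.0374749 e nm).
#' @param gap0 unperturbed vertical ionization energy, eV (default 8.97).
#' @param relaxation cation geometry relaxation energy, eV (>= 0); the
#'   unperturbed AIE is `gap0 - relaxation`.
#' @param seed integer seed.
#' @param distortion sd (nm) of the random displacement applied to the cation
#'   adiabatic geometry; with the default 0 the adiabatic state set shares the
#'   vertical geometry/charges/dipoles, which guarantees VIE >= AIE frame by
#'   frame.
#' @param gasVieExp optional experimental gas-phase VIE, eV, stored for the
#'   shift correction (`gasVieCalc` is `gap0` by construction).
#' @return A validated [RedoxSpeciesPair-class].
#' @export
makeSyntheticPair <- function(nAtoms = 12L, nStates = 7L,
                              dipoleShift = 1.8 * .DEBYE, gap0 = 8.97,
                              relaxation = 0.3, seed = 1L, distortion = 0,
                              gasVieExp = NA_real_) {
  if (nStates < 1L) .stopf("nStates must be >= 1")
  if (relaxation < 0) .stopf("relaxation must be >= 0")
  if (nAtoms < 1L) .stopf("nAtoms must be >= 1")
  set.seed(seed)
  masses <- sample(c(12.011, 14.007, 15.999, 1.008), nAtoms, replace = TRUE)
  geom <- data.frame(atom = sprintf("X%d", seq_len(nAtoms)), mass = masses,
    x = stats::runif(nAtoms, -0.15, 0.15),
    y = stats::runif(nAtoms, -0.15, 0.15),
    z = stats::runif(nAtoms, -0.15, 0.15))

  state_energies <- function(e0) {
    if (nStates == 1L) return(e0)
    c(e0, e0 + 4 + cumsum(stats::runif(nStates - 1L, 0.3, 0.8)))
  }
  charges_for <- function(Q) {
    t(vapply(seq_len(nStates), function(i) {
      raw <- stats::rnorm(nAtoms, 0, 0.2)
      raw - mean(raw) + Q / nAtoms
    }, numeric(nAtoms)))
  }
  dipoles_for <- function(mu0) {
    td <- array(0, c(nStates, nStates, 3L))
    for (i in seq_len(nStates)) {
      td[i, i, ] <- mu0 + if (i > 1L) stats::rnorm(3L, 0, 0.01) else 0
      if (i < nStates) for (j in (i + 1L):nStates) {
        v <- stats::rnorm(3L, 0, 0.015)
        td[i, j, ] <- v; td[j, i, ] <- v
      }
    }
    td
  }

  dir0 <- stats::rnorm(3L); dir0 <- dir0 / sqrt(sum(dir0^2))
  mu_red <- 0.13 * dir0                       # ~6 D neutral ground dipole
  mu_ox <- mu_red + dipoleShift * dir0

  red <- ElectronicStateSet("synthetic-red", 0L, geom, state_energies(0),
    charges_for(0), dipoles_for(mu_red))
  oxv <- ElectronicStateSet("synthetic-ox-vertical", 1L, geom,
    state_energies(gap0), charges_for(1), dipoles_for(mu_ox))
  geom_ad <- geom
  if (distortion > 0) {
    geom_ad$x <- geom_ad$x + stats::rnorm(nAtoms, 0, distortion)
    geom_ad$y <- geom_ad$y + stats::rnorm(nAtoms, 0, distortion)
    geom_ad$z <- geom_ad$z + stats::rnorm(nAtoms, 0, distortion)
    oxa <- ElectronicStateSet("synthetic-ox-adiabatic", 1L, geom_ad,
      stateEnergies(oxv) - relaxation, charges_for(1), dipoles_for(mu_ox))
  } else {
    oxa <- ElectronicStateSet("synthetic-ox-adiabatic", 1L, geom,
      stateEnergies(oxv) - relaxation, atomicCharges(oxv),
      transitionDipoles(oxv))
  }
  RedoxSpeciesPair(red, oxv, oxa, gasVieCalc = gap0, gasVieExp = gasVieExp)
}

#' Seeded Gaussian gap series with a known free energy
#'
#' Draws equal-variance Gaussian gap samples for the two ensembles.  Under
#' equal variance the mean-of-bounds estimator is exact and the analytic free
#' energy is `(meanRed + meanOx) / 2`, returned alongside the series.
#'
#' @param meanRed,meanOx ensemble gap means, eV.
#' @param sigma common standard deviation, eV (> 0).
#' @param nSamples samples per ensemble (>= 2).
#' @param seed integer seed.
#' @param kind gap kind label (default `"adiabatic"`).
#' @return List with `red` and `ox` ([GapSeries-class]) and
#'   `analyticDeltaA` (eV).
#' @export
gaussianGapSeries <- function(meanRed, meanOx, sigma, nSamples, seed = 1L,
                              kind = "adiabatic") {
  if (sigma <= 0) .stopf("sigma must be positive")
  if (nSamples < 2L) .stopf("nSamples must be >= 2")
  set.seed(seed)
  red <- stats::rnorm(nSamples, meanRed, sigma)
  ox <- stats::rnorm(nSamples, meanOx, sigma)
  list(red = GapSeries("reduced", kind, red),
    ox = GapSeries("oxidized", kind, ox),
    analyticDeltaA = (meanRed + meanOx) / 2)
}

#' Write synthetic inputs to disk with a provenance manifest
#'
#' Serializes a species pair (state-set schema files), any ensembles (XYZQ
#' trajectories) and a JSON manifest recording the generation parameters and
#' seeds, so a synthetic study can be re-read through the ordinary file-based
#' loaders.
#'
#' @param pair a [RedoxSpeciesPair-class].
#' @param ensembles named list of [FrameEnsemble-class]s (may be empty).
#' @param dir output directory (created if needed).
#' @param manifest list of generation parameters to record.
#' @return Named character vector of the files written, invisibly.
#' @export
exportSyntheticInputs <- function(pair, ensembles = list(), dir,
                                  manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    red = writeStateSet(pair@red, file.path(dir, "red.stateset.json")),
    ox_vertical = writeStateSet(pair@oxVertical,
      file.path(dir, "ox_vertical.stateset.json")),
    ox_adiabatic = writeStateSet(pair@oxAdiabatic,
      file.path(dir, "ox_adiabatic.stateset.json")))
  for (nm in names(ensembles)) {
    p <- file.path(dir, sprintf("%s.xyzq", nm))
    writeXYZQ(ensembles[[nm]], p)
    files[nm] <- p
  }
  man <- c(list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = as.list(files)), manifest)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- file.path(dir, "manifest.json")
  invisible(files)
}
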