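test_that("solvent specs validate their physical constraints", {
  s <- solventSpec(nGroups = 10, boxEdge = 2, seed = 1)
  expect_s3_class(s, "SolventSpec")
  expect_equal(sum(s$siteCharges), 0)
  expect_error(solventSpec(siteCharges = c(-0.8, 0.41, 0.41)), "sum to 0")
  expect_error(solventSpec(boxEdge = 0.5, exclusionRadius = 0.3), "fit")
})

test_that("generation is seeded-deterministic and respects the exclusion sphere", {
  pair <- makeSyntheticPair(nAtoms = 4L, nStates = 2L, seed = 2)
  spec <- solventSpec(nGroups = 15L, boxEdge = 2.0, exclusionRadius = 0.35,
    seed = 42)
  a <- generateSolventFrames(spec, geometry(pair@red), nFrames = 4, "iid")
  b <- generateSolventFrames(spec, geometry(pair@red), nFrames = 4, "iid")
  for (i in 1:4) {
    expect_identical(a[[i]]@envPoints, b[[i]]@envPoints)  # bitwise
    ## every oxygen site outside the exclusion sphere of every QC atom
    ep <- a[[i]]@envPoints
    ox <- ep[seq(1, nrow(ep), by = 3), ]
    for (j in seq_len(nrow(a[[i]]@qcCoords))) {
      d <- minimumImage(cbind(ox$x - a[[i]]@qcCoords[j, 1],
        ox$y - a[[i]]@qcCoords[j, 2], ox$z - a[[i]]@qcCoords[j, 3]), 2.0)
      expect_true(all(rowSums(d^2) > 0.35^2))
    }
  }
  ## empty solvent is a valid degenerate case
  none <- generateSolventFrames(solventSpec(nGroups = 0L, boxEdge = 2,
    seed = 1), geometry(pair@red), nFrames = 2, "iid")
  expect_equal(nrow(none[[1]]@envPoints), 0L)
})

test_that("every generated artifact passes its class validity checks", {
  for (seed in 1:100) {
    pair <- makeSyntheticPair(nAtoms = 5L, nStates = 4L, seed = seed,
      gap0 = 8.5, relaxation = 0.4)
    expect_true(validObject(pair, test = TRUE))
    expect_true(validObject(pair@red, test = TRUE))
    ## exact unperturbed gaps by construction
    expect_equal(stateEnergies(pair@oxVertical)[1] -
      stateEnergies(pair@red)[1], 8.5)
    expect_equal(stateEnergies(pair@oxVertical)[1] -
      stateEnergies(pair@oxAdiabatic)[1], 0.4)
  }
  ## relaxation 0: unperturbed AIE equals unperturbed VIE
  p0 <- makeSyntheticPair(seed = 7, relaxation = 0)
  expect_equal(stateEnergies(p0@oxAdiabatic)[1],
    stateEnergies(p0@oxVertical)[1])
  ## parameter validation
  expect_error(makeSyntheticPair(relaxation = -0.1), "relaxation")
  expect_error(makeSyntheticPair(nStates = 0), "nStates")
})

test_that("synthetic pairs survive the full serialize/load/validate round trip", {
  dir <- withr::local_tempdir()
  pair <- makeSyntheticPair(nAtoms = 6L, nStates = 3L, seed = 13)
  files <- exportSyntheticInputs(pair, dir = dir,
    manifest = list(seed = 13))
  back <- RedoxSpeciesPair(readStateSet(files[["red"]]),
    readStateSet(files[["ox_vertical"]]),
    readStateSet(files[["ox_adiabatic"]]))
  expect_equal(stateEnergies(back@red), stateEnergies(pair@red),
    tolerance = 1e-14)
  expect_equal(atomicCharges(back@oxVertical),
    atomicCharges(pair@oxVertical), tolerance = 1e-13)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 13)
})

test_that("the dipole-shift knob moves the cation ground-state dipole as requested", {
  for (shift_debye in c(0.1, 1.8)) {
    pair <- makeSyntheticPair(seed = 3,
      dipoleShift = shift_debye * pmmConstants()$debye)
    d_red <- sqrt(sum(permanentDipoles(pair@red)[1, ]^2))
    d_ox <- sqrt(sum(permanentDipoles(pair@oxVertical)[1, ]^2))
    expect_equal(d_ox - d_red, shift_debye * pmmConstants()$debye,
      tolerance = 1e-12)
  }
})

test_that("gaussian gap series have the specified moments and analytic answer", {
  gg <- gaussianGapSeries(6, 4, sigma = 0.5, nSamples = 1e4, seed = 1)
  expect_equal(gg$analyticDeltaA, 5)
  est <- oxidationFreeEnergy(ensembleAverages(gg$red, gg$ox))
  pooled_se <- 0.5 / sqrt(1e4) * sqrt(2) / 2
  expect_lt(abs(est - 5), 3 * pooled_se)
  ## CLT check on the sample means across seeds
  for (seed in 1:100) {
    gg <- gaussianGapSeries(8.2, 7.4, sigma = 0.3, nSamples = 400,
      seed = seed)
    expect_lt(abs(mean(gapValues(gg$red)) - 8.2), 4 * 0.3 / sqrt(400))
    expect_lt(abs(mean(gapValues(gg$ox)) - 7.4), 4 * 0.3 / sqrt(400))
  }
  expect_error(gaussianGapSeries(6, 4, sigma = 0, nSamples = 10), "sigma")
})

test_that("metropolis sampling is reproducible, mixes, and responds to the QC charge", {
  pair <- makeSyntheticPair(nAtoms = 4L, nStates = 2L, seed = 8)
  spec <- solventSpec(nGroups = 20L, boxEdge = 1.4, exclusionRadius = 0.3,
    seed = 21)
  q_red <- atomicCharges(pair@red)[1, ]
  q_ox <- atomicCharges(pair@oxVertical)[1, ]
  a <- generateSolventFrames(spec, geometry(pair@red), nFrames = 10,
    "metropolis", qcStateCharges = q_red)
  b <- generateSolventFrames(spec, geometry(pair@red), nFrames = 10,
    "metropolis", qcStateCharges = q_red)
  expect_identical(a[[10]]@envPoints, b[[10]]@envPoints)  # seeded determinism
  ## tuning guard on the acceptance statistics
  acc <- attr(a, "acceptanceRate")
  expect_gt(acc, 0.1); expect_lt(acc, 0.9)
  expect_error(generateSolventFrames(spec, geometry(pair@red), 2,
    "metropolis"), "qcStateCharges")

  ## Boltzmann response: sampling around the +1 cation polarizes the neutral
  ## solvent favourably, lowering the time-averaged solvent-QC energy
  e_red <- e_ox <- numeric(3)
  for (s in 1:3) {
    sp <- solventSpec(nGroups = 20L, boxEdge = 1.4, exclusionRadius = 0.3,
      seed = 100 + s)
    er <- generateSolventFrames(sp, geometry(pair@red), nFrames = 25,
      "metropolis", qcStateCharges = q_red)
    eo <- generateSolventFrames(sp, geometry(pair@red), nFrames = 25,
      "metropolis", qcStateCharges = q_ox, label = "oxidized")
    e_red[s] <- mean(attr(er, "solventQcEnergy"))
    e_ox[s] <- mean(attr(eo, "solventQcEnergy"))
  }
  d <- e_ox - e_red
  expect_lt(mean(d) + 3 * sd(d) / sqrt(3), 0)
})
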