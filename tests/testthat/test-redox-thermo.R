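test_that("VIE and AIE are guarded ensemble means", {
  expect_equal(verticalIonizationEnergy(
    GapSeries("reduced", "vertical", c(8, 8, 8))), 8)
  expect_equal(verticalIonizationEnergy(
    GapSeries("reduced", "vertical", c(7.5, 8.5))), 8)
  set.seed(50)
  x <- rnorm(1000, 8.1, 0.2)
  expect_equal(verticalIonizationEnergy(GapSeries("reduced", "vertical", x)),
    sum(x) / 1000, tolerance = 1e-12)
  ## wrong ensemble or kind is refused
  expect_error(verticalIonizationEnergy(
    GapSeries("oxidized", "vertical", x)), "reduced")
  expect_error(verticalIonizationEnergy(
    GapSeries("reduced", "adiabatic", x)), "vertical")
  expect_error(adiabaticIonizationEnergy(
    GapSeries("reduced", "vertical", x)), "adiabatic")
})

test_that("the mean-of-bounds free energy and reorganization are exact arithmetic", {
  avg <- ensembleAverages(GapSeries("reduced", "adiabatic", c(6, 6)),
    GapSeries("oxidized", "adiabatic", c(4, 4)))
  expect_equal(oxidationFreeEnergy(avg), 5)
  expect_equal(reorganizationEnergy(avg), 1)
  degenerate <- ensembleAverages(GapSeries("reduced", "adiabatic", c(5, 5)),
    GapSeries("oxidized", "adiabatic", c(5, 5)))
  expect_equal(oxidationFreeEnergy(degenerate), 5)
  ## mixing kinds or mislabeled ensembles is refused
  expect_error(ensembleAverages(GapSeries("reduced", "adiabatic", 1),
    GapSeries("oxidized", "vertical", 1)), "kind")
  vert <- ensembleAverages(GapSeries("reduced", "vertical", c(6, 6)),
    GapSeries("oxidized", "vertical", c(4, 4)))
  expect_error(oxidationFreeEnergy(vert), "adiabatic")
  expect_warning(reorganizationEnergy(ensembleAverages(
    GapSeries("reduced", "adiabatic", 4), GapSeries("oxidized", "adiabatic", 6))),
    "reorganization")
})

test_that("reduction potentials follow V_red = dA/n - V_SHE", {
  expect_equal(reductionPotential(4.281, 1, 4.281), 0)
  expect_equal(reductionPotential(5.331), 1.05, tolerance = 1e-12)
  expect_equal(reductionPotential(8.562, nElectrons = 2), 0)
  expect_error(reductionPotential(5, nElectrons = 0), "nElectrons")
  ## affine in deltaA with slope 1/n and intercept -vShe
  set.seed(3)
  for (rep in 1:10) {
    dA <- runif(1, 3, 7); n <- sample(1:3, 1); vs <- runif(1, 4, 5)
    expect_equal(reductionPotential(dA, n, vs), dA / n - vs)
  }
})

test_that("the gas-phase shift correction reproduces published worked values", {
  expect_equal(gasShiftCorrection(7.66, 7.92, 8.24), 7.98)
  expect_equal(gasShiftCorrection(8.29, 8.97, 9.14), 8.46)
  expect_equal(gasShiftCorrection(5.5, 8.0, 8.0), 5.5)  # zero shift
})

test_that("block errors follow the sd-of-block-means / sqrt(nBlocks) definition", {
  expect_equal(blockError(rep(2.5, 30)), 0)
  expect_equal(blockError(rep(c(1, 2, 3), each = 10)), sd(c(1, 2, 3)) / sqrt(3))
  ## remainder values are dropped at the end
  x <- c(rep(1, 3), rep(2, 3), rep(3, 3), 99)
  expect_equal(blockError(x, 3), sd(c(1, 2, 3)) / sqrt(3))
  expect_error(blockError(c(1, 2), 3), "shorter")
  ## sampling distribution: for iid Gaussian noise the estimator is unbiased
  ## up to the small-sample sd factor c4(3) = sqrt(2/2)*gamma(3/2)/gamma(1)
  c4 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)
  sigma <- 0.05; n <- 3000
  ratios <- vapply(1:200, function(s) {
    set.seed(s)
    blockError(rnorm(n, 0, sigma)) / (sigma / sqrt(n))
  }, numeric(1))
  expect_equal(mean(ratios), c4, tolerance = 0.12)
  expect_true(all(ratios > 0))
})

test_that("equal-variance Gaussian gaps: mean-of-bounds equals the analytic and BAR result", {
  kT <- KB * 300
  sigma <- 0.12
  mu_red <- 8.0
  mu_ox <- mu_red - sigma^2 / kT   # consistent linear-response ensembles
  gg <- gaussianGapSeries(mu_red, mu_ox, sigma, nSamples = 2e4, seed = 77)
  est <- oxidationFreeEnergy(ensembleAverages(gg$red, gg$ox))
  expect_equal(gg$analyticDeltaA, (mu_red + mu_ox) / 2)
  se <- sigma / sqrt(2e4)
  expect_lt(abs(est - gg$analyticDeltaA), 3 * se * sqrt(2))
  ## independent overlap-sampling oracle on the same samples
  bar <- bar_free_energy(gapValues(gg$red), gapValues(gg$ox), kT)
  expect_lt(abs(est - bar), 0.01)
})

test_that("the solvent-truncation scan matches brute-force recomputation", {
  pair <- makeSyntheticPair(nAtoms = 4L, nStates = 3L, seed = 19)
  spec <- solventSpec(nGroups = 20L, boxEdge = 2.2, exclusionRadius = 0.3,
    seed = 5)
  ens <- generateSolventFrames(spec, geometry(pair@red), nFrames = 6,
    mode = "iid")
  scan <- solventTruncationScan(ens, pair, c(0, 5))
  ## retaining everything: identically zero difference distribution
  expect_equal(scan$vie[scan$removed == 0],
    verticalIonizationEnergy(gapSeries(ens, pair, "vertical")))
  expect_equal(scan$sd_diff[scan$removed == 0], 0)
  expect_equal(scan$max_abs_diff[scan$removed == 0], 0)

  ## brute force: drop the 5 farthest groups by hand and recompute the VIE
  masses <- geometry(pair@red)$mass
  gaps5 <- vapply(seq_len(nFrames(ens)), function(fi) {
    fr <- ens[[fi]]
    com <- colSums(fr@qcCoords * masses) / sum(masses)
    ep <- fr@envPoints
    gids <- unique(ep$group)
    d <- vapply(gids, function(g) {
      rows <- ep[ep$group == g, ]
      ctr <- c(mean(rows$x), mean(rows$y), mean(rows$z))
      sqrt(sum(minimumImage(ctr - com, fr@boxEdge)^2))
    }, numeric(1))
    keep_ids <- gids[order(d)][1:(length(gids) - 5)]
    fr2 <- Frame(fr@boxEdge, fr@qcCoords, ep[ep$group %in% keep_ids, ])
    smp <- samplePerturbation(fr2, pair@red)
    diagonalizePMM(buildHamiltonian(smp, pair@oxVertical))@groundEnergy -
      diagonalizePMM(buildHamiltonian(smp, pair@red))@groundEnergy
  }, numeric(1))
  expect_equal(scan$vie[scan$removed == 5], mean(gaps5), tolerance = 1e-10)
  expect_error(solventTruncationScan(ens, pair, 21), "exceeds")
})
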