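zero_sample <- function(set, com = c(0, 0, 0))
  new("PerturbationSample", potentialsAtAtoms = rep(0, nAtoms(set)),
    fieldAtCom = c(0, 0, 0), com = com)

uniform_sample <- function(set, v0)
  new("PerturbationSample", potentialsAtAtoms = rep(v0, nAtoms(set)),
    fieldAtCom = c(0, 0, 0), com = c(0, 0, 0))

test_that("zero perturbation returns the unperturbed diagonal", {
  set <- toy_stateset(3L, 3L)
  H <- buildHamiltonian(zero_sample(set), set)
  expect_equal(H, diag(stateEnergies(set)))
})

test_that("a uniform potential is a pure gauge shift by Q * V0", {
  for (Q in c(0L, 1L)) {
    set <- toy_stateset(4L, 3L, Q = Q)
    v0 <- 2.37
    H <- buildHamiltonian(uniform_sample(set, v0), set)
    expect_equal(H, diag(stateEnergies(set) + Q * v0), tolerance = 1e-12)
  }
})

test_that("the Hamiltonian matches an element-by-element brute-force construction", {
  set <- toy_stateset(3L, 3L)
  set.seed(14)
  env <- env_points(runif(6, 0.6, 1.8), q = c(0.9, -0.3),
    group = c("e1", "e2"))
  fr <- toy_frame(env)
  H <- buildHamiltonian(samplePerturbation(fr, set, usePbc = FALSE), set)
  expect_equal(H, oracle_hamiltonian(set, fr), tolerance = 1e-12)
  expect_equal(H, t(H))   # exactly symmetric by construction
})

test_that("diagonalization is deterministic, ordered and matches closed forms", {
  ps <- diagonalizePMM(diag(c(0, 5)))
  expect_equal(ps@eigenvalues, c(0, 5))
  expect_equal(ps@groundVector, c(1, 0))
  ## 2-level closed form: E = (0, 1), coupling 0.5
  H2 <- matrix(c(0, 0.5, 0.5, 1), 2, 2)
  expect_equal(diagonalizePMM(H2)@groundEnergy, (1 - sqrt(2)) / 2,
    tolerance = 1e-12)
  ## random symmetric matrices: verify the eigen-decomposition property
  ## H v = lambda v with orthonormal vectors, independent of any solver
  set.seed(99)
  for (rep in 1:20) {
    A <- matrix(rnorm(49), 7, 7)
    H <- (A + t(A)) / 2
    ps <- diagonalizePMM(H)
    expect_false(is.unsorted(ps@eigenvalues))
    V <- vapply(1:7, function(k) {
      es <- eigen(H, symmetric = TRUE)    # reference decomposition
      sort(es$values)[k]
    }, numeric(1))
    expect_equal(ps@eigenvalues, V, tolerance = 1e-10)
    resid <- H %*% ps@groundVector - ps@groundEnergy * ps@groundVector
    expect_lt(max(abs(resid)), 1e-10)
    ## sign convention: the largest-magnitude coefficient is positive
    expect_gt(ps@groundVector[which.max(abs(ps@groundVector))], 0)
  }
  expect_error(diagonalizePMM(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("ground-energy series equals the per-frame compose of build + diagonalize", {
  set <- toy_stateset(3L, 3L)
  ens <- mini_ensemble(10L, set, seed = 17)
  ser <- groundEnergySeries(ens, set, usePbc = FALSE)
  expect_equal(nrow(ser), 10L)
  expect_equal(ser$frame, 1:10)
  manual <- vapply(1:10, function(i)
    diagonalizePMM(buildHamiltonian(
      samplePerturbation(ens[[i]], set, usePbc = FALSE), set))@groundEnergy,
    numeric(1))
  expect_equal(ser$energy, manual, tolerance = 1e-12)

  ## zero-charge environments -> constant unperturbed ground energy
  ens0 <- FrameEnsemble("reduced", lapply(frames(ens), function(f) {
    ep <- f@envPoints; ep$charge <- 0; Frame(f@boxEdge, f@qcCoords, ep)
  }))
  ser0 <- groundEnergySeries(ens0, set, usePbc = FALSE)
  expect_equal(ser0$energy, rep(stateEnergies(set)[1], 10L))
})

test_that("transition-dipole phase flips do not change observables", {
  set <- toy_stateset(3L, 4L)
  ens <- mini_ensemble(5L, set, seed = 23)
  ser <- groundEnergySeries(ens, set, usePbc = FALSE)
  for (k in 2:4) {
    td <- transitionDipoles(set)
    td[k, , ] <- -td[k, , ]
    td[, k, ] <- -td[, k, ]      # [k,k,] flips twice: permanent dipole kept
    flipped <- ElectronicStateSet(speciesLabel(set), totalCharge(set),
      geometry(set), stateEnergies(set), atomicCharges(set), td)
    expect_equal(groundEnergySeries(ens, flipped, usePbc = FALSE)$energy,
      ser$energy, tolerance = 1e-12)
  }
})

test_that("rigid rotations leave the perturbed eigenvalues unchanged", {
  set <- toy_stateset(3L, 3L)
  set.seed(31)
  env <- env_points(runif(9, 0.7, 2), q = runif(3, -0.8, 0.8),
    group = c("e1", "e2", "e3"))
  fr <- toy_frame(env)
  ev <- diagonalizePMM(buildHamiltonian(
    samplePerturbation(fr, set, usePbc = FALSE), set))@eigenvalues
  for (seed in 1:5) {
    R <- random_rotation_matrix(seed)
    ev_rot <- diagonalizePMM(buildHamiltonian(
      samplePerturbation(rotate_frame(fr, R), rotate_stateset(set, R),
        usePbc = FALSE), rotate_stateset(set, R)))@eigenvalues
    expect_equal(ev_rot, ev, tolerance = 1e-9)
  }
})

test_that("the weak-field residual beyond first order scales as O(eps^2)", {
  set <- toy_stateset(3L, 3L)
  env <- env_points(c(2.0, 1.5, 1.2), q = 1, group = "e1")
  resid <- function(eps) {
    e <- env; e$charge <- e$charge * eps
    smp <- samplePerturbation(toy_frame(e), set, usePbc = FALSE)
    first <- sum(atomicCharges(set)[1, ] * smp@potentialsAtAtoms)
    diagonalizePMM(buildHamiltonian(smp, set))@groundEnergy -
      stateEnergies(set)[1] - first
  }
  r1 <- resid(0.2); r2 <- resid(0.1)
  expect_gt(abs(r1), 0)
  expect_equal(r1 / r2, 4, tolerance = 0.2)   # halving eps quarters the residual
})

test_that("gap series subtract two ground-energy series on shared frames", {
  pair <- makeSyntheticPair(nAtoms = 3L, nStates = 3L, seed = 6,
    gap0 = 8.0, relaxation = 0.5)
  ens <- mini_ensemble(50L, pair@red, seed = 41)
  g <- gapSeries(ens, pair, "vertical", usePbc = FALSE)
  red_s <- groundEnergySeries(ens, pair@red, usePbc = FALSE)
  ox_s <- groundEnergySeries(ens, pair@oxVertical, usePbc = FALSE)
  expect_equal(gapValues(g), ox_s$energy - red_s$energy, tolerance = 1e-12)
  expect_equal(length(g), 50L)

  ## zero-charge environments -> the exact unperturbed gap, and the adiabatic
  ## series sits exactly `relaxation` below the vertical one
  ens0 <- FrameEnsemble("reduced", lapply(frames(ens), function(f) {
    ep <- f@envPoints; ep$charge <- 0; Frame(f@boxEdge, f@qcCoords, ep)
  }))
  gv <- gapSeries(ens0, pair, "vertical", usePbc = FALSE)
  ga <- gapSeries(ens0, pair, "adiabatic", usePbc = FALSE)
  expect_equal(gapValues(gv), rep(8.0, 50L), tolerance = 1e-12)
  expect_equal(gapValues(ga), rep(7.5, 50L), tolerance = 1e-12)
})

test_that("a uniform potential shifts red->ox gaps by exactly (Q_ox - Q_red) * V0", {
  pair <- makeSyntheticPair(nAtoms = 4L, nStates = 3L, seed = 12, gap0 = 9.0)
  v0 <- 1.234
  g0 <- diagonalizePMM(buildHamiltonian(zero_sample(pair@oxVertical),
    pair@oxVertical))@groundEnergy -
    diagonalizePMM(buildHamiltonian(zero_sample(pair@red),
      pair@red))@groundEnergy
  g1 <- diagonalizePMM(buildHamiltonian(uniform_sample(pair@oxVertical, v0),
    pair@oxVertical))@groundEnergy -
    diagonalizePMM(buildHamiltonian(uniform_sample(pair@red, v0),
      pair@red))@groundEnergy
  expect_equal(g1 - g0, v0, tolerance = 1e-10)   # charge step is +1
})

test_that("near-singular frames are skipped with a log or escalate on request", {
  set <- toy_stateset(3L, 2L)
  qc <- as.matrix(geometry(set)[, c("x", "y", "z")])
  good <- Frame(10, qc, env_points(c(2, 2, 2), q = 0.5, group = "e1"))
  bad <- Frame(10, qc, env_points(qc[1, ] + c(0.01, 0, 0), q = 0.5,
    group = "e1"))
  ens <- FrameEnsemble("reduced", list(good, bad, good))
  expect_message(ser <- groundEnergySeries(ens, set, usePbc = FALSE),
    "skipping frame 2")
  expect_equal(ser$frame, c(1L, 3L))
  expect_equal(attr(ser, "skipped"), 2L)
  expect_error(
    suppressMessages(groundEnergySeries(ens, set, usePbc = FALSE,
      onClash = "error")),
    "d_min")
  ens_bad <- FrameEnsemble("reduced", list(bad))
  expect_error(
    suppressMessages(groundEnergySeries(ens_bad, set, usePbc = FALSE)),
    "skipped")
})
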