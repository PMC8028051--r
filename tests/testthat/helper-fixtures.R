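## Shared fixtures and independent brute-force oracles.  Oracles are written
## from the defining formulas directly (plain sums, explicit image
## enumeration) so they stay independent of the package's vectorized kernels.

KE <- pmmConstants()$coulomb
KB <- pmmConstants()$boltzmann

## deterministic small state set: hand-countable numbers, no RNG
toy_stateset <- function(nAtoms = 3L, nStates = 3L, Q = 0L,
                         label = "toy") {
  geom <- data.frame(atom = sprintf("A%d", seq_len(nAtoms)),
    mass = rep(c(12.011, 1.008, 15.999), length.out = nAtoms),
    x = seq_len(nAtoms) * 0.1, y = rep(0.05, nAtoms),
    z = seq_len(nAtoms) * -0.02)
  energies <- (seq_len(nStates) - 1L) * 1.5
  ac <- matrix(0, nStates, nAtoms)
  for (i in seq_len(nStates)) {
    raw <- sin(i * seq_len(nAtoms))      # fixed, reproducible pattern
    ac[i, ] <- raw - mean(raw) + Q / nAtoms
  }
  td <- array(0, c(nStates, nStates, 3L))
  for (i in seq_len(nStates)) {
    td[i, i, ] <- c(0.02 * i, -0.01, 0.005 * i)
    if (i < nStates) for (j in (i + 1L):nStates) {
      v <- c(0.01, 0.002 * (i + j), -0.003)
      td[i, j, ] <- v; td[j, i, ] <- v
    }
  }
  ElectronicStateSet(label, Q, geom, energies, ac, td)
}

toy_frame <- function(env = NULL, box = 10, qc = NULL, nAtoms = 3L) {
  if (is.null(qc)) qc <- as.matrix(toy_stateset(nAtoms)@geometry[, c("x", "y", "z")])
  if (is.null(env)) env <- emptyEnv()
  Frame(box, qc, env)
}

env_points <- function(xyz, q, group = NULL) {
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  if (is.null(group)) group <- sprintf("g%d", seq_len(nrow(xyz)))
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], charge = q,
    group = group)
}

## plain-sum Coulomb oracles (no PBC)
oracle_potential <- function(point, env) {
  s <- 0
  for (k in seq_len(nrow(env))) {
    r <- sqrt(sum((c(env$x[k], env$y[k], env$z[k]) - point)^2))
    s <- s + env$charge[k] / r
  }
  KE * s
}

oracle_field <- function(point, env) {
  s <- c(0, 0, 0)
  for (k in seq_len(nrow(env))) {
    d <- point - c(env$x[k], env$y[k], env$z[k])
    s <- s + env$charge[k] * d / sum(d^2)^1.5
  }
  KE * s
}

## exhaustive 27-image minimum-image oracle (valid for |d| < boxEdge)
oracle_min_image <- function(d, L) {
  best <- NULL; bestn <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    cand <- d + L * c(i, j, k)
    n <- sum(cand^2)
    if (n < bestn) { bestn <- n; best <- cand }
  }
  best
}

## element-by-element Hamiltonian oracle from the defining formulas
oracle_hamiltonian <- function(set, frame) {
  ns <- nStates(set)
  masses <- geometry(set)$mass
  com <- colSums(frame@qcCoords * masses) / sum(masses)
  pot <- vapply(seq_len(nrow(frame@qcCoords)), function(a)
    oracle_potential(frame@qcCoords[a, ], frame@envPoints), numeric(1))
  fld <- oracle_field(com, frame@envPoints)
  H <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    H[i, j] <- if (i == j)
      stateEnergies(set)[i] + sum(atomicCharges(set)[i, ] * pot)
    else -sum(fld * transitionDipoles(set)[i, j, ])
  }
  H
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

rotate_stateset <- function(set, R) {
  g <- geometry(set)
  xyz <- as.matrix(g[, c("x", "y", "z")]) %*% t(R)
  g$x <- xyz[, 1]; g$y <- xyz[, 2]; g$z <- xyz[, 3]
  td <- transitionDipoles(set)
  ns <- nStates(set)
  for (i in seq_len(ns)) for (j in seq_len(ns))
    td[i, j, ] <- as.numeric(R %*% td[i, j, ])
  ElectronicStateSet(speciesLabel(set), totalCharge(set), g,
    stateEnergies(set), atomicCharges(set), td)
}

rotate_frame <- function(frame, R) {
  ep <- frame@envPoints
  if (nrow(ep)) {
    xyz <- as.matrix(ep[, c("x", "y", "z")]) %*% t(R)
    ep$x <- xyz[, 1]; ep$y <- xyz[, 2]; ep$z <- xyz[, 3]
  }
  Frame(frame@boxEdge, frame@qcCoords %*% t(R), ep)
}

## Bennett acceptance-ratio free energy from paired work samples; with equal
## sample sizes the self-consistent shift C is the free energy difference
bar_free_energy <- function(gaps_red, gaps_ox, kT) {
  wF <- gaps_red          # work of red -> ox measured in the red ensemble
  wR <- -gaps_ox          # work of ox -> red measured in the ox ensemble
  f <- function(C)
    mean(stats::plogis(-(wF - C) / kT)) - mean(stats::plogis(-(wR + C) / kT))
  stats::uniroot(f, interval = c(min(gaps_ox) - 1, max(gaps_red) + 1),
    tol = 1e-10)$root
}

## tiny ensemble of frames with hand-placed charges
mini_ensemble <- function(nFrames, set, label = "reduced", seed = 1,
                          box = 10) {
  set.seed(seed)
  qc <- as.matrix(geometry(set)[, c("x", "y", "z")])
  frames <- lapply(seq_len(nFrames), function(i) {
    n <- 4L
    Frame(box, qc, env_points(runif(3 * n, 1, 3),
      q = runif(n, -0.5, 0.5), group = sprintf("w%d", seq_len(n))))
  })
  FrameEnsemble(label, frames, temperature = 300)
}
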