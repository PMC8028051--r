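---
title: "Perturbed-matrix redox thermodynamics: model, assumptions and design"
author: "RedoxPMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbed-matrix redox thermodynamics: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RedoxPMM)
```

## The model

RedoxPMM implements the perturbed matrix method (PMM) for a quantum center
(QC) -- here, typically a DNA nucleobase -- embedded in a classical
point-charge environment. The electronic structure of the isolated QC is
computed once (elsewhere: this package performs no electronic-structure
calculation) and summarized as a set of $n$ unperturbed states with energies
$E_i$, per-state atomic partial charges $q_{N,i}$, and the real symmetric
transition-dipole matrix $\mu_{ij}$ whose diagonal holds the permanent
dipoles. For every classical configuration the environment exerts an
electrostatic potential $\mathcal{V}(\mathbf{R}_N)$ at each QC atomic
position and a field $\mathbf{E}(\mathbf{r}_0)$ at the QC center of mass,
and the perturbed Hamiltonian matrix is built as

$$
H_{ii} = E_i + \sum_N q_{N,i}\,\mathcal{V}(\mathbf{R}_N), \qquad
H_{ij} = -\mathbf{E}(\mathbf{r}_0)\cdot\mu_{ij} \quad (i \neq j),
$$

and diagonalized. The diagonal uses the atom-based expansion of the
perturbation operator truncated at the monopole (atomic-charge) term within
each atomic region; the off-diagonal uses the molecule-based expansion in
the dipolar approximation. The charge-times-potential term contributes only
to the diagonal because the unperturbed states are orthonormal. Mapping this
over a trajectory yields per-frame perturbed ground-state energies for the
reduced (neutral) and oxidized (radical-cation) species and hence per-frame
energy gaps $\Delta\mathcal{E} = \mathcal{E}^{ox}_0 - \mathcal{E}^{red}_0$.

Thermodynamics follows from the two-ensemble, mean-of-bounds estimator. With
$\langle\Delta\mathcal{E}\rangle_{red}$ and
$\langle\Delta\mathcal{E}\rangle_{ox}$ the adiabatic-gap averages in
ensembles sampled with the QC neutral and cationic respectively, and
assuming the ionic relaxation free energies of the two ensembles cancel,

$$
\Delta A \simeq \tfrac12\left(\langle\Delta\mathcal{E}\rangle_{red} +
\langle\Delta\mathcal{E}\rangle_{ox}\right), \qquad
V_{red} = \frac{\Delta A}{n} - V_{SHE},
$$

where the two averages are rigorous upper and lower bounds of $\Delta A$ and
the midpoint is exact for Gaussian gap statistics of equal variance (the
linear-response regime). The vertical ionization energy (VIE) is
$\langle\Delta\mathcal{E}^{vert}\rangle_{red}$: the average vertical gap
(cation states at the neutral geometry) in the reduced ensemble only; the
adiabatic ionization energy (AIE) uses the cation at its own relaxed
geometry. The reorganization energy is half the difference of the two
ensemble averages and must be non-negative for equilibrium sampling -- the
package warns, rather than errors, when it is not, because short or
non-equilibrium ensembles legitimately violate it.

## Units and constants

All lengths are nm, charges are in units of the elementary charge $e$,
dipoles e nm (the loader converts debye with 1 D = 0.0208194 e nm), energies
eV, potentials V, temperatures K. In this system the Coulomb constant is
$k_e = 1.439964$ eV nm/$e^2$ (stated to 7 significant figures so tests are
exactly reproducible) and a per-electron free energy in eV is numerically a
potential in V, so the Faraday constant never appears. The default
$V_{SHE} = 4.281$ V is the literature absolute potential of the standard
hydrogen electrode.

The printed form of the potential-to-free-energy relation in the source
literature is ambiguous in sign; the convention implemented,
$V_{red} = \Delta A / n - V_{SHE}$, is fixed by two constraints the
reference numbers impose: $V_{SHE}$ is subtracted, and physically positive
oxidation free energies must reproduce the published ordering and magnitude
of nucleoside reduction potentials (e.g. $\Delta A = 5.331$ eV, $n = 1$
gives 1.05 V). This is asserted in the test suite.

## Tunable parameters that matter

* `dMin` (default 0.05 nm): near-contact guard. Classical configurations
  occasionally place a point charge unphysically close to a QC probe
  position; a bare Coulomb sum would then inject huge energies silently into
  ensemble averages. Such frames raise a classed condition and are, by
  default, skipped with a log message (`onClash = "skip"`); `"error"`
  escalates instead. Skip counts are reported in every estimate.
* `usePbc` (default TRUE): minimum-image wrapping of every charge
  displacement in a cubic box, applied inside the electrostatics kernels
  only -- raw coordinates are never rewritten. There is no Ewald summation,
  cutoff or reaction field: the perturbation is the bare Coulomb sum over
  the simulated box's charges, the simplest well-defined convention.
* `nBlocks` (default 3): statistical errors are the standard deviation of
  the mean over contiguous sub-trajectory blocks; remainder frames at the
  end are dropped for determinism. The SEM-of-blocks convention (sd of block
  means divided by $\sqrt{n_{blocks}}$) is used.
* `nStates` (default 7): ground plus six excited states, the customary
  truncation for nucleobase PMM work. The engine accepts any $n \ge 1$.
* `nElectrons` (default 1) and `vShe` (default 4.281 V) in the potential
  conversion.

## Numerical choices

* Diagonalization uses the dense symmetric eigensolver; eigenvalues are
  returned ascending with a deterministic eigenvector sign convention (the
  largest-magnitude coefficient, first index on ties, is made positive).
  Transition-dipole phases are not observable, and the engine is invariant
  to flipping the sign of any state's dipole row/column pair (tested).
* The perturbed ground state is the lowest eigenvalue per frame; no
  adiabatic state-tracking is attempted across frames. The ground/first-
  excited separation is reported per frame as a crossing diagnostic.
* The field is evaluated at the center of mass computed from the *frame*
  coordinates (the instantaneous QC position), not from the gas-phase
  geometry.
* The gap of a frame skipped for either species of a pair is skipped for
  both, keeping the series paired.
* Matrix symmetry is exact by construction; asymmetric input to the
  diagonalizer beyond $10^{-10}$ eV is an error.

## What the synthetic generator emulates -- and what it does not

The paper-scale inputs (DFT state sets, 100 ns molecular-dynamics
trajectories) are not reproducible at desk scale, so the package generates
every input it needs with known answers.

**Solvent boxes.** The default `solventSpec()` mirrors the reference
simulation conditions: a cubic box of 3.1 nm side with about 1050 rigid
three-site water-like groups (SPC charges $-0.82/+0.41/+0.41$ e, O--H
0.1 nm, H--O--H 109.47°) at 300 K, with an exclusion sphere of 0.3 nm
around the QC. Two sampling modes exist. `iid` places groups uniformly with
uniform orientations -- fast, and sufficient for kernels, convergence scans
and serialization tests, but configurationally uncorrelated with the QC.
`metropolis` performs single-group translation+rotation Markov moves
accepted by the Boltzmann criterion on the point-charge Coulomb energy
(solvent--solvent plus solvent--QC in the chosen charge state), which
produces the *distinct, physically responsive* reduced and oxidized
ensembles the mean-of-bounds estimator requires. Instead of Lennard-Jones
repulsion the sampler uses site-type hard cores (intergroup O--O 0.26,
O--H 0.19, H--H 0.15 nm): the O--H core is chosen so the closest-contact
pair energy is hydrogen-bond-like (roughly $-0.25$ eV, about $10\,k_BT$),
keeping the chain liquid-like rather than glassy. Proposal widths (0.012 nm
translation, 0.35 rad rotation) were set for a mid-range acceptance rate;
the acceptance statistic is recorded on every ensemble and guarded in the
tests to the customary (0.1, 0.9) band. Burn-in and stride default to 200
and 10 attempted moves per group.

What this does **not** emulate: dispersion and exchange repulsion, solvent
polarizability, realistic water structure (radial distribution functions),
counterion dynamics, or any dynamical/kinetic property. Passing tests on
these ensembles therefore demonstrate the correctness of the PMM algebra and
the statistical estimators, and the qualitative electrostatic response of a
polar solvent to an added charge -- not force-field-level realism.

**Species pairs.** `makeSyntheticPair()` fabricates a valid
reduced/oxidized state-set triple with an exact unperturbed vertical gap
(`gap0`, default 8.97 eV, a realistic nucleobase-scale value) and a cation
adiabatic surface exactly `relaxation` (default 0.3 eV) below the vertical
one. The `dipoleShift` knob (default 1.8 D) raises the cation ground-state
dipole relative to the neutral's, reproducing the mechanism by which a
polar solvent differentially stabilizes a radical cation whose dipole grows
upon ionization. By default the adiabatic state set shares the vertical
geometry, charges and dipoles (`distortion = 0`), which makes
VIE $\ge$ AIE hold frame by frame exactly; a nonzero `distortion` displaces
the cation geometry at the cost of that guarantee -- a deliberate design
choice, since the guarantee is what the property tests exercise.

**Gaussian gap series.** `gaussianGapSeries()` draws equal-variance Gaussian
gaps for the two ensembles, for which the mean-of-bounds estimator is exact
with analytic answer $(\mu_{red}+\mu_{ox})/2$; the test suite additionally
cross-checks it against an independent Bennett acceptance-ratio evaluation
on samples generated in the thermodynamically consistent regime
$\mu_{red}-\mu_{ox} = \sigma^2/k_BT$.

## Problem sizes used by the tests and the acceptance script

The shipped checks run a 20-group, 1.4 nm Metropolis box with 60--90
recorded frames per ensemble for the bound-ordering and response
properties; a 1044-group, 3.1 nm iid box with 200 frames for the
solvent-truncation convergence scan (removal levels 0, 50 and 700 groups,
ranked by instantaneous group-center distance from the QC center of mass);
$10^4$ samples for the Gaussian-gap recovery; and 200 seeded replicates of
length 3000 for the block-error sampling-distribution check. These sizes
were chosen as the smallest at which each statistical property is
comfortably resolved.

## Reporting operations and reference tables

The package ships literature reference values (gas-phase calculated and
photoelectron-spectroscopy experimental VIEs of the four nucleobases,
PMM-calculated aqueous VIEs of the nucleosides, deoxynucleotide
monophosphates and di-homonucleotides, and cyclic-voltammetry-scale
reduction potentials of the deoxynucleosides) as plain CSVs. `vieReport()`
recomputes the derived columns: the gas-shift correction adds
$\mathrm{VIE}^{gas}_{exp} - \mathrm{VIE}^{gas}_{calc}$ of the parent base to
the aqueous calculated value, reducing the sensitivity of the final numbers
to the level of electronic-structure theory used for the unperturbed
states; the solvent-induced lowering is
$\mathrm{VIE}^{gas}_{calc}(\mathrm{base}) - \mathrm{VIE}^{aq}_{calc}$.
`deltaVred()` tabulates reduction-potential differences against adenosine,
the customary anchor.

```{r}
subset(vieReport(), class == "nucleoside",
  select = c(molecule, vie_aq_calcd, vie_aq_corr, solvent_drop))
```

## Known limitations

* No back-polarization of the environment by the QC, and no polarizable
  solvent: the perturbation is one-way electrostatics.
* Minimum-image bare Coulomb only; systems where long-range corrections
  matter quantitatively (highly charged QCs, small boxes) are outside the
  intended regime.
* The ionic relaxation terms of the two-ensemble free-energy identity are
  represented only through the cancellation assumption; the flag recording
  it is immutable.
* The atom-based diagonal stops at the monopole term per atomic region;
  per-state atomic dipoles are a documented extension point, not an
  implemented option.
* Binary trajectory formats are out of scope; the readers cover GRO-style
  text series and the package's XYZQ dialect.
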