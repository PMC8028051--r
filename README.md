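# RedoxPMM

Perturbed-matrix-method (PMM) redox thermodynamics for solvated
chromophores, in R.

## The problem

One-electron oxidation of DNA bases drives mutagenic damage and long-range
charge transfer along DNA, and guanine's position as the most easily
oxidized base organizes both. The two observables that characterize the
process — the vertical ionization energy (VIE) of a solvated nucleoside and
its standard reduction potential — are hard to measure (irreversible
electrochemistry, low solubility) and hard to compute, because the solvent
shifts them by several eV and continuum-solvent models need case-by-case
calibration.

The PMM route treats only the chromophore (the quantum center, QC) quantum
mechanically and reads the solvent, counterions and any covalently attached
scaffold as an instantaneous classical point-charge distribution along a
sampled trajectory. For each configuration the perturbed electronic
Hamiltonian is built in the basis of the QC's gas-phase states:

    H[i,i] = E_i + Σ_N  q_{N,i} · V(R_N)          (atom-based diagonal)
    H[i,j] = − E(r0) · μ_ij          (i ≠ j)      (dipolar off-diagonal)

with `V` the environment potential at QC atom N, `E(r0)` the field at the
QC center of mass, `q_{N,i}` state i's partial charge on atom N, and
`μ_ij` the transition dipoles. Diagonalizing per frame gives perturbed
ground-state energies for the reduced and oxidized species, per-frame energy
gaps ΔE, and from these:

* **VIE** = ⟨ΔE_vertical⟩ in the reduced ensemble;
* **ΔA** (oxidation free energy) = (⟨ΔE⟩_red + ⟨ΔE⟩_ox)/2 over adiabatic
  gaps — the mean-of-bounds / linear-response estimator, exact for
  equal-variance Gaussian gap statistics;
* **V_red** = ΔA/n − V_SHE (V_SHE = 4.281 V), with block-averaged errors
  from three contiguous sub-trajectories.

Everything the pipeline consumes can be generated synthetically (rigid
three-site water-like solvent sampled iid or by Metropolis Monte Carlo,
fabricated state sets with known unperturbed gaps), so the full chain is
testable without electronic-structure or molecular-dynamics inputs. See the
vignette `vignettes/perturbed-matrix-redox.Rmd` for the model, assumptions
and design decisions.

## Worked example

A complete synthetic study: a 3-state quantum center with an 8.97 eV
unperturbed vertical gap and 0.3 eV cation relaxation, solvated by 20
Boltzmann-sampled water-like groups in a 1.4 nm box, with separate
reduced-state and oxidized-state ensembles.

```r
library(RedoxPMM)

pair <- makeSyntheticPair(nAtoms = 4, nStates = 3, seed = 2,
                          gap0 = 8.97, relaxation = 0.3)
red <- generateSolventFrames(
  solventSpec(nGroups = 20, boxEdge = 1.4, exclusionRadius = 0.3, seed = 301),
  geometry(pair@red), 60, "metropolis",
  qcStateCharges = atomicCharges(pair@red)[1, ])
ox <- generateSolventFrames(
  solventSpec(nGroups = 20, boxEdge = 1.4, exclusionRadius = 0.3, seed = 302),
  geometry(pair@red), 60, "metropolis",
  qcStateCharges = atomicCharges(pair@oxVertical)[1, ], label = "oxidized")
estimateRedox(red, ox, pair)
```

```
RedoxEstimate (energies eV, potentials V vs SHE)
  VIE       9.4363 +/- 0.0796
  AIE       9.1363
  deltaA    7.6258 +/- 0.0516
  V_red     3.3448 +/- 0.0516
  reorganization 1.5105 eV, gas shift applied +0.0000 eV
  frames: 60 red (0 skipped), 60 ox (0 skipped); ionic relaxation free energies of the two ensembles assumed equal
```

Reading the output: the VIE exceeds the AIE by the 0.3 eV relaxation plus
solvent effects; ΔA sits midway between the reduced- and oxidized-ensemble
gap means (here 1.51 eV apart — twice the reorganization energy, large for
this tiny box because every solvent group is in the first shell); V_red is
ΔA minus the 4.281 V SHE reference; the errors are standard deviations of
the mean over three trajectory blocks. With a zero-charge environment the
same call returns exactly VIE = 8.97, ΔA = 8.67 and V_red = 8.67 − 4.281.

File-based inputs work the same way: state sets come from a documented JSON
schema (`readStateSet`), trajectories from concatenated GRO-style series
with a name→charge table or from the self-contained XYZQ dialect
(`readFrames`), and `runPipeline()` drives everything from a YAML/JSON
config, writing a summary JSON, per-frame CSV tables and a log.

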