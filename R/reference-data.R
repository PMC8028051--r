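## Literature reference values for DNA nucleobases, nucleosides,
## deoxynucleotide monophosphates and di-homonucleotides: gas-phase VIEs
## (DFT-calculated and photoelectron-spectroscopy experimental) for the free
## bases, PMM-calculated aqueous VIEs, and cyclic-voltammetry-scale standard
## reduction potentials of the deoxynucleosides.  Shipped as plain-text CSVs
## under extdata; the reporting helpers below recompute every derived column
## (gas-shift-corrected aqueous VIEs, solvent-induced lowerings, differences
## versus adenosine) from the primary columns.

#' Reference VIE table (nucleobases, nucleosides, nucleotides)
#'
#' Columns: `molecule`, `class` (base / nucleoside / nucleotide /
#' dinucleotide), `base` (parent nitrogenous base), `vie_gas_calcd`,
#' `vie_gas_exp` (free base, eV) and `vie_aq_calcd` (aqueous PMM value, eV).
#'
#' @return data.frame.
#' @export
referenceVIETable <- function() {
  utils::read.csv(system.file("extdata", "nucleobase_vie_reference.csv",
    package = "RedoxPMM"), stringsAsFactors = FALSE)
}

#' Reference reduction-potential table (deoxynucleosides, water)
#'
#' @return data.frame with columns `molecule` and `vred_pmm_V` (V vs SHE).
#' @export
referenceVredTable <- function() {
  utils::read.csv(system.file("extdata", "nucleoside_vred_reference.csv",
    package = "RedoxPMM"), stringsAsFactors = FALSE)
}

#' VIE report: corrected aqueous values and solvent-induced lowerings
#'
#' For every solvated species the gas-phase shift of its parent base
#' (`vie_gas_exp - vie_gas_calcd`) is added to the aqueous calculated VIE
#' ([gasShiftCorrection()]), and the solvent-induced lowering
#' `vie_gas_calcd(base) - vie_aq_calcd` is tabulated.
#'
#' @param tbl a table shaped like [referenceVIETable()] (the default).
#' @return The table with derived columns `vie_aq_corr` and `solvent_drop`
#'   (both eV, NA for the free bases).
#' @examples
#' \donttest{subset(vieReport(), molecule == "guanosine")}
#' @export
vieReport <- function(tbl = referenceVIETable()) {
  bases <- tbl[tbl$class == "base", ]
  gas_calc <- stats::setNames(bases$vie_gas_calcd, bases$base)
  gas_exp <- stats::setNames(bases$vie_gas_exp, bases$base)
  tbl$vie_aq_corr <- NA_real_
  tbl$solvent_drop <- NA_real_
  solv <- which(tbl$class != "base" & is.finite(tbl$vie_aq_calcd))
  for (i in solv) {
    b <- tbl$base[i]
    tbl$vie_aq_corr[i] <- gasShiftCorrection(tbl$vie_aq_calcd[i],
      gas_calc[[b]], gas_exp[[b]])
    tbl$solvent_drop[i] <- gas_calc[[b]] - tbl$vie_aq_calcd[i]
  }
  tbl
}

#' Reduction-potential differences against a reference molecule
#'
#' @param tbl a table shaped like [referenceVredTable()] (the default).
#' @param reference molecule whose potential is subtracted (default
#'   adenosine, the customary anchor).
#' @return The table with a `delta_vs_reference` column, V.
#' @export
deltaVred <- function(tbl = referenceVredTable(), reference = "adenosine") {
  if (!reference %in% tbl$molecule)
    .stopf("reference molecule '%s' not in table", reference)
  tbl$delta_vs_reference <-
    tbl$vred_pmm_V - tbl$vred_pmm_V[tbl$molecule == reference]
  tbl
}
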