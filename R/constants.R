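## Package-wide unit system: lengths nm, charges e, dipoles e*nm,
## energies eV, potentials V, temperature K.

.KE <- 1.439964       # Coulomb constant, eV nm / e^2 (CODATA, 7 sig. figs)
.KB <- 8.617333e-5    # Boltzmann constant, eV / K
.DEBYE <- 0.0208194   # 1 debye in e nm
.VSHE <- 4.281        # absolute standard hydrogen electrode potential, V

#' Physical constants used by the package
#'
#' All internal arithmetic uses a fixed unit system: lengths in nm, charges in
#' units of the elementary charge e, dipoles in e nm, energies in eV,
#' electrostatic potentials in V and temperatures in K.  In these units the
#' Coulomb constant is 1.439964 eV nm / e^2 and a potential in V multiplied by
#' a charge in e is an energy in eV, so no Faraday factor ever appears
#' explicitly: the per-electron free energy in eV is numerically the potential
#' in V.
#'
#' @return Named list with elements `coulomb` (eV nm / e^2), `boltzmann`
#'   (eV / K), `debye` (e nm per debye) and `v_she` (V), the default absolute
#'   potential of the standard hydrogen electrode.
#' @examples
#' pmmConstants()$coulomb
#' @export
pmmConstants <- function() {
  list(coulomb = .KE, boltzmann = .KB, debye = .DEBYE, v_she = .VSHE)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.is_vec3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
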