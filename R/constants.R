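# Physical constants. Thermodynamic quantities are kept in kcal/mol and
# Angstrom throughout the pipeline; electron-density grids stay in atomic
# units (Bohr) and are converted only where positions cross that boundary.

#' Physical constants used by pmftools
#'
#' @description
#' `kB_kcal` is the Boltzmann (= molar gas) constant in kcal mol^-1 K^-1 as
#' used in the umbrella-sampling reweighting and the Eyring equation.
#' `kB_SI` and `h_SI` are the exact SI (CODATA) values entering the Eyring
#' prefactor k_B T / h. `bohr_to_angstrom` is the single length-conversion
#' constant applied at the cube-file boundary.
#'
#' @name constants
#' @keywords internal
NULL

kB_kcal <- 0.0019872041           # kcal mol^-1 K^-1
kB_SI <- 1.380649e-23             # J K^-1 (exact)
h_SI <- 6.62607015e-34            # J s (exact)
bohr_to_angstrom <- 0.529177210903
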