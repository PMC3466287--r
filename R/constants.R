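# CODATA 2018 exact/recommended values, SI units.
.const <- list(
  e     = 1.602176634e-19,   # elementary charge, C
  k_B   = 1.380649e-23,      # Boltzmann constant, J/K
  N_A   = 6.02214076e23,     # Avogadro constant, 1/mol
  eps_0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  hbar  = 1.054571817e-34,   # reduced Planck constant, J s
  m_e   = 9.1093837015e-31   # electron mass, kg
)

#' Physical constants used by the device model
#'
#' Returns the CODATA values of the fundamental constants the screening
#' model depends on (elementary charge, Boltzmann and Avogadro constants,
#' vacuum permittivity, reduced Planck constant, electron mass), all in SI
#' units.
#'
#' @return A named list with elements `e` (C), `k_B` (J/K), `N_A` (1/mol),
#'   `eps_0` (F/m), `hbar` (J s) and `m_e` (kg).
#' @examples
#' physical_constants()$e
#' @export
physical_constants <- function() {
  .const
}
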