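# Versioned physical-constant tables. Each set is transcribed from its original
# publication and checked in the test suite against an independent second
# transcription, so a typo in one copy cannot pass silently.

#' Physical and empirical constants used by the package
#'
#' A named list collecting the constant tables used throughout the flux and
#' solubility calculations:
#' \describe{
#'   \item{wg79_ch4_nmol}{Coefficients of the Wiesenburg & Guinasso (1979)
#'     atmospheric-equilibrium solubility equation for CH4, for concentrations
#'     in nmol L^-1 and gas mole fraction input.}
#'   \item{wp80_vapor}{Coefficients of the Weiss & Price (1980) saturation
#'     water-vapor pressure formula over seawater (pressure in atm).}
#'   \item{sc_ch4_w14}{Fourth-order Schmidt-number polynomial for CH4 in
#'     seawater (35 psu), valid over -2 to 40 degC (Wanninkhof 2014).}
#'   \item{molar_mass_ch4}{Molar mass of CH4, g mol^-1.}
#'   \item{earth_radius_m}{Mean Earth radius used for cell areas, m.}
#' }
#'
#' @format A named list; see Details.
#' @export
och4_constants <- list(
  version = "1.0",
  # ln C = ln f + A1 + A2*(100/T) + A3*ln(T/100) + A4*(T/100)
  #        + S * (B1 + B2*(T/100) + B3*(T/100)^2),  T in kelvin, C in nmol/L
  wg79_ch4_nmol = c(
    A1 = -415.2807, A2 = 596.8104, A3 = 379.2599, A4 = -62.0757,
    B1 = -0.059160, B2 = 0.032174, B3 = -0.0048198
  ),
  # ln e_w[atm] = c1 + c2*(100/T) + c3*ln(T/100) + c4*S
  wp80_vapor = c(c1 = 24.4543, c2 = -67.4509, c3 = -4.8489, c4 = -0.000544),
  # Sc = a + b*T + c*T^2 + d*T^3 + e*T^4, T in degC
  sc_ch4_w14 = c(a = 2101.2, b = -131.54, c = 4.4931, d = -0.08676,
                 e = 0.00070663),
  sc_valid_range = c(-2, 40),
  molar_mass_ch4 = 16.043,   # g mol^-1
  earth_radius_m = 6371000,
  atm_pa = 101325,
  gas_constant = 8.314462,   # J mol^-1 K^-1
  # Henry solubilities, mol m^-3 Pa^-1 at 298.15 K, with van't Hoff temperature
  # coefficients (K). "air" is the 0.79/0.21 N2/O2 lump used by the bubble model.
  henry = list(
    ch4 = c(h298 = 1.4e-5, vantHoff = 1750),
    n2  = c(h298 = 6.4e-6, vantHoff = 1300),
    o2  = c(h298 = 1.3e-5, vantHoff = 1500)
  ),
  # molecular diffusivities in seawater near 10 degC, m^2 s^-1
  diffusivity = c(ch4 = 1.2e-9, air = 1.35e-9)
)

# Registry of wind-speed gas transfer velocity algorithms. Each entry gives the
# k(u10) relation in cm hr^-1 at Sc = 660; gas_transfer_velocity() applies the
# (Sc/660)^-1/2 normalization and the unit conversion to m day^-1.
k_registry <- list(
  W14 = list(id = 1L, label = "quadratic, 0.251 u^2",
             fun = function(u) 0.251 * u^2),
  W92 = list(id = 2L, label = "quadratic, 0.31 u^2",
             fun = function(u) 0.31 * u^2),
  N00 = list(id = 3L, label = "hybrid, 0.222 u^2 + 0.333 u",
             fun = function(u) 0.222 * u^2 + 0.333 * u),
  M99 = list(id = 4L, label = "cubic, 0.0283 u^3",
             fun = function(u) 0.0283 * u^3)
)

#' List the available gas transfer velocity algorithms
#'
#' @return A data frame with algorithm id, name and functional form.
#' @export
k_algorithms <- function() {
  data.frame(
    id = vapply(k_registry, function(x) x$id, integer(1)),
    name = names(k_registry),
    form = vapply(k_registry, function(x) x$label, character(1)),
    row.names = NULL
  )
}
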