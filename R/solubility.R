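#' Methane solubility per unit atmospheric partial pressure
#'
#' Evaluates the Wiesenburg & Guinasso (1979) atmospheric-equilibrium
#' solubility function for methane,
#' \deqn{\ln C = \ln f + A_1 + A_2 (100/T) + A_3 \ln(T/100) + A_4 (T/100)
#'   + S [B_1 + B_2 (T/100) + B_3 (T/100)^2]}
#' with \eqn{T} in kelvin, returning the equilibrium concentration per unit
#' partial pressure so that \code{ch4_solubility(t, s) * p_ppb} is the
#' equilibrium dissolved CH4 in nM for an atmospheric partial pressure of
#' \code{p_ppb} ppb.
#'
#' @param temperature_C Water temperature, degrees Celsius, in \[-2, 40\].
#' @param salinity_psu Practical salinity, in \[0, 45\].
#' @return Solubility in nM per ppb. Vectorized over both arguments.
#' @examples
#' # equilibrium concentration at 25 degC, S = 35, pCH4 = 1850 ppb
#' ch4_solubility(25, 35) * 1850
#' @export
ch4_solubility <- function(temperature_C, salinity_psu) {
  n <- max(length(temperature_C), length(salinity_psu))
  temperature_C <- rep_len(temperature_C, n)
  salinity_psu <- rep_len(salinity_psu, n)
  if (any(!is.finite(temperature_C)) || any(!is.finite(salinity_psu)))
    stop("ch4_solubility: temperature and salinity must be finite")
  if (any(temperature_C < -2 | temperature_C > 40))
    stop("ch4_solubility: temperature outside valid range [-2, 40] degC")
  if (any(salinity_psu < 0 | salinity_psu > 45))
    stop("ch4_solubility: salinity outside valid range [0, 45] psu")
  k <- och4_constants$wg79_ch4_nmol
  TK <- temperature_C + 273.15
  lnC <- k[["A1"]] + k[["A2"]] * (100 / TK) + k[["A3"]] * log(TK / 100) +
    k[["A4"]] * (TK / 100) +
    salinity_psu * (k[["B1"]] + k[["B2"]] * (TK / 100) +
                      k[["B3"]] * (TK / 100)^2)
  # f = 1 ppb = 1e-9 mole fraction; C comes out in nmol/L
  exp(lnC) * 1e-9
}

#' Convert dry-air pCH4 to moist-air pCH4
#'
#' Applies the saturation water-vapor correction
#' \eqn{p^{moist} = p^{dry} (1 - e_w / P_{atm})}, with \eqn{e_w} the vapor
#' pressure over seawater from the Weiss & Price (1980) formula and total
#' pressure fixed at 1 atm.
#'
#' @param p_dry_ppb Dry-air partial pressure, ppb (> 0).
#' @param temperature_C Sea surface temperature, degC.
#' @param salinity_psu Surface salinity, psu.
#' @return Moist-air partial pressure, ppb.
#' @export
moist_pch4 <- function(p_dry_ppb, temperature_C, salinity_psu) {
  if (any(p_dry_ppb <= 0)) stop("moist_pch4: p_dry_ppb must be > 0")
  p_dry_ppb * (1 - vapor_pressure_atm(temperature_C, salinity_psu))
}

# Saturation water vapor pressure over seawater, atm (Weiss & Price 1980).
vapor_pressure_atm <- function(temperature_C, salinity_psu) {
  k <- och4_constants$wp80_vapor
  TK <- temperature_C + 273.15
  exp(k[["c1"]] + k[["c2"]] * (100 / TK) + k[["c3"]] * log(TK / 100) +
        k[["c4"]] * salinity_psu)
}

#' Schmidt number for methane in seawater
#'
#' Fourth-order polynomial in temperature for CH4 in seawater at 35 psu
#' (Wanninkhof 2014), used to normalize gas transfer velocities between gases.
#'
#' @param temperature_C Temperature in degC, within the polynomial's stated
#'   validity range of -2 to 40 degC.
#' @return Dimensionless Schmidt number.
#' @export
schmidt_ch4 <- function(temperature_C) {
  rng <- och4_constants$sc_valid_range
  if (any(!is.finite(temperature_C)))
    stop("schmidt_ch4: non-finite temperature")
  if (any(temperature_C < rng[1] | temperature_C > rng[2]))
    stop(sprintf("schmidt_ch4: temperature outside validity range [%g, %g]",
                 rng[1], rng[2]))
  k <- och4_constants$sc_ch4_w14
  t <- temperature_C
  k[["a"]] + k[["b"]] * t + k[["c"]] * t^2 + k[["d"]] * t^3 + k[["e"]] * t^4
}
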