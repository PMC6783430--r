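# Bubble-mediated (ebullitive) emissions. A minimal two-gas bubble model --
# CH4 plus a lumped N2/O2 "air" gas -- tracks diffusive gas exchange across
# the bubble wall, hydrostatic expansion and diameter-dependent rise velocity
# to give the transfer efficiency eps_tr(d0, z0): the fraction of released
# CH4 that survives to the surface. Integrated across the bubble size
# spectrum and the hypsometry of the seep depth interval it yields the
# flux-weighted mean efficiency used in
#   Sum(F_eb) = mean(eps_tr) * Sum(F_sf).

#' Water-column environment for the bubble model
#'
#' Constant-temperature water column with ambient dissolved CH4 ~ 0 and
#' air-saturated water; the defaults are characteristic shelf conditions.
#'
#' @param temperature_C Water temperature, degC.
#' @param pressure_atm_pa Atmospheric pressure at the surface, Pa.
#' @param density Seawater density, kg m^-3.
#' @param ambient_ch4 Ambient dissolved CH4, mol m^-3 (default 0).
#' @return Named list of environment parameters.
#' @export
bubble_environment <- function(temperature_C = 10, pressure_atm_pa = och4_constants$atm_pa,
                               density = 1027, ambient_ch4 = 0) {
  TK <- temperature_C + 273.15
  henry <- function(g) {
    h <- och4_constants$henry[[g]]
    h[["h298"]] * exp(h[["vantHoff"]] * (1 / TK - 1 / 298.15))
  }
  h_air <- 0.79 * henry("n2") + 0.21 * henry("o2")
  list(TK = TK, P0 = pressure_atm_pa, rho = density,
       H_ch4 = henry("ch4"), H_air = h_air,
       C_amb_ch4 = ambient_ch4,
       C_amb_air = h_air * pressure_atm_pa,  # air-saturated water column
       D_ch4 = och4_constants$diffusivity[["ch4"]],
       D_air = och4_constants$diffusivity[["air"]])
}

# Diameter-dependent terminal rise velocity (m s^-1) of a contaminated
# (dirty) bubble: Stokes-like for small radii, a 0.23 m/s plateau across the
# mm range, and a weak power law for large bubbles. Continuous at the
# junctions.
bubble_rise_velocity <- function(d_m) {
  r <- d_m / 2
  ifelse(r < 7e-4, 4474 * r^1.357,
         ifelse(r < 5.1e-3, 0.23, 4.202 * r^0.547))
}

# Penetration-theory mass transfer coefficient, m s^-1.
bubble_kl <- function(D, w, d) 2 / sqrt(pi) * sqrt(D * w / d)

#' Fraction of bubble CH4 surviving to the surface
#'
#' Integrates the bubble state (moles CH4, moles lumped background gas) in
#' depth from release to the surface. CH4 effluxes to the (undersaturated)
#' water while background gas invades the bubble from air-saturated water;
#' the bubble expands hydrostatically; rise velocity and mass transfer follow
#' the diameter. Returns the transfer efficiency
#' \code{eps_tr = moles CH4 at surface / moles released}, zero if the bubble
#' dissolves before surfacing.
#'
#' @param d0_mm Release diameter, mm, in \[0.5, 12\].
#' @param z0_m Release depth, m, in \[0, 500\].
#' @param environment See \code{\link{bubble_environment}}.
#' @param details If TRUE, return the full bookkeeping (moles released,
#'   surfaced, dissolved, final diameter) instead of the bare fraction.
#' @param rtol Relative integration tolerance.
#' @return Transfer efficiency in \[0, 1\] (or a list if \code{details}).
#' @export
bubble_rise <- function(d0_mm, z0_m, environment = bubble_environment(),
                        details = FALSE, rtol = 1e-8) {
  if (d0_mm < 0.5 || d0_mm > 12)
    stop("bubble_rise: release diameter outside [0.5, 12] mm")
  if (z0_m < 0 || z0_m > 500)
    stop("bubble_rise: release depth outside [0, 500] m")
  env <- environment
  Rg <- och4_constants$gas_constant
  d0 <- d0_mm * 1e-3
  P_rel <- env$P0 + env$rho * 9.81 * z0_m
  n0 <- P_rel * (pi / 6) * d0^3 / (Rg * env$TK)
  if (z0_m == 0) {
    if (details) return(list(eps_tr = 1, n0 = n0, n_surface = n0,
                             n_dissolved = 0, d_surface_mm = d0_mm))
    return(1)
  }
  d_min <- 2e-5  # below this the bubble is treated as fully dissolved

  geometry <- function(nc, na, z) {
    P <- env$P0 + env$rho * 9.81 * z
    V <- (nc + na) * Rg * env$TK / P
    list(P = P, d = (6 * V / pi)^(1 / 3))
  }
  rhs <- function(s, y, parms) {
    nc <- max(y[1], 0); na <- max(y[2], 0)
    g <- geometry(nc, na, z0_m - s)
    A <- pi * g$d^2
    w <- bubble_rise_velocity(g$d)
    xc <- nc / (nc + na)
    dnc <- -bubble_kl(env$D_ch4, w, g$d) * A *
      (env$H_ch4 * g$P * xc - env$C_amb_ch4) / w
    dna <- -bubble_kl(env$D_air, w, g$d) * A *
      (env$H_air * g$P * (1 - xc) - env$C_amb_air) / w
    list(c(dnc, dna, -dnc))
  }
  rootfun <- function(s, y, parms) {
    geometry(max(y[1], 0), max(y[2], 0), z0_m - s)$d - d_min
  }
  sol <- deSolve::ode(y = c(nc = n0, na = 0, ndis = 0),
                      times = c(0, z0_m), func = rhs, parms = NULL,
                      method = "lsodar", rootfunc = rootfun,
                      rtol = rtol, atol = n0 * 1e-12, hmax = 0.5)
  last <- sol[nrow(sol), ]
  dissolved_out <- last[["time"]] < z0_m  # root hit before the surface
  nc_surf <- if (dissolved_out) 0 else max(last[["nc"]], 0)
  n_dis <- if (dissolved_out) n0 else last[["ndis"]]
  eps <- min(max(nc_surf / n0, 0), 1)
  if (details) {
    g <- geometry(max(last[["nc"]], 0), max(last[["na"]], 0),
                  z0_m - last[["time"]])
    return(list(eps_tr = eps, n0 = n0, n_surface = nc_surf,
                n_dissolved = n_dis,
                d_surface_mm = if (dissolved_out) 0 else g$d * 1e3))
  }
  eps
}

#' Spectrum-weighted transfer efficiency at one release depth
#'
#' Volume-weighted average of \code{\link{bubble_rise}} across the bubble
#' size spectrum.
#'
#' @param spectrum Data frame \code{diameter_mm}, \code{volume_fraction}
#'   (weights must sum to 1).
#' @param z0_m Release depth, m.
#' @param environment Bubble environment.
#' @return Efficiency in \[0, 1\].
#' @export
spectrum_efficiency <- function(spectrum, z0_m,
                                environment = bubble_environment()) {
  if (abs(sum(spectrum$volume_fraction) - 1) > 1e-6)
    stop("spectrum_efficiency: volume fractions must sum to 1")
  eff <- vapply(spectrum$diameter_mm, bubble_rise, numeric(1),
                z0_m = z0_m, environment = environment)
  sum(spectrum$volume_fraction * eff)
}

#' Transfer-efficiency profile over release depth
#'
#' @param spectrum Bubble size spectrum.
#' @param depths_m Release depths, m.
#' @param environment Bubble environment.
#' @return Data frame \code{depth_m}, \code{efficiency}.
#' @export
efficiency_profile <- function(spectrum, depths_m = seq(0, 200, by = 5),
                               environment = bubble_environment()) {
  data.frame(depth_m = depths_m,
             efficiency = vapply(depths_m, function(z)
               spectrum_efficiency(spectrum, z, environment), numeric(1)))
}

#' Area-weighted mean transfer efficiency over a seep depth interval
#'
#' Assumes the seafloor flux is uniform per unit area within the interval and
#' averages the efficiency profile weighted by the ocean area at each depth
#' (hypsometry).
#'
#' @param profile Data frame \code{depth_m}, \code{efficiency} (e.g. from
#'   \code{\link{efficiency_profile}}).
#' @param hyps Hypsometry table from \code{\link{hypsometry}}.
#' @param interval Depth interval \code{c(lo, hi)}, m.
#' @return Flux-weighted mean efficiency in \[0, 1\].
#' @export
depth_averaged_efficiency <- function(profile, hyps, interval = c(0, 200)) {
  h <- hyps[hyps$depth_lo >= interval[1] & hyps$depth_hi <= interval[2] &
              is.finite(hyps$depth_hi), ]
  if (nrow(h) == 0 || sum(h$area_m2) == 0)
    stop("depth_averaged_efficiency: no seafloor area in the interval")
  eff <- stats::approx(profile$depth_m, profile$efficiency,
                       xout = h$depth_mid, rule = 2)$y
  sum(eff * h$area_m2) / sum(h$area_m2)
}

#' Ebullitive emissions to the atmosphere by interval arithmetic
#'
#' Applies \code{Sum(F_eb) = mean(eps_tr) * Sum(F_sf)} to a transfer
#' efficiency range and a seafloor flux (point value or range), assuming
#' uniform probability within the resulting interval.
#'
#' @param eps_range Transfer-efficiency bounds (fractions in \[0, 1\]).
#' @param sf_flux Seafloor ebullition, Tg yr^-1: a single value or a
#'   \code{c(lo, hi)} range.
#' @return List with the emission \code{interval} (Tg yr^-1), its
#'   \code{midpoint}, and the inputs.
#' @export
ebullitive_emissions <- function(eps_range, sf_flux) {
  if (any(eps_range < 0 | eps_range > 1))
    stop("ebullitive_emissions: efficiency must be within [0, 1]")
  if (any(sf_flux < 0))
    stop("ebullitive_emissions: seafloor flux must be non-negative")
  lo <- min(eps_range) * min(sf_flux)
  hi <- max(eps_range) * max(sf_flux)
  list(interval = c(lo, hi), midpoint = (lo + hi) / 2,
       eps_range = range(eps_range), sf_flux = range(sf_flux))
}

#' Total oceanic emissions: diffusive plus ebullitive
#'
#' Sums independent draws from the diffusive flux distribution (ensemble
#' samples) and the uniform ebullitive interval.
#'
#' @param diffusive_samples Global diffusive emissions samples, Tg yr^-1
#'   (e.g. \code{mc$draws$global}).
#' @param ebullitive Result of \code{\link{ebullitive_emissions}} (or a
#'   length-2 interval).
#' @param n Number of combined draws.
#' @param seed RNG seed.
#' @return List with \code{samples}, \code{mean} and the 10/50/90th
#'   percentiles of the total.
#' @export
total_emissions <- function(diffusive_samples, ebullitive, n = 10000,
                            seed = 1L) {
  if (length(diffusive_samples) == 0)
    stop("total_emissions: empty diffusive sample")
  iv <- if (is.list(ebullitive)) ebullitive$interval else range(ebullitive)
  tot <- with_seed(stage_seed(seed, "total_emissions"), {
    sample(diffusive_samples, n, replace = TRUE) +
      stats::runif(n, iv[1], iv[2])
  })
  list(samples = tot, mean = mean(tot),
       p10 = stats::quantile(tot, 0.10, names = FALSE),
       p50 = stats::quantile(tot, 0.50, names = FALSE),
       p90 = stats::quantile(tot, 0.90, names = FALSE))
}
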