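# Synthetic world generator. Produces every input the pipeline needs -- truth
# fields, cruise-track observations, atmospheric stations, wind/ice products
# and a bubble size spectrum -- with the statistical structure of the real
# observational system: a coastal power-law decline of dCH4 with seafloor
# depth, an open-ocean linear relation to net primary production, sparse
# ship-track sampling that densifies towards the coast, multi-product wind and
# ice spread, and a 2-8 mm bubble spectrum with ~4 mm volume-weighted mean.

#' Configuration for the synthetic world
#'
#' Collects every knob of the generator with defaults anchored to the binned
#' observational fits the generator is meant to emulate: coastal
#' \eqn{\Delta CH_4 = 69 z^{-0.8}} (nM, z in m) and open-ocean
#' \eqn{\Delta CH_4 = (0.3\,NPP + 14)/10^3} (NPP in mg C m^-2 d^-1), an
#' atmospheric dry pCH4 history rising from ~1650 to ~1850 ppb over 1980-2016,
#' five wind and three sea-ice products, and a bubble spectrum concentrated in
#' 2-8 mm diameters.
#'
#' @param resolution_deg Grid resolution, degrees.
#' @param lat_range,lon_range Basin extent, degrees.
#' @param n_tracks,obs_per_track Number of cruise tracks and records per track.
#' @param track_leg_obs Records per monthly leg of a track (long cruises span
#'   successive months).
#' @param noise_sigma Lognormal sigma of the mean-preserving multiplicative
#'   observation (measurement) noise applied to true dCH4 (dimensionless).
#' @param het_coastal,het_open Lognormal sigma of the mean-one heterogeneity
#'   of the truth field around its depth/NPP skeleton, in coastal and open
#'   waters (the order-of-magnitude scatter of the real dCH4 distribution
#'   around those relationships).
#' @param het_pred_frac,het_pred_frac_open Fraction of the heterogeneity
#'   log-variance carried by the secondary predictor fields (learnable by the
#'   mapping models) in coastal and open waters; the remainder is a
#'   short-scale free field no predictor explains.
#' @param coastal_A,coastal_b Coastal power-law amplitude (nM) and exponent
#'   (dimensionless, must be negative).
#' @param npp_slope,npp_intercept Open-ocean linear coefficients, in units of
#'   10^-3 nM per (mg C m^-2 d^-1) and 10^-3 nM.
#' @param blend_range Depth interval (m) over which the coastal and open-ocean
#'   truth are blended by a smooth ramp.
#' @param polar_offset_nM Amplitude of the Southern-Ocean-like undersaturation
#'   patch (subtracted south of 50 S with a 10-degree ramp).
#' @param atm_base_ppb,atm_trend_ppb_yr,atm_seasonal_ppb,atm_lat_grad
#'   Atmospheric station model: baseline at 1980, linear trend, seasonal
#'   amplitude, and meridional gradient (ppb per degree latitude).
#' @param years Observation/date window (inclusive).
#' @param n_wind,wind_perturb Number of wind products and the fractional scale
#'   of the smooth inter-product perturbations.
#' @param n_ice,ice_perturb,ice_lat Number of ice products, their perturbation
#'   scale, and the equatorward latitude limit of sea ice (degrees).
#' @param below_mld_frac Fraction of records deliberately placed below the
#'   mixed layer (to exercise the filter).
#' @param out_window_frac Fraction of records dated outside \code{years}.
#' @param missing_t_frac,missing_s_frac Fractions of records with missing
#'   temperature / salinity.
#' @param bubble_diameters_mm,bubble_meanlog,bubble_sdlog Bubble spectrum
#'   support (mm) and lognormal volume-weight parameters.
#' @param area_fractions Target seafloor area fractions of the four bathymetric
#'   region classes (near-shore, outer shelf, slope, open ocean).
#' @param depth_range Minimum and maximum seafloor depth, m.
#' @param seed Master RNG seed; every generator derives its own stream from it.
#' @return A validated list of class \code{och4_config}.
#' @export
synth_config <- function(resolution_deg = 0.5,
                         lat_range = c(-70, 70),
                         lon_range = c(0, 40),
                         n_tracks = 8,
                         obs_per_track = 300,
                         track_leg_obs = 100,
                         noise_sigma = 0.3,
                         het_coastal = 1.25,
                         het_open = 0.6,
                         het_pred_frac = 0.5,
                         het_pred_frac_open = 0.15,
                         coastal_A = 69,
                         coastal_b = -0.8,
                         npp_slope = 0.3,
                         npp_intercept = 14,
                         blend_range = c(1500, 2500),
                         polar_offset_nM = 0.08,
                         atm_base_ppb = 1650,
                         atm_trend_ppb_yr = 200 / 36,
                         atm_seasonal_ppb = 10,
                         atm_lat_grad = 0.5,
                         years = c(1980, 2016),
                         n_wind = 5,
                         wind_perturb = 0.08,
                         n_ice = 3,
                         ice_perturb = 0.15,
                         ice_lat = 60,
                         below_mld_frac = 0.10,
                         out_window_frac = 0.03,
                         missing_t_frac = 0.02,
                         missing_s_frac = 0.05,
                         bubble_diameters_mm = seq(1, 10, by = 0.5),
                         bubble_meanlog = log(4),
                         bubble_sdlog = 0.22,
                         area_fractions = c(nearshore = 0.03, shelf = 0.04,
                                            slope = 0.08, open = 0.85),
                         depth_range = c(2, 4500),
                         seed = 42L) {
  cfg <- as.list(environment())
  if (cfg$resolution_deg <= 0) stop("synth_config: resolution must be > 0")
  if (cfg$noise_sigma < 0) stop("synth_config: noise_sigma must be >= 0")
  if (cfg$coastal_b >= 0)
    stop("synth_config: coastal exponent must be negative (dCH4 declines with depth)")
  if (abs(sum(cfg$area_fractions) - 1) > 1e-8)
    stop("synth_config: area_fractions must sum to 1")
  if (cfg$n_wind < 1 || cfg$n_ice < 1) stop("synth_config: need >= 1 product")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "och4_config"
  cfg
}

# Deterministic per-stage seed derived from the master seed by hashing the
# stage name, so one stage's draw count never perturbs another's stream.
stage_seed <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * (seq_along(u)^2 + 17)) %% 97651
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth random surface on the grid: a truncated Fourier series with seeded
# coefficients, normalized to zero mean and unit sd. The wavenumber cap kmax
# sets the correlation scale (wavelengths >= basin size / kmax). Because the
# field is a function of continuous position, regridding the same seed at a
# different resolution samples the same surface. Used for inter-product
# perturbations, predictor texture, and the truth heterogeneity.
smooth_field <- function(grid, seed, n_modes = 6, kmax = 3) {
  with_seed(seed, {
    lx <- diff(grid$lon_range); ly <- diff(grid$lat_range)
    f <- numeric(grid$n_cell)
    for (i in seq_len(n_modes)) {
      p <- sample(seq_len(kmax), 1); q <- sample(seq_len(kmax), 1)
      a <- stats::rnorm(1); ph <- stats::runif(1, 0, 2 * pi)
      f <- f + a * sin(2 * pi * (p * (grid$lon - grid$lon_range[1]) / lx +
                                   q * (grid$lat - grid$lat_range[1]) / ly) + ph)
    }
    (f - mean(f)) / stats::sd(f)
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
ramp <- function(x) clamp(x, 0, 1)

# Stationary short-scale random surface: white noise generated on a padded
# grid, smoothed by a separable Gaussian kernel, then cropped -- so the local
# variance is uniform everywhere including the basin walls (an exponential
# link would otherwise turn any edge variance inflation into a systematic
# near-shore bias). Standardized to zero mean, unit sd.
smooth_noise_field <- function(grid, seed, sigma_cells = 1.0) {
  half <- max(2L, ceiling(3 * sigma_cells))
  kern <- stats::dnorm(-half:half, 0, sigma_cells)
  kern <- kern / sum(kern)
  conv_valid <- function(v) {
    # stats::filter pads with NA; the padded margin keeps the interior valid
    as.numeric(stats::filter(v, kern, sides = 2))
  }
  with_seed(seed, {
    nr <- grid$nlon + 2 * half; nc <- grid$nlat + 2 * half
    M <- matrix(stats::rnorm(nr * nc), nr, nc)
    M <- apply(M, 2, conv_valid)
    M <- t(apply(M, 1, conv_valid))
    M <- M[(half + 1):(half + grid$nlon), (half + 1):(half + grid$nlat)]
    f <- as.numeric(M)
    (f - mean(f)) / stats::sd(f)
  })
}

#' Synthetic seafloor bathymetry for a closed basin
#'
#' Depth increases monotonically (on average) with distance from the nearest
#' basin edge, which plays the role of the coastline. The depth profile is the
#' inverse of a target hypsometric curve, so the four bathymetric region
#' classes occupy prescribed area fractions (defaults emulate the real ocean:
#' ~3% near-shore, ~4% outer shelf, ~8% slope, ~85% open ocean).
#'
#' @param grid An \code{och4_grid}.
#' @param config An \code{och4_config}.
#' @return Numeric vector of seafloor depths (m, positive down) per cell.
#' @export
make_bathymetry <- function(grid, config) {
  d_edge <- pmin(grid$lat - grid$lat_range[1], grid$lat_range[2] - grid$lat,
                 grid$lon - grid$lon_range[1], grid$lon_range[2] - grid$lon)
  # break ties between cells in the same edge-distance ring
  jit <- 0.35 * grid$resolution *
    smooth_field(grid, stage_seed(config$seed, "bathy_jitter"))
  ord <- order(d_edge + jit)
  t <- numeric(grid$n_cell)
  t[ord] <- (cumsum(grid$area_m2[ord]) - grid$area_m2[ord] / 2) /
    sum(grid$area_m2)
  f <- config$area_fractions
  qbreaks <- cumsum(c(0, f))
  dbreaks <- c(config$depth_range[1], region_breaks[2:4], config$depth_range[2])
  depth <- stats::approx(qbreaks, dbreaks, xout = t, rule = 2)$y
  ripple <- 1 + 0.03 * smooth_field(grid, stage_seed(config$seed, "bathy_ripple"))
  pmax(depth * ripple, 1)
}

# Monthly seasonal shape: signed hemispheric amplitude so the two hemispheres
# are half a year out of phase and the tropics are nearly aseasonal.
seasonal_cycle <- function(lat, months, peak_month, amp) {
  outer(amp * tanh(lat / 25), cos(2 * pi * (months - peak_month) / 12))
}

#' Gridded predictor climatologies for the synthetic world
#'
#' Generates sea surface temperature and salinity, net primary production
#' (highest in the tropics, lowest at the poles, enhanced near the coast),
#' POC export, surface phosphate, shallow subsurface oxygen, a sediment
#' hydrate-inventory proxy peaking on the slope, an independent DMS field, and
#' a mixed layer depth climatology. Monthly fields are n_cell x 12 matrices.
#'
#' @param grid An \code{och4_grid}.
#' @param depth Seafloor depth per cell, m.
#' @param config An \code{och4_config}.
#' @return Named list of predictor fields.
#' @export
make_predictors <- function(grid, depth, config) {
  m <- 1:12
  latr <- grid$lat * pi / 180
  seed <- function(s) stage_seed(config$seed, s)

  # Latent smooth anomaly surfaces shared between the secondary predictors
  # and the predictor-linked part of the truth heterogeneity (see
  # make_truth_field); positional only, so they carry no depth/NPP signal.
  L1 <- smooth_field(grid, stage_seed(config$seed, "latent1"), kmax = 8)
  L2 <- smooth_field(grid, stage_seed(config$seed, "latent2"), kmax = 8)
  L3 <- smooth_field(grid, stage_seed(config$seed, "latent3"), kmax = 8)

  sst <- clamp(-1.5 + 29 * pmax(cos(latr), 0)^1.8 +
                 seasonal_cycle(grid$lat, m, 2.5, 3.5), -1.9, 31)
  sss <- clamp(35 + 1.0 * cos(3 * latr) + 0.4 * L3, 30, 38)
  sss <- matrix(sss, grid$n_cell, 12)

  npp_lat <- 120 + 780 * pmax(cos(latr), 0)^3
  npp_coast <- 1 + 1.2 * exp(-depth / 400)
  npp_lon <- 1 + 0.15 * smooth_field(grid, seed("npp"))
  npp <- pmax(npp_lat * npp_coast * npp_lon *
                (1 + seasonal_cycle(grid$lat, m, 4, 0.3)), 5)

  er <- 0.08 + 0.22 * (abs(grid$lat) / 70)
  poc <- npp * er  # recycles npp's monthly structure

  po4 <- pmax(0.15 + 1.6 * (abs(grid$lat) / 70)^2 + 0.25 * L1, 0.02)
  po4 <- matrix(po4, grid$n_cell, 12)

  o2 <- clamp(365 - 6.2 * rowMeans(sst) + 8 * L2, 100, 420)
  o2 <- matrix(o2, grid$n_cell, 12)

  hydrate <- pmax(exp(-(log10(depth) - log10(700))^2 / (2 * 0.35^2)) *
                    (1 + 0.3 * smooth_field(grid, seed("hydrate"))), 0)
  hydrate <- matrix(hydrate, grid$n_cell, 12)

  dms <- matrix(pmax(2 + 1.2 * smooth_field(grid, seed("dms")), 0.05),
                grid$n_cell, 12)

  mld <- pmax(25 + 0.25 * abs(grid$lat) +
                seasonal_cycle(grid$lat, m, 1.5, 15), 8)

  list(sst = sst, sss = sss, npp = npp, poc = poc, po4 = po4, o2 = o2,
       hydrate = hydrate, dms = dms, mld = mld)
}

#' True dCH4 field of the synthetic world
#'
#' Coastal power law \code{A * depth^b} where the seafloor is shallow, an
#' open-ocean linear NPP relation where it is deep, blended continuously over
#' \code{config$blend_range}, with an optional Southern-Ocean-like
#' undersaturation patch south of 50 S. The truth field carries no seasonal
#' cycle by construction.
#'
#' @param config An \code{och4_config}.
#' @param grid An \code{och4_grid}.
#' @param depth Seafloor depth per cell, m.
#' @param predictors Output of \code{\link{make_predictors}}.
#' @return Vector of true dCH4 (nM) per cell.
#' @export
make_truth_field <- function(config, grid, depth, predictors) {
  npp_ann <- rowMeans(predictors$npp)
  w <- ramp((depth - config$blend_range[1]) / diff(config$blend_range))
  coastal <- config$coastal_A * depth^config$coastal_b
  open <- (config$npp_slope * npp_ann + config$npp_intercept) / 1e3
  skeleton <- (1 - w) * coastal + w * open
  # Mean-one lognormal heterogeneity around the skeleton: the real dCH4 field
  # scatters by orders of magnitude around its depth/NPP relationships. A
  # fraction (het_pred_frac) of that log-variance is carried by the other
  # predictor fields -- the premise of multi-predictor statistical mapping --
  # and the rest is a short-scale free field no predictor explains. Mean-one
  # by construction, so binned refits still recover the skeleton
  # coefficients.
  sig <- (1 - w) * config$het_coastal + w * config$het_open
  polar <- config$polar_offset_nM * ramp((-50 - grid$lat) / 10)
  if (all(sig == 0)) return(skeleton - polar)
  std <- function(x) (x - mean(x)) / stats::sd(x)
  # Predictor-linked part: the latent anomaly surfaces that also form the
  # texture of PO4, O2 and SSS (see make_predictors), so mapping models can
  # recover it from those predictors. Free part: a short-scale field no
  # predictor explains. Both are positional only; residualizing against the
  # skeleton drivers removes incidental correlation so the heterogeneity
  # scatters the field around the generating relationships without tilting
  # them.
  L1 <- smooth_field(grid, stage_seed(config$seed, "latent1"), kmax = 8)
  L2 <- smooth_field(grid, stage_seed(config$seed, "latent2"), kmax = 8)
  L3 <- smooth_field(grid, stage_seed(config$seed, "latent3"), kmax = 8)
  eta_pred <- std(0.6 * L1 - 0.5 * L2 + 0.45 * L3 + 0.4 * L1 * L2)
  eta_free <- smooth_noise_field(grid, stage_seed(config$seed, "heterogeneity"))
  # predictor-linked share: substantial in coastal waters, small in the open
  # ocean (where secondary predictors add little explanatory power)
  pfz <- (1 - w) * config$het_pred_frac + w * config$het_pred_frac_open
  eta <- sqrt(pfz) * eta_pred + sqrt(1 - pfz) * eta_free
  coastal_cells <- factor(depth < 2000)
  # linear in log-depth (the coastal relation is a log-log line), cubic in
  # NPP (the open-ocean relation is fitted on linearly binned means, so
  # low-order curvature in the realized field would masquerade as slope)
  pdeg <- function(x) max(1, min(3, length(unique(x)) - 1))
  lz <- log10(depth)
  pn <- stats::poly(npp_ann, pdeg(npp_ann))
  fml <- if (nlevels(droplevels(coastal_cells)) > 1)
    eta ~ (lz + pn) * coastal_cells
  else eta ~ lz + pn
  eta <- std(as.numeric(stats::residuals(stats::lm(fml))))
  skeleton * exp(sig * eta - sig^2 / 2) - polar
}

#' Assemble the complete synthetic world
#'
#' Convenience constructor running the full generator chain: grid, bathymetry,
#' region mask, predictors, truth field, atmospheric stations, wind and ice
#' products, and bubble spectrum. Fully deterministic for a fixed
#' \code{config$seed}.
#'
#' @param config An \code{och4_config} (default \code{synth_config()}).
#' @return An object of class \code{och4_world}.
#' @export
make_world <- function(config = synth_config()) {
  grid <- make_grid(config$resolution_deg, config$lat_range, config$lon_range)
  depth <- make_bathymetry(grid, config)
  predictors <- make_predictors(grid, depth, config)
  truth <- make_truth_field(config, grid, depth, predictors)
  w <- list(
    config = config, grid = grid, depth = depth,
    region = region_mask(depth),
    predictors = predictors,
    truth_dch4 = truth,
    stations = make_atm_stations(config),
    wind_products = make_wind_products(config, grid),
    ice_products = make_ice_products(config, grid),
    spectrum = make_bubble_spectrum(config)
  )
  class(w) <- "och4_world"
  w
}

#' @export
print.och4_world <- function(x, ...) {
  cat("och4_world\n")
  print(x$grid)
  tab <- tapply(x$grid$area_m2, x$region, sum) / sum(x$grid$area_m2)
  cat("  region area fractions:",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab), collapse = ", "), "\n")
  cat(sprintf("  truth dCH4: %.3g to %.3g nM; %d wind, %d ice products\n",
              min(x$truth_dch4), max(x$truth_dch4),
              length(x$wind_products), length(x$ice_products)))
  invisible(x)
}

#' Atmospheric station dry pCH4 time series
#'
#' A small network of monitoring stations with a meridional gradient, a linear
#' trend carrying the configured ~1650 to ~1850 ppb rise over 1980-2016, and a
#' seasonal cycle that is half a year out of phase between hemispheres.
#'
#' @param config An \code{och4_config}.
#' @return Data frame: \code{station_id, lat, lon, year, month, pch4_ppb}.
#' @export
make_atm_stations <- function(config) {
  lat_s <- c(-65, -30, 0, 30, 65)
  lat_s <- lat_s[lat_s >= config$lat_range[1] & lat_s <= config$lat_range[2]]
  if (length(lat_s) < 3) lat_s <- seq(config$lat_range[1] + 5,
                                      config$lat_range[2] - 5, length.out = 3)
  lon_s <- rep(mean(config$lon_range), length(lat_s))
  yrs <- seq(config$years[1], config$years[2])
  g <- expand.grid(month = 1:12, year = yrs, station = seq_along(lat_s))
  lat <- lat_s[g$station]
  tfrac <- (g$year - config$years[1]) + (g$month - 0.5) / 12
  seas <- config$atm_seasonal_ppb * tanh(lat / 25) *
    sin(2 * pi * (g$month - 0.5) / 12 + pi / 3)
  p <- config$atm_base_ppb + config$atm_trend_ppb_yr * tfrac +
    config$atm_lat_grad * lat + seas
  data.frame(station_id = paste0("ST", g$station), lat = lat,
             lon = lon_s[g$station], year = g$year, month = g$month,
             pch4_ppb = p)
}

#' Daily wind-speed products
#'
#' Five (configurable) products sharing one base field -- a meridional profile
#' with westerly maxima, a weak seasonal cycle, and a shared synoptic AR(1)
#' day-to-day component -- each modulated by its own smooth spatial
#' perturbation of fractional scale \code{wind_perturb}. Product 1 is the
#' unperturbed base. Winds are truncated at zero.
#'
#' @param config An \code{och4_config}.
#' @param grid An \code{och4_grid}.
#' @return List of product descriptors understood by \code{\link{wind_daily}}.
#' @export
make_wind_products <- function(config, grid) {
  synoptic <- with_seed(stage_seed(config$seed, "wind_synoptic"), {
    as.numeric(stats::arima.sim(list(ar = 0.8), n = 365,
                                sd = 1.2 * sqrt(1 - 0.8^2)))
  })
  lapply(seq_len(config$n_wind), function(p) {
    bias <- if (p == 1) numeric(grid$n_cell) else
      smooth_field(grid, stage_seed(config$seed, paste0("wind_prod", p)))
    list(id = p, synoptic = synoptic,
         perturb = config$wind_perturb, bias_field = bias)
  })
}

#' Materialize a wind product as a daily field
#'
#' @param world An \code{och4_world}.
#' @param product_id Wind product index.
#' @param days Days of year (default all 365).
#' @return Matrix n_cell x length(days) of U10 wind speed, m s^-1 (>= 0).
#' @export
wind_daily <- function(world, product_id, days = 1:365) {
  prod <- world$wind_products[[product_id]]
  grid <- world$grid
  base_lat <- 4 + 4.5 * exp(-((abs(grid$lat) - 50) / 18)^2) +
    1.5 * exp(-((abs(grid$lat) - 10) / 8)^2)
  seas <- outer(0.8 * tanh(grid$lat / 30), cos(2 * pi * (days - 15) / 365))
  u <- (base_lat + seas +
          matrix(prod$synoptic[days], grid$n_cell, length(days), byrow = TRUE)) *
    (1 + prod$perturb * prod$bias_field)
  pmax(u, 0)
}

#' Monthly sea-ice fraction products
#'
#' Ice appears only poleward of \code{config$ice_lat}, with a seasonal cycle
#' peaking in late winter of each hemisphere; each product applies its own
#' smooth perturbation before clamping to \[0, 1\].
#'
#' @param config An \code{och4_config}.
#' @param grid An \code{och4_grid}.
#' @return List of n_cell x 12 matrices of ice fraction.
#' @export
make_ice_products <- function(config, grid) {
  m <- 1:12
  north <- ramp((grid$lat - config$ice_lat) / 8)
  south <- ramp((-grid$lat - config$ice_lat) / 8)
  seas_n <- 0.55 + 0.45 * cos(2 * pi * (m - 2.5) / 12)
  seas_s <- 0.55 + 0.45 * cos(2 * pi * (m - 8.5) / 12)
  base <- outer(north, seas_n) + outer(south, seas_s)
  lapply(seq_len(config$n_ice), function(p) {
    pert <- if (p == 1) 0 else
      config$ice_perturb *
        smooth_field(grid, stage_seed(config$seed, paste0("ice_prod", p)))
    clamp(base * (1 + pert), 0, 1)
  })
}

#' Discrete bubble size spectrum
#'
#' Volume-weighted diameter distribution on \[1, 10\] mm with lognormal
#' weights; under the defaults at least 99% of the bubble volume lies between
#' 2 and 8 mm and the volume-weighted mean diameter is ~4 mm.
#'
#' @param config An \code{och4_config}.
#' @return Data frame \code{diameter_mm}, \code{volume_fraction} (sums to 1).
#' @export
make_bubble_spectrum <- function(config) {
  d <- config$bubble_diameters_mm
  w <- stats::dlnorm(d, meanlog = config$bubble_meanlog,
                     sdlog = config$bubble_sdlog)
  data.frame(diameter_mm = d, volume_fraction = w / sum(w))
}

#' Sample shipboard observations along synthetic cruise tracks
#'
#' Tracks are persistent random walks entering the basin from a random edge,
#' so sampling density rises towards the coast, as in the real database. Each
#' record carries \code{[CH4] = S(T,S) p_CH4^moist + dCH4_true * noise} with
#' mean-preserving lognormal noise, plus position, date, sampling depth,
#' temperature and salinity. Configured fractions of records are placed below
#' the mixed layer, dated outside the analysis window, or stripped of
#' temperature/salinity, to exercise the downstream filters. Extra columns
#' (\code{dch4_true}, \code{cell}, flags) support testing and are not part of
#' the on-disk schema.
#'
#' @param world An \code{och4_world}.
#' @param config Optional config override (defaults to \code{world$config}).
#' @return Data frame of observation records.
#' @export
sample_observations <- function(world, config = world$config) {
  grid <- world$grid
  n_obs <- config$n_tracks * config$obs_per_track
  with_seed(stage_seed(config$seed, "observations"), {
    lat <- numeric(n_obs); lon <- numeric(n_obs)
    year <- integer(n_obs); month <- integer(n_obs)
    i <- 1L
    for (tr in seq_len(config$n_tracks)) {
      side <- sample(1:4, 1)
      pos <- c(stats::runif(1, grid$lon_range[1], grid$lon_range[2]),
               stats::runif(1, grid$lat_range[1], grid$lat_range[2]))
      if (side == 1) pos[1] <- grid$lon_range[1] + stats::runif(1, 0, 2)
      if (side == 2) pos[1] <- grid$lon_range[2] - stats::runif(1, 0, 2)
      if (side == 3) pos[2] <- grid$lat_range[1] + stats::runif(1, 0, 2)
      if (side == 4) pos[2] <- grid$lat_range[2] - stats::runif(1, 0, 2)
      ctr <- c(mean(grid$lon_range), mean(grid$lat_range))
      heading <- atan2(ctr[2] - pos[2], ctr[1] - pos[1]) +
        stats::rnorm(1, 0, 0.3)
      yr <- sample(seq(config$years[1], config$years[2] - 1L), 1)
      mo <- sample(1:12, 1)
      step <- 1.2 * grid$resolution
      for (k in seq_len(config$obs_per_track)) {
        lat[i] <- pos[2]; lon[i] <- pos[1]
        # long cruises span successive calendar months (one leg per
        # track_leg_obs records), rolling over the year end
        mo_k <- mo + (k - 1L) %/% config$track_leg_obs
        year[i] <- yr + (mo_k - 1L) %/% 12L
        month[i] <- (mo_k - 1L) %% 12L + 1L
        i <- i + 1L
        heading <- heading + stats::rnorm(1, 0, 0.25)
        pos <- pos + step * c(cos(heading), sin(heading))
        # reflect off the basin walls
        if (pos[1] < grid$lon_range[1] || pos[1] > grid$lon_range[2]) {
          heading <- pi - heading
          pos[1] <- clamp(pos[1], grid$lon_range[1], grid$lon_range[2])
        }
        if (pos[2] < grid$lat_range[1] || pos[2] > grid$lat_range[2]) {
          heading <- -heading
          pos[2] <- clamp(pos[2], grid$lat_range[1], grid$lat_range[2])
        }
      }
    }
    cell <- cell_index(grid, lat, lon)
    day <- sample(1:28, n_obs, replace = TRUE)

    # deliberately out-of-window dates
    out_win <- stats::runif(n_obs) < config$out_window_frac
    year[out_win] <- sample(c(seq(config$years[1] - 5, config$years[1] - 1),
                              seq(config$years[2] + 1, config$years[2] + 3)),
                            sum(out_win), replace = TRUE)

    mld <- world$predictors$mld[cbind(cell, month)]
    depth_m <- stats::runif(n_obs, 0.2, 0.9) * mld
    below <- stats::runif(n_obs) < config$below_mld_frac
    depth_m[below] <- mld[below] * stats::runif(sum(below), 1.2, 3)

    temperature_C <- world$predictors$sst[cbind(cell, month)]
    salinity_psu <- world$predictors$sss[cbind(cell, month)]

    noise <- if (config$noise_sigma > 0)
      stats::rlnorm(n_obs, meanlog = -config$noise_sigma^2 / 2,
                    sdlog = config$noise_sigma) else rep(1, n_obs)
    dch4_true <- world$truth_dch4[cell]
    dch4_obs <- dch4_true * noise

    # out-of-window records still need a generated concentration; clamp the
    # year into the station window for the generating atmosphere only
    yr_gen <- clamp(year, config$years[1], config$years[2])
    p_dry <- krige_atmospheric(world$stations, lat, lon, yr_gen, month)
    p_moist <- moist_pch4(p_dry, temperature_C, salinity_psu)
    ch4_nM <- ch4_solubility(temperature_C, salinity_psu) * p_moist + dch4_obs

    source <- rep("synthetic", n_obs)
    miss_t <- stats::runif(n_obs) < config$missing_t_frac
    temperature_C[miss_t] <- NA_real_
    source[miss_t] <- "synthetic_noT"
    miss_s <- !miss_t & stats::runif(n_obs) < config$missing_s_frac
    salinity_psu[miss_s] <- NA_real_

    data.frame(
      lat = lat, lon = lon,
      date = as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
      depth_m = depth_m, temperature_C = temperature_C,
      salinity_psu = salinity_psu, ch4_nM = ch4_nM,
      source = source, cell = cell, year = year, month = month,
      dch4_true = dch4_true, below_mld = below, out_window = out_win
    )
  })
}

#' Sample point values of the generating relationships
#'
#' Draws cells uniformly from the requested bathymetric subset and returns
#' their depth, NPP and noisy true dCH4 -- the direct (mapping-free) input for
#' the power-law and NPP parameter-recovery fits.
#'
#' @param world An \code{och4_world}.
#' @param n Number of points.
#' @param region \code{"coastal"} (seafloor < 2000 m) or \code{"open"}.
#' @param seed RNG seed.
#' @param noise Apply the configured multiplicative lognormal noise?
#' @return Data frame \code{depth_m}, \code{npp}, \code{dch4_nM}.
#' @export
sample_truth_points <- function(world, n, region = c("coastal", "open"),
                                seed = world$config$seed, noise = TRUE) {
  region <- match.arg(region)
  idx <- if (region == "coastal") which(world$depth < 2000)
         else which(world$depth >= 2000)
  with_seed(stage_seed(seed, paste0("truth_points_", region)), {
    cells <- sample(idx, n, replace = TRUE)
    f <- if (noise && world$config$noise_sigma > 0)
      stats::rlnorm(n, -world$config$noise_sigma^2 / 2,
                    world$config$noise_sigma) else rep(1, n)
    data.frame(depth_m = world$depth[cells],
               npp = rowMeans(world$predictors$npp)[cells],
               dch4_nM = world$truth_dch4[cells] * f)
  })
}
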