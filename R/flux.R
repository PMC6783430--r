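# Diffusive air-sea flux: F = (1 - eps_ice * f_ice) * k * dCH4, computed at
# daily resolution (monthly fields linearly interpolated to days with
# wrap-around), integrated to annual regional and global emissions, with
# wind-product, ice-product, k-algorithm and eps_ice uncertainty propagated by
# Monte Carlo.

#' Gas transfer velocity from wind speed
#'
#' Evaluates one of four published wind-speed relations (see
#' \code{\link{k_algorithms}}), normalized to the methane Schmidt number by
#' \code{(Sc/660)^(-1/2)} and converted from cm hr^-1 to m day^-1.
#'
#' @param u10 Wind speed at 10 m, m s^-1 (>= 0).
#' @param sc Schmidt number (e.g. \code{\link{schmidt_ch4}}).
#' @param algorithm Algorithm id (1-4) or name.
#' @return k in m day^-1, same shape as \code{u10}.
#' @export
gas_transfer_velocity <- function(u10, sc, algorithm = 1L) {
  if (any(u10 < 0)) stop("gas_transfer_velocity: wind speed must be >= 0")
  if (is.character(algorithm)) {
    if (!algorithm %in% names(k_registry))
      stop("gas_transfer_velocity: unknown algorithm ", algorithm)
    alg <- k_registry[[algorithm]]
  } else {
    ids <- vapply(k_registry, function(x) x$id, integer(1))
    if (!algorithm %in% ids)
      stop("gas_transfer_velocity: unknown algorithm id ", algorithm)
    alg <- k_registry[[which(ids == algorithm)]]
  }
  k_cmhr <- alg$fun(u10) * (sc / 660)^(-0.5)
  k_cmhr * 0.24  # cm hr^-1 -> m day^-1
}

# Linear month-center to day-of-year interpolation weights with wrap-around:
# W[d, m] is the weight of month m on day d; each row has two nonzero weights
# summing to 1.
month_day_weights <- function() {
  mlen <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  centers <- cumsum(mlen) - mlen / 2
  W <- matrix(0, 365, 12)
  for (d in 1:365) {
    if (d < centers[1]) {
      w <- (d + 365 - centers[12]) / (centers[1] + 365 - centers[12])
      W[d, 12] <- 1 - w; W[d, 1] <- w
    } else if (d >= centers[12]) {
      w <- (d - centers[12]) / (centers[1] + 365 - centers[12])
      W[d, 12] <- 1 - w; W[d, 1] <- w
    } else {
      m <- findInterval(d, centers)
      w <- (d - centers[m]) / (centers[m + 1] - centers[m])
      W[d, m] <- 1 - w; W[d, m + 1] <- w
    }
  }
  W
}

#' Daily diffusive CH4 flux field for one transfer draw
#'
#' Applies \code{F = (1 - eps_ice f_ice) k dCH4} cellwise for one day of year,
#' with monthly dCH4, ice fraction and SST linearly interpolated to the day.
#' Negative fluxes (uptake into undersaturated water) are allowed.
#'
#' @param world An \code{och4_world} providing wind/ice products and SST.
#' @param dch4_map Monthly dCH4 map, n_cell x 12 (nM).
#' @param day Day of year (1-365).
#' @param wind_id,ice_id,k_id Product/algorithm selection.
#' @param eps_ice Ice gas-exchange blocking efficiency in \[0, 1\].
#' @return Flux per cell, mmol m^-2 day^-1.
#' @export
daily_flux <- function(world, dch4_map, day, wind_id = 1L, ice_id = 1L,
                       k_id = 1L, eps_ice = 1) {
  grid <- world$grid
  if (!is.matrix(dch4_map) || nrow(dch4_map) != grid$n_cell ||
      ncol(dch4_map) != 12)
    stop("daily_flux: dch4 map does not match the grid (need n_cell x 12)")
  W <- month_day_weights()[day, ]
  dch4_d <- as.numeric(dch4_map %*% W)
  fice_d <- as.numeric(world$ice_products[[ice_id]] %*% W)
  sst_d <- as.numeric(world$predictors$sst %*% W)
  u <- wind_daily(world, wind_id, days = day)[, 1]
  k <- gas_transfer_velocity(u, schmidt_ch4(sst_d), k_id)
  (1 - eps_ice * fice_d) * k * dch4_d * 1e-3
}

#' Integrate flux fields to annual regional and global emissions
#'
#' @param flux Either an n_cell vector of annual flux (mmol m^-2 yr^-1) or an
#'   n_cell x n_day matrix of daily fluxes (mmol m^-2 day^-1) which is summed
#'   over days.
#' @param area_m2 Cell areas.
#' @param region Region factor (\code{\link{region_mask}}).
#' @return Named vector of emissions in Tg CH4 yr^-1: one entry per region
#'   class plus \code{global} (their exact sum).
#' @export
integrate_annual <- function(flux, area_m2, region) {
  annual <- if (is.matrix(flux)) rowSums(flux) else flux
  gram_per_mmol <- och4_constants$molar_mass_ch4 * 1e-3
  tg <- annual * area_m2 * gram_per_mmol / 1e12
  by_region <- tapply(tg, region, sum, default = 0)
  out <- c(by_region[region_levels], global = sum(by_region))
  names(out) <- c(region_levels, "global")
  out
}

#' Precompute annual transfer fields for all product permutations
#'
#' The annual flux is linear in the monthly dCH4 map and in eps_ice:
#' summing \code{k_d (1 - eps f_d) dCH4_d} over days with day-interpolated
#' dCH4 equals \code{sum_m dCH4_m (A_m - eps B_m)} with
#' \code{A = sum_d W_dm k_d} and \code{B = sum_d W_dm k_d f_d}. This function
#' computes A for every wind x k-algorithm pair and B for every
#' wind x ice x k-algorithm permutation, after which each Monte-Carlo draw
#' costs only O(n_cell x 12).
#'
#' @param world An \code{och4_world}.
#' @return List with arrays \code{A[[wind]][[k]]} and
#'   \code{B[[wind]][[ice]][[k]]} (n_cell x 12 each).
#' @export
transfer_terms <- function(world) {
  W <- month_day_weights()
  n_k <- length(k_registry)
  sst_d <- world$predictors$sst %*% t(W)
  scfac <- (schmidt_ch4(clamp(sst_d, -1.9, 39.9)) / 660)^(-0.5)
  fice_d <- lapply(world$ice_products, function(f) f %*% t(W))
  A <- vector("list", length(world$wind_products))
  B <- vector("list", length(world$wind_products))
  for (w in seq_along(world$wind_products)) {
    u <- wind_daily(world, w)
    A[[w]] <- vector("list", n_k)
    B[[w]] <- lapply(seq_along(world$ice_products), function(i)
      vector("list", n_k))
    for (ka in seq_len(n_k)) {
      K <- k_registry[[ka]]$fun(u) * scfac * 0.24
      A[[w]][[ka]] <- K %*% W
      for (i in seq_along(world$ice_products))
        B[[w]][[i]][[ka]] <- (K * fice_d[[i]]) %*% W
    }
  }
  list(A = A, B = B)
}

# Annual per-cell flux (mmol m^-2 yr^-1) for one map and one transfer draw,
# using precomputed terms.
annual_flux_cells <- function(dch4_map, terms, wind_id, ice_id, k_id, eps_ice) {
  tr <- terms$A[[wind_id]][[k_id]] - eps_ice * terms$B[[wind_id]][[ice_id]][[k_id]]
  rowSums(dch4_map * tr) * 1e-3
}

#' Monte-Carlo propagation of mapping and gas-transfer uncertainty
#'
#' Each draw pairs one random ensemble dCH4 map with a random wind product,
#' ice product, k algorithm, and an ice blocking efficiency drawn uniformly
#' from \code{eps_range}, then integrates annual emissions by region.
#'
#' @param ensemble An \code{och4_ensemble}.
#' @param world An \code{och4_world}.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @param eps_range Range of the ice gas-exchange blocking efficiency
#'   (default 0.9 to 1).
#' @param terms Optional precomputed \code{\link{transfer_terms}}.
#' @return Object of class \code{och4_flux}: data frame \code{draws} with the
#'   random selections and regional/global emissions (Tg yr^-1) per member.
#' @export
monte_carlo_flux <- function(ensemble, world, n_draws = 1000, seed = 1L,
                             eps_range = c(0.9, 1), terms = NULL) {
  if (is.null(terms)) terms <- transfer_terms(world)
  n_maps <- length(ensemble$maps)
  draws <- with_seed(stage_seed(seed, "monte_carlo"), {
    data.frame(
      draw = seq_len(n_draws),
      map_id = sample.int(n_maps, n_draws, replace = TRUE),
      wind_id = sample.int(length(world$wind_products), n_draws, replace = TRUE),
      ice_id = sample.int(length(world$ice_products), n_draws, replace = TRUE),
      k_id = sample.int(length(k_registry), n_draws, replace = TRUE),
      eps_ice = stats::runif(n_draws, eps_range[1], eps_range[2])
    )
  })
  draws$family <- ensemble$members$family[draws$map_id]
  em <- t(vapply(seq_len(n_draws), function(j) {
    f <- annual_flux_cells(ensemble$maps[[draws$map_id[j]]], terms,
                           draws$wind_id[j], draws$ice_id[j], draws$k_id[j],
                           draws$eps_ice[j])
    integrate_annual(f, world$grid$area_m2, world$region)
  }, numeric(5)))
  out <- list(draws = cbind(draws, em), regions = region_levels)
  class(out) <- "och4_flux"
  out
}

#' @export
print.och4_flux <- function(x, ...) {
  cat(sprintf("och4_flux: %d Monte-Carlo draws\n", nrow(x$draws)))
  s <- summary(x)
  print(s[s$scope == "pooled" & s$quantity == "global", ], row.names = FALSE)
  invisible(x)
}

#' Summarize a flux ensemble
#'
#' Mean, s.d. and the 10/25/50/75/90th percentiles of annual emissions, per
#' region and globally, pooled and per mapping family (the 10-90th range is
#' the ensemble's likely range).
#'
#' @param object An \code{och4_flux}.
#' @param ... Unused.
#' @return Data frame of summary rows.
#' @export
summary.och4_flux <- function(object, ...) {
  qs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  scopes <- c("pooled", unique(object$draws$family))
  rows <- list()
  for (sc in scopes) {
    d <- if (sc == "pooled") object$draws else
      object$draws[object$draws$family == sc, , drop = FALSE]
    for (q in c(object$regions, "global")) {
      v <- d[[q]]
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, quantity = q, mean = mean(v), sd = stats::sd(v),
        p10 = stats::quantile(v, qs[1], names = FALSE),
        p25 = stats::quantile(v, qs[2], names = FALSE),
        p50 = stats::quantile(v, qs[3], names = FALSE),
        p75 = stats::quantile(v, qs[4], names = FALSE),
        p90 = stats::quantile(v, qs[5], names = FALSE))
    }
  }
  do.call(rbind, rows)
}

#' Partition flux variance between gas transfer and dCH4 mapping
#'
#' Builds two ensembles: (A) every wind x ice x k-algorithm permutation
#' applied to the single ensemble-mean dCH4 map, and (B) the
#' permutation-mean transfer applied to each individual dCH4 map. The
#' variances of the global flux across the two compare the uncertainty
#' contributed by gas transfer versus by the dCH4 distribution.
#'
#' @param ensemble An \code{och4_ensemble}.
#' @param world An \code{och4_world}.
#' @param eps_ice Fixed blocking efficiency (default mid-range 0.95).
#' @param terms Optional precomputed \code{\link{transfer_terms}}.
#' @param k_ids Subset of k algorithms to permute (default all four).
#' @return List with \code{var_transfer}, \code{var_dch4} and the underlying
#'   global-flux vectors.
#' @export
variance_partition <- function(ensemble, world, eps_ice = 0.95, terms = NULL,
                               k_ids = seq_along(k_registry)) {
  if (is.null(terms)) terms <- transfer_terms(world)
  mean_map <- ensemble_mean(ensemble)
  perms <- expand.grid(w = seq_along(world$wind_products),
                       i = seq_along(world$ice_products),
                       k = k_ids)
  tr_list <- lapply(seq_len(nrow(perms)), function(j)
    terms$A[[perms$w[j]]][[perms$k[j]]] -
      eps_ice * terms$B[[perms$w[j]]][[perms$i[j]]][[perms$k[j]]])
  flux_transfer <- vapply(tr_list, function(tr)
    integrate_annual(rowSums(mean_map * tr) * 1e-3, world$grid$area_m2,
                     world$region)[["global"]], numeric(1))
  mean_tr <- Reduce(`+`, tr_list) / length(tr_list)
  flux_dch4 <- vapply(ensemble$maps, function(m)
    integrate_annual(rowSums(m * mean_tr) * 1e-3, world$grid$area_m2,
                     world$region)[["global"]], numeric(1))
  var1 <- function(x) if (length(x) > 1) stats::var(x) else 0
  list(var_transfer = var1(flux_transfer), var_dch4 = var1(flux_dch4),
       flux_transfer = flux_transfer, flux_dch4 = flux_dch4)
}

#' Global flux as a function of grid resolution
#'
#' Reruns bin -> train -> flux at each requested resolution with a small
#' ensemble, holding the observation records fixed. Fields are regenerated at
#' each resolution from the same configuration (the generator's smooth fields
#' are resolution-independent functions of position).
#'
#' @param config An \code{och4_config} (its resolution is overridden).
#' @param observations Records from \code{\link{sample_observations}} (with
#'   dCH4 already attached by the processing chain or to be recomputed).
#' @param resolutions Resolutions to test, degrees.
#' @param n_members Ensemble members per family at each resolution.
#' @param n_draws Monte-Carlo draws at each resolution.
#' @param seed RNG seed.
#' @param ... Extra arguments to \code{\link{train_member}}.
#' @return Data frame \code{resolution}, \code{global_flux_tg},
#'   \code{n_gridded} (training rows).
#' @export
resolution_sweep <- function(config, observations, resolutions,
                             n_members = 4, n_draws = 100, seed = 1L, ...) {
  out <- lapply(resolutions, function(res) {
    cfg <- config; cfg$resolution_deg <- res
    world <- make_world(cfg)
    recs <- mixed_layer_filter(observations, world$grid,
                               world$predictors$mld, world$predictors$sss)
    recs <- delta_ch4(recs, world$stations)
    clim <- bin_climatology(recs, world$grid, world$depth)
    tab <- build_training_table(clim, world$depth, world$predictors)
    gtab <- build_grid_table(world$grid, world$depth, world$predictors)
    ens <- generate_ensemble(tab, gtab, world$grid$n_cell,
                             n_members = n_members, seed = seed, ...)
    mc <- monte_carlo_flux(ens, world, n_draws = n_draws, seed = seed)
    data.frame(resolution = res, global_flux_tg = mean(mc$draws$global),
               n_gridded = nrow(tab))
  })
  do.call(rbind, out)
}

#' Coarsest resolution within tolerance of the finest
#'
#' Plateau detection on a resolution sweep: returns the coarsest resolution
#' whose global flux lies within \code{tol} (relative) of the finest grid's.
#'
#' @param sweep Output of \code{\link{resolution_sweep}}.
#' @param tol Relative tolerance (default 5%).
#' @return The selected resolution (degrees).
#' @export
find_plateau <- function(sweep, tol = 0.05) {
  s <- sweep[order(sweep$resolution), ]  # fine -> coarse
  ref <- s$global_flux_tg[1]
  ok <- abs(s$global_flux_tg - ref) <= tol * abs(ref)
  max(s$resolution[ok])
}
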