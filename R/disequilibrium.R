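# Observation-to-climatology processing: interpolate atmospheric dry pCH4 to
# each record, convert [CH4] to disequilibrium
#   dCH4 = [CH4] - S_CH4 * pCH4_moist
# and bin the surviving records into a monthly gridded climatology.

#' Ordinary kriging of station dry pCH4 to arbitrary points
#'
#' Ordinary kriging with an exponential covariance model
#' \code{C(h) = exp(-h/range)} and zero nugget, using great-circle distances.
#' With zero nugget the estimate interpolates the stations exactly; with a
#' single reporting station it degenerates to that station's value. Points in
#' a year-month with no station data get \code{NA}.
#'
#' @param stations Data frame \code{station_id, lat, lon, year, month,
#'   pch4_ppb}.
#' @param lat,lon Target coordinates (degrees), vectorized.
#' @param year,month Target times, recycled against the coordinates.
#' @param range_km Covariance e-folding range (default 3000 km; atmospheric
#'   CH4 is smooth at monthly scale).
#' @return Vector of dry pCH4 estimates, ppb.
#' @export
krige_atmospheric <- function(stations, lat, lon, year, month,
                              range_km = 3000) {
  n <- max(length(lat), length(lon), length(year), length(month))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  year <- rep_len(year, n); month <- rep_len(month, n)
  out <- rep(NA_real_, n)

  st_pos <- unique(stations[, c("station_id", "lat", "lon")])
  ns <- nrow(st_pos)
  cov_fun <- function(h_m) exp(-h_m / (range_km * 1000))
  D <- geosphere::distm(cbind(st_pos$lon, st_pos$lat))
  Kaug <- rbind(cbind(cov_fun(D), 1), c(rep(1, ns), 0))

  key <- paste(year, month)
  st_key <- paste(stations$year, stations$month)
  for (k in unique(key)) {
    tgt <- which(key == k)
    rows <- stations[st_key == k, ]
    if (nrow(rows) == 0) next
    v <- rows$pch4_ppb[match(st_pos$station_id, rows$station_id)]
    avail <- which(!is.na(v))
    if (length(avail) == 0) next
    if (length(avail) == 1) { out[tgt] <- v[avail]; next }
    d_t <- geosphere::distm(cbind(st_pos$lon[avail], st_pos$lat[avail]),
                            cbind(lon[tgt], lat[tgt]))
    na <- length(avail)
    Ka <- rbind(cbind(cov_fun(geosphere::distm(
      cbind(st_pos$lon[avail], st_pos$lat[avail]))), 1), c(rep(1, na), 0))
    lambda <- solve(Ka, rbind(cov_fun(d_t), rep(1, length(tgt))))
    out[tgt] <- as.numeric(crossprod(lambda[seq_len(na), , drop = FALSE],
                                     v[avail]))
  }
  out
}

#' Filter records to the mixed layer and fill missing hydrography
#'
#' Keeps records sampled at or above the interpolated mixed layer depth for
#' their cell and month. Records with missing salinity are retained with
#' salinity filled from the climatology and flagged; records with missing
#' temperature are rejected unless their \code{source} is on the allow-list,
#' in which case temperature is filled from the SST climatology and flagged.
#'
#' @param records Observation data frame (needs \code{lat}, \code{lon},
#'   \code{date}, \code{depth_m}, \code{temperature_C}, \code{salinity_psu};
#'   optional \code{source}).
#' @param grid An \code{och4_grid}.
#' @param mld Mixed layer depth climatology, n_cell x 12 matrix (m).
#' @param sss,sst Salinity and temperature climatologies (n_cell x 12) used
#'   for filling.
#' @param allow_missing_t Character vector of \code{source} values accepted
#'   without temperature (default none).
#' @return The surviving records with logical columns \code{filled_salinity},
#'   \code{filled_temperature}; attribute \code{dropped} counts the reasons.
#' @export
mixed_layer_filter <- function(records, grid, mld, sss = NULL, sst = NULL,
                               allow_missing_t = character()) {
  cell <- cell_index(grid, records$lat, records$lon)
  month <- as.integer(format(records$date, "%m"))
  in_grid <- !is.na(cell)
  mld_at <- rep(NA_real_, nrow(records))
  mld_at[in_grid] <- mld[cbind(cell[in_grid], month[in_grid])]
  in_ml <- in_grid & records$depth_m <= mld_at

  src <- if ("source" %in% names(records)) records$source else
    rep("", nrow(records))
  miss_t <- is.na(records$temperature_C)
  t_ok <- !miss_t | src %in% allow_missing_t

  keep <- in_ml & t_ok
  out <- records[keep, , drop = FALSE]
  cell_k <- cell[keep]; month_k <- month[keep]

  out$filled_salinity <- is.na(out$salinity_psu)
  if (any(out$filled_salinity)) {
    if (is.null(sss)) stop("mixed_layer_filter: salinity climatology needed to fill")
    i <- which(out$filled_salinity)
    out$salinity_psu[i] <- sss[cbind(cell_k[i], month_k[i])]
  }
  out$filled_temperature <- is.na(out$temperature_C)
  if (any(out$filled_temperature)) {
    if (is.null(sst)) stop("mixed_layer_filter: SST climatology needed to fill")
    i <- which(out$filled_temperature)
    out$temperature_C[i] <- sst[cbind(cell_k[i], month_k[i])]
  }
  attr(out, "dropped") <- c(below_mld = sum(!in_ml),
                            missing_temperature = sum(in_ml & !t_ok))
  out
}

#' Convert [CH4] records to methane disequilibrium
#'
#' Applies \code{dCH4 = [CH4] - S_CH4(T, S) * pCH4_moist}, where dry pCH4 is
#' kriged from the station network at each record's position and year-month
#' and converted to its moist-air value at the record's temperature and
#' salinity. Records dated in a year-month with no station data (outside the
#' station window) are dropped and counted.
#'
#' @param records Filtered observation records.
#' @param stations Atmospheric station series (see
#'   \code{\link{krige_atmospheric}}).
#' @return Records with added columns \code{pch4_dry_ppb}, \code{pch4_moist_ppb},
#'   \code{dch4_nM}; attribute \code{dropped_no_atm} counts rejections.
#' @export
delta_ch4 <- function(records, stations) {
  year <- as.integer(format(records$date, "%Y"))
  month <- as.integer(format(records$date, "%m"))
  p_dry <- krige_atmospheric(stations, records$lat, records$lon, year, month)
  ok <- !is.na(p_dry)
  out <- records[ok, , drop = FALSE]
  out$pch4_dry_ppb <- p_dry[ok]
  out$pch4_moist_ppb <- moist_pch4(out$pch4_dry_ppb, out$temperature_C,
                                   out$salinity_psu)
  sol <- ch4_solubility(out$temperature_C, out$salinity_psu)
  out$dch4_nM <- out$ch4_nM - sol * out$pch4_moist_ppb
  attr(out, "dropped_no_atm") <- sum(!ok)
  out
}

#' Bin dCH4 records into a monthly gridded climatology
#'
#' All records falling in a calendar month (regardless of year) are binned
#' onto the grid and averaged arithmetically per cell. Cells without data are
#' missing (\code{NA}), never zero.
#'
#' @param records Records carrying \code{dch4_nM} (from
#'   \code{\link{delta_ch4}}).
#' @param grid An \code{och4_grid}; its resolution sets the climatology
#'   resolution.
#' @param depth Optional seafloor depth per cell, used to attach the region
#'   mask.
#' @return An object of class \code{och4_clim}: matrices \code{dch4}
#'   (n_cell x 12, nM) and \code{count}, the grid, cell areas and region mask.
#' @export
bin_climatology <- function(records, grid, depth = NULL) {
  cell <- cell_index(grid, records$lat, records$lon)
  month <- as.integer(format(records$date, "%m"))
  ok <- !is.na(cell) & !is.na(records$dch4_nM)
  idx <- (month[ok] - 1L) * grid$n_cell + cell[ok]  # cell-month linear index
  sums <- rep(0, grid$n_cell * 12L)
  cnts <- rep(0L, grid$n_cell * 12L)
  agg_s <- tapply(records$dch4_nM[ok], idx, sum)
  agg_n <- tapply(rep(1L, sum(ok)), idx, sum)
  pos <- as.integer(names(agg_s))
  sums[pos] <- agg_s; cnts[pos] <- agg_n
  dch4 <- matrix(ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                 grid$n_cell, 12)
  out <- list(grid = grid,
              dch4 = dch4,
              count = matrix(as.integer(cnts), grid$n_cell, 12),
              region = if (!is.null(depth)) region_mask(depth) else NULL,
              depth = depth)
  class(out) <- "och4_clim"
  out
}

#' @export
print.och4_clim <- function(x, ...) {
  cat(sprintf("och4_clim: %d cell-months with data (%d cells), %.3g deg grid\n",
              sum(x$count > 0), sum(rowSums(x$count) > 0), x$grid$resolution))
  invisible(x)
}

#' Annual-mean map of a climatology
#'
#' Count-weighted mean over the months present in each cell.
#'
#' @param clim An \code{och4_clim}.
#' @return Vector of annual-mean dCH4 per cell (NA where never observed).
#' @export
clim_annual_mean <- function(clim) {
  num <- rowSums(ifelse(clim$count > 0, clim$dch4 * clim$count, 0))
  den <- rowSums(clim$count)
  as.numeric(ifelse(den > 0, num / den, NA_real_))
}

#' Perturb measured [CH4] values by a uniform relative error
#'
#' Each record's concentration is replaced by a value drawn uniformly in
#' \code{[(1-re)*ch4, (1+re)*ch4]} -- the measurement-error sensitivity
#' perturbation (typical cases re = 0.25 and 0.5).
#'
#' @param records Observation records with \code{ch4_nM}.
#' @param re Relative error, in \[0, 1).
#' @param seed RNG seed.
#' @return Records with perturbed \code{ch4_nM}.
#' @export
perturb_measurements <- function(records, re, seed = 1L) {
  if (!is.numeric(re) || re < 0 || re >= 1)
    stop("perturb_measurements: relative error must be in [0, 1)")
  if (re == 0) return(records)
  with_seed(stage_seed(seed, "perturb"), {
    records$ch4_nM <- records$ch4_nM *
      stats::runif(nrow(records), 1 - re, 1 + re)
    records
  })
}
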