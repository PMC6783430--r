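#' Build a regular latitude/longitude grid with spherical cell areas
#'
#' Cells are defined on a regular grid with half-open edges \[lo, hi) and
#' cell-center coordinates. Areas are exact spherical-zone areas,
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}, so the
#' cosine-of-latitude weighting is built in.
#'
#' @param resolution_deg Grid resolution in degrees (> 0); must divide both
#'   extents.
#' @param lat_range,lon_range Numeric length-2 extents in degrees; latitude
#'   within \[-90, 90\], longitude in \[-180, 180\].
#' @return An object of class \code{och4_grid}: cell-center \code{lat},
#'   \code{lon}, \code{area_m2} (all length \code{n_cell}, longitude varying
#'   fastest), plus the axis vectors and edges.
#' @export
make_grid <- function(resolution_deg, lat_range = c(-70, 70),
                      lon_range = c(0, 40)) {
  if (!is.numeric(resolution_deg) || length(resolution_deg) != 1 ||
      !is.finite(resolution_deg) || resolution_deg <= 0)
    stop("make_grid: resolution must be a positive number")
  lat_range <- sort(as.numeric(lat_range))
  lon_range <- sort(as.numeric(lon_range))
  if (lat_range[1] < -90 || lat_range[2] > 90 || diff(lat_range) <= 0)
    stop("make_grid: invalid latitude extent")
  if (diff(lon_range) <= 0) stop("make_grid: invalid longitude extent")
  nlat <- diff(lat_range) / resolution_deg
  nlon <- diff(lon_range) / resolution_deg
  if (abs(nlat - round(nlat)) > 1e-8 || abs(nlon - round(nlon)) > 1e-8)
    stop("make_grid: resolution must divide the lat/lon extents")
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  lat_edges <- seq(lat_range[1], lat_range[2], by = resolution_deg)
  lon_edges <- seq(lon_range[1], lon_range[2], by = resolution_deg)
  lat_c <- (lat_edges[-1] + lat_edges[-length(lat_edges)]) / 2
  lon_c <- (lon_edges[-1] + lon_edges[-length(lon_edges)]) / 2
  R <- och4_constants$earth_radius_m
  zone <- R^2 * (resolution_deg * pi / 180) *
    (sin(lat_edges[-1] * pi / 180) - sin(lat_edges[-length(lat_edges)] * pi / 180))
  g <- list(
    resolution = resolution_deg,
    lat_range = lat_range, lon_range = lon_range,
    nlat = nlat, nlon = nlon, n_cell = nlat * nlon,
    lat_centers = lat_c, lon_centers = lon_c,
    lat_edges = lat_edges, lon_edges = lon_edges,
    lat = rep(lat_c, each = nlon),
    lon = rep(lon_c, times = nlat),
    area_m2 = rep(zone, each = nlon)
  )
  class(g) <- "och4_grid"
  g
}

#' @export
print.och4_grid <- function(x, ...) {
  cat(sprintf("och4_grid: %.3g deg, lat [%g, %g], lon [%g, %g], %d cells\n",
              x$resolution, x$lat_range[1], x$lat_range[2],
              x$lon_range[1], x$lon_range[2], x$n_cell))
  invisible(x)
}

#' Map point coordinates to grid cell indices
#'
#' Half-open binning \code{[lo, hi)}; points exactly on the upper boundary are
#' assigned to the last cell so track endpoints are not lost.
#'
#' @param grid An \code{och4_grid}.
#' @param lat,lon Point coordinates, degrees.
#' @return Integer cell indices (NA outside the grid).
#' @export
cell_index <- function(grid, lat, lon) {
  ilat <- findInterval(lat, grid$lat_edges, rightmost.closed = TRUE)
  ilon <- findInterval(lon, grid$lon_edges, rightmost.closed = TRUE)
  ok <- ilat >= 1 & ilat <= grid$nlat & ilon >= 1 & ilon <= grid$nlon
  out <- rep(NA_integer_, length(lat))
  out[ok] <- (ilat[ok] - 1L) * grid$nlon + ilon[ok]
  out
}

# Depth-class boundaries shared by the region mask, the regional flux
# integrals and the attribution split.
region_breaks <- c(0, 50, 200, 2000, Inf)
region_levels <- c("nearshore", "shelf", "slope", "open")

#' Classify cells into bathymetric regions
#'
#' Four classes by seafloor depth: near-shore 0-50 m, outer shelf 50-200 m,
#' continental slope 200-2000 m, open ocean > 2000 m.
#'
#' @param depth_m Seafloor depth, m, positive down.
#' @return Factor with levels nearshore, shelf, slope, open.
#' @export
region_mask <- function(depth_m) {
  cut(depth_m, breaks = region_breaks, labels = region_levels, right = TRUE)
}

#' Seafloor area per depth bin (hypsometry)
#'
#' @param depth_m Cell seafloor depths, m.
#' @param area_m2 Cell areas, m^2.
#' @param breaks Depth bin edges, m. Default 10 m bins to 500 m then one open
#'   bin; bins are \code{(lo, hi]}.
#' @return Data frame with columns \code{depth_lo}, \code{depth_hi},
#'   \code{depth_mid}, \code{area_m2}.
#' @export
hypsometry <- function(depth_m, area_m2, breaks = c(seq(0, 500, by = 10), Inf)) {
  stopifnot(length(depth_m) == length(area_m2))
  bin <- cut(depth_m, breaks = breaks, right = TRUE, include.lowest = TRUE)
  a <- tapply(area_m2, bin, sum, default = 0)
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  data.frame(depth_lo = lo, depth_hi = hi,
             depth_mid = ifelse(is.finite(hi), (lo + hi) / 2, lo),
             area_m2 = as.numeric(a))
}
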