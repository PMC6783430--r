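# On-disk interchange. Observations travel as plain CSV; gridded monthly
# fields travel in a self-describing JSON container with named dimensions and
# units attributes; configurations are YAML key:value hierarchies.

obs_schema <- c("lat", "lon", "date", "depth_m", "temperature_C",
                "salinity_psu", "ch4_nM")

#' Write / read observation records as CSV
#'
#' The canonical schema is \code{lat, lon, date (ISO-8601), depth_m,
#' temperature_C, salinity_psu, ch4_nM}; extra working columns are dropped on
#' write.
#'
#' @param records Observation data frame.
#' @param path File path.
#' @export
write_observations <- function(records, path) {
  out <- records[, intersect(obs_schema, names(records)), drop = FALSE]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @return \code{read_observations}: the records with \code{date} parsed.
#' @export
read_observations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(obs_schema, names(x))
  if (length(missing) > 0)
    stop("read_observations: missing columns: ",
         paste(missing, collapse = ", "))
  x$date <- as.Date(x$date)
  x
}

#' Write / read gridded monthly fields
#'
#' A self-describing JSON container: named dimensions (\code{time = 12},
#' \code{lat}, \code{lon}), per-variable units attributes, and the grid
#' definition. Values are stored in cell-major order matching the package's
#' n_cell x 12 matrices.
#'
#' @param fields Named list of n_cell x 12 matrices or n_cell vectors.
#' @param grid An \code{och4_grid}.
#' @param path Output path.
#' @param units Named character vector of units per variable.
#' @export
write_gridded <- function(fields, grid, path, units = NULL) {
  vars <- lapply(names(fields), function(nm) {
    f <- fields[[nm]]
    list(dims = if (is.matrix(f)) c("cell", "time") else "cell",
         units = if (!is.null(units) && nm %in% names(units))
           units[[nm]] else "",
         values = as.numeric(f))
  })
  names(vars) <- names(fields)
  obj <- list(
    container = "och4-gridded-1",
    dimensions = list(time = 12L, lat = grid$nlat, lon = grid$nlon,
                      cell = grid$n_cell),
    grid = list(resolution_deg = grid$resolution, lat_range = grid$lat_range,
                lon_range = grid$lon_range),
    variables = vars)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_gridded
#' @return \code{read_gridded}: list with the reconstructed \code{grid} and
#'   \code{fields}.
#' @export
read_gridded <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- make_grid(obj$grid$resolution_deg, obj$grid$lat_range,
                    obj$grid$lon_range)
  fields <- lapply(obj$variables, function(v) {
    vals <- as.numeric(v$values)
    if (length(v$dims) == 2) matrix(vals, grid$n_cell, 12) else vals
  })
  list(grid = grid, fields = fields)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{synth_config}}; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return An \code{och4_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    stop("read_config: unknown keys: ", paste(bad, collapse = ", "))
  do.call(synth_config, y)
}
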