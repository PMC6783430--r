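# What drives the dCH4 distribution: per-predictor correlations split at the
# 2000 m isobath, the coastal depth power law, the open-ocean NPP and NPP+PO4
# regressions, and latitudinal-band averages.

#' Per-predictor R^2 against annual-mean dCH4
#'
#' Correlates dCH4 against each predictor in turn, separately for coastal
#' (seafloor < 2000 m) and open-ocean cells, under configurable axis
#' transforms. Cells with non-positive dCH4 (or predictor) are excluded from
#' the log variants and counted.
#'
#' @param dch4 Annual-mean dCH4 per cell, nM.
#' @param predictors Named list of per-cell predictor vectors (annual means).
#' @param depth Seafloor depth per cell, m.
#' @param region \code{"coastal"} (< 2000 m) or \code{"open"}.
#' @param transforms Subset of \code{"identity"}, \code{"logy"} (log10 dCH4),
#'   \code{"loglog"} (log10 both axes).
#' @return Data frame \code{predictor}, \code{transform}, \code{r2}, \code{n},
#'   \code{n_excluded}.
#' @export
predictor_correlations <- function(dch4, predictors, depth,
                                   region = c("coastal", "open"),
                                   transforms = c("identity", "logy", "loglog")) {
  region <- match.arg(region)
  sel <- if (region == "coastal") depth < 2000 else depth >= 2000
  sel <- sel & !is.na(dch4)
  if (!any(sel)) stop("predictor_correlations: empty region subset")
  rows <- list()
  for (p in names(predictors)) {
    x_all <- predictors[[p]][sel]; y_all <- dch4[sel]
    for (tr in transforms) {
      x <- x_all; y <- y_all
      excl <- 0L
      if (tr %in% c("logy", "loglog")) {
        keep <- y > 0
        if (tr == "loglog") keep <- keep & x > 0
        excl <- sum(!keep)
        x <- x[keep]; y <- y[keep]
        y <- log10(y)
        if (tr == "loglog") x <- log10(x)
      }
      r2 <- if (length(y) > 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y)^2 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, transform = tr, r2 = r2, n = length(y),
        n_excluded = excl)
    }
  }
  do.call(rbind, rows)
}

#' Power-law fit of dCH4 versus seafloor depth
#'
#' Bins observations into log-spaced depth bins, then fits
#' \code{log10(mean dCH4) ~ log10(depth)} by ordinary least squares:
#' \code{dCH4 = A * depth^b}.
#'
#' @param dch4 dCH4 values, nM (non-positive values are excluded from the
#'   log fit and counted).
#' @param depth_m Seafloor depth at each value, m.
#' @param n_bins Number of log-spaced bins (default 12).
#' @param depth_range Fit range, m (default 10-2000).
#' @return List \code{A} (nM), \code{b} (dimensionless), \code{r2} (of the
#'   binned fit), \code{n_bins_used}, \code{n_excluded}, and the binned table.
#' @export
powerlaw_fit <- function(dch4, depth_m, n_bins = 12,
                         depth_range = c(10, 2000)) {
  keep <- is.finite(dch4) & dch4 > 0 & depth_m >= depth_range[1] &
    depth_m <= depth_range[2]
  n_excluded <- sum(is.finite(dch4) & dch4 <= 0)
  edges <- 10^seq(log10(depth_range[1]), log10(depth_range[2]),
                  length.out = n_bins + 1)
  bin <- cut(depth_m[keep], edges, include.lowest = TRUE)
  ym <- tapply(dch4[keep], bin, mean)
  xm <- tapply(depth_m[keep], bin, mean)
  use <- !is.na(ym)
  if (sum(use) < 3) stop("powerlaw_fit: fewer than 3 non-empty depth bins")
  fit <- stats::lm(log10(ym[use]) ~ log10(xm[use]))
  list(A = 10^stats::coef(fit)[[1]], b = stats::coef(fit)[[2]],
       r2 = summary(fit)$r.squared, n_bins_used = sum(use),
       n_excluded = n_excluded,
       bins = data.frame(depth_m = xm[use], dch4_nM = ym[use]))
}

#' Binned linear fit of dCH4 versus NPP
#'
#' Bins observations by NPP and fits a straight line to the binned means:
#' \code{dCH4 = slope * NPP + intercept}. Note the open-ocean convention of
#' reporting the coefficients multiplied by 10^3 (dCH4 in 10^-3 nM).
#'
#' @param dch4 dCH4 values, nM.
#' @param npp NPP at each value, mg C m^-2 d^-1.
#' @param n_bins Number of equal-width NPP bins.
#' @return List \code{slope} (nM per mg C m^-2 d^-1), \code{intercept} (nM),
#'   \code{r2} of the binned fit, and the binned table.
#' @export
npp_fit <- function(dch4, npp, n_bins = 12) {
  keep <- is.finite(dch4) & is.finite(npp)
  bin <- cut(npp[keep], n_bins, include.lowest = TRUE)
  ym <- tapply(dch4[keep], bin, mean)
  xm <- tapply(npp[keep], bin, mean)
  use <- !is.na(ym)
  if (sum(use) < 3) stop("npp_fit: fewer than 3 non-empty NPP bins")
  fit <- stats::lm(ym[use] ~ xm[use])
  list(slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
       r2 = summary(fit)$r.squared,
       bins = data.frame(npp = xm[use], dch4_nM = ym[use]))
}

#' Multiple regression of dCH4 on NPP and phosphate
#'
#' Unbinned OLS fit \code{dCH4 ~ NPP + PO4} (open-ocean cells); flags
#' near-collinear predictors (|r| > 0.99).
#'
#' @param dch4 dCH4, nM.
#' @param npp NPP, mg C m^-2 d^-1.
#' @param po4 Phosphate, uM.
#' @return List \code{coefficients} (intercept, npp, po4), \code{r2},
#'   \code{collinear} flag.
#' @export
mlr_fit <- function(dch4, npp, po4) {
  keep <- is.finite(dch4) & is.finite(npp) & is.finite(po4)
  collinear <- abs(stats::cor(npp[keep], po4[keep])) > 0.99
  if (collinear) warning("mlr_fit: NPP and PO4 nearly collinear")
  fit <- stats::lm(dch4[keep] ~ npp[keep] + po4[keep])
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "npp", "po4")
  list(coefficients = cf, r2 = summary(fit)$r.squared, collinear = collinear)
}

#' Latitudinal band classification
#'
#' Fixed latitude cuts: tropical < 23, subtropical 23-45, subpolar 45-60,
#' polar > 60 degrees (absolute latitude).
#'
#' @param lat Latitude, degrees.
#' @return Factor with levels tropical, subtropical, subpolar, polar.
#' @export
latitude_bands <- function(lat) {
  cut(abs(lat), breaks = c(0, 23, 45, 60, 90),
      labels = c("tropical", "subtropical", "subpolar", "polar"),
      include.lowest = TRUE)
}

#' Area-weighted band averages
#'
#' @param values Per-cell values.
#' @param area_m2 Cell areas.
#' @param bands Band factor (e.g. \code{\link{latitude_bands}}).
#' @return Data frame \code{band}, \code{mean} (area-weighted; NA for an
#'   empty band, with a warning), \code{area_m2}.
#' @export
band_averages <- function(values, area_m2, bands) {
  lv <- levels(bands)
  out <- lapply(lv, function(b) {
    i <- which(bands == b & !is.na(values))
    if (length(i) == 0) {
      warning("band_averages: empty band ", b)
      return(data.frame(band = b, mean = NA_real_, area_m2 = 0))
    }
    data.frame(band = b, mean = sum(values[i] * area_m2[i]) / sum(area_m2[i]),
               area_m2 = sum(area_m2[i]))
  })
  do.call(rbind, out)
}

#' Full attribution analysis of a mapped dCH4 distribution
#'
#' Runs the predictor correlation tables (coastal and open), the coastal
#' depth power-law fit, the open-ocean NPP and NPP+PO4 fits, and the
#' latitudinal band averages of dCH4 and NPP.
#'
#' @param dch4 Annual-mean dCH4 per cell (e.g. from
#'   \code{\link{ensemble_mean}} or \code{\link{clim_annual_mean}}).
#' @param world An \code{och4_world}.
#' @return Object of class \code{och4_attribution}.
#' @export
attribution_report <- function(dch4, world) {
  ann <- lapply(world$predictors[c("sst", "sss", "npp", "poc", "po4", "o2",
                                   "hydrate", "dms")], function(f)
    if (is.matrix(f)) rowMeans(f) else f)
  ann$depth <- world$depth
  coastal <- world$depth < 2000
  open <- !coastal
  out <- list(
    correlations_coastal = predictor_correlations(dch4, ann, world$depth,
                                                  "coastal"),
    correlations_open = predictor_correlations(dch4, ann, world$depth, "open"),
    powerlaw = powerlaw_fit(dch4[coastal], world$depth[coastal]),
    npp = npp_fit(dch4[open], ann$npp[open]),
    mlr = mlr_fit(dch4[open], ann$npp[open], ann$po4[open]),
    bands_dch4 = band_averages(ifelse(open, dch4, NA), world$grid$area_m2,
                               latitude_bands(world$grid$lat)),
    bands_npp = band_averages(ifelse(open, ann$npp, NA), world$grid$area_m2,
                              latitude_bands(world$grid$lat))
  )
  class(out) <- "och4_attribution"
  out
}

#' @export
print.och4_attribution <- function(x, ...) {
  cat("och4_attribution\n")
  cat(sprintf("  coastal power law: dCH4 = %.3g * depth^%.3f (R2 = %.2f)\n",
              x$powerlaw$A, x$powerlaw$b, x$powerlaw$r2))
  cat(sprintf("  open-ocean NPP fit: dCH4 = (%.3g NPP + %.3g)/10^3 (R2 = %.2f)\n",
              x$npp$slope * 1e3, x$npp$intercept * 1e3, x$npp$r2))
  cat(sprintf("  NPP+PO4 MLR R2 = %.2f (PO4 coefficient %.3g)\n",
              x$mlr$r2, x$mlr$coefficients[["po4"]]))
  invisible(x)
}
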