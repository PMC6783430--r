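test_that("ordinary kriging honors its interpolation contracts", {
  st <- data.frame(station_id = c("A", "B"), lat = c(-30, 30), lon = c(20, 20),
                   year = 2000, month = 6, pch4_ppb = c(1700, 1760))
  # exact at station locations
  expect_equal(krige_atmospheric(st, c(-30, 30), c(20, 20), 2000, 6),
               c(1700, 1760), tolerance = 1e-8)
  # between stations the estimate stays within the data range
  v <- krige_atmospheric(st, 0, 20, 2000, 6)
  expect_gt(v, 1700); expect_lt(v, 1760)
  # two equal-valued stations give that value everywhere
  st2 <- st; st2$pch4_ppb <- c(1725, 1725)
  expect_equal(krige_atmospheric(st2, c(-60, 0, 45), c(5, 20, 35), 2000, 6),
               rep(1725, 3), tolerance = 1e-9)
  # single reporting station degenerates to a constant field
  st1 <- st[1, ]
  expect_equal(krige_atmospheric(st1, c(-60, 60), c(0, 40), 2000, 6),
               rep(1700, 2))
  # a year-month with no data yields NA
  expect_true(is.na(krige_atmospheric(st, 0, 20, 1979, 6)))
})

test_that("equilibrium records give zero disequilibrium to machine precision", {
  w <- world_small()
  n <- 20
  set.seed(1)
  recs <- data.frame(
    lat = runif(n, -60, 60), lon = runif(n, 2, 38),
    date = as.Date("2005-06-15"), depth_m = 5,
    temperature_C = runif(n, 0, 28), salinity_psu = runif(n, 32, 37))
  p_dry <- krige_atmospheric(w$stations, recs$lat, recs$lon, 2005, 6)
  p_moist <- moist_pch4(p_dry, recs$temperature_C, recs$salinity_psu)
  recs$ch4_nM <- ch4_solubility(recs$temperature_C, recs$salinity_psu) * p_moist
  out <- delta_ch4(recs, w$stations)
  expect_equal(out$dch4_nM, rep(0, n), tolerance = 1e-12)
  # [CH4] = 0 gives the negative equilibrium concentration
  recs0 <- recs; recs0$ch4_nM <- 0
  out0 <- delta_ch4(recs0, w$stations)
  expect_true(all(out0$dch4_nM < 0))
  expect_equal(out0$dch4_nM, -(out$ch4_nM - out$dch4_nM), tolerance = 1e-12)
})

test_that("mixed-layer filter keeps, drops, fills and flags as specified", {
  grid <- make_grid(2, c(0, 10), c(0, 10))
  mld <- matrix(30, grid$n_cell, 12)
  sss <- matrix(35, grid$n_cell, 12)
  sst <- matrix(15, grid$n_cell, 12)
  recs <- data.frame(
    lat = 5, lon = 5, date = as.Date("2000-07-01"),
    depth_m = c(5, 50, 10, 10),
    temperature_C = c(10, 10, NA, NA),
    salinity_psu = c(35, 35, 35, NA),
    source = c("a", "a", "b", "allowed"))
  out <- mixed_layer_filter(recs, grid, mld, sss = sss, sst = sst,
                            allow_missing_t = "allowed")
  # record at 5 m with MLD 30 kept; at 50 m dropped; missing T dropped unless
  # allow-listed
  expect_equal(nrow(out), 2L)
  expect_equal(out$source, c("a", "allowed"))
  expect_equal(out$filled_temperature, c(FALSE, TRUE))
  expect_equal(out$filled_salinity, c(FALSE, TRUE))
  expect_equal(out$salinity_psu[2], 35)
  expect_equal(unname(attr(out, "dropped")["below_mld"]), 1L)
  expect_equal(unname(attr(out, "dropped")["missing_temperature"]), 1L)
})

test_that("below-mixed-layer records are removed at the configured rate", {
  w <- world_small()
  obs <- sample_observations(w)
  out <- mixed_layer_filter(obs, w$grid, w$predictors$mld,
                            sss = w$predictors$sss)
  expect_equal(unname(attr(out, "dropped")["below_mld"]), sum(obs$below_mld))
  expect_false(any(out$below_mld))
})

test_that("records outside the station window are rejected in conversion", {
  ch <- chain_small()
  survived_filter <- mixed_layer_filter(ch$obs, ch$world$grid,
                                        ch$world$predictors$mld,
                                        sss = ch$world$predictors$sss)
  expect_equal(attr(ch$recs, "dropped_no_atm"), sum(survived_filter$out_window))
  expect_gt(attr(ch$recs, "dropped_no_atm"), 0)
  expect_false(any(ch$recs$out_window))
})

test_that("binning averages per cell-month and respects missingness", {
  grid <- make_grid(2, c(0, 10), c(0, 10))
  recs <- data.frame(
    lat = c(1, 1, 1, 9), lon = c(1, 1, 1, 9),
    date = as.Date(c("2000-03-05", "2001-03-20", "2000-04-01", "2000-03-01")),
    dch4_nM = c(1, 3, 10, 7))
  clim <- bin_climatology(recs, grid)
  c1 <- cell_index(grid, 1, 1); c2 <- cell_index(grid, 9, 9)
  # two observations of 1 and 3 nM average to 2 (same month, any year)
  expect_equal(clim$dch4[c1, 3], 2)
  expect_equal(clim$count[c1, 3], 2L)
  expect_equal(clim$dch4[c1, 4], 10)
  expect_equal(clim$dch4[c2, 3], 7)
  # cells without data are missing, not zero
  expect_true(is.na(clim$dch4[c2, 5]))
  expect_lte(sum(clim$count), nrow(recs))
  # permutation invariance
  clim2 <- bin_climatology(recs[sample(4), ], grid)
  expect_equal(clim$dch4, clim2$dch4)
  # annual mean is the count-weighted mean of months present
  ann <- clim_annual_mean(clim)
  expect_equal(ann[c1], (2 * 2 + 10 * 1) / 3)
})

test_that("a noiseless dense climatology reproduces the truth cellwise", {
  w <- make_world(small_config(noise_sigma = 0))
  obs <- sample_observations(w)
  recs <- mixed_layer_filter(obs, w$grid, w$predictors$mld,
                             sss = w$predictors$sss)
  recs <- delta_ch4(recs, w$stations)
  clim <- bin_climatology(recs, w$grid, w$depth)
  ann <- clim_annual_mean(clim)
  have <- !is.na(ann)
  expect_gt(sum(have), 100)
  expect_equal(ann[have], w$truth_dch4[have], tolerance = 1e-9)
})

test_that("measurement perturbation is bounded, centered and validated", {
  recs <- data.frame(ch4_nM = rep(10, 4000))
  expect_identical(perturb_measurements(recs, 0), recs)
  out <- perturb_measurements(recs, 0.25, seed = 2)
  expect_true(all(out$ch4_nM >= 7.5 & out$ch4_nM <= 12.5))
  # uniform perturbation is mean-preserving (Monte-Carlo tolerance)
  se <- 10 * 0.25 / sqrt(3) / sqrt(4000)
  expect_lt(abs(mean(out$ch4_nM) - 10), 4 * se)
  expect_error(perturb_measurements(recs, 1), "\\[0, 1\\)")
  expect_error(perturb_measurements(recs, -0.1), "\\[0, 1\\)")
})
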