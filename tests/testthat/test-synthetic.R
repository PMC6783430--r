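test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_config()
  w1 <- make_world(cfg); w2 <- make_world(cfg)
  expect_identical(w1$depth, w2$depth)
  expect_identical(w1$truth_dch4, w2$truth_dch4)
  o1 <- sample_observations(w1); o2 <- sample_observations(w2)
  expect_identical(o1, o2)
  # and a different seed changes the draw
  w3 <- make_world(small_config(seed = 8L))
  expect_false(identical(w3$truth_dch4, w1$truth_dch4))
})

test_that("config validation enforces the generator invariants", {
  expect_error(synth_config(resolution_deg = 0), "> 0")
  expect_error(synth_config(noise_sigma = -1), ">= 0")
  expect_error(synth_config(coastal_b = 0.5), "negative")
})

test_that("the truth skeleton evaluates the configured relationships", {
  cfg <- small_config(het_coastal = 0, het_open = 0, polar_offset_nM = 0)
  g <- make_grid(2, cfg$lat_range, cfg$lon_range)
  depth <- rep(c(50, 3000), length.out = g$n_cell)
  preds <- list(npp = matrix(500, g$n_cell, 12))
  truth <- make_truth_field(cfg, g, depth, preds)
  # coastal power law at 50 m: 69 * 50^-0.8
  expect_equal(truth[depth == 50][1], 69 * 50^-0.8, tolerance = 1e-12)
  expect_equal(69 * 50^-0.8, 3.0, tolerance = 0.01)
  # open-ocean NPP relation at NPP = 500: (0.3*500 + 14)/1e3
  expect_equal(truth[depth == 3000][1], 0.164, tolerance = 1e-12)
})

test_that("noiseless dense sampling refits the generating coefficients exactly", {
  w <- make_world(small_config(het_coastal = 0, het_open = 0,
                               polar_offset_nM = 0, noise_sigma = 0))
  coastal <- w$depth >= 10 & w$depth < 1500  # pure power-law zone
  fit <- powerlaw_fit(w$truth_dch4[coastal], w$depth[coastal],
                      depth_range = c(10, 1400))
  # binned means carry a small within-bin discretization (Jensen) term
  expect_equal(fit$b, -0.8, tolerance = 5e-3)
  expect_equal(fit$A, 69, tolerance = 2e-2)
  open <- w$depth >= 2600
  nf <- suppressWarnings(  # lm warns on a perfect fit
    npp_fit(w$truth_dch4[open], rowMeans(w$predictors$npp)[open]))
  expect_equal(nf$slope * 1e3, 0.3, tolerance = 1e-6)
  expect_equal(nf$intercept * 1e3, 14, tolerance = 1e-4)
})

test_that("default truth field has the study's qualitative structure", {
  w <- world_default()
  # negative (undersaturated) polar patch exists
  expect_true(any(w$truth_dch4 < 0))
  expect_true(all(w$grid$lat[w$truth_dch4 < 0] < -45))
  # NPP highest in tropics, lowest at poles
  npp <- rowMeans(w$predictors$npp)
  expect_gt(mean(npp[abs(w$grid$lat) < 15]), mean(npp[abs(w$grid$lat) > 60]))
})

test_that("observation records carry the configured contaminations", {
  w <- world_small()
  obs <- sample_observations(w)
  cfg <- w$config
  n <- nrow(obs)
  # below-mixed-layer fraction within 4 binomial sigmas of the target
  p <- cfg$below_mld_frac
  expect_lt(abs(mean(obs$below_mld) - p), 4 * sqrt(p * (1 - p) / n))
  expect_gt(sum(obs$out_window), 0)
  expect_gt(sum(is.na(obs$temperature_C)), 0)
  expect_gt(sum(is.na(obs$salinity_psu)), 0)
  # observation density per unit area rises towards the coast
  dens <- table(w$region[obs$cell]) /
    tapply(w$grid$area_m2, w$region, sum)[levels(w$region)]
  expect_gt(dens[["nearshore"]], dens[["open"]])
})

test_that("zero observation noise reproduces the cell truth through the disequilibrium conversion", {
  w <- make_world(small_config(noise_sigma = 0))
  obs <- sample_observations(w)
  recs <- mixed_layer_filter(obs, w$grid, w$predictors$mld,
                             sss = w$predictors$sss, sst = w$predictors$sst,
                             allow_missing_t = "synthetic_noT")
  recs <- delta_ch4(recs, w$stations)
  ok <- !recs$filled_temperature  # filled T changes solubility, skip those
  expect_equal(recs$dch4_nM[ok], recs$dch4_true[ok], tolerance = 1e-9)
})

test_that("atmospheric stations carry the configured trend, gradient and cycle", {
  cfg <- small_config()
  st <- make_atm_stations(cfg)
  eq <- st[st$lat == 0, ]
  first <- mean(eq$pch4_ppb[eq$year == cfg$years[1]])
  last <- mean(eq$pch4_ppb[eq$year == cfg$years[2]])
  expect_lt(abs(first - 1650), 5)   # ~1650 ppb at the 1980 end
  expect_lt(abs(last - 1850), 10)   # ~1850 ppb at the 2016 end
  # trend disabled: yearly means constant
  st0 <- make_atm_stations(small_config(atm_trend_ppb_yr = 0))
  eq0 <- st0[st0$lat == 0, ]
  ym <- tapply(eq0$pch4_ppb, eq0$year, mean)
  expect_lt(diff(range(ym)), 1e-9)
  # harmonic regression recovers the seasonal amplitude (trend off, so the
  # within-year ramp cannot alias into the harmonics)
  s1 <- st0[st0$station_id == "ST1" & st0$year == 2000, ]
  fit <- lm(pch4_ppb ~ sin(2 * pi * (month - 0.5) / 12) +
              cos(2 * pi * (month - 0.5) / 12), data = s1)
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amp, cfg$atm_seasonal_ppb * abs(tanh(s1$lat[1] / 25)),
               tolerance = 1e-6)
})

test_that("wind products share a base field and stay non-negative", {
  w <- world_small()
  u1 <- wind_daily(w, 1, days = 1:30)
  expect_true(all(u1 >= 0))
  # perturbation scale 0 makes all products identical
  w0 <- make_world(small_config(wind_perturb = 0))
  expect_equal(wind_daily(w0, 1, days = 1:10), wind_daily(w0, 3, days = 1:10))
  # nonzero scale separates them
  expect_false(isTRUE(all.equal(wind_daily(w, 1, days = 1:10),
                                wind_daily(w, 2, days = 1:10))))
})

test_that("ice products are valid fractions confined poleward of the ice line", {
  w <- world_small()
  for (f in w$ice_products) {
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(f[abs(w$grid$lat) < w$config$ice_lat, ] == 0))
  }
  # some ice exists somewhere poleward
  expect_gt(max(w$ice_products[[1]]), 0.5)
})

test_that("bubble spectrum satisfies the observed size constraints", {
  sp <- make_bubble_spectrum(synth_config())
  expect_equal(sum(sp$volume_fraction), 1, tolerance = 1e-12)
  in28 <- sp$diameter_mm >= 2 & sp$diameter_mm <= 8
  expect_gte(sum(sp$volume_fraction[in28]), 0.99)
  vwm <- sum(sp$diameter_mm * sp$volume_fraction)
  expect_gte(vwm, 3.5); expect_lte(vwm, 4.5)
})

test_that("truth-point sampling respects the regional split", {
  w <- world_small()
  cp <- sample_truth_points(w, 500, "coastal", seed = 3)
  op <- sample_truth_points(w, 500, "open", seed = 3)
  expect_true(all(cp$depth_m < 2000))
  expect_true(all(op$depth_m >= 2000))
  # deterministic under the seed
  cp2 <- sample_truth_points(w, 500, "coastal", seed = 3)
  expect_identical(cp, cp2)
})
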