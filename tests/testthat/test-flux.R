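test_that("gas transfer velocity evaluates the published relations", {
  # quadratic algorithm, u = 10, Sc = 660: 0.251 * 100 = 25.1 cm/hr = 6.024 m/day
  expect_equal(gas_transfer_velocity(10, 660, 1L), 25.1 * 0.24,
               tolerance = 1e-12)
  # zero wind: quadratic and cubic forms vanish
  expect_equal(gas_transfer_velocity(0, 660, 1L), 0)
  expect_equal(gas_transfer_velocity(0, 660, 4L), 0)
  # Schmidt normalization: k scales as (Sc/660)^-1/2
  expect_equal(gas_transfer_velocity(10, 1320, 1L),
               gas_transfer_velocity(10, 660, 1L) / sqrt(2))
  # name and id access agree
  expect_equal(gas_transfer_velocity(7, 660, "N00"),
               gas_transfer_velocity(7, 660, 3L))
  expect_error(gas_transfer_velocity(5, 660, 9L), "unknown")
  expect_error(gas_transfer_velocity(-1, 660, 1L), ">= 0")
})

test_that("the four k algorithms diverge by more than 20% at 5-10 m/s", {
  for (u in seq(5, 10, by = 1)) {
    ks <- sapply(1:4, function(a) gas_transfer_velocity(u, 660, a))
    expect_gt((max(ks) - min(ks)) / mean(ks), 0.2)
  }
})

test_that("daily flux implements the gas-transfer equation cellwise with ice blocking", {
  w <- world_small()
  n <- w$grid$n_cell
  map1 <- matrix(1, n, 12)
  # full ice with eps = 1 shuts the flux off exactly
  w_ice <- w
  w_ice$ice_products[[1]] <- matrix(1, n, 12)
  f_blocked <- daily_flux(w_ice, map1, day = 30, wind_id = 1, ice_id = 1,
                          k_id = 1, eps_ice = 1)
  expect_equal(f_blocked, rep(0, n))
  # eps = 0.9 under full ice leaves 10% of the open-water flux
  f_open <- daily_flux(w_ice, map1, day = 30, eps_ice = 0)
  f_leak <- daily_flux(w_ice, map1, day = 30, eps_ice = 0.9)
  expect_equal(f_leak, 0.1 * f_open, tolerance = 1e-12)
  # zero disequilibrium, zero flux
  expect_equal(daily_flux(w, matrix(0, n, 12), day = 100), rep(0, n))
  # negative dCH4 gives uptake
  expect_true(all(daily_flux(w, matrix(-1, n, 12), day = 100,
                             eps_ice = 0) < 0))
  expect_error(daily_flux(w, matrix(1, 5, 12), day = 1), "match")
})

test_that("annual integration converts units and partitions regions exactly", {
  w <- world_small()
  A <- sum(w$grid$area_m2)
  # uniform 1 mmol m^-2 yr^-1: emissions = A * 16.043e-3 g / 1e12 Tg
  out <- integrate_annual(rep(1, w$grid$n_cell), w$grid$area_m2, w$region)
  expect_equal(out[["global"]], A * 16.043e-3 / 1e12, tolerance = 1e-12)
  # regions partition the ocean: global equals the sum of the four regions
  expect_equal(out[["global"]],
               sum(out[c("nearshore", "shelf", "slope", "open")]))
  expect_equal(unname(integrate_annual(rep(0, w$grid$n_cell), w$grid$area_m2,
                                       w$region)), rep(0, 5))
})

test_that("precomputed transfer terms match the direct daily summation", {
  w <- world_small()
  terms <- transfer_terms(w)
  set.seed(31)
  map <- matrix(abs(rnorm(w$grid$n_cell * 12)), w$grid$n_cell, 12)
  for (draw in list(c(1, 1, 1, 1), c(2, 3, 4, 0.93))) {
    fast <- oceanch4:::annual_flux_cells(map, terms, draw[1], draw[2],
                                         draw[3], draw[4])
    direct <- rowSums(sapply(1:365, function(d)
      daily_flux(w, map, d, draw[1], draw[2], draw[3], draw[4])))
    expect_equal(fast, direct, tolerance = 1e-10)
  }
})

test_that("flux is linear in the dCH4 map at a fixed draw", {
  w <- world_small()
  terms <- transfer_terms(w)
  map <- matrix(runif(w$grid$n_cell * 12), w$grid$n_cell, 12)
  f1 <- oceanch4:::annual_flux_cells(map, terms, 1, 1, 2, 0.95)
  f3 <- oceanch4:::annual_flux_cells(3 * map, terms, 1, 1, 2, 0.95)
  expect_equal(f3, 3 * f1, tolerance = 1e-12)
})

test_that("monte carlo flux is deterministic and statistically coherent", {
  ch <- chain_small()
  ens <- generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell,
                           n_members = 2, seed = 3, skill_floor = NULL,
                           maxit = 60)
  terms <- transfer_terms(ch$world)
  mc1 <- monte_carlo_flux(ens, ch$world, n_draws = 150, seed = 9,
                          terms = terms)
  mc2 <- monte_carlo_flux(ens, ch$world, n_draws = 150, seed = 9,
                          terms = terms)
  expect_identical(mc1$draws, mc2$draws)
  expect_true(all(mc1$draws$eps_ice >= 0.9 & mc1$draws$eps_ice <= 1))
  s <- summary(mc1)
  g <- s[s$scope == "pooled" & s$quantity == "global", ]
  # percentiles are monotone and bracket the median
  expect_true(g$p10 <= g$p25 && g$p25 <= g$p50 && g$p50 <= g$p75 &&
                g$p75 <= g$p90)
  # the global column equals the regional sum per draw
  expect_equal(mc1$draws$global,
               rowSums(mc1$draws[, c("nearshore", "shelf", "slope", "open")]),
               tolerance = 1e-12)
  # doubling the draw count leaves the mean within Monte-Carlo error
  mc4 <- monte_carlo_flux(ens, ch$world, n_draws = 300, seed = 10,
                          terms = terms)
  se <- sd(mc1$draws$global) / sqrt(150) + sd(mc4$draws$global) / sqrt(300)
  expect_lt(abs(mean(mc4$draws$global) - mean(mc1$draws$global)), 5 * se)
  # single draw degenerates to a point
  mc0 <- monte_carlo_flux(ens, ch$world, n_draws = 1, seed = 2, terms = terms)
  expect_equal(nrow(mc0$draws), 1L)
})

test_that("variance partition isolates the two uncertainty sources", {
  ch <- chain_small()
  ens <- generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell,
                           n_members = 2, seed = 3, skill_floor = NULL,
                           maxit = 60)
  terms <- transfer_terms(ch$world)
  # identical maps: the dCH4 ensemble variance is exactly zero
  ens_dup <- ens
  ens_dup$maps <- list(ens$maps[[1]], ens$maps[[1]])
  vp <- variance_partition(ens_dup, ch$world, terms = terms)
  expect_equal(vp$var_dch4, 0)
  expect_gt(vp$var_transfer, 0)
  # identical products and a single k algorithm: transfer variance zero
  w1 <- make_world(small_config(wind_perturb = 0, ice_perturb = 0))
  t1 <- transfer_terms(w1)
  vp1 <- variance_partition(ens, w1, terms = t1, k_ids = 2L)
  expect_equal(vp1$var_transfer, 0, tolerance = 1e-12)
})

test_that("plateau detection picks the coarsest resolution within tolerance", {
  sweep <- data.frame(resolution = c(0.25, 0.5, 1, 2),
                      global_flux_tg = c(1.00, 1.02, 1.10, 1.50))
  expect_equal(find_plateau(sweep, tol = 0.05), 0.5)
  expect_equal(find_plateau(sweep, tol = 0.12), 1)
  expect_equal(find_plateau(sweep, tol = 1), 2)
})
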