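# Shared fixtures, built once per test run. The small world (2 degrees) keeps
# unit tests fast; the default world exercises the study conditions in the
# acceptance suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_config <- function(...) {
  args <- list(resolution_deg = 2, n_tracks = 6, obs_per_track = 150,
               track_leg_obs = 50, seed = 7L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

world_small <- function() memo("world_small", function() make_world(small_config()))

chain_small <- function() memo("chain_small", function() {
  w <- world_small()
  obs <- sample_observations(w)
  recs <- mixed_layer_filter(obs, w$grid, w$predictors$mld,
                             sss = w$predictors$sss)
  recs <- delta_ch4(recs, w$stations)
  clim <- bin_climatology(recs, w$grid, w$depth)
  tab <- build_training_table(clim, w$depth, w$predictors)
  gtab <- build_grid_table(w$grid, w$depth, w$predictors)
  list(world = w, obs = obs, recs = recs, clim = clim, tab = tab, gtab = gtab)
})

world_default <- function() memo("world_default", function() make_world())

chain_default <- function() memo("chain_default", function() {
  w <- world_default()
  obs <- sample_observations(w)
  recs <- mixed_layer_filter(obs, w$grid, w$predictors$mld,
                             sss = w$predictors$sss)
  recs <- delta_ch4(recs, w$stations)
  clim <- bin_climatology(recs, w$grid, w$depth)
  tab <- build_training_table(clim, w$depth, w$predictors)
  gtab <- build_grid_table(w$grid, w$depth, w$predictors)
  list(world = w, obs = obs, recs = recs, clim = clim, tab = tab, gtab = gtab)
})

terms_default <- function() memo("terms_default", function()
  transfer_terms(world_default()))

ensemble_default <- function() memo("ensemble_default", function() {
  ch <- chain_default()
  generate_ensemble(ch$tab, ch$gtab, ch$world$grid$n_cell, n_members = 8,
                    seed = 5L)
})

profile_default <- function() memo("profile_default", function()
  efficiency_profile(world_default()$spectrum))
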