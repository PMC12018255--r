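# Shared seeded scenarios, generated once per test run.
.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(key, cfg) {
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- generate_scenario(cfg)
  }
  .scenario_cache[[key]]
}

# Mid-size scenario for unit tests.
unit_scenario <- function() {
  cached_scenario("unit", scenario_config(seed = 11, n_rows = 80,
                                          n_cols = 80))
}

# Study-scale scenario used by the acceptance checks (200 x 200, designed
# loss fraction 0.60).
study_scenario <- function() {
  cached_scenario("study", scenario_config(seed = 42))
}

# Small helper grid builders.
mk_grid <- function(m, lat_max = 1, lon_min = 0, resolution = 1 / 12) {
  grid_layer(m, lat_max = lat_max, lon_min = lon_min,
             resolution = resolution)
}
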