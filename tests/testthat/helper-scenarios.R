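# Simulated fixtures are expensive enough to share across test files; each
# is generated once per test run under a fixed seed (the study conditions)
# and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (!exists(key, envir = .sim_cache))
    assign(key, fun(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# full-size default scenario: 2 Mb, 100 islands, mean depth 5/bp
default_sim <- function() {
  cached("default", function()
    simulate_scenario(scenario_default(), seed = 42L))
}

# small default-shaped scenario for unit-scale checks
small_sim <- function() {
  cached("small", function()
    simulate_scenario(scenario_default(genome_length = 3e5, n_genes = 14,
                                       n_islands = 16, gene_gap = 3000),
                      seed = 7L))
}

xinact_sim <- function() {
  cached("xinact", function()
    simulate_scenario(scenario_xinactivation(), seed = 42L))
}

tumour_sim <- function() {
  cached("tumour", function()
    simulate_scenario(scenario_tumour(), seed = 42L))
}

truth_mcols <- function(sim) as.data.frame(S4Vectors::mcols(sim$truth))

# standard pipeline fragments reused by several tests
normalized_cap <- function(sim = default_sim()) {
  cached("norm_cap", function() normalize_tracks(sim$tracks$CAP, "CAP")$tracks)
}

normalized_map <- function(sim = default_sim()) {
  cached("norm_map", function() normalize_tracks(sim$tracks$MAP, "MAP")$tracks)
}
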