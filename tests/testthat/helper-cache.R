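# Heavy example runs are shared across test files through a lazy cache.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .run_cache)) assign(key, force(expr), .run_cache)
  get(key, .run_cache)
}

carbon_run <- function() cached("carbon", run_simulation(carbon_example_config()))

carbon_run_half_dt <- function()
  cached("carbon_half", run_simulation(carbon_example_config(list(dt = 0.5))))

nitrogen_run <- function()
  cached("nitrogen", run_simulation(nitrogen_example_config()))

nitrogen_run_nodenit <- function()
  cached("nitrogen_nodenit", run_simulation(nitrogen_example_config(
    list(disable_reactions = "Denitrification_DZ"))))
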