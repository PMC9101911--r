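# Shared fixtures. Expensive simulations are memoised so several test files
# can reuse one run; coarse output grids (dt 0.1-0.25 h) keep unit tests
# fast without touching solver tolerances.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_model <- function() cached("model", pbpk_model())

oral_2day_coarse <- function() {
  cached("oral_2day", simulate(default_model(),
                               schedule = oral_schedule(days = 2),
                               t_end = 48, dt = 0.1))
}

dermal_2day_coarse <- function() {
  cached("dermal_2day", simulate(default_model(),
                                 schedule = continuous_dose("dermal", 0.68, 48),
                                 t_end = 48, dt = 0.2))
}
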