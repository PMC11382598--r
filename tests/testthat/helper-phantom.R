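# Shared fixtures: small specs and a memoized default phantom so expensive
# generation runs once per test session.

quiet_spec <- function(...) {
  # no injected artifacts unless explicitly overridden
  defaults <- list(motion_spike_times = integer(),
                   motion_spike_magnitudes = numeric(),
                   variance_lines = data.frame(i = integer(), j = integer(),
                                               scale = numeric()),
                   networks = list())
  user <- list(...)
  defaults[names(user)] <- user
  do.call(simSpec, defaults)
}

tiny_spec <- function(...) {
  # small grid for brute-force oracles
  quiet_spec(dims = c(16L, 16L, 16L), n_volumes = 30L, ...)
}

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_sim <- function() memo_fixture("default_sim", function()
  simulateEpi(simSpec(seed = 11L)))

clean_sim <- function() memo_fixture("clean_sim", function()
  simulateEpi(quiet_spec(seed = 12L)))

# Brute-force Pearson correlation (independent of the package's vectorized
# paths).
naive_cor <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
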