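# Shared fixtures, built lazily once per test run.

# 4^4 = 256-model database on the reference grid: large enough that the
# base cell classifies [H, M, L] and the slow/medium/fast band triplets
# are all populated, small enough to build in seconds.
test_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_database(default_grid_spec(4))
    db
  }
})

test_bands <- function() derive_bands(test_db())

# small E-only / E-I configs at reduced scale for fast network tests
small_config <- function(n_pyr = 100, n_pv = 5, duration = 500, seed = 42,
                         ...) {
  cfg <- network_config(duration = duration, seed = seed, ...)
  cfg$n_pyr <- as.integer(n_pyr)
  cfg$n_pv <- as.integer(n_pv)
  validate_network_config(cfg)
}

# closed-form simple-regression slope, independent of lm()
ls_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}
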