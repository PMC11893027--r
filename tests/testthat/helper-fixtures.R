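# Shared fixtures: tiny phantoms and acquisition settings kept small so the
# suite stays fast. Built fresh per call; seeds fixed for reproducibility.

TE3 <- c(42, 107, 172)

small_spec <- function(ga = 30, ...) {
  phantom_spec(ga, grid_shape = 48, seed = 42, ...)
}

small_acq <- function(n_dynamics = 2) {
  acquisition_spec(n_dynamics = n_dynamics)
}

# cached small phantom scan (expensive pieces reused across tests)
small_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_scan(small_spec(), small_acq())
    cache
  }
})

# a noiseless control cohort generated exactly from the reference curves
noiseless_cohort <- function(seed = 7) {
  simulate_regional_cohort(seed = seed, noise_scale = 0)
}
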