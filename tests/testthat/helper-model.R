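# Shared fixtures.  The scenario battery (several multi-year runs on a
# reduced grid) is expensive, so it is computed lazily once per test run
# and cached in this environment.

.cache <- new.env(parent = emptyenv())

# reduced-size study configuration used by the run-level tests: same
# physics and forcing as the defaults, smaller grid and shorter spin-up
test_config <- function(scenario = "gm_redi", eddy = list(), ...) {
  run_config(grid = list(ny = 16, nz = 40),
             run = utils::modifyList(
               list(scenario = scenario, years_spinup = 7, years_output = 2,
                    dt = 21600, seed = 42, init_noise_sd = 0),
               list(...)),
             eddy = eddy)
}

get_run <- function(scenario = "gm_redi", eddy = list(), key = scenario,
                    ...) {
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- suppressWarnings(
      run_experiment(test_config(scenario, eddy, ...)))
  }
  .cache[[key]]
}

# small grids used by operator tests
tiny_grid <- function(ny = 6, nz = 8, Ly = 1.2e6, H = 3000) {
  build_grid(ny, nz, Ly, H, stretching = "uniform")
}

# linear stratified front: b = N2 * z + M2 * y
linear_b <- function(grid, N2 = 4e-6, M2 = 2e-9) {
  outer(M2 * grid$y_centers, rep(1, grid$nz)) +
    outer(rep(1, grid$ny), N2 * grid$z_centers)
}
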