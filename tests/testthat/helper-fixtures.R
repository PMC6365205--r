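# Shared fixtures for expensive, deterministic computations. Helpers are
# sourced once per test run; results are cached in this environment so the
# full-physics scenarios and the Monte Carlo batch are computed a single time
# and reused by module and acceptance tests.
.fx <- new.env(parent = emptyenv())

fx_transducer <- function() {
  if (is.null(.fx$xd)) .fx$xd <- default_transducer()
  .fx$xd
}

# full-physics validation scenarios at thermometry resolution (0.5 mm)
fx_t8 <- function() {
  if (is.null(.fx$t8))
    .fx$t8 <- simulate_sonication(fus_scenario(10, 6.3), fx_transducer())
  .fx$t8
}

fx_t9 <- function() {
  if (is.null(.fx$t9))
    .fx$t9 <- simulate_sonication(fus_scenario(50, 7.9), fx_transducer())
  .fx$t9
}

# reduced-fidelity grid used by the Monte Carlo analyses (1 mm spacing,
# 30 x 30 x 60 mm box cropped around the beam axis)
fx_mc_scenario <- function(milk, power)
  fus_scenario(milk, power, spacing_mm = 1.0, box_mm = c(30, 30, 60))

# Monte Carlo batch over all eight (composition x power) scenarios
fx_mc_batch <- function(n = 50, seed = 101) {
  key <- sprintf("mc_%d_%d", n, seed)
  if (is.null(.fx[[key]])) {
    xd <- fx_transducer()
    runs <- list()
    for (p in c(6.3, 7.9))
      for (m in c(10, 30, 50, 70)) {
        sc <- fx_mc_scenario(m, p)
        model <- scenario_mc_model(sc, xd)
        runs[[sprintf("%g_%g", m, p)]] <-
          run_mc(model, scenario_distributions(m, p), n = n,
                 seed = seed + length(runs))
      }
    .fx[[key]] <- runs
  }
  .fx[[key]]
}

# small analytic linear model used by the UQ tests (no physics)
linear_dists <- function() {
  list(param_dist("x1", 10, 2), param_dist("x2", 5, 1),
       param_dist("x3", 2, 0.5))
}

linear_model <- function(coefs = c(3, -1, 0)) {
  function(p) c(y = unname(coefs[1] * p[["x1"]] + coefs[2] * p[["x2"]] +
                  coefs[3] * p[["x3"]]))
}

# homogeneous phantom material map, used by solver oracles
uniform_model <- function(shape, spacing_mm, props, origin = NULL) {
  grid <- voxel_grid(shape, spacing_mm, origin = origin)
  material_map(grid, array(1L, dim = shape), list(props))
}

# water-only propagation of the calibrated driven plane on the t8 grid;
# used by the angular-spectrum oracle test and the calibration gate
fx_water_prop <- function() {
  if (is.null(.fx$wp)) {
    sc <- fus_scenario(10, 6.3)
    xd <- fx_transducer()
    grid <- fusuq:::scenario_grid(sc)
    erfa <- fusuq:::scenario_erfa(sc, xd)
    set <- drive_settings(rep(0, xd$n_elements), rep(1, xd$n_elements), 6.3)
    plane <- drive_array(erfa, set, xd)
    model <- uniform_model(grid$shape, grid$spacing, water_properties(),
                           origin = grid$origin)
    .fx$wp <- list(pf = has_propagate(plane, model, 940e3), plane = plane,
                   grid = grid, model = model, xd = xd)
  }
  .fx$wp
}
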