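# Shared fixtures: coarse-grid solver settings for fast unit tests, a
# memoised solved field, and a synthetic analytic wall profile.

coarse_numerics <- function(...) {
  numerics_config(axial_cells = 128L, radial_cells = 24L, ...)
}

# memoise expensive solves across tests within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a converged coarse 50% axisymmetric stenosis solve
fixture_field_50 <- function() {
  cached("field_50", {
    spec <- stenosis_spec(1.5e-3, 50, 8e-3, 19e-3)
    geom <- make_stenosis_profile(spec, 38e-3, 128L)
    ic <- inlet_condition(0.45, 0.225, 1.5e-3, 130, 80)
    solve_steady_flow(geom, ic, numerics = coarse_numerics())
  })
}

# hand-built wall profile with known extrema (no solver involved)
synthetic_profile <- function(n = 401) {
  s <- seq(0, 0.04, length.out = n)
  wss <- 2 + 10 * exp(-((s - 0.018) / 0.002)^2)      # peak at s = 18 mm
  pressure <- 12000 - 2e5 * s + 500 * exp(-((s - 0.012) / 0.004)^2)
  structure(data.frame(s = s, wss = wss, pressure = pressure),
            class = c("wall_profile", "data.frame"))
}
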