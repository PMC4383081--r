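# Shared fixtures, built once per test run. Small grids keep the suite
# fast; the acceptance tests use larger, study-condition problem sizes.

fixture_env <- new.env(parent = emptyenv())

# 64-voxel, 6.25 A/voxel decorated 14-pf phantom (400 A, 5 repeats) with
# its cached projector
fx_phantom <- function() {
  if (is.null(fixture_env$phantom)) {
    spec <- lattice_spec(n_pf = 14)
    grid <- list(n = rep(64, 3), voxel = 6.25)
    vol <- render_density(build_lattice(spec, 7), grid, resolution = 15,
                          periodic_z = TRUE)
    fixture_env$phantom <- list(spec = spec, grid = grid, vol = vol,
                                projector = make_projector(vol),
                                step = helical_step(spec))
  }
  fixture_env$phantom
}

# matching undecorated phantom
fx_phantom_bare <- function() {
  if (is.null(fixture_env$bare)) {
    spec <- lattice_spec(n_pf = 14, decoration_occupancy = 0)
    grid <- fx_phantom()$grid
    fixture_env$bare <- render_density(build_lattice(spec, 7), grid,
                                       resolution = 15, periodic_z = TRUE)
  }
  fixture_env$bare
}

# a small noise-free projection of the phantom at a generic orientation
fx_projection <- function() {
  fx_phantom()$projector(37, 90, 0, "+")
}

expect_cor_gt <- function(a, b, threshold) {
  expect_gt(stats::cor(as.vector(a), as.vector(b)), threshold)
}
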