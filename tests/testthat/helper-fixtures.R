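# Small fixtures shared across test files. Grids are kept tiny: the solver
# properties under test are resolution-independent.

# single uniform slab with thresholds far above any applied field (linear
# regime): |E| = U/d under plate electrodes
slab_stack <- function(sigma = 0.2, thickness = 1e-2) {
  layer_stack(list(skin_layer("homog", thickness, sigma,
                              v_per_cm(1e9), v_per_cm(2e9), 2)))
}

two_layer_stack <- function(s1 = 0.05, d1 = 2e-3, s2 = 0.4, d2 = 8e-3) {
  layer_stack(list(
    skin_layer("a", d1, s1, v_per_cm(1e9), v_per_cm(2e9), 2),
    skin_layer("b", d2, s2, v_per_cm(1e9), v_per_cm(2e9), 2)))
}

# coarse grid over the full 8-layer skin stack, small enough for fast
# protocol runs in tests
tiny_skin_grid <- function(nx = 15L) {
  build_grid(default_skin_stack(), lateral_extent = 24e-3,
             resolution = list(nx = nx,
                               nz_layer = c(2L, 2L, 2L, 2L, 2L, 2L, 3L, 3L)))
}

plate_solution <- function(stack, nx = 5L, nz_layer = 10L, U = 100) {
  g <- build_grid(stack, lateral_extent = 1e-2,
                  resolution = list(nx = nx, nz_layer = nz_layer))
  sol <- solve_field(g, list(contact_patch(g, U, "top"),
                             contact_patch(g, 0, "bottom")))
  list(grid = g, sol = sol, U = U)
}
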