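# Shared fixture builders. Everything is generated in code; nothing binary
# ships with the package.

# a small uniform-spacing geometry around the origin
tiny_geometry <- function(dims = c(10, 10, 10), spacing = 1,
                          origin = c(0, 0, 0)) {
  grid_geometry(origin, rep(spacing, 3), dims)
}

# uniform-dose cube
uniform_dose <- function(gy = 40, dims = c(10, 10, 10), spacing = 1,
                         origin = c(0, 0, 0)) {
  g <- tiny_geometry(dims, spacing, origin)
  dose_grid(array(gy, dim = dims), g)
}

# affine dose field a + bx x + by y + bz z on a grid (trilinear-exact)
affine_dose <- function(a, b, geometry) {
  pts <- as.matrix(expand.grid(x = grid_axis(geometry, 1),
                               y = grid_axis(geometry, 2),
                               z = grid_axis(geometry, 3)))
  v <- a + pts %*% b
  dose_grid(array(v, dim = geometry$dims), geometry)
}

# axis-aligned square contour [x0, x0+w) x [y0, y0+w) at height z
square_contour <- function(x0, y0, w, z) {
  rt_contour(cbind(c(x0, x0 + w, x0 + w, x0),
                   c(y0, y0, y0 + w, y0 + w), z))
}

# random paired dose grids for gamma oracle comparisons; the evaluated grid
# extends past the reference by more than the search radius so every
# candidate point is interpolable
random_gamma_pair <- function(dims_ref, pad_mm = 8, dose_range = c(0.5, 3)) {
  rg <- tiny_geometry(dims_ref)
  ref <- dose_grid(array(stats::runif(prod(dims_ref), dose_range[1],
                                      dose_range[2]), dim = dims_ref), rg)
  ed <- dims_ref + 2L * pad_mm
  eg <- grid_geometry(rg$origin - pad_mm, rg$spacing, ed)
  ev <- dose_grid(array(stats::runif(prod(ed), dose_range[1], dose_range[2]),
                        dim = ed), eg)
  list(reference = ref, evaluated = ev)
}

# steep linear-gradient pair: evaluated is the reference field translated by
# `shift_mm` along x, on a larger grid
gradient_shift_pair <- function(shift_mm = 2, g_per_mm = 1, base = 10,
                                dims_ref = c(8, 8, 8), pad_mm = 8) {
  rg <- tiny_geometry(dims_ref)
  ref <- affine_dose(base, c(g_per_mm, 0, 0), rg)
  eg <- grid_geometry(rg$origin - pad_mm, rg$spacing, dims_ref + 2L * pad_mm)
  # eval(x) = ref(x - shift): dose match found at candidate x + shift
  ev <- affine_dose(base - g_per_mm * shift_mm, c(g_per_mm, 0, 0), eg)
  list(reference = ref, evaluated = ev)
}
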