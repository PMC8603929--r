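# Shared fixtures, built in code at test time.

SPACING <- c(0.3, 0.313, 0.313)

# Uniform-conductivity map on the acquisition grid.
uniform_sigma <- function(value = 0.5, ny = 64, nx = 128) {
  conductivity_map(array(value, c(1, ny, nx)), SPACING)
}

# Quadratic phase a*((x-xc)^2+(y-yc)^2) as a full-grid array (radians).
quad_phase_grid <- function(a, ny = 64, nx = 128) {
  array(crmrept:::quadratic_phase_slice(ny, nx, SPACING[2] * 1e-3,
                                        SPACING[3] * 1e-3, a),
        c(1, ny, nx))
}

# Two-compartment phantom: inner ellipse sigma_in inside background sigma_bg.
two_compartment_phantom <- function(sigma_bg = 0.44, sigma_in = 0.96,
                                    ny = 64, nx = 128) {
  spec <- phantom_spec(grid_shape = c(1, ny, nx), spacing_mm = SPACING,
                       regions = list(region_spec("inner",
                                                  c(0, ny / 2, nx / 2),
                                                  c(1, round(ny * 0.3), round(nx * 0.27)),
                                                  sigma = sigma_in, md = 0.8, t2 = 50)),
                       background_sigma = sigma_bg)
  build_phantom(spec)
}

# Smooth random field spanning several wrap cycles (seeded). The requested
# span is reduced if needed so neighbouring voxels never differ by more
# than ~0.8*pi (the Itoh condition any unwrapper needs).
random_smooth_field <- function(seed, ny = 48, nx = 48, span_rad = 6 * pi) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(ny * nx), ny, nx)
    m <- crmrept:::smooth_gaussian2d(m, radius = 6)
    m <- (m - min(m)) / diff(range(m)) * span_rad
    steep <- max(abs(diff(m)), abs(t(diff(t(m)))))
    if (steep > 0.8 * pi) m <- m * (0.8 * pi / steep)
    m
  })
}

# Independently coded Welch t-test (textbook formulas), used as an oracle.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), dof)
  list(t = t, dof = dof, p = p)
}
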