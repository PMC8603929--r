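test_that("homogeneous phantom paints the background value everywhere", {
  spec <- phantom_spec(grid_shape = c(1, 16, 20), background_sigma = 0.5)
  ph <- build_phantom(spec)
  expect_true(all(ph$sigma$values == 0.5))
  expect_true(all(ph$vois$labels == 0L))
})

test_that("default six-region phantom carries the reference tissue values", {
  ph <- build_phantom(default_phantom_spec())
  truth_sigma <- c(contralateral_cortex = 0.44, tumor_rim = 0.96,
                   viable_tumor = 0.93, tumor_core = 0.84,
                   ventricles = 0.72, edema = 0.77)
  truth_md <- c(contralateral_cortex = 0.69, tumor_rim = 0.81,
                viable_tumor = 0.76, tumor_core = 0.89,
                ventricles = 1.23, edema = 0.89)
  sig_means <- vapply(region_values(ph$sigma, ph$vois), mean, numeric(1))
  md_means <- vapply(region_values(ph$md, ph$vois), mean, numeric(1))
  expect_equal(sig_means[names(truth_sigma)], truth_sigma, tolerance = 1e-12)
  expect_equal(md_means[names(truth_md)], truth_md, tolerance = 1e-12)
})

test_that("ellipsoid labelling matches a brute-force voxel scan", {
  ny <- 33; nx <- 47
  center <- c(0, 14.5, 22); semi <- c(1, 6.5, 9.25)
  spec <- phantom_spec(grid_shape = c(1, ny, nx),
                       regions = list(region_spec("blob", center, semi,
                                                  sigma = 1, md = 1, t2 = 50)))
  ph <- build_phantom(spec)
  count <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    q <- ((iy - 1 - center[2]) / semi[2])^2 + ((ix - 1 - center[3]) / semi[3])^2
    if (q <= 1) count <- count + 1L
  }
  expect_identical(sum(ph$vois$labels == 1L), count)
})

test_that("invalid region specifications are rejected", {
  r1 <- region_spec("a", c(0, 8, 8), c(1, 3, 3), 1, 1, 50)
  expect_error(phantom_spec(grid_shape = c(1, 16, 16), regions = list(r1, r1)),
               "duplicated region label")
  r2 <- region_spec("edge", c(0, 15, 15), c(1, 4, 4), 1, 1, 50)
  expect_error(phantom_spec(grid_shape = c(1, 16, 16), regions = list(r2)),
               "exceeds grid bounds")
})

test_that("forward solve reproduces the closed-form quadratic solution", {
  f <- 4e8
  rhs <- 2 * crmrept:::MU0 * 2 * pi * f
  a <- rhs * 0.5 / 4          # lap(phi) = 4a = 2 mu0 omega sigma, sigma = 0.5
  bound <- quad_phase_grid(a)
  phi <- forward_phase(uniform_sigma(0.5), larmor_hz = f, boundary = bound)
  rel <- abs(phi$values - bound) / (abs(bound) + 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("forward solution scales linearly with sigma for uniform media", {
  f <- 4e8
  rhs <- 2 * crmrept:::MU0 * 2 * pi * f
  a <- rhs * 0.5 / 4
  bound <- quad_phase_grid(a, ny = 32, nx = 40)
  p1 <- forward_phase(uniform_sigma(0.5, 32, 40), larmor_hz = f, boundary = bound)
  p2 <- forward_phase(uniform_sigma(1.0, 32, 40), larmor_hz = f, boundary = 2 * bound)
  expect_equal(p2$values, 2 * p1$values, tolerance = 1e-9)
})

test_that("forward solution satisfies the divergence stencil (independent check)", {
  ph <- two_compartment_phantom()
  phi <- forward_phase(ph$sigma)
  rhs <- 2 * crmrept:::MU0 * 2 * pi * larmor_hz(9.4)
  S <- ph$sigma$values[1, , ]; P <- phi$values[1, , ]
  hy <- SPACING[2] * 1e-3; hx <- SPACING[3] * 1e-3
  beta <- 1 / S
  ny <- nrow(S); nx <- ncol(S)
  worst <- 0
  for (iy in 2:(ny - 1)) for (ix in 2:(nx - 1)) {
    lhs <- ((beta[iy, ix] + beta[iy + 1, ix]) / 2 * (P[iy + 1, ix] - P[iy, ix]) +
            (beta[iy, ix] + beta[iy - 1, ix]) / 2 * (P[iy - 1, ix] - P[iy, ix])) / hy^2 +
           ((beta[iy, ix] + beta[iy, ix + 1]) / 2 * (P[iy, ix + 1] - P[iy, ix]) +
            (beta[iy, ix] + beta[iy, ix - 1]) / 2 * (P[iy, ix - 1] - P[iy, ix])) / hx^2
    worst <- max(worst, abs(lhs - rhs))
  }
  expect_lt(worst, 1e-8 * rhs)
})

test_that("simulated acquisition is noiseless-exact and seed-deterministic", {
  ph <- two_compartment_phantom(ny = 24, nx = 32)
  spec1 <- phantom_spec(grid_shape = c(1, 24, 32), coil_count = 1L)
  phi <- forward_phase(ph$sigma)
  raw <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec1, noise_sd = 0, seed = 1)
  # single channel carries a zero phase offset: stored phase is wrap(phi_tr)
  stored <- wrap_to_pi(Arg(raw$complex_values[1, 1, 1, , ]))
  expect_equal(stored, wrap_to_pi(phi$values[1, , ]), tolerance = 1e-12)
  # T2 decay: |echo n| / |echo 1| = exp(-(TEn - TE1)/T2) voxelwise
  m1 <- Mod(raw$complex_values[1, 1, 1, , ])
  m5 <- Mod(raw$complex_values[1, 5, 1, , ])
  expect_equal(m5 / m1, exp(-(raw$te_ms[5] - raw$te_ms[1]) / ph$t2_ms[1, , ]),
               tolerance = 1e-12)
  # determinism contract
  spec4 <- phantom_spec(grid_shape = c(1, 24, 32), coil_count = 4L)
  r1 <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec4, noise_sd = 0.01, seed = 7)
  r2 <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec4, noise_sd = 0.01, seed = 7)
  r3 <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec4, noise_sd = 0.01, seed = 8)
  expect_identical(r1$complex_values, r2$complex_values)
  expect_false(identical(r1$complex_values, r3$complex_values))
  # t2 <= 0 anywhere in the mask is rejected
  bad_t2 <- ph$t2_ms; bad_t2[1, 3, 3] <- 0
  expect_error(simulate_acquisition(ph$sigma, bad_t2, phi, spec1, seed = 1),
               "t2 must be > 0")
})

test_that("DWI simulation follows the mono-exponential closed form", {
  md <- md_map(array(0.7, c(1, 6, 6)), SPACING)
  bt <- default_dwi_btable()
  dwi <- simulate_dwi(md, bt$bvals, bt$bvecs, noise_sd = 0, seed = 1)
  # b = 1000 s/mm^2 x 0.7 um^2/ms -> exp(-0.7)
  expect_equal(unname(dwi$signal[2, 1, 1, 1]), exp(-0.7), tolerance = 1e-12)
  expect_equal(unname(dwi$signal[1, 1, 1, 1]), 1, tolerance = 1e-15)
  md0 <- md_map(array(0, c(1, 4, 4)), SPACING)
  dwi0 <- simulate_dwi(md0, bt$bvals, bt$bvecs, noise_sd = 0, seed = 1)
  expect_true(all(dwi0$signal == 1))
  expect_error(simulate_dwi(md, bvals = c(1000, 2000), bvecs = rbind(c(1, 0, 0), c(0, 1, 0))),
               "b = 0")
})

test_that("round trip: phase-based estimate recovers a uniform conductivity", {
  phi <- forward_phase(uniform_sigma(0.72))
  sig <- phase_based_sigma(phi, recon_config())
  v <- sig$values[sig$mask]
  expect_lt(max(abs(v - 0.72) / 0.72), 0.01)
})
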