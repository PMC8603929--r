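test_that("derivative kernels are exact on polynomials", {
  f <- 4e8
  rhs <- 2 * crmrept:::MU0 * 2 * pi * f
  a <- rhs * 0.5 / 4
  pm <- phase_map(quad_phase_grid(a, 32, 40), SPACING)
  for (kern in c("central", "savgol")) {
    cfg <- recon_config(larmor_hz = f, laplacian_kernel = kern)
    sd_ <- spatial_derivatives(pm, cfg)
    expect_equal(sd_$lap[sd_$valid], rep(4 * a, sum(sd_$valid)), tolerance = 1e-9)
  }
  # constant field: all derivatives vanish
  pm0 <- phase_map(array(1.3, c(1, 16, 16)), SPACING)
  sd0 <- spatial_derivatives(pm0, recon_config())
  expect_true(all(abs(sd0$grad) < 1e-12) && all(abs(sd0$lap) < 1e-12))
  # linear ramp g*x: gradient g along x, zero Laplacian
  g <- 50
  x <- (seq_len(20) - 1) * SPACING[3] * 1e-3
  ramp <- array(rep(g * x, each = 16), c(1, 16, 20))
  sdl <- spatial_derivatives(phase_map(ramp, SPACING), recon_config())
  expect_equal(sdl$grad[3, , , ][sdl$valid], rep(g, sum(sdl$valid)), tolerance = 1e-9)
  expect_lt(max(abs(sdl$lap[sdl$valid])), 1e-6)
  expect_lt(max(abs(sdl$grad[2, , , ][sdl$valid])), 1e-9)
  # a grid thinner than the kernel is rejected
  thin <- phase_map(array(0, c(1, 2, 10)), SPACING)
  expect_error(spatial_derivatives(thin, recon_config()), "thinner")
})

test_that("phase-based estimate matches the closed form", {
  f <- 4e8
  rhs <- 2 * crmrept:::MU0 * 2 * pi * f
  a <- rhs * 0.5 / 4
  cfg <- recon_config(larmor_hz = f)
  sig <- phase_based_sigma(phase_map(quad_phase_grid(a), SPACING), cfg)
  expect_equal(sig$values[sig$mask], rep(0.5, sum(sig$mask)), tolerance = 1e-9)
  # scaling the curvature scales sigma: 0.44 S/m case
  sig2 <- phase_based_sigma(phase_map(quad_phase_grid(a * 0.44 / 0.5), SPACING), cfg)
  expect_equal(sig2$values[sig2$mask], rep(0.44, sum(sig2$mask)), tolerance = 1e-9)
  # constant phase: nothing is physical, everything masked
  sig0 <- phase_based_sigma(phase_map(array(2, c(1, 16, 16)), SPACING), cfg)
  expect_false(any(sig0$mask))
})

test_that("uniform-sigma round trip is exact with exact boundary and c = 0", {
  f <- 4e8
  phi <- forward_phase(uniform_sigma(0.5), larmor_hz = f)
  cfg <- recon_config(larmor_hz = f, c_mode = "fixed", c_value = 0)
  rr <- cr_mrept_solve(phi, cfg, boundary_u = 2.0)
  v <- rr$sigma$values[rr$sigma$mask]
  expect_lt(max(abs(v - 0.5) / 0.5), 0.001)
  # homogeneous-limit agreement of the phase-based estimate
  pb <- phase_based_sigma(phi, cfg)
  expect_lt(max(abs(pb$values[pb$mask] - 0.5) / 0.5), 0.01)
})

test_that("zero RHS with zero Dirichlet boundary gives the trivial solution", {
  phi <- forward_phase(uniform_sigma(0.5, 24, 32))
  rr <- suppressWarnings(cr_mrept_solve(phi, recon_config(c_mode = "fixed", c_value = 1e-3),
                                        boundary_u = 0, rhs_value = 0))
  expect_equal(max(abs(rr$u), na.rm = TRUE), 0)
})

test_that("two-compartment round trip recovers region medians within 10%", {
  ph <- two_compartment_phantom(0.44, 0.96)
  phi <- smooth_phase(forward_phase(ph$sigma), 3)
  rr <- cr_mrept_solve(phi, recon_config())
  rr <- erode_and_mask(rr, ph$vois, 3)
  med_in <- stats::median(rr$sigma$values[ph$vois$labels == 1 & rr$sigma$mask])
  med_out <- stats::median(rr$sigma$values[ph$vois$labels == 0 & rr$sigma$mask])
  expect_lt(abs(med_in - 0.96) / 0.96, 0.10)
  expect_lt(abs(med_out - 0.44) / 0.44, 0.10)
})

test_that("returned residual norm matches an independent stencil application", {
  ph <- two_compartment_phantom(0.44, 0.96, ny = 32, nx = 48)
  phi <- forward_phase(ph$sigma)
  for (cfg in list(recon_config(),
                   recon_config(c_mode = "fixed", c_value = 0))) {
    rr <- cr_mrept_solve(phi, cfg)
    oracle <- cr_residual_oracle(rr, phi, cfg)
    expect_lt(abs(oracle - rr$residual_norm), 1e-10)
  }
})

test_that("reported conductivities are physical, violations masked not clipped", {
  ph <- two_compartment_phantom(0.44, 0.96, ny = 32, nx = 48)
  phi <- forward_phase(ph$sigma)
  raw <- simulate_acquisition(ph$sigma, ph$t2_ms, phi,
                              phantom_spec(grid_shape = c(1, 32, 48)),
                              noise_sd = 0.02, seed = 3)
  ec <- combine_echoes(grpc_combine(raw))
  rr <- suppressWarnings(cr_mrept_solve(smooth_phase(ec$phase, 3), recon_config()))
  v <- rr$sigma$values[rr$sigma$mask]
  expect_true(all(v > 0 & v < 10))
  # and none of the surviving values sit exactly on a clip boundary
  expect_false(any(v == 10))
})

test_that("erosion masks boundary shells as expected", {
  lab <- array(0L, c(1, 17, 17))
  lab[1, 5:13, 5:13] <- 1L              # 9 x 9 square region
  vois <- voi_set(lab, c(`1` = "sq"), spacing_mm = SPACING)
  phi <- forward_phase(uniform_sigma(0.5, 17, 17))
  rr <- cr_mrept_solve(phi, recon_config(), boundary_u = 2)
  r0 <- erode_and_mask(rr, vois, 0)
  expect_identical(r0$sigma$mask, rr$sigma$mask)
  r2 <- erode_and_mask(rr, vois, 2)
  core <- which(r2$sigma$mask & lab == 1L, arr.ind = TRUE)
  expect_identical(nrow(core), 25L)     # 5 x 5 surviving core
  expect_true(all(core[, 2] %in% 7:11 & core[, 3] %in% 7:11))
  expect_warning(erode_and_mask(rr, vois, 5), "fully masked")
})

test_that("median absolute error grows with acquisition noise", {
  ph <- two_compartment_phantom(0.44, 0.96, ny = 32, nx = 48)
  spec <- phantom_spec(grid_shape = c(1, 32, 48))
  phi <- forward_phase(ph$sigma)
  truth <- ph$sigma$values
  cfg <- recon_config(laplacian_kernel = "savgol", savgol_radius_vox = 2)
  med_err <- sapply(c(0.002, 0.01, 0.05), function(ns) {
    errs <- sapply(1:20, function(s) {
      raw <- simulate_acquisition(ph$sigma, ph$t2_ms, phi, spec,
                                  noise_sd = ns, seed = 500 + s)
      ec <- combine_echoes(grpc_combine(raw))
      rr <- suppressWarnings(cr_mrept_solve(smooth_phase(ec$phase, 3), cfg))
      stats::median(abs(rr$sigma$values - truth)[rr$sigma$mask])
    })
    stats::median(errs)
  })
  expect_true(all(diff(med_err) >= 0))
})
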