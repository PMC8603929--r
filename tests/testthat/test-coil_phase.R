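make_multicoil <- function(phi_true, mags, psis, noise_sd = 0, seed = 1,
                           te_ms = c(8, 16)) {
  ny <- nrow(phi_true); nx <- ncol(phi_true)
  nch <- length(mags); nec <- length(te_ms)
  vals <- array(complex(real = 0), c(nch, nec, 1, ny, nx))
  for (k in seq_len(nch)) for (e in seq_len(nec))
    vals[k, e, 1, , ] <- mags[[k]] * exp(1i * (phi_true + psis[[k]]))
  if (noise_sd > 0)
    vals <- vals + withr::with_seed(seed, array(
      complex(real = rnorm(length(vals), sd = noise_sd),
              imaginary = rnorm(length(vals), sd = noise_sd)), dim(vals)))
  multicoil_echo_data(vals, te_ms, noise_sd, seed, SPACING)
}

circ_sd <- function(x) sqrt(-2 * log(Mod(mean(exp(1i * x)))))

test_that("single-channel combination is an identity pass-through", {
  phi <- random_smooth_field(1, 16, 16, span_rad = 2)
  raw <- make_multicoil(phi, list(matrix(1, 16, 16)), list(matrix(0, 16, 16)))
  comb <- grpc_combine(raw)
  expect_equal(Arg(comb$complex_values[1, 1, , ]), phi, tolerance = 1e-12)
})

test_that("constant channel offsets are removed up to the reference offset", {
  phi <- random_smooth_field(2, 24, 24, span_rad = 2)
  mags <- list(matrix(1.2, 24, 24), matrix(1, 24, 24),
               matrix(0.9, 24, 24), matrix(0.8, 24, 24))
  psis <- list(matrix(0.4, 24, 24), matrix(-1.1, 24, 24),
               matrix(2.0, 24, 24), matrix(0.7, 24, 24))
  raw <- make_multicoil(phi, mags, psis)
  comb <- grpc_combine(raw)
  # channel 1 (highest magnitude) is the reference, so its offset survives
  expect_identical(comb$provenance$reference_channel, 1L)
  resid <- wrap_to_pi(Arg(comb$complex_values[1, 1, , ]) - phi - 0.4)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("combination beats the best single channel under noise", {
  # Monte Carlo over seeds: circular SD of (combined - truth) must not
  # exceed that of the best individual channel
  wins <- 0L
  n_seeds <- 50L
  phi <- random_smooth_field(3, 24, 24, span_rad = 1.5)
  mags <- list(1.1 + 0 * phi, 0.9 + 0 * phi, 1 + 0 * phi, 0.95 + 0 * phi)
  psis <- list(0 * phi, 0.8 - 0.02 * row(phi) * 0.05, -1.2 + 0.01 * col(phi),
               0.5 + 0.0005 * (row(phi) - 12)^2)
  for (s in seq_len(n_seeds)) {
    raw <- make_multicoil(phi, mags, psis, noise_sd = 0.15, seed = 100 + s,
                          te_ms = 8)
    comb <- grpc_combine(raw)
    err_comb <- circ_sd(Arg(comb$complex_values[1, 1, , ]) - phi)
    err_ch <- vapply(1:4, function(k)
      circ_sd(Arg(raw$complex_values[k, 1, 1, , ]) - phi - psis[[k]]), numeric(1))
    if (err_comb <= min(err_ch)) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})

test_that("all-zero channels are excluded with a warning", {
  phi <- random_smooth_field(4, 12, 12, span_rad = 1)
  raw <- make_multicoil(phi, list(1 + 0 * phi, 0 * phi), list(0 * phi, 0 * phi))
  expect_warning(comb <- grpc_combine(raw), "all-zero")
  expect_equal(Arg(comb$complex_values[1, 1, , ]), phi, tolerance = 1e-12)
})

test_that("unwrapping is exactly congruent and recovers smooth fields", {
  for (s in 1:10) {
    f <- random_smooth_field(s, 32, 32, span_rad = 6 * pi)
    w <- phase_map(array(wrap_to_pi(f), c(1, 32, 32)), SPACING, wrapped = TRUE)
    u <- unwrap_phase(w)
    # congruence: rewrap reproduces the wrapped input bitwise
    expect_identical(wrap_phase(u)$values, w$values)
    # numeric congruence of the unwrapped values themselves
    expect_lt(max(abs(wrap_to_pi(u$values - w$values))), 1e-9)
    # recovery up to one global 2*pi*k constant
    dev <- u$values[1, , ] - f
    dev <- dev - 2 * pi * round(stats::median(dev) / (2 * pi))
    expect_lt(max(abs(dev)), 1e-9)
  }
})

test_that("a quadratic spanning > 8 pi is recovered after unwrapping", {
  a <- 10 * pi / (0.02^2)   # ~12 pi span across the FOV
  q <- quad_phase_grid(a, 64, 128)
  expect_gt(diff(range(q)), 8 * pi)
  w <- phase_map(wrap_to_pi(q), SPACING, wrapped = TRUE)
  u <- unwrap_phase(w)
  dev <- u$values - q
  dev <- dev - 2 * pi * round(stats::median(dev) / (2 * pi))
  expect_lt(max(abs(dev)), 1e-9)
  expect_identical(wrap_phase(u)$values, w$values)
})

test_that("disconnected mask components unwrap independently", {
  f <- random_smooth_field(9, 24, 24, span_rad = 4 * pi)
  mask <- array(TRUE, c(1, 24, 24)); mask[1, , 12:13] <- FALSE
  w <- phase_map(array(wrap_to_pi(f), c(1, 24, 24)), SPACING,
                 wrapped = TRUE, mask = mask)
  u <- unwrap_phase(w)
  expect_identical(sort(unique(u$components[u$components > 0])), c(1L, 2L))
  for (comp in 1:2) {
    sel <- u$components == comp
    dev <- (u$values - array(f, c(1, 24, 24)))[sel]
    dev <- dev - 2 * pi * round(stats::median(dev) / (2 * pi))
    expect_lt(max(abs(dev)), 1e-9)
  }
})

test_that("echo weighting follows the squared-magnitude rule", {
  # two echoes, magnitudes (2, 1), phases (0, 0.3): output = 0.3/5 = 0.06
  ny <- 4; nx <- 4
  vals <- array(complex(real = 0), c(2, 1, ny, nx))
  vals[1, 1, , ] <- 2 * exp(1i * 0)
  vals[2, 1, , ] <- 1 * exp(1i * 0.3)
  comb <- combined_complex_image(vals, c(8, 16), list(), SPACING)
  res <- combine_echoes(comb)
  expect_equal(res$phase$values[1, 1, 1], 0.06, tolerance = 1e-12)
  expect_equal(apply(res$weights$weights, 2:4, sum),
               array(1, c(1, ny, nx)), tolerance = 1e-12)
})

test_that("identical echo phases pass through regardless of magnitudes", {
  phi <- random_smooth_field(5, 16, 16, span_rad = 2)
  vals <- array(complex(real = 0), c(3, 1, 16, 16))
  for (e in 1:3) vals[e, 1, , ] <- (4 - e) * exp(1i * phi)
  comb <- combined_complex_image(vals, c(8, 16, 24), list(), SPACING)
  res <- combine_echoes(comb)
  expect_equal(res$phase$values[1, , ], phi, tolerance = 1e-10)
})

test_that("zero-magnitude voxels are masked out of the combined phase", {
  vals <- array(complex(real = 1), c(2, 1, 4, 4))
  vals[, 1, 2, 3] <- 0
  comb <- combined_complex_image(vals, c(8, 16), list(), SPACING)
  res <- combine_echoes(comb)
  expect_false(res$phase$mask[1, 2, 3])
  expect_true(is.na(res$phase$values[1, 2, 3]))
})

test_that("weighted echo averaging reduces phase noise versus echo 1", {
  # 10-echo decay (T2 = 40 ms): the M^2-weighted phase must beat echo 1
  wins <- 0L
  n_seeds <- 50L
  te <- seq(8, by = 8, length.out = 10)
  decay <- exp(-te / 40)
  phi <- random_smooth_field(6, 16, 16, span_rad = 1)
  for (s in seq_len(n_seeds)) {
    vals <- array(complex(real = 0), c(10, 1, 16, 16))
    for (e in 1:10) vals[e, 1, , ] <- decay[e] * exp(1i * phi)
    vals <- vals + withr::with_seed(2000 + s, array(
      complex(real = rnorm(length(vals), sd = 0.05),
              imaginary = rnorm(length(vals), sd = 0.05)), dim(vals)))
    comb <- combined_complex_image(vals, te, list(), SPACING)
    res <- combine_echoes(comb, unwrap = FALSE)
    err_w <- stats::var(as.vector(wrap_to_pi(res$phase$values[1, , ] - phi)))
    err_1 <- stats::var(as.vector(wrap_to_pi(Arg(vals[1, 1, , ]) - phi)))
    if (err_w < err_1) wins <- wins + 1L
  }
  expect_gte(wins, 48L)
})
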