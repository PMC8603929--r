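#' Multi-coil multi-echo complex data container
#'
#' @param complex_values complex array, dim (channel, echo, nz, ny, nx).
#' @param te_ms strictly increasing echo times, ms.
#' @param noise_sd complex-channel noise standard deviation used.
#' @param seed RNG seed used for the noise realisation.
#' @param spacing_mm voxel spacing (z, y, x), mm.
#' @export
multicoil_echo_data <- function(complex_values, te_ms, noise_sd = 0,
                                seed = NA_integer_, spacing_mm) {
  d <- dim(complex_values)
  if (length(d) != 5) stop("complex_values must be (channel, echo, z, y, x)")
  if (d[2] != length(te_ms)) stop("echo axis length must equal length(te_ms)")
  if (any(diff(te_ms) <= 0)) stop("te_ms must be strictly increasing")
  structure(list(complex_values = complex_values, te_ms = as.numeric(te_ms),
                 noise_sd = noise_sd, seed = seed,
                 spacing_mm = check_spacing(spacing_mm)),
            class = "multicoil_echo_data")
}

## Smooth receive-coil profiles: Gaussian magnitude lobes centred at the four
## in-plane corners plus low-order polynomial phase offsets. Channel 1 has a
## zero phase offset by construction, so noiseless single-channel simulations
## store exactly the wrapped transceive phase.
coil_profiles <- function(ny, nx, coil_count) {
  u <- (seq_len(ny) - 1) / max(ny - 1, 1) - 0.5   # normalised y
  v <- (seq_len(nx) - 1) / max(nx - 1, 1) - 0.5   # normalised x
  U <- matrix(u, ny, nx); V <- matrix(v, ny, nx, byrow = TRUE)
  corners <- matrix(c(-0.5, -0.5, -0.5, 0.5, 0.5, -0.5, 0.5, 0.5),
                    ncol = 2, byrow = TRUE)
  # psi coefficients: (const, y, x, y^2, x^2, xy); first channel identically 0
  psi_tab <- matrix(c(0, 0, 0, 0, 0, 0,
                      0.8, -0.9, 1.5, 0.6, 1.1, -0.7,
                      -1.2, 1.3, -0.7, 1.0, -0.8, 0.5,
                      2.0, 0.8, 0.9, -1.2, 0.7, 0.9),
                    ncol = 6, byrow = TRUE)
  mags <- vector("list", coil_count)
  psis <- vector("list", coil_count)
  for (k in seq_len(coil_count)) {
    cc <- corners[((k - 1) %% 4) + 1, ]
    # the first element is the strongest; it also carries the zero-offset
    # convention, so the reference channel's phase is the transceive phase
    scale <- if (k == 1) 1.2 else 1
    mags[[k]] <- scale * (0.3 + exp(-((U - cc[1])^2 + (V - cc[2])^2) / (2 * 0.35^2)))
    p <- psi_tab[((k - 1) %% 4) + 1, ] * (1 + 0.15 * ((k - 1) %/% 4))
    psis[[k]] <- p[1] + p[2] * U + p[3] * V + p[4] * U^2 + p[5] * V^2 + p[6] * U * V
  }
  list(magnitude = mags, phase_offset = psis)
}

#' Simulate a multi-coil multi-echo spin-echo acquisition
#'
#' Each channel k and echo n records
#' `M0 * exp(-TE_n / T2) * S_k * exp(i (phi_tr + psi_k))` plus i.i.d. complex
#' Gaussian noise, where `S_k` is a smooth positive magnitude profile and
#' `psi_k` a smooth per-channel phase offset (zero for channel 1). Defaults
#' mirror a preclinical MSME protocol: first echo 8 ms, echo spacing 8 ms,
#' 10 echoes.
#'
#' @param sigma ground-truth [conductivity_map()] (used for grid checks).
#' @param t2_map numeric array of T2 values, ms; must be positive.
#' @param phase unwrapped transceive [phase_map()].
#' @param spec the [phantom_spec()] supplying `coil_count`.
#' @param noise_sd standard deviation of the complex Gaussian noise per
#'   channel (real and imaginary parts independently).
#' @param seed RNG seed; required for reproducibility.
#' @param te_ms echo times, ms.
#' @param m0 equilibrium signal magnitude.
#' @return a [multicoil_echo_data()].
#' @export
simulate_acquisition <- function(sigma, t2_map, phase, spec, noise_sd = 0,
                                 seed = 1L,
                                 te_ms = seq(8, by = 8, length.out = 10),
                                 m0 = 1) {
  stopifnot(inherits(sigma, "conductivity_map"), inherits(phase, "phase_map"),
            noise_sd >= 0)
  t2_map <- as_grid(t2_map)
  d <- dim(sigma$values)
  check_same_grid(dim(t2_map), d, "sigma and t2_map")
  check_same_grid(dim(phase$values), d, "sigma and phase")
  if (any(t2_map[sigma$mask] <= 0)) stop("t2 must be > 0 everywhere in the mask")
  nch <- spec$coil_count
  nec <- length(te_ms)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  prof <- coil_profiles(ny, nx, nch)
  vals <- array(complex(real = 0), c(nch, nec, nz, ny, nx))
  for (z in seq_len(nz)) {
    phi <- phase$values[z, , ]
    t2 <- t2_map[z, , ]
    for (k in seq_len(nch)) {
      phasor <- exp(1i * (phi + prof$phase_offset[[k]])) * prof$magnitude[[k]]
      for (e in seq_len(nec)) {
        vals[k, e, z, , ] <- m0 * exp(-te_ms[e] / t2) * phasor
      }
    }
  }
  if (noise_sd > 0) {
    n <- length(vals)
    noise <- with_seed(seed, complex(real = stats::rnorm(n, sd = noise_sd),
                                     imaginary = stats::rnorm(n, sd = noise_sd)))
    vals <- vals + array(noise, dim(vals))
  }
  multicoil_echo_data(vals, te_ms, noise_sd, seed, sigma$spacing_mm)
}

#' Diffusion-weighted image stack container
#'
#' @param signal numeric array, dim (volume, nz, ny, nx).
#' @param bvals b-values per volume, s/mm^2.
#' @param bvecs matrix (volume x 3) of gradient directions; unit norm where
#'   the b-value is positive.
#' @param seed RNG seed used for the noise realisation.
#' @param spacing_mm voxel spacing (z, y, x), mm.
#' @export
dwi_stack <- function(signal, bvals, bvecs, seed = NA_integer_, spacing_mm) {
  d <- dim(signal)
  if (length(d) != 4) stop("signal must be (volume, z, y, x)")
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (d[1] != length(bvals) || nrow(bvecs) != length(bvals) || ncol(bvecs) != 3)
    stop("bvals/bvecs must match the volume axis")
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  nz <- sqrt(rowSums(bvecs^2))
  if (any(abs(nz[bvals > 0] - 1) > 1e-6))
    stop("bvecs must have unit norm where bval > 0")
  structure(list(signal = signal, bvals = bvals, bvecs = bvecs, seed = seed,
                 spacing_mm = check_spacing(spacing_mm)),
            class = "dwi_stack")
}

#' Evenly spread diffusion gradient directions
#'
#' Generates `n` unit vectors by electrostatic repulsion of antipodal point
#' pairs on the sphere, starting from a seeded random configuration; the
#' result is deterministic for a given seed.
#'
#' @param n number of directions.
#' @param seed RNG seed for the initial configuration.
#' @param n_iter repulsion iterations.
#' @export
dwi_directions <- function(n = 15, seed = 20240214L, n_iter = 400) {
  v <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  v <- v / sqrt(rowSums(v^2))
  step <- 0.02
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      di <- sweep(-v, 2, v[i, ], `+`)        # v_i - v_j
      si <- sweep(v, 2, v[i, ], `+`)         # v_i + v_j (antipodal images)
      r3 <- pmax(sqrt(rowSums(di^2)), 1e-6)^3
      s3 <- pmax(sqrt(rowSums(si^2)), 1e-6)^3
      di <- di / r3; si <- si / s3
      di[i, ] <- 0
      f[i, ] <- colSums(di) + colSums(si)
    }
    # project force onto the tangent plane and take a small step
    f <- f - v * rowSums(f * v)
    v <- v + step * f
    v <- v / sqrt(rowSums(v^2))
  }
  v
}

#' Default multi-shell b-table (b = 0, 1000, 2000 s/mm^2, 15 directions)
#' @export
default_dwi_btable <- function() {
  dirs <- dwi_directions(15)
  list(bvals = c(0, rep(1000, 15), rep(2000, 15)),
       bvecs = rbind(c(0, 0, 0), dirs, dirs))
}

#' Simulate a diffusion-weighted acquisition
#'
#' Noiseless signal follows the tensor model `S = S0 exp(-b g' D g)`; by
#' default the tensor is isotropic, `D = MD * I`. Units: b in s/mm^2 and
#' diffusivities in um^2/ms, so the exponent is `b * adc / 1000`. Noise is
#' added on complex channels and the magnitude taken, i.e. Rician.
#'
#' @param md an [md_map()] of mean diffusivities, um^2/ms.
#' @param bvals,bvecs b-table; default [default_dwi_btable()].
#' @param s0_map non-diffusion-weighted signal (array or scalar, default 1).
#' @param noise_sd complex-channel noise standard deviation.
#' @param seed RNG seed.
#' @param tensor optional full tensor field, dim (6, nz, ny, nx) with unique
#'   elements ordered (xx, yy, zz, xy, xz, yz); overrides the isotropic model.
#' @return a [dwi_stack()].
#' @export
simulate_dwi <- function(md, bvals = NULL, bvecs = NULL, s0_map = 1,
                         noise_sd = 0, seed = 1L, tensor = NULL) {
  stopifnot(inherits(md, "md_map"), noise_sd >= 0)
  if (any(md$values[md$mask] < 0)) stop("mean diffusivity must be >= 0")
  if (is.null(bvals) || is.null(bvecs)) {
    bt <- default_dwi_btable()
    bvals <- bt$bvals; bvecs <- bt$bvecs
  }
  bvecs <- as.matrix(bvecs)
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  d <- dim(md$values)
  nvol <- length(bvals)
  s0 <- if (length(s0_map) == 1) array(s0_map, d) else as_grid(s0_map)
  sig <- array(0, c(nvol, d))
  for (vv in seq_len(nvol)) {
    if (is.null(tensor)) {
      adc <- md$values
    } else {
      g <- bvecs[vv, ]
      w <- c(g[1]^2, g[2]^2, g[3]^2,
             2 * g[1] * g[2], 2 * g[1] * g[3], 2 * g[2] * g[3])
      adc <- array(colSums(matrix(tensor, 6, prod(d)) * w), d)
    }
    sig[vv, , , ] <- s0 * exp(-bvals[vv] * adc / 1000)
  }
  if (noise_sd > 0) {
    n <- length(sig)
    sig <- with_seed(seed, {
      re <- sig + array(stats::rnorm(n, sd = noise_sd), dim(sig))
      im <- array(stats::rnorm(n, sd = noise_sd), dim(sig))
      sqrt(re^2 + im^2)
    })
  }
  dwi_stack(sig, bvals, bvecs, seed, md$spacing_mm)
}
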