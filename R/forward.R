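#' Forward transceive-phase model over a conductivity phantom
#'
#' Solves, slice by slice, the divergence-form elliptic equation
#' \deqn{\nabla\cdot\left(\frac{1}{\sigma}\nabla\phi_{tr}\right) = 2\mu_0\omega}
#' for the transceive phase with Dirichlet boundary values. This is the
#' algebraic twin of the convection-reaction equation the reconstruction
#' inverts, so forward simulation and inversion form a self-consistent round
#' trip; model error can be introduced deliberately by smoothing `sigma`
#' before the forward solve.
#'
#' Discretisation is a 5-point finite-difference stencil with face
#' coefficients taken as arithmetic means of 1/sigma at neighbouring voxel
#' centres; for uniform sigma and a quadratic boundary the discrete solution
#' reproduces the closed-form Poisson solution exactly.
#'
#' @param sigma a [conductivity_map()]; strictly positive on its mask.
#' @param larmor_hz operating frequency in Hz; default derives from
#'   `b0_tesla` via [larmor_hz()].
#' @param boundary optional numeric array on the full grid supplying
#'   Dirichlet phase values on the outer ring of each slice; default is the
#'   homogeneous-medium quadratic solution for the boundary-ring median
#'   conductivity, centred on the slice.
#' @param b0_tesla main field used when `larmor_hz` is NULL.
#' @return an unwrapped [phase_map()] on the same grid.
#' @export
forward_phase <- function(sigma, larmor_hz = NULL, boundary = NULL,
                          b0_tesla = 9.4) {
  stopifnot(inherits(sigma, "conductivity_map"))
  if (is.null(larmor_hz)) larmor_hz <- larmor_hz(b0_tesla)
  omega <- 2 * pi * larmor_hz
  rhs_val <- 2 * MU0 * omega
  d <- dim(sigma$values)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (ny < 3 || nx < 3) stop("grid too small for the 5-point stencil")
  if (!is.null(boundary)) {
    boundary <- as_grid(boundary)
    check_same_grid(dim(boundary), d, "sigma and boundary")
    if (any(!is.finite(boundary))) stop("boundary values must be finite")
  }
  hy <- sigma$spacing_mm[2] * 1e-3
  hx <- sigma$spacing_mm[3] * 1e-3
  phi <- array(NA_real_, d)
  for (z in seq_len(nz)) {
    S <- sigma$values[z, , ]
    if (any(!is.finite(S) | S <= 0))
      stop("sigma must be strictly positive and finite on every voxel of the slice")
    if (is.null(boundary)) {
      ring <- c(S[1, ], S[ny, ], S[, 1], S[, nx])
      phi_b <- quadratic_phase_slice(ny, nx, hy, hx,
                                     a = rhs_val * stats::median(ring) / 4)
    } else {
      phi_b <- boundary[z, , ]
    }
    phi[z, , ] <- solve_divergence_slice(S, phi_b, hy, hx, rhs_val)
  }
  phase_map(phi, sigma$spacing_mm, wrapped = FALSE)
}

## Quadratic phase a*((x-xc)^2 + (y-yc)^2) on a slice, coordinates in metres.
quadratic_phase_slice <- function(ny, nx, hy, hx, a, center = NULL) {
  y <- axis_coords_m(ny, hy * 1e3)
  x <- axis_coords_m(nx, hx * 1e3)
  if (is.null(center)) center <- c(mean(y), mean(x))
  outer((y - center[1])^2, (x - center[2])^2, `+`) * a
}

## Solve div((1/sigma) grad phi) = rhs_val on one slice with Dirichlet
## boundary phi_b on the outer ring. Returns the full (ny, nx) phase.
solve_divergence_slice <- function(S, phi_b, hy, hx, rhs_val) {
  ny <- nrow(S); nx <- ncol(S)
  beta <- 1 / S
  niy <- ny - 2L; nix <- nx - 2L
  idmat <- matrix(NA_integer_, ny, nx)
  idmat[2:(ny - 1), 2:(nx - 1)] <- seq_len(niy * nix)
  iy <- rep(2:(ny - 1), times = nix)
  ix <- rep(2:(nx - 1), each = niy)
  ids <- idmat[cbind(iy, ix)]
  b <- rep(rhs_val, niy * nix)
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  diagv <- numeric(niy * nix)
  for (dir in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ny_off <- dir[1]; nx_off <- dir[2]
    h2 <- if (ny_off != 0) hy^2 else hx^2
    nb_iy <- iy + ny_off; nb_ix <- ix + nx_off
    bface <- (beta[cbind(iy, ix)] + beta[cbind(nb_iy, nb_ix)]) / 2
    a <- bface / h2
    diagv <- diagv - a
    nb_id <- idmat[cbind(nb_iy, nb_ix)]
    inb <- !is.na(nb_id)
    ti <- c(ti, ids[inb]); tj <- c(tj, nb_id[inb]); tv <- c(tv, a[inb])
    # boundary neighbours contribute known values to the RHS
    b[ids[!inb]] <- b[ids[!inb]] - a[!inb] * phi_b[cbind(nb_iy, nb_ix)][!inb]
  }
  A <- Matrix::sparseMatrix(i = c(ti, ids), j = c(tj, ids), x = c(tv, diagv),
                            dims = c(niy * nix, niy * nix))
  x <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("forward solver failed (singular or ill-conditioned system): ",
                                         conditionMessage(e)))
  res <- max(abs(as.numeric(A %*% x - b)))
  if (!is.finite(res) || res > 1e-6 * abs(rhs_val))
    stop(sprintf("forward solver did not converge: residual %.3e vs RHS %.3e",
                 res, abs(rhs_val)))
  out <- phi_b
  out[2:(ny - 1), 2:(nx - 1)] <- matrix(x, niy, nix)
  out
}
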