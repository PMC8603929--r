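#' Reconstruction configuration
#'
#' Collects the tunable parameters of conductivity reconstruction.
#'
#' @param larmor_hz operating frequency, Hz; default derives from `b0_tesla`.
#' @param b0_tesla main field, tesla (used when `larmor_hz` is NULL).
#' @param c_mode `"auto"` sets the artificial diffusion coefficient per
#'   slice to `0.25 * h * q25(|grad phi|)` (h = largest voxel spacing, q25
#'   the lower quartile of the in-plane phase-gradient magnitude over the
#'   solve domain): the weakly-convected quartile of the domain then sits at
#'   mesh Peclet <= 2 and is centrally differenced, while
#'   stronger-convection voxels fall back to monotone first-order upwinding
#'   via the Peclet switch. `"fixed"` uses `c_value`.
#' @param c_value diffusion coefficient used when `c_mode = "fixed"` (>= 0).
#' @param laplacian_kernel `"central"` (3-point) or `"savgol"`
#'   (local-quadratic Savitzky-Golay of radius `savgol_radius_vox`).
#' @param savgol_radius_vox Savitzky-Golay window radius, voxels.
#' @param boundary_mode `"phase_based"` derives Dirichlet values for 1/sigma
#'   from a 3x3-median-filtered phase-based estimate on the domain ring;
#'   `"provided"` expects explicit boundary values.
#' @param erosion_vox default erosion applied by [erode_and_mask()].
#' @export
recon_config <- function(larmor_hz = NULL, b0_tesla = 9.4,
                         c_mode = c("auto", "fixed"), c_value = 0,
                         laplacian_kernel = c("central", "savgol"),
                         savgol_radius_vox = 2L,
                         boundary_mode = c("phase_based", "provided"),
                         erosion_vox = 2L) {
  c_mode <- match.arg(c_mode)
  laplacian_kernel <- match.arg(laplacian_kernel)
  boundary_mode <- match.arg(boundary_mode)
  if (is.null(larmor_hz)) larmor_hz <- larmor_hz(b0_tesla)
  stopifnot(larmor_hz > 0, c_value >= 0, savgol_radius_vox >= 1)
  structure(list(larmor_hz = larmor_hz, mu0 = MU0, c_mode = c_mode,
                 c_value = c_value, laplacian_kernel = laplacian_kernel,
                 savgol_radius_vox = as.integer(savgol_radius_vox),
                 boundary_mode = boundary_mode,
                 erosion_vox = as.integer(erosion_vox)),
            class = "recon_config")
}

## Savitzky-Golay (local quadratic) 1-D kernels on window -r..r: smoothing,
## first- and second-derivative filters evaluated at the window centre.
savgol_kernels <- function(radius) {
  j <- seq(-radius, radius)
  V <- cbind(1, j, j^2)
  P <- solve(crossprod(V), t(V))
  list(smooth = P[1, ], d1 = P[2, ], d2 = 2 * P[3, ])
}

derivative_kernels <- function(cfg) {
  if (cfg$laplacian_kernel == "central")
    list(smooth = 1, d1 = c(-0.5, 0, 0.5), d2 = c(1, -2, 1), radius = 1L)
  else c(savgol_kernels(cfg$savgol_radius_vox),
         list(radius = cfg$savgol_radius_vox))
}

## Convolve a (nz, ny, nx) array along the z axis.
conv_along_z <- function(arr, kernel) {
  d <- dim(arr)
  m <- matrix(arr, d[1], d[2] * d[3])
  array(conv1d_replicate(m, kernel, "row"), d)
}

#' Spatial derivatives of an unwrapped phase map
#'
#' Gradient and Laplacian of the transceive phase in SI units (rad/m,
#' rad/m^2), by 3-point central differences or separable Savitzky-Golay
#' local-quadratic filtering; both differentiate quadratics exactly. For
#' single-slice (or thin) grids the z derivative is zero and the Laplacian
#' is the in-plane one. Voxels within the kernel radius of the grid edge
#' are flagged invalid.
#'
#' @param phase unwrapped [phase_map()].
#' @param cfg a [recon_config()].
#' @return list with `grad` (array dim (3, nz, ny, nx), components ordered
#'   (z, y, x)), `lap` (array), `valid` (logical array) and `radius`.
#' @export
spatial_derivatives <- function(phase, cfg = recon_config()) {
  stopifnot(inherits(phase, "phase_map"))
  if (phase$wrapped) stop("phase must be unwrapped before differentiation")
  kern <- derivative_kernels(cfg)
  r <- kern$radius
  d <- dim(phase$values)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (ny < 2 * r + 1 || nx < 2 * r + 1)
    stop(sprintf("grid (%d x %d in-plane) thinner than the derivative kernel (radius %d)",
                 ny, nx, r))
  hz <- phase$spacing_mm[1] * 1e-3
  hy <- phase$spacing_mm[2] * 1e-3
  hx <- phase$spacing_mm[3] * 1e-3
  use_z <- nz >= 2 * r + 1
  grad <- array(0, c(3, nz, ny, nx))
  lap <- array(0, d)
  for (z in seq_len(nz)) {
    m <- matrix(phase$values[z, , ], ny, nx)
    sy <- conv1d_replicate(m, kern$smooth, "row")    # smoothed along y
    sx <- conv1d_replicate(m, kern$smooth, "col")    # smoothed along x
    grad[2, z, , ] <- conv1d_replicate(sx, kern$d1, "row") / hy
    grad[3, z, , ] <- conv1d_replicate(sy, kern$d1, "col") / hx
    lap[z, , ] <- conv1d_replicate(sx, kern$d2, "row") / hy^2 +
      conv1d_replicate(sy, kern$d2, "col") / hx^2
  }
  if (use_z) {
    # smooth in-plane first, then differentiate along z
    smoothed <- phase$values
    for (z in seq_len(nz)) {
      m <- matrix(phase$values[z, , ], ny, nx)
      smoothed[z, , ] <- conv1d_replicate(conv1d_replicate(m, kern$smooth, "row"),
                                          kern$smooth, "col")
    }
    grad[1, , , ] <- conv_along_z(smoothed, kern$d1) / hz
    lap <- lap + conv_along_z(smoothed, kern$d2) / hz^2
  }
  valid <- array(TRUE, d)
  valid[, c(seq_len(r), ny - seq_len(r) + 1L), ] <- FALSE
  valid[, , c(seq_len(r), nx - seq_len(r) + 1L)] <- FALSE
  if (use_z) valid[c(seq_len(r), nz - seq_len(r) + 1L), , ] <- FALSE
  for (i in 1:3) valid <- valid & array(is.finite(grad[i, , , ]), d)
  valid <- valid & is.finite(lap)
  list(grad = grad, lap = lap, valid = valid, radius = r)
}

#' Phase-based conductivity estimate
#'
#' The piecewise-constant limit of the convection-reaction equation:
#' `sigma = lap(phi_tr) / (2 mu0 omega)`. Fast and local, but biased at
#' tissue interfaces where the gradient terms it neglects are large.
#' Non-positive estimates are masked invalid, never clipped.
#'
#' @param phase unwrapped [phase_map()].
#' @param cfg a [recon_config()].
#' @return a [conductivity_map()].
#' @export
phase_based_sigma <- function(phase, cfg = recon_config()) {
  sd_ <- spatial_derivatives(phase, cfg)
  denom <- 2 * cfg$mu0 * 2 * pi * cfg$larmor_hz
  sig <- sd_$lap / denom
  mask <- sd_$valid & is.finite(sig) & sig > 0
  sig[!mask] <- NA_real_
  conductivity_map(sig, phase$spacing_mm, mask)
}

#' Solve the convection-reaction equation for conductivity
#'
#' Reconstructs `u = 1/sigma` from the optimized transceive phase by
#' assembling and solving, slice by slice, the sparse linear system for
#' \deqn{-c\nabla^2 u + \nabla\phi_{tr}\cdot\nabla u + (\nabla^2\phi_{tr})\,u = 2\mu_0\omega}
#' with Dirichlet boundary values on the ring of the differentiable domain.
#' The artificial diffusion c suppresses the oscillations of the
#' convection-dominated problem; in auto mode it is sized from the lower
#' quartile of the phase-gradient magnitude (see [recon_config()]), large
#' enough to damp node-to-node oscillations but small enough not to blur
#' region interiors. First-order upwinding replaces central differencing of
#' the convection term at any voxel whose local Peclet number exceeds 2
#' (everywhere when c = 0), so stability never depends on c alone.
#'
#' @param phase unwrapped [phase_map()].
#' @param cfg a [recon_config()].
#' @param boundary_u optional Dirichlet values for u = 1/sigma (m/S): a
#'   scalar, or a full-grid array sampled on the domain ring. Default
#'   (`cfg$boundary_mode = "phase_based"`) uses the inverse of the
#'   3x3-median-filtered phase-based estimate.
#' @param rhs_value right-hand side of the equation; default `2 mu0 omega`.
#'   Exposed for degenerate-system checks.
#' @return object of class `recon_result`: `sigma` ([conductivity_map()]),
#'   `u` (full grid, NA outside the solved domain), `residual_norm`
#'   (2-norm of the discrete residual over all interior equations),
#'   `solver_iterations`, `c_used` (per slice), and `config_echo`.
#' @export
cr_mrept_solve <- function(phase, cfg = recon_config(), boundary_u = NULL,
                           rhs_value = NULL) {
  stopifnot(inherits(phase, "phase_map"))
  sd_ <- spatial_derivatives(phase, cfg)
  r <- sd_$radius
  d <- dim(phase$values)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (ny < 2 * r + 3 || nx < 2 * r + 3)
    stop("grid too small for the convection-reaction solve")
  hy <- phase$spacing_mm[2] * 1e-3
  hx <- phase$spacing_mm[3] * 1e-3
  omega <- 2 * pi * cfg$larmor_hz
  if (is.null(rhs_value)) rhs_value <- 2 * cfg$mu0 * omega
  if (is.null(boundary_u) && cfg$boundary_mode == "provided")
    stop("boundary_mode = 'provided' but no boundary_u given")
  sig_pb <- if (is.null(boundary_u)) phase_based_sigma(phase, cfg) else NULL
  u <- array(NA_real_, d)
  res_sq <- 0
  c_used <- numeric(nz)
  a <- r + 1L
  by <- ny - r; bx <- nx - r
  for (z in seq_len(nz)) {
    gy <- matrix(sd_$grad[2, z, , ], ny, nx)
    gx <- matrix(sd_$grad[3, z, , ], ny, nx)
    lp <- matrix(sd_$lap[z, , ], ny, nx)
    dom_gy <- gy[a:by, a:bx]; dom_gx <- gx[a:by, a:bx]
    gq <- stats::quantile(sqrt(dom_gy^2 + dom_gx^2), 0.25, names = FALSE)
    cc <- if (cfg$c_mode == "auto") 0.25 * max(hy, hx) * gq else cfg$c_value
    c_used[z] <- cc
    ub <- matrix(NA_real_, ny, nx)
    if (is.null(boundary_u)) {
      # robust boundary estimate: median-filtered, heavily smoothed
      # phase-based sigma so that phase noise cannot leak in through the
      # Dirichlet ring
      sp <- matrix(sig_pb$values[z, , ], ny, nx)
      sp[!is.finite(sp)] <- stats::median(sp[is.finite(sp)])
      sp <- median_filter3(sp)
      sp <- smooth_gaussian2d(sp, radius = 6)
      sp <- pmin(pmax(sp, 0.05), 10)
      ub <- 1 / sp
    } else if (length(boundary_u) == 1) {
      ub[] <- boundary_u
    } else {
      bu <- as_grid(boundary_u)
      check_same_grid(dim(bu), d, "phase and boundary_u")
      ub <- matrix(bu[z, , ], ny, nx)
    }
    sol <- solve_cr_slice(gy, gx, lp, ub, hy, hx, cc, rhs_value, a, by, bx)
    uz <- matrix(NA_real_, ny, nx)
    # Dirichlet ring keeps its boundary values, interior takes the solution
    uz[a:by, a:bx] <- ub[a:by, a:bx]
    uz[(a + 1):(by - 1), (a + 1):(bx - 1)] <- sol$u_int
    u[z, , ] <- uz
    res_sq <- res_sq + sol$res_sq
  }
  nonpos <- sum(is.finite(u) & u <= 0)
  if (nonpos > 0)
    warning(sprintf("%d voxel(s) with non-physical u <= 0 masked out", nonpos))
  sig <- 1 / u
  mask <- is.finite(sig) & sig > 0 & sig < 10
  sig[!mask] <- NA_real_
  structure(list(sigma = conductivity_map(sig, phase$spacing_mm, mask),
                 u = u, residual_norm = sqrt(res_sq), solver_iterations = 1L,
                 c_used = c_used, config_echo = cfg),
            class = "recon_result")
}

## Assemble and solve one slice of the convection-reaction system.
## Unknowns are the voxels strictly inside the ring [a..by] x [a..bx].
solve_cr_slice <- function(gy, gx, lp, ub, hy, hx, cc, rhs_value, a, by, bx) {
  iy_rng <- (a + 1):(by - 1)
  ix_rng <- (a + 1):(bx - 1)
  niy <- length(iy_rng); nix <- length(ix_rng)
  ny <- nrow(gy); nx <- ncol(gy)
  idmat <- matrix(NA_integer_, ny, nx)
  idmat[iy_rng, ix_rng] <- seq_len(niy * nix)
  iy <- rep(iy_rng, times = nix)
  ix <- rep(ix_rng, each = niy)
  ids <- idmat[cbind(iy, ix)]
  n <- niy * nix
  b <- rep(rhs_value, n)
  diagv <- lp[cbind(iy, ix)]                    # reaction term
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  for (axis in c("y", "x")) {
    h <- if (axis == "y") hy else hx
    v <- if (axis == "y") gy[cbind(iy, ix)] else gx[cbind(iy, ix)]
    upwind <- if (cc > 0) abs(v) * h / (2 * cc) > 2 else rep(TRUE, n)
    coef_m <- coef_p <- rep(0, n)               # neighbour coefficients
    # artificial diffusion: -c lap(u)
    if (cc > 0) {
      diagv <- diagv + 2 * cc / h^2
      coef_m <- coef_m - cc / h^2
      coef_p <- coef_p - cc / h^2
    }
    # convection: central where Peclet allows, first-order upwind otherwise
    cen <- !upwind
    coef_p[cen] <- coef_p[cen] + v[cen] / (2 * h)
    coef_m[cen] <- coef_m[cen] - v[cen] / (2 * h)
    upos <- upwind & v > 0
    uneg <- upwind & v < 0
    diagv[upos] <- diagv[upos] + v[upos] / h
    coef_m[upos] <- coef_m[upos] - v[upos] / h
    diagv[uneg] <- diagv[uneg] - v[uneg] / h
    coef_p[uneg] <- coef_p[uneg] + v[uneg] / h
    for (side in c(-1L, 1L)) {
      coef <- if (side < 0) coef_m else coef_p
      nb_iy <- iy + if (axis == "y") side else 0L
      nb_ix <- ix + if (axis == "x") side else 0L
      nb_id <- idmat[cbind(nb_iy, nb_ix)]
      inb <- !is.na(nb_id) & coef != 0
      ti <- c(ti, ids[inb]); tj <- c(tj, nb_id[inb]); tv <- c(tv, coef[inb])
      onb <- is.na(nb_id) & coef != 0
      b[ids[onb]] <- b[ids[onb]] - coef[onb] * ub[cbind(nb_iy, nb_ix)][onb]
    }
  }
  A <- Matrix::sparseMatrix(i = c(ti, ids), j = c(tj, ids), x = c(tv, diagv),
                            dims = c(n, n))
  x <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("convection-reaction solver failed: ",
                                         conditionMessage(e)))
  resid <- as.numeric(A %*% x - b)
  if (any(!is.finite(x)))
    stop(sprintf("convection-reaction solver did not converge: residual norm %.3e",
                 sqrt(sum(resid^2))))
  list(u_int = matrix(x, niy, nix), res_sq = sum(resid^2))
}

#' Mask voxels near region boundaries
#'
#' Laplacian-based reconstruction blurs conductivity at interfaces between
#' tissues; this masks every voxel within `erosion_vox` (4/6-neighbour graph
#' distance) of any label boundary so that region statistics are taken over
#' interface-free cores.
#'
#' @param result a `recon_result` from [cr_mrept_solve()].
#' @param vois a [voi_set()] on the same grid.
#' @param erosion_vox non-negative integer erosion depth; default taken from
#'   the result's configuration.
#' @return a modified copy of `result` with the eroded mask.
#' @export
erode_and_mask <- function(result, vois, erosion_vox = NULL) {
  stopifnot(inherits(result, "recon_result"), inherits(vois, "voi_set"))
  if (is.null(erosion_vox)) erosion_vox <- result$config_echo$erosion_vox
  stopifnot(erosion_vox >= 0)
  if (erosion_vox == 0) return(result)
  lab <- vois$labels
  d <- dim(lab)
  check_same_grid(d, dim(result$sigma$values), "result and vois")
  near <- array(FALSE, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    idx <- lapply(d, seq_len)
    fwd <- idx; fwd[[ax]] <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
    bwd <- idx; bwd[[ax]] <- c(1L, seq_len(d[ax] - 1L))
    near <- near | (do.call(`[`, c(list(lab), fwd, list(drop = FALSE))) != lab) |
      (do.call(`[`, c(list(lab), bwd, list(drop = FALSE))) != lab)
  }
  if (erosion_vox > 1) near <- dilate_labels(near, erosion_vox - 1L)
  out <- result
  newmask <- result$sigma$mask & !near
  for (id in sort(unique(lab[lab > 0]))) {
    inreg <- lab == id
    if (any(result$sigma$mask[inreg]) && !any(newmask[inreg]))
      warning(sprintf("region '%s' fully masked by erosion of %d voxel(s)",
                      vois$label_names[[as.character(id)]], erosion_vox))
  }
  out$sigma$mask <- newmask
  out
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> residual norm %.3e, c = %s\n",
              x$residual_norm, paste(signif(x$c_used, 3), collapse = ", ")))
  print(x$sigma)
  invisible(x)
}
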