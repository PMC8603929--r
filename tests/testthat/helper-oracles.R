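# Independently coded convection-reaction stencil. Recomputes the discrete
# residual of the solved system from the returned u grid, mirroring the
# documented discretisation (central convection with first-order upwind
# where the local Peclet number exceeds 2) in plain voxel loops.
cr_residual_oracle <- function(result, phase, cfg) {
  sd_ <- spatial_derivatives(phase, cfg)
  r <- sd_$radius
  d <- dim(phase$values)
  hy <- phase$spacing_mm[2] * 1e-3; hx <- phase$spacing_mm[3] * 1e-3
  rhs <- 2 * cfg$mu0 * 2 * pi * cfg$larmor_hz
  total <- 0
  for (z in seq_len(d[1])) {
    u <- result$u[z, , ]
    gy <- matrix(sd_$grad[2, z, , ], d[2], d[3])
    gx <- matrix(sd_$grad[3, z, , ], d[2], d[3])
    lp <- matrix(sd_$lap[z, , ], d[2], d[3])
    cc <- result$c_used[z]
    a <- r + 1L; by <- d[2] - r; bx <- d[3] - r
    for (iy in (a + 1):(by - 1)) for (ix in (a + 1):(bx - 1)) {
      acc <- lp[iy, ix] * u[iy, ix]
      for (ax in 1:2) {
        h <- if (ax == 1) hy else hx
        v <- if (ax == 1) gy[iy, ix] else gx[iy, ix]
        up <- if (ax == 1) u[iy + 1, ix] else u[iy, ix + 1]
        um <- if (ax == 1) u[iy - 1, ix] else u[iy, ix - 1]
        if (cc > 0) acc <- acc - cc * (up - 2 * u[iy, ix] + um) / h^2
        upwind <- if (cc > 0) abs(v) * h / (2 * cc) > 2 else TRUE
        if (!upwind) {
          acc <- acc + v * (up - um) / (2 * h)
        } else if (v > 0) {
          acc <- acc + v * (u[iy, ix] - um) / h
        } else if (v < 0) {
          acc <- acc + v * (up - u[iy, ix]) / h
        }
      }
      total <- total + (acc - rhs)^2
    }
  }
  sqrt(total)
}
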