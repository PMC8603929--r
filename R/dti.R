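#' Fitted diffusion tensor field container
#'
#' @param tensor numeric array dim (6, nz, ny, nx); unique tensor elements
#'   ordered (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), um^2/ms.
#' @param s0 fitted non-diffusion-weighted signal per voxel.
#' @param fit_residual per-voxel root-mean-square log-signal residual.
#' @param mask logical array of fitted voxels.
#' @param neg_eig logical array flagging voxels with a negative eigenvalue
#'   (permitted by the linear fit, propagated rather than clipped).
#' @param spacing_mm voxel spacing (z, y, x), mm.
#' @export
tensor_map <- function(tensor, s0, fit_residual, mask, neg_eig, spacing_mm) {
  d <- dim(tensor)
  if (length(d) != 4 || d[1] != 6) stop("tensor must be (6, z, y, x)")
  structure(list(tensor = tensor, s0 = s0, fit_residual = fit_residual,
                 mask = mask, neg_eig = neg_eig,
                 spacing_mm = check_spacing(spacing_mm)),
            class = "tensor_map")
}

## Diffusion design matrix: ln S = ln S0 - b g' D g, with D in um^2/ms and
## b in s/mm^2 (hence the 1e-3 scale). Columns: lnS0, Dxx, Dyy, Dzz, Dxy,
## Dxz, Dyz.
dti_design_matrix <- function(bvals, bvecs) {
  g <- as.matrix(bvecs)
  cbind(1,
        -bvals * g[, 1]^2 / 1000,
        -bvals * g[, 2]^2 / 1000,
        -bvals * g[, 3]^2 / 1000,
        -bvals * 2 * g[, 1] * g[, 2] / 1000,
        -bvals * 2 * g[, 1] * g[, 3] / 1000,
        -bvals * 2 * g[, 2] * g[, 3] / 1000)
}

#' Log-linear least-squares diffusion tensor fit
#'
#' Solves `ln(S) = ln(S0) - b g' D g` per voxel for the six unique tensor
#' elements and S0 by ordinary least squares over all volumes (all shells
#' enter one mono-exponential fit). Voxels with any non-positive signal are
#' refitted on their positive subset when it still spans the design, and
#' masked out otherwise.
#'
#' @param dwi a [dwi_stack()].
#' @param shells optional numeric vector restricting the fit to volumes with
#'   these b-values (b = 0 volumes are always kept).
#' @return a [tensor_map()].
#' @export
fit_tensor <- function(dwi, shells = NULL) {
  stopifnot(inherits(dwi, "dwi_stack"))
  keep <- if (is.null(shells)) rep(TRUE, length(dwi$bvals))
          else dwi$bvals == 0 | dwi$bvals %in% shells
  bvals <- dwi$bvals[keep]
  bvecs <- dwi$bvecs[keep, , drop = FALSE]
  sig <- dwi$signal[keep, , , , drop = FALSE]
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  X <- dti_design_matrix(bvals, bvecs)
  qrX <- qr(X)
  if (qrX$rank < 7) {
    ndir <- length(unique(asplit(round(abs(bvecs[bvals > 0, , drop = FALSE]), 6), 1)))
    stop(sprintf(
      "rank-deficient diffusion design (rank %d < 7): %d distinct direction(s) at b > 0; >= 6 non-collinear directions plus b = 0 are required",
      qrX$rank, ndir))
  }
  d <- dim(sig)[-1]
  nvol <- dim(sig)[1]
  nvox <- prod(d)
  S <- matrix(sig, nvol, nvox)
  pos_all <- colSums(S <= 0 | !is.finite(S)) == 0
  beta <- matrix(NA_real_, 7, nvox)
  rss <- rep(NA_real_, nvox)
  if (any(pos_all)) {
    Y <- log(S[, pos_all, drop = FALSE])
    fit <- qr.coef(qrX, Y)
    beta[, pos_all] <- fit
    rss[pos_all] <- sqrt(colMeans((Y - X %*% fit)^2))
  }
  for (vx in which(!pos_all)) {
    ok <- S[, vx] > 0 & is.finite(S[, vx])
    if (sum(ok) >= 7 && qr(X[ok, , drop = FALSE])$rank == 7) {
      y <- log(S[ok, vx])
      fit <- qr.coef(qr(X[ok, , drop = FALSE]), y)
      beta[, vx] <- fit
      rss[vx] <- sqrt(mean((y - X[ok, , drop = FALSE] %*% fit)^2))
    }
  }
  mask <- array(is.finite(beta[1, ]), d)
  tensor <- array(beta[2:7, ], c(6, d))
  s0 <- array(exp(beta[1, ]), d)
  neg <- array(FALSE, d)
  ev <- tensor_eigenvalues(tensor_map(tensor, s0, array(rss, d), mask, neg,
                                      dwi$spacing_mm))
  neg <- array(apply(ev < 0, 2:4, any) & mask, d)
  tensor_map(tensor, s0, array(rss, d), mask, neg, dwi$spacing_mm)
}

#' Eigenvalues of a fitted tensor field
#'
#' @param tensors a [tensor_map()].
#' @return array dim (3, nz, ny, nx) of eigenvalues sorted decreasing;
#'   NA outside the fit mask.
#' @export
tensor_eigenvalues <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_map"))
  d <- dim(tensors$tensor)[-1]
  t6 <- matrix(tensors$tensor, 6, prod(d))
  out <- matrix(NA_real_, 3, prod(d))
  for (vx in which(as.vector(tensors$mask))) {
    Dm <- matrix(c(t6[1, vx], t6[4, vx], t6[5, vx],
                   t6[4, vx], t6[2, vx], t6[6, vx],
                   t6[5, vx], t6[6, vx], t6[3, vx]), 3, 3)
    out[, vx] <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
  }
  array(out, c(3, d))
}

#' Mean diffusivity from a tensor field
#'
#' `MD = (lambda1 + lambda2 + lambda3) / 3 = trace(D) / 3` per voxel. The
#' trace form is exact even when the linear fit produced a negative
#' eigenvalue; such voxels stay in the map and keep their flag.
#'
#' @param tensors a [tensor_map()].
#' @return an [md_map()] in um^2/ms.
#' @export
mean_diffusivity <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_map"))
  d <- dim(tensors$tensor)[-1]
  md <- (array(tensors$tensor[1, , , ], d) +
           array(tensors$tensor[2, , , ], d) +
           array(tensors$tensor[3, , , ], d)) / 3
  md[!tensors$mask] <- NA_real_
  md_map(md, tensors$spacing_mm, tensors$mask)
}
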