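#' Channel-combined complex image container
#'
#' @param complex_values complex array, dim (echo, nz, ny, nx).
#' @param te_ms echo times, ms.
#' @param provenance list with `reference_channel` and `smoothing_radius`.
#' @param spacing_mm voxel spacing (z, y, x), mm.
#' @export
combined_complex_image <- function(complex_values, te_ms, provenance,
                                   spacing_mm) {
  d <- dim(complex_values)
  if (length(d) != 4) stop("complex_values must be (echo, z, y, x)")
  if (d[1] != length(te_ms)) stop("echo axis must match te_ms")
  structure(list(complex_values = complex_values, te_ms = as.numeric(te_ms),
                 provenance = provenance,
                 spacing_mm = check_spacing(spacing_mm)),
            class = "combined_complex_image")
}

#' Per-voxel echo weights container
#'
#' Weights are non-negative and sum to one over the echo axis at every voxel
#' that carries signal.
#'
#' @param weights numeric array, dim (echo, nz, ny, nx).
#' @export
echo_weights <- function(weights) {
  d <- dim(weights)
  if (length(d) != 4) stop("weights must be (echo, z, y, x)")
  if (any(weights[is.finite(weights)] < 0)) stop("weights must be >= 0")
  s <- apply(weights, 2:4, sum)
  ok <- is.finite(s)
  if (any(abs(s[ok] - 1) > 1e-12))
    stop("per-voxel weights must sum to 1 (within 1e-12)")
  structure(list(weights = weights), class = "echo_weights")
}

#' Two-step referenceless combination of receive-channel phases
#'
#' Step 1 selects the channel with the highest mean magnitude as reference
#' and estimates every channel's phase-offset map as the low-pass-filtered
#' phase of `channel * Conj(reference)` (echoes pooled for SNR). Step 2
#' subtracts the offsets and forms the magnitude-squared-weighted complex
#' sum per voxel and echo. The output phase is the argument of that sum; it
#' equals the transceive phase up to the reference channel's own offset,
#' which is spatially smooth and irrelevant after differentiation.
#'
#' @param raw a [multicoil_echo_data()].
#' @param smoothing_radius_vox radius of the Gaussian low-pass used for the
#'   offset maps, voxels (default 3).
#' @return a [combined_complex_image()].
#' @export
grpc_combine <- function(raw, smoothing_radius_vox = 3L) {
  stopifnot(inherits(raw, "multicoil_echo_data"))
  v <- raw$complex_values
  d <- dim(v)
  nch <- d[1]; nec <- d[2]; nz <- d[3]; ny <- d[4]; nx <- d[5]
  ch_mean_mag <- vapply(seq_len(nch), function(k) mean(Mod(v[k, , , , , drop = FALSE])),
                        numeric(1))
  keep <- which(ch_mean_mag > 0)
  if (length(keep) == 0) stop("all channels are zero")
  if (length(keep) < nch)
    warning(sprintf("excluding %d all-zero channel(s)", nch - length(keep)))
  if (length(keep) == 1) {
    k <- keep[1]
    out <- array(v[k, , , , ], c(nec, nz, ny, nx))
    return(combined_complex_image(out, raw$te_ms,
                                  list(reference_channel = k,
                                       smoothing_radius = smoothing_radius_vox),
                                  raw$spacing_mm))
  }
  ref <- keep[which.max(ch_mean_mag[keep])]
  out <- array(complex(real = 0), c(nec, nz, ny, nx))
  for (z in seq_len(nz)) {
    refdat <- array(v[ref, , z, , ], c(nec, ny, nx))
    for (k in keep) {
      chdat <- array(v[k, , z, , ], c(nec, ny, nx))
      prod_sum <- matrix(0i, ny, nx)
      for (e in seq_len(nec))
        prod_sum <- prod_sum + chdat[e, , ] * Conj(refdat[e, , ])
      sm <- smooth_gaussian2d(Re(prod_sum), smoothing_radius_vox) +
        1i * smooth_gaussian2d(Im(prod_sum), smoothing_radius_vox)
      psi <- Arg(sm)
      corr <- exp(-1i * psi)
      for (e in seq_len(nec))
        out[e, z, , ] <- out[e, z, , ] + Mod(chdat[e, , ]) * chdat[e, , ] * corr
    }
  }
  combined_complex_image(out, raw$te_ms,
                         list(reference_channel = ref,
                              smoothing_radius = smoothing_radius_vox),
                         raw$spacing_mm)
}

## Shift a matrix by (di, dj), filling vacated entries with `fill`.
shift_mat <- function(m, di, dj, fill = NA) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  si <- seq_len(n) - di; sj <- seq_len(p) - dj
  ok_i <- si >= 1 & si <= n; ok_j <- sj >= 1 & sj <= p
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

## Flood-fill unwrap of one 2-D slice. Returns the unwrapped values, the
## integer wrap counts k (u = w + 2*pi*k) and a component label matrix.
## Each connected mask component is unwrapped independently, growing
## breadth-first from its highest-quality voxel (quality = negative summed
## wrapped phase difference to neighbours); new voxels take the wrap count
## closest to the mean of their already-unwrapped neighbours.
unwrap_slice <- function(w, mask) {
  ny <- nrow(w); nx <- ncol(w)
  u <- matrix(NA_real_, ny, nx)
  k <- matrix(NA_integer_, ny, nx)
  comp <- matrix(0L, ny, nx)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  # quality map: smooth regions (small wrapped gradients) grow first
  q <- matrix(0, ny, nx)
  for (s in shifts) {
    dn <- abs(wrap_to_pi(shift_mat(w, s[1], s[2], fill = NA) - w))
    dn[is.na(dn)] <- 0
    q <- q - dn
  }
  visited <- !mask  # treat non-mask voxels as done
  comp_id <- 0L
  while (any(!visited)) {
    comp_id <- comp_id + 1L
    todo <- which(!visited)
    seed <- todo[which.max(q[todo])]
    u[seed] <- w[seed]; k[seed] <- 0L; comp[seed] <- comp_id
    grown <- matrix(FALSE, ny, nx); grown[seed] <- TRUE
    repeat {
      adj <- matrix(FALSE, ny, nx)
      for (s in shifts) adj <- adj | shift_mat(grown, s[1], s[2], fill = FALSE)
      cand <- which(adj & !visited & !grown & mask)
      if (length(cand) == 0) break
      est <- rep(0, length(cand)); cnt <- rep(0L, length(cand))
      for (s in shifts) {
        un <- shift_mat(u, s[1], s[2], fill = NA)
        gn <- shift_mat(grown, s[1], s[2], fill = FALSE)
        ok <- gn[cand] & !is.na(un[cand])
        est[ok] <- est[ok] + un[cand][ok]
        cnt[ok] <- cnt[ok] + 1L
      }
      est <- est / pmax(cnt, 1L)
      kk <- as.integer(round((est - w[cand]) / (2 * pi)))
      u[cand] <- w[cand] + 2 * pi * kk
      k[cand] <- kk
      comp[cand] <- comp_id
      grown[cand] <- TRUE
      visited[cand] <- TRUE
    }
    visited[seed] <- TRUE
    visited <- visited | grown
  }
  list(u = u, k = k, comp = comp)
}

#' Unwrap a wrapped phase map
#'
#' Quality-guided flood-fill unwrapping with exact congruence: every output
#' voxel equals the input plus an integer multiple of 2*pi (the integer wrap
#' counts are retained in the result, so re-wrapping with [wrap_phase()]
#' reproduces the input exactly). Slices and disconnected mask components
#' are unwrapped independently; each component carries an arbitrary global
#' 2*pi*k constant, which is irrelevant downstream because only derivatives
#' of the phase enter the reconstruction.
#'
#' @param wrapped a wrapped [phase_map()].
#' @return an unwrapped [phase_map()] with extra fields `wrap_counts`
#'   (integer array), `wrapped_values` (the input values) and `components`
#'   (integer array of connected-component ids per slice).
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(inherits(wrapped, "phase_map"))
  if (!wrapped$wrapped) stop("input phase map is not flagged as wrapped")
  d <- dim(wrapped$values)
  u <- array(NA_real_, d); k <- array(NA_integer_, d); comp <- array(0L, d)
  for (z in seq_len(d[1])) {
    r <- unwrap_slice(wrapped$values[z, , ], wrapped$mask[z, , ])
    u[z, , ] <- r$u; k[z, , ] <- r$k; comp[z, , ] <- r$comp
  }
  out <- phase_map(u, wrapped$spacing_mm, wrapped = FALSE, mask = wrapped$mask)
  out$wrap_counts <- k
  out$wrapped_values <- wrapped$values
  out$components <- comp
  out
}

#' Wrap a phase map back to the principal interval
#'
#' For maps produced by [unwrap_phase()] the retained wrapped representation
#' is returned, so the round trip is exact; otherwise values are wrapped
#' numerically with [wrap_to_pi()].
#'
#' @param pm a [phase_map()].
#' @export
wrap_phase <- function(pm) {
  stopifnot(inherits(pm, "phase_map"))
  if (pm$wrapped) return(pm)
  vals <- if (!is.null(pm$wrapped_values)) pm$wrapped_values else wrap_to_pi(pm$values)
  phase_map(vals, pm$spacing_mm, wrapped = TRUE, mask = pm$mask)
}

#' SNR-optimal weighted average of multi-echo phases
#'
#' Spin-echo transceive phase is echo-time independent in expectation while
#' the magnitude decays with T2, so later echoes carry noisier phase. The
#' per-voxel weights are `w_n = M_n^2 / sum_k M_k^2` (squared-magnitude
#' weighting, the phase-noise-optimal choice for complex Gaussian noise) and
#' the output phase is `sum_n w_n phi_n`. Per-echo phases are unwrapped
#' slice-wise and aligned to the first echo by the nearest global 2*pi
#' multiple before averaging.
#'
#' @param combined a [combined_complex_image()].
#' @param unwrap logical; set FALSE only if the stored phases are already
#'   smooth enough to average directly.
#' @return list with `phase` (unwrapped [phase_map()]) and `weights`
#'   ([echo_weights()]); voxels with zero total magnitude are masked out.
#' @export
combine_echoes <- function(combined, unwrap = TRUE) {
  stopifnot(inherits(combined, "combined_complex_image"))
  v <- combined$complex_values
  d <- dim(v)
  nec <- d[1]; nz <- d[2]; ny <- d[3]; nx <- d[4]
  M2 <- Mod(v)^2
  tot <- apply(M2, 2:4, sum)
  valid <- tot > 0
  wts <- M2
  for (e in seq_len(nec)) {
    we <- array(M2[e, , , ], c(nz, ny, nx)) / tot
    we[!valid] <- NA_real_
    wts[e, , , ] <- we
  }
  phases <- array(NA_real_, d)
  for (z in seq_len(nz)) {
    vmask <- matrix(valid[z, , ], ny, nx)
    ph1 <- NULL
    for (e in seq_len(nec)) {
      wph <- wrap_to_pi(Arg(matrix(v[e, z, , ], ny, nx)))
      if (unwrap) {
        ph <- unwrap_slice(wph, vmask)$u
      } else {
        ph <- wph; ph[!vmask] <- NA_real_
      }
      if (e == 1) {
        ph1 <- ph
      } else {
        dlt <- stats::median(ph[vmask] - ph1[vmask], na.rm = TRUE)
        ph <- ph - 2 * pi * round(dlt / (2 * pi))
      }
      phases[e, z, , ] <- ph
    }
  }
  out <- apply(wts * phases, 2:4, sum)
  out[!valid] <- NA_real_
  pm <- phase_map(out, combined$spacing_mm, wrapped = FALSE,
                  mask = valid & is.finite(out))
  list(phase = pm, weights = echo_weights(wts))
}
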