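#' @keywords internal
"_PACKAGE"

## Physical constants (SI)
MU0 <- 4 * pi * 1e-7              # vacuum permeability, H/m
GAMMA_MHZ_PER_T <- 42.577         # 1H gyromagnetic ratio, MHz/T

#' Larmor frequency for a given main field
#'
#' @param b0_tesla main magnetic field strength in tesla.
#' @return Proton Larmor frequency in Hz (`b0_tesla` x 42.577 MHz/T).
#' @examples
#' larmor_hz(9.4) / 1e6   # ~400 MHz
#' @export
larmor_hz <- function(b0_tesla = 9.4) {
  stopifnot(is.numeric(b0_tesla), b0_tesla > 0)
  b0_tesla * GAMMA_MHZ_PER_T * 1e6
}

#' Wrap phase values to the principal interval
#'
#' @param x numeric vector/array of phase values in radians.
#' @return values wrapped to `[-pi, pi)`.
#' @export
wrap_to_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

## Derive a stage-specific seed from the root seed. All randomness in the
## package flows from one root seed through this splitter so that pipelines
## are reproducible end to end. Kept below 2^31 - 1.
split_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    acquisition = 104729L, dwi = 224737L, coil = 350377L,
    noise = 479909L, replicate = 611953L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) %% 1e6) * 2039 + off) %% 2147483647L
}

## Evaluate expr with a temporarily seeded RNG; restores global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Voxel-centre coordinates along one axis, in metres (0-based index times
## spacing). Index order throughout the package is (z, y, x).
axis_coords_m <- function(n, spacing_mm) {
  (seq_len(n) - 1) * spacing_mm * 1e-3
}

## 1-D convolution along rows/cols of a matrix with replicate padding.
conv1d_replicate <- function(mat, kernel, along = c("row", "col")) {
  along <- match.arg(along)
  if (along == "col") return(t(conv1d_replicate(t(mat), kernel, "row")))
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(mat)
  idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
  padded <- mat[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out
}

## Separable Gaussian smoothing of a 2-D matrix (replicate padding).
## sigma defaults to radius/2; kernel support is 2*radius+1.
smooth_gaussian2d <- function(mat, radius, sigma = radius / 2) {
  if (radius < 1) return(mat)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1d_replicate(conv1d_replicate(mat, k, "row"), k, "col")
}

## 3x3 median filter of a 2-D matrix (replicate padding).
median_filter3 <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  ri <- pmin(pmax(rep(seq_len(n), 3) + rep(-1:1, each = n), 1L), n)
  stack <- array(NA_real_, c(n, m, 9))
  s <- 0L
  for (di in -1:1) for (dj in -1:1) {
    s <- s + 1L
    ii <- pmin(pmax(seq_len(n) + di, 1L), n)
    jj <- pmin(pmax(seq_len(m) + dj, 1L), m)
    stack[, , s] <- mat[ii, jj]
  }
  apply(stack, c(1, 2), stats::median)
}

## Binary dilation of a (z,y,x) logical array with the 6-neighbourhood
## (4-neighbourhood within a slice), n iterations.
dilate_labels <- function(b, n_iter) {
  d <- dim(b)
  for (it in seq_len(n_iter)) {
    out <- b
    for (ax in 1:3) {
      if (d[ax] < 2) next
      idx_lo <- lapply(d, seq_len); idx_hi <- idx_lo
      idx_lo[[ax]] <- c(1L, seq_len(d[ax] - 1L))   # shift +1
      idx_hi[[ax]] <- c(seq_len(d[ax] - 1L) + 1L, d[ax])  # shift -1
      out <- out | do.call(`[`, c(list(b), idx_lo, list(drop = FALSE))) |
        do.call(`[`, c(list(b), idx_hi, list(drop = FALSE)))
    }
    b <- out
  }
  b
}

## Stop unless all spacings match (shared-grid contract).
check_same_grid <- function(a_dim, b_dim, what = "inputs") {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop(sprintf("%s must share the same grid: %s vs %s", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")))
  invisible(TRUE)
}
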