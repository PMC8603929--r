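#' Specify an ellipsoidal phantom region
#'
#' Regions are ellipsoids in 0-based voxel coordinates. Later regions in a
#' [phantom_spec()] overwrite earlier ones, so nested structures (tumour rim
#' enclosing viable tumour enclosing necrotic core) are built by listing the
#' enclosing region first.
#'
#' @param label region name; the six rat-brain regions are
#'   `contralateral_cortex`, `tumor_rim`, `viable_tumor`, `tumor_core`,
#'   `ventricles`, `edema`, but any string is accepted.
#' @param center numeric length-3 ellipsoid centre, 0-based voxel (z, y, x).
#' @param semi_axes numeric length-3 semi-axes in voxels (>= 1 where the grid
#'   has extent; a singleton axis may use semi-axis < 1 to mean "this slice").
#' @param sigma electrical conductivity, S/m (> 0).
#' @param md mean diffusivity, um^2/ms (>= 0).
#' @param t2_ms transverse relaxation time, ms (> 0); a simulation nuisance
#'   parameter that drives the multi-echo magnitude decay.
#' @export
region_spec <- function(label, center, semi_axes, sigma, md, t2_ms) {
  stopifnot(is.character(label), length(label) == 1,
            length(center) == 3, length(semi_axes) == 3,
            sigma > 0, md >= 0, t2_ms > 0)
  structure(list(label = label, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 sigma = sigma, md = md, t2_ms = t2_ms),
            class = "region_spec")
}

#' Specify a conductivity/diffusivity phantom
#'
#' @param grid_shape integer length-3 grid dimensions (nz, ny, nx).
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @param regions list of [region_spec()] objects, applied in order.
#' @param background_sigma background conductivity, S/m.
#' @param background_md background mean diffusivity, um^2/ms.
#' @param background_t2_ms background T2, ms.
#' @param b0_tesla main field strength (default 9.4 T).
#' @param coil_count number of receive channels (default 4).
#' @export
phantom_spec <- function(grid_shape = c(1L, 64L, 128L),
                         spacing_mm = c(0.3, 0.313, 0.313),
                         regions = list(),
                         background_sigma = 0.44,
                         background_md = 0.69,
                         background_t2_ms = 40,
                         b0_tesla = 9.4,
                         coil_count = 4L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            background_sigma > 0, background_md >= 0, background_t2_ms > 0,
            b0_tesla > 0, coil_count >= 1)
  spacing_mm <- check_spacing(spacing_mm)
  labs <- vapply(regions, function(r) r$label, character(1))
  if (anyDuplicated(labs))
    stop("overlapping identical labels: duplicated region label(s) ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  for (r in regions) {
    eff <- ifelse(grid_shape == 1, 0, r$semi_axes)  # singleton axes span the slice
    lo <- r$center - eff
    hi <- r$center + eff
    if (any(lo < -0.5) || any(hi > grid_shape - 0.5))
      stop(sprintf("region '%s' exceeds grid bounds: extent [%s]..[%s] on a %s grid",
                   r$label, paste(round(lo, 1), collapse = ","),
                   paste(round(hi, 1), collapse = ","),
                   paste(grid_shape, collapse = "x")))
    sa <- r$semi_axes[grid_shape > 1]
    if (any(sa < 1))
      stop(sprintf("region '%s': semi-axes must be >= 1 voxel on non-singleton axes",
                   r$label))
  }
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 regions = regions, background_sigma = background_sigma,
                 background_md = background_md,
                 background_t2_ms = background_t2_ms,
                 b0_tesla = b0_tesla, coil_count = as.integer(coil_count)),
            class = "phantom_spec")
}

## Logical mask of an ellipsoid in 0-based voxel coordinates.
ellipsoid_mask <- function(grid_shape, center, semi_axes) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  z <- (seq_len(nz) - 1 - center[1]) / max(semi_axes[1], 1e-9)
  y <- (seq_len(ny) - 1 - center[2]) / max(semi_axes[2], 1e-9)
  x <- (seq_len(nx) - 1 - center[3]) / max(semi_axes[3], 1e-9)
  if (nz == 1) z <- 0  # single-slice phantoms ignore the z semi-axis
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  array(q <= 1, grid_shape)
}

#' Build ground-truth phantom maps from a specification
#'
#' Paints the background and then each region in order onto conductivity,
#' mean-diffusivity and T2 grids, and records the region voxels as an
#' integer label volume.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `sigma` ([conductivity_map()]), `md`
#'   ([md_map()]), `t2_ms` (numeric array, ms) and `vois` ([voi_set()]).
#' @examples
#' ph <- build_phantom(default_phantom_spec())
#' ph$vois
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sig <- array(spec$background_sigma, gs)
  md <- array(spec$background_md, gs)
  t2 <- array(spec$background_t2_ms, gs)
  labels <- array(0L, gs)
  nm <- character(0)
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    m <- ellipsoid_mask(gs, r$center, r$semi_axes)
    sig[m] <- r$sigma
    md[m] <- r$md
    t2[m] <- r$t2_ms
    labels[m] <- i
    nm[as.character(i)] <- r$label
  }
  list(sigma = conductivity_map(sig, spec$spacing_mm),
       md = md_map(md, spec$spacing_mm),
       t2_ms = t2,
       vois = voi_set(labels, nm, spacing_mm = spec$spacing_mm))
}

#' Default six-region rat-brain tumour phantom
#'
#' A single coronal slice on the acquisition grid (128 x 64 in-plane voxels,
#' 0.313 mm in-plane, 0.3 mm slice) containing the six regions analysed in
#' F98 glioblastoma studies: contralateral cortex, ventricles, peritumoral
#' edema, tumour rim, viable tumour and necrotic tumour core. Conductivity
#' (S/m) and mean diffusivity (um^2/ms) default to literature tissue values
#' for rat brain tumours at 9.4 T; T2 values are plausible simulation
#' choices at that field.
#'
#' @param sigma named conductivity overrides per region, S/m.
#' @param md named mean-diffusivity overrides per region, um^2/ms.
#' @param drop character vector of region labels to omit (e.g. the necrotic
#'   core on early imaging days when it has not yet formed).
#' @param coil_count number of receive channels.
#' @export
default_phantom_spec <- function(sigma = NULL, md = NULL, drop = NULL,
                                 coil_count = 4L) {
  base <- list(
    contralateral_cortex = list(center = c(0, 32, 30), semi = c(1, 13, 16),
                                sigma = 0.44, md = 0.69, t2 = 42),
    ventricles           = list(center = c(0, 32, 57), semi = c(1, 9, 7),
                                sigma = 0.72, md = 1.23, t2 = 110),
    edema                = list(center = c(0, 30, 92), semi = c(1, 22, 24),
                                sigma = 0.77, md = 0.89, t2 = 65),
    tumor_rim            = list(center = c(0, 30, 92), semi = c(1, 16, 18),
                                sigma = 0.96, md = 0.81, t2 = 55),
    viable_tumor         = list(center = c(0, 30, 92), semi = c(1, 11, 13),
                                sigma = 0.93, md = 0.76, t2 = 50),
    tumor_core           = list(center = c(0, 30, 92), semi = c(1, 6, 7),
                                sigma = 0.84, md = 0.89, t2 = 70)
  )
  regions <- list()
  for (lab in names(base)) {
    if (lab %in% drop) next
    b <- base[[lab]]
    s <- if (!is.null(sigma) && lab %in% names(sigma)) sigma[[lab]] else b$sigma
    m <- if (!is.null(md) && lab %in% names(md)) md[[lab]] else b$md
    regions[[length(regions) + 1L]] <-
      region_spec(lab, b$center, b$semi, s, m, b$t2)
  }
  phantom_spec(regions = regions, coil_count = coil_count)
}
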