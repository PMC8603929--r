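#' Voxel map containers
#'
#' Lightweight S3 containers for parametric maps on a regular voxel grid.
#' All grids use index order (z, y, x) with voxel-centred coordinates and
#' spacing stored in millimetres; internal mathematics is carried out in SI
#' units (metres, radians, seconds, S/m).
#'
#' @param values numeric array, dim (nz, ny, nx).
#' @param spacing_mm positive numeric length-3 spacing (z, y, x) in mm.
#' @param mask logical array of valid voxels (default: all finite values).
#' @return An object of class `conductivity_map`.
#' @export
conductivity_map <- function(values, spacing_mm, mask = NULL) {
  values <- as_grid(values)
  spacing_mm <- check_spacing(spacing_mm)
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as_grid(mask); storage.mode(mask) <- "logical"
  check_same_grid(dim(values), dim(mask), "values and mask")
  bad <- mask & (!is.finite(values) | values <= 0)
  if (any(bad))
    stop("conductivity values must be positive and finite wherever mask is TRUE")
  structure(list(values = values, spacing_mm = spacing_mm, mask = mask),
            class = "conductivity_map")
}

#' @rdname conductivity_map
#' @param wrapped logical; TRUE if values are wrapped to `[-pi, pi)`.
#' @export
phase_map <- function(values, spacing_mm, wrapped = FALSE, mask = NULL) {
  values <- as_grid(values)
  spacing_mm <- check_spacing(spacing_mm)
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as_grid(mask); storage.mode(mask) <- "logical"
  check_same_grid(dim(values), dim(mask), "values and mask")
  if (wrapped) {
    v <- values[mask]
    if (length(v) && (min(v) < -pi || max(v) >= pi))
      stop("wrapped phase values must lie in [-pi, pi)")
  }
  structure(list(values = values, spacing_mm = spacing_mm,
                 wrapped = isTRUE(wrapped), mask = mask),
            class = "phase_map")
}

#' @rdname conductivity_map
#' @export
md_map <- function(values, spacing_mm, mask = NULL) {
  values <- as_grid(values)
  spacing_mm <- check_spacing(spacing_mm)
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as_grid(mask); storage.mode(mask) <- "logical"
  check_same_grid(dim(values), dim(mask), "values and mask")
  structure(list(values = values, spacing_mm = spacing_mm, mask = mask),
            class = "md_map")
}

#' Volume-of-interest label set
#'
#' @param labels integer array (nz, ny, nx); 0 is background.
#' @param label_names character vector naming each nonzero label id; its
#'   names attribute holds the ids as strings.
#' @param day optional acquisition day tag (e.g. 8, 11, 14).
#' @param spacing_mm voxel spacing in mm.
#' @export
voi_set <- function(labels, label_names, day = NA_integer_, spacing_mm = NULL) {
  labels <- as_grid(labels); storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("label ids must be >= 0")
  ids <- sort(unique(labels[labels > 0]))
  if (!all(as.character(ids) %in% names(label_names)))
    stop("every nonzero label id must have a name")
  structure(list(labels = labels, label_names = label_names, day = day,
                 spacing_mm = if (is.null(spacing_mm)) NULL else check_spacing(spacing_mm)),
            class = "voi_set")
}

as_grid <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(1L, 1L, length(x))
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x))
  if (length(dim(x)) != 3L) stop("expected a (z, y, x) array")
  x
}

check_spacing <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite values (z, y, x)")
  spacing_mm
}

#' @export
print.conductivity_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<conductivity_map> %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  if (length(v))
    cat(sprintf("  sigma [S/m]: median %.3f, range %.3f..%.3f, %d valid voxels\n",
                stats::median(v), min(v), max(v), length(v)))
  invisible(x)
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %s voxels, %s, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              if (x$wrapped) "wrapped" else "unwrapped",
              paste(signif(x$spacing_mm, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.voi_set <- function(x, ...) {
  tb <- table(x$labels[x$labels > 0])
  cat(sprintf("<voi_set> %d regions%s\n", length(tb),
              if (is.na(x$day)) "" else sprintf(", day %s", x$day)))
  for (id in names(tb))
    cat(sprintf("  %s (%s): %d voxels\n", x$label_names[[id]], id, tb[[id]]))
  invisible(x)
}
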