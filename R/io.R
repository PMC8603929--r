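#' Read a NIfTI-1 volume as a (z, y, x) grid
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `values` (numeric array, dim (nz, ny, nx)),
#'   `spacing_mm` (z, y, x) and `affine` (4x4 matrix or NULL).
#' @export
read_nifti <- function(path) {
  check_nifti_file(path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3) stop("expected a 3-D NIfTI volume: ", path)
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  spacing <- rev(pd[1:3])
  aff <- tryCatch(structure(RNifti::xform(img), class = NULL),
                  error = function(e) NULL)
  list(values = aperm(arr, c(3, 2, 1)), spacing_mm = spacing, affine = aff)
}

#' Write a (z, y, x) grid as a NIfTI-1 volume
#'
#' Values are stored as float64 so that a write/read round trip preserves
#' them bitwise. Use a plain `.nii` suffix for byte-reproducible files
#' (gzip headers embed no timestamp here, but uncompressed output keeps
#' hashing trivial).
#'
#' @param values numeric array, dim (nz, ny, nx) (NA allowed).
#' @param spacing_mm voxel spacing (z, y, x), mm.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(values, spacing_mm, path) {
  values <- as_grid(values)
  spacing_mm <- check_spacing(spacing_mm)
  arr <- aperm(values, c(3, 2, 1))
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- rev(spacing_mm)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

## Validate the NIfTI-1 magic before handing the file to the reader, so
## corrupt or foreign files fail with a clear format error.
check_nifti_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head2 <- readBin(con, "raw", n = 2)
  if (length(head2) == 2 && head2[1] == as.raw(0x1f) && head2[2] == as.raw(0x8b))
    return(invisible(TRUE))  # gzip container; let the reader validate inside
  if (sz < 348)
    stop(sprintf("not a NIfTI file (truncated, %d bytes): %s", sz, path))
  seek(con, 0)
  hdr <- readBin(con, "raw", n = 348)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("not a NIfTI file: magic bytes '%s' (0x%s) in %s",
                 magic, paste(format(hdr[345:348]), collapse = ""), path))
  invisible(TRUE)
}

#' Write a region statistics table as CSV
#'
#' Fixed column order, no row names; the inverse of [utils::read.csv()].
#'
#' @param tab data.frame from [region_summary()] or the test tables.
#' @param path output path.
#' @export
write_stats_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
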