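#' CT volume with voxel spacing metadata
#'
#' A 3-D grid of CT attenuation values (Hounsfield units) together with
#' the voxel spacing and world origin needed to interpret voxel indices
#' as millimetre coordinates.  Axis order is (slice, row, col) throughout
#' the package; voxel \code{(s, r, c)} (1-based) has world centre
#' \code{origin + (c(s, r, c) - 1) * spacing} mm.
#'
#' @param values numeric 3-D array of HU values.
#' @param spacing positive numeric triple, voxel size in mm per axis.
#' @param origin numeric triple, world coordinate (mm) of voxel (1,1,1).
#' @return An object of class \code{ct_volume}.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as_grid3d(values, "values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be a strictly positive mm triple", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite mm triple", call. = FALSE)
  if (any(!is.finite(values)))
    stop("HU values must be finite", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Binary voxel mask aligned to a CT volume
#'
#' @param values logical (or 0/1) 3-D array; TRUE marks nodule voxels.
#' @param spacing,origin grid metadata, as for [ct_volume()].
#' @return An object of class \code{voxel_mask}.
#' @export
voxel_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as_grid3d(values, "values")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be 0/1", call. = FALSE)
    storage.mode(values) <- "logical"
  }
  if (!is.logical(values))
    stop("mask values must be logical or 0/1", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be a strictly positive mm triple", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

as_grid3d <- function(x, what) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("'", what, "' must be a 3-D array", call. = FALSE)
  x
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, %d foreground\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' @export
dim.voxel_mask <- function(x) dim(x$values)

#' Check that a mask shares its volume's grid
#'
#' Verifies equal shape and spacing/origin agreement to 1e-6 mm; raises an
#' alignment error naming the first differing field otherwise.
#'
#' @param volume a [ct_volume()] (or another mask).
#' @param mask a [voxel_mask()].
#' @param tol mm tolerance for spacing/origin comparison.
#' @return Invisibly TRUE on success.
#' @export
check_aligned <- function(volume, mask, tol = 1e-6) {
  if (!identical(dim(volume$values), dim(mask$values)))
    stop(sprintf("alignment error: shape differs (%s vs %s)",
                 paste(dim(volume$values), collapse = "x"),
                 paste(dim(mask$values), collapse = "x")), call. = FALSE)
  if (any(abs(volume$spacing - mask$spacing) > tol))
    stop("alignment error: spacing differs beyond 1e-6 mm", call. = FALSE)
  if (any(abs(volume$origin - mask$origin) > tol))
    stop("alignment error: origin differs beyond 1e-6 mm", call. = FALSE)
  invisible(TRUE)
}

# world-mm coordinates of the given (slice,row,col) index matrix
voxel_centers_mm <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}
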