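#' Segmentation parameters for seed-voxel region growing
#'
#' Growing accepts voxels whose HU lies in \code{[hu_low, hu_high]};
#' defaults bracket the ground-glass-to-solid range so both sub-solid and
#' solid nodules are captured while aerated lung and bone are excluded.
#' Growth is confined to an axis-aligned volume of interest (VOI) box
#' around the seed, clipped at the grid boundary.
#'
#' @param hu_low,hu_high inclusive HU thresholds (\code{hu_low < hu_high}).
#' @param connectivity 6 or 26 voxel connectivity.
#' @param voi_half_extent half-width (mm) of the VOI box.
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(hu_low = -750, hu_high = 200,
                                connectivity = 26L, voi_half_extent = 20) {
  if (hu_low >= hu_high) stop("hu_low must be < hu_high", call. = FALSE)
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (voi_half_extent <= 0) stop("voi_half_extent must be > 0", call. = FALSE)
  structure(list(hu_low = hu_low, hu_high = hu_high,
                 connectivity = as.integer(connectivity),
                 voi_half_extent = voi_half_extent),
            class = "segmentation_params")
}

#' Grow a nodule mask from a seed voxel
#'
#' Returns the maximal connected component (under the configured
#' connectivity) of in-threshold voxels containing the seed, clipped to
#' the VOI box.  Deterministic.
#'
#' @param volume a [ct_volume()].
#' @param seed voxel triple (slice, row, col), 1-based, inside the grid.
#' @param params a [segmentation_params()].
#' @return A [voxel_mask()] containing the seed.
#' @export
region_grow <- function(volume, seed, params = segmentation_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$values)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel outside grid bounds", call. = FALSE)
  seed_hu <- volume$values[seed[1], seed[2], seed[3]]
  if (seed_hu < params$hu_low || seed_hu > params$hu_high)
    stop(sprintf("seed rejected: HU %.0f outside [%.0f, %.0f]",
                 seed_hu, params$hu_low, params$hu_high), call. = FALSE)

  half <- ceiling(params$voi_half_extent / volume$spacing)
  lo <- pmax(seed - half, 1L)
  hi <- pmin(seed + half, d)
  sub <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  inthr <- sub >= params$hu_low & sub <= params$hu_high
  comp <- connected_component(inthr, seed - lo + 1L, params$connectivity)

  full <- array(FALSE, dim = d)
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp
  voxel_mask(full, volume$spacing, volume$origin)
}

#' Eraser-sphere edit operation
#'
#' Removes mask voxels whose centres lie within \code{radius} mm of
#' \code{center} (closed ball; radius 0 removes at most the voxel at the
#' centre itself).
#'
#' @param center mm triple (world coordinates).
#' @param radius mm, >= 0.
#' @return An \code{edit_op}.
#' @export
eraser_sphere <- function(center, radius) {
  if (radius < 0) stop("eraser radius must be >= 0", call. = FALSE)
  structure(list(kind = "eraser_sphere", center = as.numeric(center),
                 radius = radius), class = "edit_op")
}

#' Exclusion-plane edit operation
#'
#' Removes mask voxels strictly on the \code{normal} side of the plane
#' through \code{point}; voxels on the plane itself are kept.
#'
#' @param point mm triple on the plane.
#' @param normal nonzero direction triple; the excluded half-space.
#' @return An \code{edit_op}.
#' @export
exclusion_plane <- function(point, normal) {
  normal <- as.numeric(normal)
  if (sqrt(sum(normal^2)) == 0)
    stop("plane normal must be nonzero", call. = FALSE)
  structure(list(kind = "exclusion_plane", point = as.numeric(point),
                 normal = normal / sqrt(sum(normal^2))), class = "edit_op")
}

#' Apply manual edit operations to a mask
#'
#' Edits are applied in order; each only removes voxels, so the output is
#' a subset of the input.
#'
#' @param mask a [voxel_mask()].
#' @param edits list of \code{edit_op} objects.
#' @return The edited [voxel_mask()].
#' @export
apply_edits <- function(mask, edits) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(edits) == 0L) return(mask)
  vals <- mask$values
  for (op in edits) {
    idx <- which(vals, arr.ind = TRUE)
    if (nrow(idx) == 0L) break
    xyz <- voxel_centers_mm(idx, mask$spacing, mask$origin)
    drop <- switch(op$kind,
      eraser_sphere = {
        rowSums(sweep(xyz, 2, op$center)^2) <= op$radius^2
      },
      exclusion_plane = {
        sweep(xyz, 2, op$point) %*% op$normal > 0
      },
      stop("unknown edit kind '", op$kind, "'", call. = FALSE))
    vals[idx[as.vector(drop), , drop = FALSE]] <- FALSE
  }
  if (!any(vals))
    stop("edit emptied the mask; observer must re-seed", call. = FALSE)
  voxel_mask(vals, mask$spacing, mask$origin)
}

#' Record a segmentation session
#'
#' A session is the audit trail of one observer's segmentation: the seed,
#' the growing parameters, the ordered edits, and the resulting mask.
#' Replaying \code{seed + params + edits} must reproduce \code{result}
#' exactly.
#'
#' @param volume the [ct_volume()] segmented.
#' @param seed voxel triple.
#' @param params a [segmentation_params()].
#' @param edits list of \code{edit_op} objects (may be empty).
#' @return An object of class \code{segmentation_session} with the result
#'   mask attached.
#' @export
segment_nodule <- function(volume, seed, params = segmentation_params(),
                           edits = list()) {
  grown <- region_grow(volume, seed, params)
  result <- apply_edits(grown, edits)
  structure(list(seed = as.integer(round(seed)), params = params,
                 edits = edits, result = result),
            class = "segmentation_session")
}

#' Replay a stored segmentation session
#'
#' Re-runs the seed growing and edits and verifies the reproduced mask is
#' identical to the stored result, enabling exact inter-observer audit.
#'
#' @param volume the [ct_volume()] the session was recorded on.
#' @param session a \code{segmentation_session}.
#' @return The reproduced [voxel_mask()].
#' @export
replay_session <- function(volume, session) {
  stopifnot(inherits(session, "segmentation_session"))
  grown <- region_grow(volume, session$seed, session$params)
  redone <- apply_edits(grown, session$edits)
  if (!identical(redone$values, session$result$values))
    stop("reproducibility error: replayed mask differs from stored result",
         call. = FALSE)
  redone
}

#' Write a segmentation session to JSON
#'
#' The result mask is stored run-length encoded over the flattened
#' (slice fastest) grid, so sessions are plain text and replay can verify
#' bit-identity.
#'
#' @param session a \code{segmentation_session}.
#' @param path destination .json path.
#' @return Invisibly, \code{path}.
#' @export
write_session <- function(session, path) {
  r <- rle(as.vector(session$result$values))
  obj <- list(
    seed = session$seed,
    params = unclass(session$params),
    edits = lapply(session$edits, unclass),
    result = list(dim = dim(session$result$values),
                  spacing = session$result$spacing,
                  origin = session$result$origin,
                  rle_lengths = r$lengths, rle_values = r$values))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a segmentation session from JSON
#'
#' @param path a session file written by [write_session()].
#' @return A \code{segmentation_session}.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- obj$params
  params <- segmentation_params(p$hu_low, p$hu_high,
                                as.integer(p$connectivity),
                                p$voi_half_extent)
  edits <- lapply(obj$edits, function(e) {
    if (e$kind == "eraser_sphere")
      eraser_sphere(as.numeric(unlist(e$center)), e$radius)
    else
      exclusion_plane(as.numeric(unlist(e$point)),
                      as.numeric(unlist(e$normal)))
  })
  res <- obj$result
  vals <- array(inverse.rle(list(lengths = as.integer(unlist(res$rle_lengths)),
                                 values = as.logical(unlist(res$rle_values)))),
                dim = as.integer(unlist(res$dim)))
  result <- voxel_mask(vals, as.numeric(unlist(res$spacing)),
                       as.numeric(unlist(res$origin)))
  structure(list(seed = as.integer(unlist(obj$seed)), params = params,
                 edits = edits, result = result),
            class = "segmentation_session")
}
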