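#' Specify a synthetic CT nodule phantom
#'
#' A phantom is a lung-attenuation background holding one spherical
#' nodule whose attenuation runs from pure ground-glass (no solid core)
#' to fully solid (core radius equal to the nodule radius), optionally
#' with an abutting vessel and a chest-wall slab, plus additive i.i.d.
#' Gaussian noise.  Default HU values straddle the standard lung-window
#' tissue classes (lung -850, ground-glass -550, solid soft tissue 40).
#'
#' @param grid_shape voxel-count triple (slices, rows, cols).
#' @param spacing mm triple; default emulates anisotropic chest CT
#'   (1.25 mm slices, 0.7 mm in-plane).
#' @param nodule_center voxel triple (1-based) of the nodule centre.
#' @param nodule_radius nodule radius in mm.
#' @param solid_core_radius radius (mm) of the solid core,
#'   \code{<= nodule_radius}; 0 gives a pure ground-glass nodule.
#' @param solid_hu,ggo_hu,lung_hu attenuation (HU) of solid tissue,
#'   ground-glass shell, and lung background.
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param vessel_radius radius (mm) of a vessel cylinder tangent to the
#'   nodule surface, or \code{NA} for no vessel.
#' @param chest_wall logical; add a soft-tissue slab along the last rows.
#' @param rng_seed integer seed controlling the noise draw.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(36L, 48L, 48L),
                         spacing = c(1.25, 0.7, 0.7),
                         nodule_center = round(grid_shape / 2),
                         nodule_radius = 7,
                         solid_core_radius = 3.5,
                         solid_hu = 40, ggo_hu = -550, lung_hu = -850,
                         noise_sd = 20,
                         vessel_radius = NA_real_,
                         chest_wall = FALSE,
                         rng_seed = 1L) {
  if (solid_core_radius > nodule_radius)
    stop("solid_core_radius must not exceed nodule_radius", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  hu <- c(solid_hu, ggo_hu, lung_hu)
  if (any(hu < -1024 | hu > 3071))
    stop("HU values must lie in [-1024, 3071]", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 nodule_center = as.numeric(nodule_center),
                 nodule_radius = nodule_radius,
                 solid_core_radius = solid_core_radius,
                 solid_hu = solid_hu, ggo_hu = ggo_hu, lung_hu = lung_hu,
                 noise_sd = noise_sd, vessel_radius = vessel_radius,
                 chest_wall = chest_wall, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' Builds the CT volume, the true nodule mask, and a per-voxel tissue
#' label map (\code{lung}, \code{ggo}, \code{solid}, \code{vessel},
#' \code{wall}).  Deterministic given \code{spec$rng_seed}.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class \code{ground_truth}: list with elements
#'   \code{volume} ([ct_volume()]), \code{nodule_mask} ([voxel_mask()]),
#'   \code{class_map} (character array), and \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  ctr <- spec$nodule_center
  r_vox <- ceiling(spec$nodule_radius / sp)
  if (any(ctr - r_vox - 10 < 1) || any(ctr + r_vox + 10 > d))
    stop("bounds error: nodule (plus 10-voxel margin) extends outside grid",
         call. = FALSE)

  ax <- lapply(1:3, function(i) ((seq_len(d[i]) - ctr[i]) * sp[i])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  nodule <- d2 <= spec$nodule_radius^2
  core <- d2 <= spec$solid_core_radius^2

  class_map <- array("lung", dim = d)
  vals <- array(spec$lung_hu, dim = d)

  if (!is.na(spec$vessel_radius)) {
    # vessel: cylinder along the col axis, axis tangent to the nodule sphere
    vrow <- ctr[2] + spec$nodule_radius / sp[2]
    dv2 <- outer(ax[[1]], ((seq_len(d[2]) - vrow) * sp[2])^2, "+")
    vessel <- array(rep(dv2 <= spec$vessel_radius^2, d[3]), dim = d)
    vessel <- vessel & !nodule
    class_map[vessel] <- "vessel"
    vals[vessel] <- spec$solid_hu
  }
  if (isTRUE(spec$chest_wall)) {
    nwall <- ceiling(5 / sp[2])
    wall <- array(FALSE, dim = d)
    wall[, (d[2] - nwall + 1):d[2], ] <- TRUE
    wall <- wall & !nodule & class_map != "vessel"
    class_map[wall] <- "wall"
    vals[wall] <- spec$solid_hu
  }
  vals[nodule] <- spec$ggo_hu
  vals[core] <- spec$solid_hu
  class_map[nodule] <- "ggo"
  class_map[core & nodule] <- "solid"

  if (spec$noise_sd > 0)
    vals <- vals + with_seed(spec$rng_seed,
                             array(rnorm(prod(d), sd = spec$noise_sd), dim = d))

  structure(list(volume = ct_volume(vals, sp),
                 nodule_mask = voxel_mask(nodule, sp),
                 class_map = class_map,
                 spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> nodule r=%.1f mm (core %.1f mm), %d nodule voxels\n",
              x$spec$nodule_radius, x$spec$solid_core_radius,
              sum(x$nodule_mask$values)))
  invisible(x)
}

#' Default phantom sampler for cohort generation
#'
#' Draws nodule radius uniformly on 4--8 mm and solid-core fraction
#' uniformly on [0, 1], so a cohort spans pure ground-glass through fully
#' solid nodules; 30% of phantoms get an abutting vessel.  Must be called
#' inside an active RNG context (as [generate_cohort()] does).
#'
#' @param i phantom index (used as a label only).
#' @param rng_seed noise seed to embed in the spec.
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(i, rng_seed = i) {
  r <- runif(1, 4, 8)
  frac <- runif(1)
  vr <- if (runif(1) < 0.3) runif(1, 1, 2) else NA_real_
  phantom_spec(nodule_radius = r, solid_core_radius = r * frac,
               vessel_radius = vr, rng_seed = rng_seed)
}

#' Generate a cohort of phantoms with a manifest
#'
#' @param n number of phantoms (>= 1).
#' @param spec_sampler function \code{(i, rng_seed)} returning a
#'   [phantom_spec()]; called under the cohort RNG stream.
#' @param seed integer master seed; the manifest and all phantoms are
#'   reproducible from it.
#' @return List with \code{phantoms} (list of \code{ground_truth}) and
#'   \code{manifest} (one data-frame row per phantom).
#' @export
generate_cohort <- function(n, spec_sampler = sample_phantom_spec, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  specs <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) spec_sampler(i, rng_seed = seeds[i]))
  })
  phantoms <- lapply(specs, generate_phantom)
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- specs[[i]]
    data.frame(id = i,
               nodule_radius = s$nodule_radius,
               solid_core_radius = s$solid_core_radius,
               solid_hu = s$solid_hu, ggo_hu = s$ggo_hu,
               lung_hu = s$lung_hu, noise_sd = s$noise_sd,
               vessel_radius = s$vessel_radius,
               chest_wall = s$chest_wall, rng_seed = s$rng_seed)
  }))
  list(phantoms = phantoms, manifest = manifest)
}

#' Observer jitter model
#'
#' Simulated observers perturb the true nodule border with a smooth
#' Gaussian random displacement field (marginal sd \code{boundary_sd} mm,
#' fixed 3 mm correlation length) and may retain an abutting vessel
#' segment with probability \code{vessel_inclusion_prob}.
#'
#' @param boundary_sd surface displacement sd in mm (>= 0).
#' @param vessel_inclusion_prob probability in [0, 1].
#' @param rng_seed integer seed for this observer's random draws.
#' @return An object of class \code{observer_jitter}.
#' @export
observer_jitter <- function(boundary_sd = 0.5, vessel_inclusion_prob = 0.2,
                            rng_seed = 1L) {
  if (boundary_sd < 0) stop("boundary_sd must be >= 0", call. = FALSE)
  if (vessel_inclusion_prob < 0 || vessel_inclusion_prob > 1)
    stop("vessel_inclusion_prob must be in [0, 1]", call. = FALSE)
  structure(list(boundary_sd = boundary_sd,
                 vessel_inclusion_prob = vessel_inclusion_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "observer_jitter")
}

#' Simulate one observer's segmentation of a phantom nodule
#'
#' The true surface is displaced by a smooth random field: a voxel is kept
#' in the mask iff its signed distance to the true surface (negative
#' inside) does not exceed the local field value.  The field is clamped at
#' 3.5 sd, the result is restricted to the 26-connected component meeting
#' the true nodule, and an abutting vessel segment (vessel voxels within
#' two voxels of the nodule) is retained with the configured probability.
#' Deterministic given \code{jitter$rng_seed}.
#'
#' @param truth a \code{ground_truth} from [generate_phantom()].
#' @param jitter an [observer_jitter()].
#' @return A [voxel_mask()] on the truth's grid.
#' @export
simulate_observer_mask <- function(truth, jitter) {
  stopifnot(inherits(truth, "ground_truth"), inherits(jitter, "observer_jitter"))
  mask <- truth$nodule_mask$values
  if (!any(mask)) stop("truth nodule mask is empty", call. = FALSE)
  sp <- truth$nodule_mask$spacing

  draws <- with_seed(jitter$rng_seed, {
    field <- NULL
    if (jitter$boundary_sd > 0) {
      noise <- array(rnorm(prod(dim(mask))), dim = dim(mask))
      field <- gaussian_smooth3d(noise, 3 / sp)
      field <- field / stats::sd(field) * jitter$boundary_sd
      cap <- 3.5 * jitter$boundary_sd
      field[field > cap] <- cap
      field[field < -cap] <- -cap
    }
    list(field = field, keep_vessel = runif(1) < jitter$vessel_inclusion_prob)
  })

  out <- mask
  if (!is.null(draws$field)) {
    # signed distance to the mask boundary: negative inside, positive out;
    # a voxel is foreground iff the field lifts the boundary past it
    band <- 3.5 * jitter$boundary_sd
    d_in <- chamfer_distance(!mask, sp, max_dist = band)   # dist to background
    d_out <- chamfer_distance(mask, sp, max_dist = band)   # dist to mask
    signed <- ifelse(mask, -d_in, d_out)
    out <- signed <= draws$field
  }
  if (draws$keep_vessel && any(truth$class_map == "vessel")) {
    abut <- (truth$class_map == "vessel") & dilate3d(mask, 6L, steps = 2L)
    out <- out | abut
  }
  out <- component_containing(out, mask, 26L)
  if (!any(out))
    stop("perturbation emptied the observer mask; re-seed required",
         call. = FALSE)
  voxel_mask(out, sp, truth$nodule_mask$origin)
}
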