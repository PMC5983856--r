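#' Feature configuration for 9x9 voxel patches
#'
#' Each classified voxel is described by its in-plane 9x9 neighbourhood
#' (the centre voxel plus its surrounding 80 voxels): a normalized
#' b-bin HU histogram over \code{[hu_min, hu_max]} (half-open bins, last
#' bin closed, out-of-range values clamped to the range ends), the patch
#' mean HU, the patch HU standard deviation, and the histogram entropy
#' (natural log).
#'
#' @param n_bins number of histogram bins.
#' @param hu_min,hu_max histogram range (HU); the default spans aerated
#'   lung through soft tissue.
#' @return An object of class \code{feature_config}.
#' @export
feature_config <- function(n_bins = 16L, hu_min = -1024, hu_max = 200) {
  if (hu_min >= hu_max) stop("hu_min must be < hu_max", call. = FALSE)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), hu_min = hu_min,
                 hu_max = hu_max), class = "feature_config")
}

#' Window half-width of the 9x9 in-plane patch (fixed by design)
#' @keywords internal
PATCH_HALF <- 4L
PATCH_SIZE <- 81L

#' Sample 9x9 VOI patches from a training cohort
#'
#' Eligible centres are nodule-mask voxels whose in-plane 9x9 window lies
#' fully inside the grid.  \code{n} centres are drawn uniformly without
#' replacement across the pooled cohort; deterministic given \code{seed}.
#'
#' @param cohort list of \code{ground_truth} phantoms (or any objects with
#'   \code{volume} and \code{nodule_mask}).
#' @param n number of patches to draw.
#' @param seed integer RNG seed.
#' @return List of \code{voi_patch} objects, each with \code{values}
#'   (9x9 matrix), \code{nodule_id} and \code{center}.
#' @export
sample_vois <- function(cohort, n, seed = 1L) {
  eligible <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    m <- cohort[[i]]$nodule_mask$values
    d <- dim(m)
    idx <- which(m, arr.ind = TRUE)
    ok <- idx[, 2] > PATCH_HALF & idx[, 2] <= d[2] - PATCH_HALF &
          idx[, 3] > PATCH_HALF & idx[, 3] <= d[3] - PATCH_HALF
    if (!any(ok)) return(NULL)
    cbind(nodule = i, idx[ok, , drop = FALSE])
  }))
  if (is.null(eligible) || nrow(eligible) < n)
    stop(sprintf("capacity error: %d eligible centers for %d requested VOIs",
                 if (is.null(eligible)) 0L else nrow(eligible), n),
         call. = FALSE)
  pick <- with_seed(seed, sample.int(nrow(eligible), n))
  lapply(pick, function(j) {
    row <- eligible[j, ]
    vol <- cohort[[row[["nodule"]]]]$volume$values
    patch <- vol[row[["dim1"]],
                 (row[["dim2"]] - PATCH_HALF):(row[["dim2"]] + PATCH_HALF),
                 (row[["dim3"]] - PATCH_HALF):(row[["dim3"]] + PATCH_HALF)]
    structure(list(values = matrix(patch, 9L, 9L),
                   nodule_id = row[["nodule"]],
                   center = unname(row[2:4])),
              class = "voi_patch")
  })
}

#' Extract the feature vector of one patch
#'
#' @param patch a \code{voi_patch} or an 81-value numeric vector/matrix.
#' @param config a [feature_config()].
#' @return Named numeric vector: \code{hist01..hist16} (or per
#'   \code{n_bins}), \code{mean}, \code{sd}, \code{entropy}.
#' @export
extract_features <- function(patch, config = feature_config()) {
  v <- if (inherits(patch, "voi_patch")) patch$values else patch
  v <- as.numeric(v)
  if (length(v) != PATCH_SIZE)
    stop("patch must contain exactly 81 values", call. = FALSE)
  drop(patch_feature_matrix(matrix(v, nrow = 1L), config))
}

# Vectorized feature extraction: rows of P are 81-voxel patches.
patch_feature_matrix <- function(P, config) {
  b <- config$n_bins
  width <- (config$hu_max - config$hu_min) / b
  X <- pmin(pmax(P, config$hu_min), config$hu_max)
  bin <- pmin(floor((X - config$hu_min) / width) + 1, b)   # last bin closed
  H <- matrix(0, nrow = nrow(P), ncol = b)
  for (k in seq_len(b)) H[, k] <- rowSums(bin == k)
  H <- H / PATCH_SIZE
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowSums((X - mu)^2), 0) / (PATCH_SIZE - 1))
  Hp <- H
  ent <- -rowSums(ifelse(Hp > 0, Hp * log(Hp), 0))
  out <- cbind(H, mean = mu, sd = sdv, entropy = ent)
  colnames(out) <- c(sprintf("hist%02d", seq_len(b)), "mean", "sd", "entropy")
  out
}

#' Pairwise similarity matrix for affinity propagation
#'
#' Similarity is the negative squared Euclidean distance between
#' column-standardized feature vectors (zero-variance columns are dropped
#' from the distance).  The diagonal carries the affinity-propagation
#' preference; \code{"median"} uses the median off-diagonal similarity.
#'
#' @param features numeric matrix (rows = VOIs) or list of feature
#'   vectors of equal length.
#' @param preference scalar or \code{"median"}.
#' @param standardize column-standardize features first (default); set
#'   FALSE to use raw feature distances.
#' @return List of class \code{similarity_matrix}: \code{S} (n x n),
#'   \code{preference}, and the standardization (\code{center},
#'   \code{scale}) applied.
#' @export
pairwise_similarity <- function(features, preference = "median",
                                standardize = TRUE) {
  if (is.list(features) && !is.data.frame(features)) {
    len <- vapply(features, length, 1L)
    if (length(unique(len)) != 1L)
      stop("dimension error: feature vectors differ in length", call. = FALSE)
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  n <- nrow(features)
  if (standardize) {
    std <- standardize_features(features)
  } else {
    std <- list(Z = features, center = rep(0, ncol(features)),
                scale = rep(1, ncol(features)))
  }
  Z <- std$Z
  sq <- rowSums(Z^2)
  S <- -(outer(sq, sq, "+") - 2 * tcrossprod(Z))
  S[S > 0] <- 0  # clip numerical noise; distances are nonnegative
  S <- (S + t(S)) / 2
  pref <- if (identical(preference, "median")) {
    if (n > 1L) stats::median(S[row(S) != col(S)]) else 0
  } else as.numeric(preference)
  diag(S) <- pref
  structure(list(S = S, preference = pref,
                 center = std$center, scale = std$scale),
            class = "similarity_matrix")
}

standardize_features <- function(features, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(features)
  if (is.null(scale)) {
    scale <- apply(features, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  Z <- sweep(sweep(features, 2, center), 2, scale, "/")
  list(Z = Z, center = center, scale = scale)
}
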