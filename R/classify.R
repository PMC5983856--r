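#' Classify a single 9x9 patch against the exemplar model
#'
#' The patch's feature vector is standardized with the model's training
#' statistics and assigned the label of the nearest exemplar (minimal
#' squared Euclidean feature distance); exact ties go to the
#' lowest-index exemplar.
#'
#' @param patch a \code{voi_patch} or 81-value numeric vector/matrix.
#' @param model an \code{exemplar_model}.
#' @return A single class label (character).
#' @export
classify_voxel <- function(patch, model) {
  f <- extract_features(patch, model$feature_config)
  z <- (f - model$center) / model$scale
  EZ <- sweep(sweep(model$features, 2, model$center), 2, model$scale, "/")
  d2 <- rowSums(sweep(EZ, 2, z)^2)
  model$labels[which.min(d2)]
}

#' Classify every voxel of a segmented nodule
#'
#' Each mask voxel whose in-plane 9x9 window lies fully inside the grid
#' is classified by nearest exemplar; mask voxels without full window
#' support are left unclassified (padding would fabricate attenuation)
#' and excluded from, but reported alongside, the signature.
#'
#' @param volume a [ct_volume()].
#' @param mask a [voxel_mask()] aligned to \code{volume}.
#' @param model an \code{exemplar_model}.
#' @return List of class \code{nodule_classification}: \code{class_map}
#'   (character array: class labels inside the mask, \code{"unclassified"}
#'   where support is lacking, NA outside) and \code{signature} (a
#'   [parametric_signature()]).
#' @export
classify_nodule <- function(volume, mask, model) {
  check_aligned(volume, mask)
  d <- dim(volume$values)
  idx <- which(mask$values, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  ok <- idx[, 2] > PATCH_HALF & idx[, 2] <= d[2] - PATCH_HALF &
        idx[, 3] > PATCH_HALF & idx[, 3] <= d[3] - PATCH_HALF
  if (!any(ok))
    stop("no mask voxel has full 9x9 in-plane support", call. = FALSE)
  eligible <- idx[ok, , drop = FALSE]

  # gather the 81-voxel in-plane window of every eligible voxel
  lin0 <- eligible[, 1] + d[1] * (eligible[, 2] - 1) +
    d[1] * d[2] * (eligible[, 3] - 1)
  offs <- expand.grid(dr = -PATCH_HALF:PATCH_HALF, dc = -PATCH_HALF:PATCH_HALF)
  P <- matrix(0, nrow = nrow(eligible), ncol = PATCH_SIZE)
  for (j in seq_len(PATCH_SIZE))
    P[, j] <- volume$values[lin0 + d[1] * offs$dr[j] +
                              d[1] * d[2] * offs$dc[j]]

  FT <- patch_feature_matrix(P, model$feature_config)
  Z <- sweep(sweep(FT, 2, model$center), 2, model$scale, "/")
  EZ <- sweep(sweep(model$features, 2, model$center), 2, model$scale, "/")
  D2 <- outer(rowSums(Z^2), rowSums(EZ^2), "+") - 2 * tcrossprod(Z, EZ)
  nearest <- max.col(-D2, ties.method = "first")
  labels <- model$labels[nearest]

  class_map <- array(NA_character_, dim = d)
  class_map[idx] <- "unclassified"
  class_map[eligible] <- labels

  sig <- parametric_signature(table(factor(labels, levels = PALETTE)),
                              n_unclassified = sum(!ok))
  structure(list(class_map = class_map, signature = sig),
            class = "nodule_classification")
}

#' Parametric signature of a nodule
#'
#' Per-class voxel counts and fractions over the classified voxels, plus
#' the VIRO (solid/invasive), lepidic, and intermediate group fractions.
#'
#' @param counts named integer vector of per-class voxel counts over the
#'   palette classes.
#' @param n_unclassified mask voxels excluded for lacking window support.
#' @return An object of class \code{parametric_signature}.
#' @export
parametric_signature <- function(counts, n_unclassified = 0L) {
  counts <- counts[PALETTE]
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  if (total == 0L) stop("zero classified voxels", call. = FALSE)
  fractions <- as.numeric(counts) / total
  names(fractions) <- PALETTE
  structure(list(counts = stats::setNames(as.integer(counts), PALETTE),
                 fractions = fractions,
                 total_classified = as.integer(total),
                 n_unclassified = as.integer(n_unclassified),
                 viro_fraction = sum(fractions[VIRO_CLASSES]),
                 lepidic_fraction = sum(fractions[LEPIDIC_CLASSES]),
                 intermediate_fraction = sum(fractions[INTERMEDIATE_CLASSES])),
            class = "parametric_signature")
}

#' @export
print.parametric_signature <- function(x, ...) {
  cat("<parametric_signature>", x$total_classified, "voxels classified,",
      x$n_unclassified, "unclassified\n")
  print(round(100 * x$fractions, 1))
  cat(sprintf("VIRO %.1f%%  lepidic %.1f%%  intermediate %.1f%%\n",
              100 * x$viro_fraction, 100 * x$lepidic_fraction,
              100 * x$intermediate_fraction))
  invisible(x)
}

#' VIRO burden of a signature
#'
#' The summed fraction of the V, I, R, O classes — the solid,
#' invasion-associated share of the nodule.
#'
#' @param signature a [parametric_signature()].
#' @return Fraction in [0, 1].
#' @export
viro_fraction <- function(signature) {
  stopifnot(inherits(signature, "parametric_signature"))
  signature$viro_fraction
}

#' Risk rule mapping VIRO burden to Good/Intermediate/Poor
#'
#' The printed cut-points for the published characterization are not part
#' of this implementation's sources; the defaults are explicit,
#' configurable assumptions, and every risk call records the rule it
#' applied.  Boundary values go to the more severe category.
#'
#' @param t_good VIRO fraction below which the call is Good.
#' @param t_poor VIRO fraction at or above which the call is Poor.
#' @return An object of class \code{risk_rule}.
#' @export
risk_rule <- function(t_good = 0.10, t_poor = 0.45) {
  if (!(t_good >= 0 && t_good < t_poor && t_poor <= 1))
    stop("config error: need 0 <= t_good < t_poor <= 1", call. = FALSE)
  structure(list(t_good = t_good, t_poor = t_poor), class = "risk_rule")
}

#' Characterize a nodule as Good, Intermediate, or Poor
#'
#' Poor if \code{viro_fraction >= t_poor}; Good if
#' \code{viro_fraction < t_good}; Intermediate otherwise.
#'
#' @param signature a [parametric_signature()].
#' @param rule a [risk_rule()].
#' @return List of class \code{risk_call}: \code{category} and a
#'   \code{trace} holding the thresholds and VIRO fraction used.
#' @export
risk_characterize <- function(signature, rule = risk_rule()) {
  stopifnot(inherits(rule, "risk_rule"))
  v <- viro_fraction(signature)
  category <- if (v >= rule$t_poor) "Poor"
    else if (v < rule$t_good) "Good"
    else "Intermediate"
  structure(list(category = category,
                 trace = list(viro_fraction = v, t_good = rule$t_good,
                              t_poor = rule$t_poor)),
            class = "risk_call")
}

#' @export
print.risk_call <- function(x, ...) {
  cat(sprintf("<risk_call> %s (VIRO %.1f%%; cuts %.0f%%/%.0f%%)\n",
              x$category, 100 * x$trace$viro_fraction,
              100 * x$trace$t_good, 100 * x$trace$t_poor))
  invisible(x)
}

#' Export signatures as one CSV row per nodule-observer
#'
#' @param signatures named list of [parametric_signature()] objects; names
#'   are "nodule:observer" identifiers or arbitrary labels.
#' @param rule a [risk_rule()] used to attach the risk category.
#' @return A data.frame with 9 fraction columns (percent), VIRO percent,
#'   and the risk category.
#' @export
signature_table <- function(signatures, rule = risk_rule()) {
  rows <- lapply(names(signatures), function(id) {
    s <- signatures[[id]]
    fr <- as.list(100 * s$fractions)
    names(fr) <- paste0("pct_", PALETTE)
    c(list(id = id), fr,
      list(pct_VIRO = 100 * s$viro_fraction,
           risk = risk_characterize(s, rule)$category,
           total_classified = s$total_classified,
           n_unclassified = s$n_unclassified))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}
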