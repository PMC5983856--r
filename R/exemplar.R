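#' The nine voxel-class palette and its prognostic grouping
#'
#' Classes are Violet, Indigo, Blue, Green, Yellow, Orange, Red, Cyan,
#' Pink.  V, I, R, O (the VIRO group) mark solid, invasion-associated
#' attenuation; B, C, G mark ground-glass / lepidic attenuation; P and Y
#' sit between.
#'
#' @format Character vectors.
#' @name class_palette
NULL

#' @rdname class_palette
#' @export
PALETTE <- c("V", "I", "B", "G", "Y", "O", "R", "C", "P")

#' @rdname class_palette
#' @export
VIRO_CLASSES <- c("V", "I", "R", "O")

#' @rdname class_palette
#' @export
LEPIDIC_CLASSES <- c("B", "C", "G")

#' @rdname class_palette
#' @export
INTERMEDIATE_CLASSES <- c("P", "Y")

# class labels in descending order of exemplar mean attenuation; the
# within-group sub-order is a frozen convention (groups, not sub-order,
# carry meaning)
LABELS_BY_DESC_HU <- c("R", "O", "V", "I", "Y", "P", "B", "C", "G")

#' Train the nine-class exemplar model on a cohort
#'
#' Samples 9x9 in-plane VOI patches from the cohort's nodules, extracts
#' histogram features, builds the pairwise similarity matrix, calibrates
#' the affinity-propagation preference to exactly \code{k} exemplars, and
#' labels the exemplar classes along the density spectrum.
#'
#' @param cohort list of \code{ground_truth} nodules (see
#'   [generate_cohort()]).
#' @param n_vois number of training patches (default 774).
#' @param k number of exemplar classes (default 9; labelling requires 9).
#' @param seed integer RNG seed for patch sampling.
#' @param config a [feature_config()].
#' @param ap an [ap_config()].
#' @return An object of class \code{exemplar_model}: exemplar feature
#'   vectors, class labels, feature configuration, standardization, and a
#'   training manifest.
#' @export
train_exemplar_model <- function(cohort, n_vois = 774L, k = 9L, seed = 1L,
                                 config = feature_config(),
                                 ap = ap_config()) {
  patches <- sample_vois(cohort, n_vois, seed)
  P <- do.call(rbind, lapply(patches, function(p) as.numeric(p$values)))
  FT <- patch_feature_matrix(P, config)
  sim <- pairwise_similarity(FT, preference = ap$preference)
  cal <- calibrate_preference(sim, target_k = k, config = ap)
  ex <- cal$fit$exemplars
  model <- structure(list(
    features = FT[ex, , drop = FALSE],
    labels = rep(NA_character_, length(ex)),
    feature_config = config,
    center = sim$center,
    scale = sim$scale,
    manifest = list(
      n_vois = n_vois, k = k, seed = seed,
      preference = cal$preference,
      ap_iterations = cal$fit$iterations,
      net_similarity = cal$fit$net_similarity,
      exemplar_vois = ex,
      exemplar_nodules = vapply(patches[ex], function(p) p$nodule_id, 1),
      cluster_sizes = as.vector(table(cal$fit$assignment)))),
    class = "exemplar_model")
  if (k == 9L) model <- label_classes(model)
  model
}

#' Label the nine exemplars along the density spectrum
#'
#' Exemplars are ranked by mean HU: the four highest-attenuation
#' exemplars receive the VIRO labels (descending R, O, V, I), the three
#' lowest the lepidic labels (ascending G, C, B), and the middle two the
#' intermediate labels (P below Y).  The resulting labelling is a
#' bijection onto the palette and is recorded in the manifest.
#'
#' @param model an \code{exemplar_model} with exactly 9 exemplars.
#' @return The model with \code{labels} filled in.
#' @export
label_classes <- function(model) {
  stopifnot(inherits(model, "exemplar_model"))
  if (nrow(model$features) != 9L)
    stop("arity error: labelling requires exactly 9 exemplars, got ",
         nrow(model$features), call. = FALSE)
  mean_hu <- model$features[, "mean"]
  ord <- order(mean_hu, decreasing = TRUE)
  labels <- character(9L)
  labels[ord] <- LABELS_BY_DESC_HU
  model$labels <- labels
  model$manifest$label_mean_hu <- stats::setNames(mean_hu, labels)
  model
}

#' @export
print.exemplar_model <- function(x, ...) {
  cat(sprintf("<exemplar_model> %d exemplars (%s), %d features, preference %.4g\n",
              nrow(x$features),
              paste(x$labels, collapse = ""),
              ncol(x$features),
              x$manifest$preference))
  invisible(x)
}

#' Write an exemplar model to a JSON manifest
#'
#' Full-precision serialization; [read_exemplar_model()] round-trips the
#' model exactly.
#'
#' @param model an \code{exemplar_model}.
#' @param path destination .json path.
#' @return Invisibly, \code{path}.
#' @export
write_exemplar_model <- function(model, path) {
  obj <- list(features = model$features,
              feature_names = colnames(model$features),
              labels = model$labels,
              feature_config = unclass(model$feature_config),
              center = model$center,
              scale = model$scale,
              manifest = model$manifest)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read an exemplar model from JSON
#'
#' @param path a file written by [write_exemplar_model()].
#' @return An \code{exemplar_model}.
#' @export
read_exemplar_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ft <- as.matrix(obj$features)
  colnames(ft) <- obj$feature_names
  fc <- obj$feature_config
  structure(list(features = ft,
                 labels = obj$labels,
                 feature_config = feature_config(fc$n_bins, fc$hu_min,
                                                 fc$hu_max),
                 center = stats::setNames(obj$center, obj$feature_names),
                 scale = stats::setNames(obj$scale, obj$feature_names),
                 manifest = obj$manifest),
            class = "exemplar_model")
}
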