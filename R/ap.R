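#' Affinity-propagation configuration
#'
#' @param damping message damping factor in [0.5, 1).
#' @param max_iterations iteration cap.
#' @param convergence_window iterations the exemplar set must stay
#'   unchanged to declare convergence.
#' @param preference diagonal preference: scalar or \code{"median"}.
#' @return An object of class \code{ap_config}.
#' @export
ap_config <- function(damping = 0.9, max_iterations = 1000L,
                      convergence_window = 50L, preference = "median") {
  if (damping < 0.5 || damping >= 1)
    stop("damping must be in [0.5, 1)", call. = FALSE)
  structure(list(damping = damping,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 preference = preference),
            class = "ap_config")
}

#' Cluster by affinity propagation
#'
#' From-scratch exemplar clustering by responsibility/availability message
#' passing with damping.  Every point is assigned to the exemplar with
#' maximal similarity (ties to the lowest index); exemplars are
#' self-assigned.  Non-convergence is flagged with a warning, never
#' silent.
#'
#' @param sim a [pairwise_similarity()] result, or a square numeric
#'   similarity matrix whose diagonal already carries the preference.
#' @param config an [ap_config()].
#' @return List of class \code{ap_result}: \code{exemplars} (indices),
#'   \code{assignment} (exemplar index per point), \code{net_similarity},
#'   \code{iterations}, \code{converged}.
#' @export
affinity_propagation <- function(sim, config = ap_config()) {
  S <- if (inherits(sim, "similarity_matrix")) sim$S else as.matrix(sim)
  n <- nrow(S)
  if (n != ncol(S)) stop("similarity matrix must be square", call. = FALSE)
  if (n == 1L)
    return(structure(list(exemplars = 1L, assignment = 1L,
                          net_similarity = S[1, 1], iterations = 0L,
                          converged = TRUE),
                     class = "ap_result"))
  # exactly symmetric inputs (e.g. duplicate points) make the message
  # passing oscillate; break ties with a deterministic, vanishing jitter
  eps <- .Machine$double.eps
  Sj <- S + (eps * abs(S) + 100 * .Machine$double.xmin) *
    with_seed(0L, matrix(stats::rnorm(n * n), n, n))
  run <- .ap_run(Sj, config$damping, config$max_iterations,
                 config$convergence_window)
  if (!run$converged)
    warning("affinity propagation did not converge within ",
            config$max_iterations, " iterations", call. = FALSE)
  ex <- which(run$is_exemplar)
  if (length(ex) == 0L) {
    # degenerate non-converged state: fall back to the single best exemplar
    ex <- which.max(colSums(S))
  }
  # within-cluster exemplar refinement to a fixed point, then reassignment
  for (pass in 1:10) {
    assignment <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
    assignment[ex] <- ex
    new_ex <- sort(vapply(ex, function(k) {
      members <- which(assignment == k)
      members[which.max(colSums(S[members, members, drop = FALSE]))]
    }, 1L))
    if (identical(new_ex, ex)) break
    ex <- new_ex
  }
  assignment <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assignment[ex] <- ex
  net <- sum(S[cbind(seq_len(n), assignment)])
  structure(list(exemplars = ex, assignment = assignment,
                 net_similarity = net, iterations = run$iterations,
                 converged = run$converged),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> %d exemplars, net similarity %.4g, %d iterations%s\n",
              length(x$exemplars), x$net_similarity, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Calibrate the preference to a target exemplar count
#'
#' Bisects the shared diagonal preference between \code{min(S)} and the
#' saturation end (zero, or the maximum off-diagonal similarity if that is
#' larger) until affinity propagation returns exactly \code{target_k}
#' exemplars.  The exemplar count is (up to rare
#' message-passing flips) non-decreasing in the preference, which makes
#' bisection well-posed.
#'
#' @param sim a [pairwise_similarity()] result or square similarity
#'   matrix; the diagonal is overwritten during the search.
#' @param target_k desired number of exemplars (<= n).
#' @param config an [ap_config()].
#' @param max_steps bisection step cap.
#' @return List of class \code{preference_calibration}: \code{preference},
#'   \code{fit} (the \code{ap_result} at that preference), \code{k},
#'   \code{steps}.
#' @export
calibrate_preference <- function(sim, target_k = 9L, config = ap_config(),
                                 max_steps = 40L) {
  S <- if (inherits(sim, "similarity_matrix")) sim$S else as.matrix(sim)
  n <- nrow(S)
  if (target_k > n)
    stop("target_k must not exceed the number of points", call. = FALSE)
  off <- S[row(S) != col(S)]
  lo <- min(c(off, diag(S)))
  # preference 0 makes every point self-sufficient for distance-based
  # (non-positive) similarities, so the saturation end is max(0, max(off))
  hi <- max(0, max(off))
  if (hi <= lo) hi <- lo + abs(lo) + 1

  run_at <- function(p) {
    diag(S) <- p
    affinity_propagation(S, config)
  }
  k_lo_fit <- run_at(lo); k_lo <- length(k_lo_fit$exemplars)
  k_hi_fit <- run_at(hi); k_hi <- length(k_hi_fit$exemplars)
  best <- list(fit = k_lo_fit, preference = lo,
               gap = abs(k_lo - target_k))
  note_best <- function(fit, p) {
    gap <- abs(length(fit$exemplars) - target_k)
    if (gap < best$gap) best <<- list(fit = fit, preference = p, gap = gap)
  }
  note_best(k_hi_fit, hi)

  if (best$gap == 0)
    return(structure(list(preference = best$preference, fit = best$fit,
                          k = target_k, steps = 0L),
                     class = "preference_calibration"))
  if (k_lo > target_k || k_hi < target_k)
    stop(sprintf(paste0("calibration error: exemplar count %d cannot be ",
                        "reached; achievable range at the search bounds is ",
                        "[%d, %d]"), target_k, k_lo, k_hi), call. = FALSE)

  steps <- 0L
  while (steps < max_steps) {
    steps <- steps + 1L
    mid <- (lo + hi) / 2
    fit <- run_at(mid)
    k <- length(fit$exemplars)
    note_best(fit, mid)
    if (k == target_k)
      return(structure(list(preference = mid, fit = fit, k = k,
                            steps = steps),
                       class = "preference_calibration"))
    if (k < target_k) lo <- mid else hi <- mid
  }
  stop(sprintf(paste0("calibration error: no preference reached %d ",
                      "exemplars in %d bisection steps; nearest achieved ",
                      "was %d"), target_k, max_steps,
               length(best$fit$exemplars)), call. = FALSE)
}
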