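#' Build a long-format observer table
#'
#' One record per (nodule, observer, class) holding the class fraction on
#' the percent scale.  This is the unit of the variance-component / ICC
#' analysis.
#'
#' @param nodule,observer,class vectors of equal length (ids/labels).
#' @param fraction_pct class fractions in percent, in [0, 100].
#' @return A data.frame of class \code{observer_table}.
#' @export
observer_table <- function(nodule, observer, class, fraction_pct) {
  if (any(fraction_pct < 0 | fraction_pct > 100))
    stop("fractions must be percentages in [0, 100]", call. = FALSE)
  df <- data.frame(nodule = nodule, observer = observer, class = class,
                   fraction_pct = fraction_pct)
  if (anyDuplicated(df[, c("nodule", "observer", "class")]))
    stop("each (nodule, observer, class) must appear once", call. = FALSE)
  class(df) <- c("observer_table", "data.frame")
  df
}

# nodule x observer response matrix for one class; errors unless the
# crossing is complete and balanced
class_matrix <- function(table, class) {
  sub <- table[table$class == class, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records for class '", class, "'", call. = FALSE)
  y <- tapply(sub$fraction_pct, list(sub$nodule, sub$observer), identity)
  if (any(is.na(y)))
    stop("balance error: incomplete nodule x observer crossing for class '",
         class, "'", call. = FALSE)
  y
}

#' Two-way variance components of one class
#'
#' Method-of-moments decomposition from the balanced two-way
#' random-effects ANOVA: the residual component is the mean-square error,
#' the observer component is \code{(MS_obs - MSE) / n_nodules}, and the
#' nodule component is \code{(MS_nod - MSE) / n_observers}.  Negative
#' estimates are truncated to zero and flagged.
#'
#' @param table an [observer_table()].
#' @param class class label to decompose.
#' @return List of class \code{variance_components}:
#'   \code{sigma2_nodule}, \code{sigma2_observer}, \code{sigma2_residual}
#'   (squared-percent units), \code{truncated} (character vector of
#'   truncated components), and the underlying mean squares.
#' @export
variance_components <- function(table, class) {
  y <- class_matrix(table, class)
  n <- nrow(y)
  k <- ncol(y)
  if (n < 2L || k < 2L)
    stop("arity error: need >= 2 nodules and >= 2 observers", call. = FALSE)
  gm <- mean(y)
  rm_ <- rowMeans(y)
  cm <- colMeans(y)
  ms_nod <- k * sum((rm_ - gm)^2) / (n - 1)
  ms_obs <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2) /
    ((n - 1) * (k - 1))
  raw <- c(nodule = (ms_nod - mse) / k,
           observer = (ms_obs - mse) / n,
           residual = mse)
  truncated <- names(raw)[raw < 0]
  est <- pmax(raw, 0)
  structure(list(sigma2_nodule = est[["nodule"]],
                 sigma2_observer = est[["observer"]],
                 sigma2_residual = est[["residual"]],
                 raw = raw, truncated = truncated,
                 ms = c(nodule = ms_nod, observer = ms_obs, error = mse),
                 n_nodules = n, n_observers = k),
            class = "variance_components")
}

#' Intraclass correlation of one class with a 95% confidence interval
#'
#' Two-way random effects, absolute agreement, single measurement: the
#' ratio of the between-nodule variance to the total (nodule + observer +
#' residual) variance, estimated from ANOVA mean squares.  The confidence
#' interval is the F-based interval of McGraw and Wong for this ICC form;
#' its lower bound is deliberately not truncated at zero.
#'
#' @param table an [observer_table()].
#' @param class class label.
#' @param conf confidence level (default 0.95).
#' @return List of class \code{icc_result}: \code{icc}, \code{ci}
#'   (length 2), \code{n_nodules}, \code{n_observers}, \code{components}.
#' @export
icc <- function(table, class, conf = 0.95) {
  vc <- variance_components(table, class)
  ms <- vc$ms
  n <- vc$n_nodules
  k <- vc$n_observers
  msr <- ms[["nodule"]]; msc <- ms[["observer"]]; mse <- ms[["error"]]
  if (msr == 0 && msc == 0 && mse == 0)
    stop("undefined ICC: zero total variance", call. = FALSE)
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  est <- (msr - mse) / denom
  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {
    ci <- c(est, est)  # exact agreement: degenerate interval
  } else {
    if (mse == 0) {
      v <- k - 1
    } else {
      fj <- msc / mse
      a <- k * est * fj + n * (1 + (k - 1) * est) - k * est
      v <- ((k - 1) * (n - 1) * a^2) /
        ((n - 1) * k^2 * est^2 * fj^2 + (n * (1 + (k - 1) * est) - k * est)^2)
    }
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = est, ci = ci, conf = conf,
                 n_nodules = n, n_observers = k, components = vc),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (%.0f%% CI %.3f, %.3f); %d nodules x %d observers\n",
              x$icc, 100 * x$conf, x$ci[1], x$ci[2],
              x$n_nodules, x$n_observers))
  invisible(x)
}

#' ICC panel over the nine classes, VIRO, and their average
#'
#' One ICC per palette class, one for the VIRO group (computed on the
#' summed V+I+R+O percent fractions, which must be present as class
#' \code{"VIRO"} in the table), and an \code{"Avg."} row holding the
#' arithmetic mean of the nine per-class ICCs.  Optionally stratified by
#' a grouping column; strata with fewer than two nodules are skipped with
#' a warning.  Classes whose total variance is zero in a stratum yield NA
#' with a note.
#'
#' @param table an [observer_table()], optionally with extra columns.
#' @param classes class labels to report (default: palette then VIRO).
#' @param strata_col optional name of a grouping column in \code{table}.
#' @return A data.frame with columns stratum, class, icc, ci_low,
#'   ci_high, n_nodules, n_observers, note.
#' @export
icc_panel <- function(table, classes = c(PALETTE, "VIRO"),
                      strata_col = NULL) {
  strata <- if (is.null(strata_col)) list(`all` = table)
    else split(table, table[[strata_col]])
  out <- list()
  for (sname in names(strata)) {
    sub <- strata[[sname]]
    if (length(unique(sub$nodule)) < 2L) {
      warning("stratum '", sname, "' has fewer than 2 nodules; skipped",
              call. = FALSE)
      next
    }
    rows <- lapply(classes, function(cl) {
      res <- tryCatch(icc(sub, cl), error = function(e) e)
      if (inherits(res, "error"))
        data.frame(stratum = sname, class = cl, icc = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   n_nodules = length(unique(sub$nodule)),
                   n_observers = length(unique(sub$observer)),
                   note = conditionMessage(res))
      else
        data.frame(stratum = sname, class = cl, icc = res$icc,
                   ci_low = res$ci[1], ci_high = res$ci[2],
                   n_nodules = res$n_nodules, n_observers = res$n_observers,
                   note = "")
    })
    panel <- do.call(rbind, rows)
    class_iccs <- panel$icc[panel$class %in% PALETTE]
    avg <- data.frame(stratum = sname, class = "Avg.",
                      icc = mean(class_iccs, na.rm = TRUE),
                      ci_low = NA_real_, ci_high = NA_real_,
                      n_nodules = panel$n_nodules[1],
                      n_observers = panel$n_observers[1],
                      note = if (anyNA(class_iccs))
                        "mean over classes with defined ICC" else "")
    out[[sname]] <- rbind(panel, avg)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dice similarity coefficient of two masks
#'
#' \code{2 |A n B| / (|A| + |B|)}; 0.7 is the conventional threshold for
#' strong overlap in segmentation validation.
#'
#' @param mask_a,mask_b aligned [voxel_mask()] objects.
#' @return Numeric in [0, 1] with attribute \code{strong_overlap}
#'   (TRUE if > 0.7).
#' @export
dsc <- function(mask_a, mask_b) {
  check_aligned(mask_a, mask_b)
  na <- sum(mask_a$values)
  nb <- sum(mask_b$values)
  if (na + nb == 0L)
    stop("undefined DSC: both masks are empty", call. = FALSE)
  val <- 2 * sum(mask_a$values & mask_b$values) / (na + nb)
  structure(val, strong_overlap = val > 0.7)
}

#' Fleiss kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement of a fixed number of raters assigning each
#' subject one of several categories, with the large-sample standard
#' error for the confidence interval and the conventional interpretation
#' band (0.61-0.8 substantial, 0.81-1.0 almost perfect).
#'
#' @param ratings subjects x raters matrix/data.frame of category labels.
#' @param categories category levels (default: observed).
#' @param conf confidence level.
#' @return List of class \code{kappa_result}: \code{kappa}, \code{ci},
#'   \code{category_counts}, \code{band}.
#' @export
fleiss_kappa <- function(ratings, categories = NULL, conf = 0.95) {
  ratings <- as.matrix(ratings)
  N <- nrow(ratings)
  n <- ncol(ratings)
  if (N < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  counts <- matrix(0L, nrow = N, ncol = length(categories),
                   dimnames = list(NULL, categories))
  for (i in seq_len(N))
    counts[i, ] <- as.integer(table(factor(ratings[i, ],
                                           levels = categories)))
  pj <- colSums(counts) / (N * n)
  pe <- sum(pj^2)
  if (pe >= 1)
    stop("undefined kappa: all ratings fall in a single category",
         call. = FALSE)
  pi_ <- (rowSums(counts^2) - n) / (n * (n - 1))
  pbar <- mean(pi_)
  kappa <- (pbar - pe) / (1 - pe)
  se <- sqrt(2 / (N * n * (n - 1))) *
    sqrt(pe - (2 * n - 3) * pe^2 + 2 * (n - 2) * sum(pj^3)) / (1 - pe)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  band <- if (kappa > 0.8) "almost perfect (0.81-1.0)"
    else if (kappa > 0.6) "substantial (0.61-0.8)"
    else if (kappa > 0.4) "moderate (0.41-0.6)"
    else if (kappa > 0.2) "fair (0.21-0.4)"
    else "slight or poor (<= 0.2)"
  structure(list(kappa = kappa, ci = c(kappa - z * se, kappa + z * se),
                 se = se, conf = conf,
                 category_counts = colSums(counts), band = band),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Fleiss kappa %.3f (%.0f%% CI %.3f, %.3f): %s\n",
              x$kappa, 100 * x$conf, x$ci[1], x$ci[2], x$band))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on
#' \code{groups - 1} degrees of freedom (delegated to
#' \code{stats::kruskal.test}).
#'
#' @param groups list of numeric vectors, one per group.
#' @return List of class \code{kw_result}: \code{H}, \code{df}, \code{p},
#'   \code{group_sizes}, \code{ties_corrected}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, 1L)
  if (any(sizes == 0L)) stop("groups must be nonempty", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("degenerate data: all values identical across groups",
         call. = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(values, g)
  structure(list(H = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p = kt$p.value,
                 group_sizes = sizes,
                 ties_corrected = anyDuplicated(values) > 0),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g (%d groups)%s\n",
              x$H, x$df, x$p, length(x$group_sizes),
              if (x$ties_corrected) " [tie-corrected]" else ""))
  invisible(x)
}

#' Simulate a balanced two-way random-effects observer table
#'
#' Draws \code{y_ij = mu + a_i + b_j + e_ij} with independent normal
#' nodule, observer, and residual effects — the generative model under
#' which the ICC estimator and its interval are evaluated.
#'
#' @param n_nodules,n_observers table dimensions.
#' @param sigma2_nodule,sigma2_observer,sigma2_residual true variance
#'   components.
#' @param mu grand mean (percent scale).
#' @param seed integer RNG seed.
#' @param class label to attach (default "sim").
#' @return An [observer_table()].
#' @export
simulate_observer_table <- function(n_nodules, n_observers,
                                    sigma2_nodule, sigma2_observer,
                                    sigma2_residual, mu = 50, seed = 1L,
                                    class = "sim") {
  y <- with_seed(seed, {
    a <- rnorm(n_nodules, sd = sqrt(sigma2_nodule))
    b <- rnorm(n_observers, sd = sqrt(sigma2_observer))
    e <- matrix(rnorm(n_nodules * n_observers, sd = sqrt(sigma2_residual)),
                n_nodules, n_observers)
    mu + outer(a, rep(1, n_observers)) + outer(rep(1, n_nodules), b) + e
  })
  y <- pmin(pmax(y, 0), 100)
  observer_table(nodule = rep(seq_len(n_nodules), n_observers),
                 observer = rep(seq_len(n_observers), each = n_nodules),
                 class = class, fraction_pct = as.vector(y))
}
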