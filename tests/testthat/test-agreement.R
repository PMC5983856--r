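make_table <- function(y, class = "V") {
  observer_table(nodule = rep(seq_len(nrow(y)), ncol(y)),
                 observer = rep(seq_len(ncol(y)), each = nrow(y)),
                 class = class, fraction_pct = as.vector(y))
}

test_that("variance components match a direct two-way ANOVA fit", {
  y <- matrix(c(12, 14, 13,
                40, 42, 45,
                70, 66, 68,
                25, 27, 24), nrow = 4, byrow = TRUE)
  vc <- variance_components(make_table(y), "V")

  # independent oracle: mean squares from stats::aov
  df <- data.frame(y = as.vector(y),
                   nod = factor(rep(1:4, 3)),
                   obs = factor(rep(1:3, each = 4)))
  ms <- summary(stats::aov(y ~ nod + obs, data = df))[[1]][["Mean Sq"]]
  expect_equal(unname(vc$ms["nodule"]), ms[1], tolerance = 1e-12)
  expect_equal(unname(vc$ms["observer"]), ms[2], tolerance = 1e-12)
  expect_equal(unname(vc$ms["error"]), ms[3], tolerance = 1e-12)
  expect_equal(vc$sigma2_residual, ms[3], tolerance = 1e-12)
  expect_equal(vc$sigma2_observer, max((ms[2] - ms[3]) / 4, 0),
               tolerance = 1e-12)
  expect_equal(vc$sigma2_nodule, max((ms[1] - ms[3]) / 3, 0),
               tolerance = 1e-12)
})

test_that("perfect agreement zeroes the observer and residual components", {
  y <- matrix(rep(c(10, 40, 70, 25), 3), nrow = 4)
  vc <- variance_components(make_table(y), "V")
  expect_equal(vc$sigma2_observer, 0)
  expect_equal(vc$sigma2_residual, 0)
  expect_gt(vc$sigma2_nodule, 0)
})

test_that("a constant shift of one observer loads only the observer component", {
  base <- c(12, 40, 70, 25, 55, 33, 61, 18, 47, 29)
  y <- matrix(rep(base, 3), nrow = 10)   # perfectly agreeing observers
  a <- variance_components(make_table(y), "V")
  y2 <- y
  y2[, 2] <- y2[, 2] + 5
  b <- variance_components(make_table(y2), "V")
  expect_gt(b$sigma2_observer, a$sigma2_observer)
  expect_equal(b$sigma2_nodule, a$sigma2_nodule, tolerance = 1e-9)
  expect_equal(b$sigma2_residual, a$sigma2_residual, tolerance = 1e-9)
})

test_that("balance and arity violations are rejected", {
  tab <- make_table(matrix(1:6 * 1.0, nrow = 3))
  expect_error(variance_components(tab[-1, ], "V"), "balance error")
  one_obs <- observer_table(nodule = 1:3, observer = 1, class = "V",
                            fraction_pct = c(1, 2, 3))
  expect_error(variance_components(one_obs, "V"), "arity error")
  expect_error(variance_components(tab, "Q"), "no records")
})

test_that("ICC is 1 under perfect agreement and undefined for flat tables", {
  y <- matrix(rep(c(10, 40, 70, 25), 3), nrow = 4)
  res <- icc(make_table(y), "V")
  expect_equal(res$icc, 1)
  expect_equal(res$ci, c(1, 1))

  flat <- matrix(5, 4, 3)
  expect_error(icc(make_table(flat), "V"), "zero total variance")
})

test_that("ICC recovers the generating ratio at n = 200 nodules", {
  # true components (9, 0.5, 0.5) -> ICC 0.9
  ests <- vapply(1:20, function(s) {
    tab <- simulate_observer_table(200, 3, 9, 0.5, 0.5, seed = s)
    icc(tab, "sim")$icc
  }, 1)
  expect_lt(abs(mean(ests) - 0.9), 0.03)
})

test_that("a pure-noise table yields ICC near 0 with a CI covering 0", {
  ests <- t(vapply(1:20, function(s) {
    tab <- simulate_observer_table(60, 3, 0, 0.5, 4, seed = 100 + s)
    r <- icc(tab, "sim")
    c(r$icc, r$ci)
  }, numeric(3)))
  expect_lt(abs(mean(ests[, 1])), 0.05)
  expect_gt(mean(ests[, 2] <= 0 & ests[, 3] >= 0), 0.8)
})

test_that("the 95% interval covers the truth in at least 90% of tables", {
  # minimal observer contribution, as the study regime reports; coverage
  # of the F interval is known to degrade when the rater variance share
  # grows (k - 1 = 2 df), documented in the methods vignette
  truth <- 0.5
  cover <- vapply(1:200, function(s) {
    tab <- simulate_observer_table(50, 3, 10 * truth, 0.5,
                                   9.5 - 10 * truth, seed = 5000 + s)
    r <- icc(tab, "sim")
    r$ci[1] <= truth && truth <= r$ci[2]
  }, TRUE)
  expect_gte(mean(cover), 0.90)
})

test_that("the ICC panel reports classes, VIRO, and their average", {
  set.seed(44)
  classes <- c(PALETTE, "VIRO")
  rows <- list()
  for (cl in classes) {
    y <- matrix(stats::rnorm(30, 30, 8), nrow = 10) +
      stats::rnorm(10, 0, 6)   # nodule effect
    y <- pmin(pmax(y, 0), 100)
    rows[[cl]] <- data.frame(nodule = rep(1:10, 3),
                             observer = rep(1:3, each = 10),
                             class = cl, fraction_pct = as.vector(y))
  }
  tab <- do.call(rbind, rows)
  panel <- icc_panel(tab)
  expect_setequal(panel$class, c(classes, "Avg."))
  avg <- panel$icc[panel$class == "Avg."]
  expect_equal(avg, mean(panel$icc[panel$class %in% PALETTE]),
               tolerance = 1e-12)
  # VIRO row is its own ICC computation, not an average of class ICCs
  expect_equal(panel$icc[panel$class == "VIRO"], icc(tab, "VIRO")$icc)

  # perfect-agreement table -> every defined entry is 1
  perf <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(nodule = rep(1:4, 3), observer = rep(1:3, each = 4),
               class = cl, fraction_pct = rep(c(5, 20, 40, 70), 3))
  }))
  p2 <- icc_panel(perf)
  expect_true(all(p2$icc == 1))
})

test_that("Dice matches hand counts and its edge contracts", {
  grid <- function(idx) {
    v <- array(FALSE, c(1, 1, 10))
    v[1, 1, idx] <- TRUE
    voxel_mask(v, c(1, 1, 1))
  }
  a <- grid(1:6)
  b <- grid(4:7)   # |A| = 6, |B| = 4, overlap = 3
  expect_equal(as.numeric(dsc(a, b)), 0.6)
  expect_equal(as.numeric(dsc(b, a)), 0.6)
  expect_false(attr(dsc(a, b), "strong_overlap"))
  expect_equal(as.numeric(dsc(a, a)), 1.0)
  expect_true(attr(dsc(a, a), "strong_overlap"))
  expect_equal(as.numeric(dsc(grid(1:3), grid(7:9))), 0.0)
  expect_error(dsc(grid(integer(0)), grid(integer(0))), "undefined DSC")
  misaligned <- voxel_mask(array(FALSE, c(1, 1, 10)), c(1, 1, 2))
  expect_error(dsc(a, misaligned), "alignment")
})

test_that("Fleiss kappa matches the direct formula and its symmetries", {
  ratings <- rbind(c("Good", "Good", "Good"),
                   c("Good", "Intermediate", "Good"),
                   c("Poor", "Poor", "Intermediate"),
                   c("Intermediate", "Intermediate", "Intermediate"),
                   c("Poor", "Poor", "Poor"))
  res <- fleiss_kappa(ratings)
  expect_equal(res$kappa, oracle_fleiss(ratings), tolerance = 1e-12)
  expect_true(res$ci[1] <= res$kappa && res$kappa <= res$ci[2])

  # relabelling categories leaves kappa unchanged
  relabel <- matrix(c(A = "x", B = "y", C = "z")[
    match(ratings, c("Good", "Intermediate", "Poor"))], nrow = 5)
  expect_equal(fleiss_kappa(relabel)$kappa, res$kappa, tolerance = 1e-12)

  unanimous <- matrix(rep(c("G", "P", "I", "G"), 3), ncol = 3)
  expect_equal(fleiss_kappa(unanimous)$kappa, 1)

  expect_error(fleiss_kappa(matrix("G", 4, 3)), "undefined kappa")
})

test_that("two raters reduce exactly to Scott's pi (pooled-marginal kappa)", {
  set.seed(9)
  for (r in 1:10) {
    r1 <- sample(c("Good", "Poor"), 30, replace = TRUE)
    r2 <- ifelse(stats::runif(30) < 0.7, r1,
                 sample(c("Good", "Poor"), 30, replace = TRUE))
    if (length(unique(c(r1, r2))) < 2) next
    expect_equal(fleiss_kappa(cbind(r1, r2))$kappa,
                 oracle_scott_pi(r1, r2), tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis matches the rank-sum formula and its invariances", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$H, oracle_kw_no_ties(list(c(1, 2), c(3, 4), c(5, 6))),
               tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_false(res$ties_corrected)

  # all-distinct values match the no-ties closed form exactly
  set.seed(15)
  g <- split(sample(seq(1, 300, by = 7), 24), rep(1:3, 8))
  expect_equal(kruskal_wallis(g)$H, oracle_kw_no_ties(g), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  expect_equal(kruskal_wallis(lapply(g, function(x) exp(x / 50)))$H,
               kruskal_wallis(g)$H, tolerance = 1e-12)

  # identical groups: fully tied, H = 0 and p = 1 after tie correction
  same <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_true(same$ties_corrected)

  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})
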