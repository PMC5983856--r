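# Small, fast phantom configurations and independent oracles shared
# across the test files.  Fixtures are generated in code, cached for the
# duration of the test run.

small_spec <- function(nodule_radius = 3.5, solid_core_radius = 1.75, ...) {
  phantom_spec(grid_shape = c(32L, 36L, 36L), spacing = c(1, 0.7, 0.7),
               nodule_center = c(16, 18, 18), nodule_radius = nodule_radius,
               solid_core_radius = solid_core_radius, ...)
}

# cohort sampler spanning pure ground-glass to fully solid small nodules
small_sampler <- function(i, rng_seed = i) {
  r <- runif(1, 3, 4.2)
  frac <- runif(1)
  vr <- if (runif(1) < 0.3) runif(1, 1, 1.5) else NA_real_
  small_spec(nodule_radius = r, solid_core_radius = r * frac,
             vessel_radius = vr, rng_seed = rng_seed)
}

.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(8, small_sampler, seed = 42)
  .fixtures$cohort
}

fixture_model <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- train_exemplar_model(fixture_cohort()$phantoms,
                                            n_vois = 250, k = 9, seed = 7)
  .fixtures$model
}

# cohort whose solid cores exceed the 6.3 mm in-plane window, so pure-solid
# patches exist and the densest exemplar is a solid-tissue patch
fixture_solid_model <- function() {
  if (is.null(.fixtures$solid_model)) {
    fracs <- c(1, 1, 0.8, 0.5, 0.2, 0)
    sampler <- function(i, rng_seed = i)
      small_spec(nodule_radius = 4.2, solid_core_radius = 4.2 * fracs[i],
                 rng_seed = rng_seed)
    coh <- generate_cohort(6, sampler, seed = 17)
    .fixtures$solid_model <- train_exemplar_model(coh$phantoms,
                                                  n_vois = 250, k = 9,
                                                  seed = 7)
  }
  .fixtures$solid_model
}

# --- independent oracles -------------------------------------------------

# exhaustive exemplar-subset search maximizing net similarity
brute_force_net_similarity <- function(S) {
  n <- nrow(S)
  best <- -Inf
  for (m in seq_len(2^n - 1)) {
    E <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    rest <- setdiff(seq_len(n), E)
    v <- sum(diag(S)[E]) +
      sum(apply(S[rest, E, drop = FALSE], 1, max))
    if (v > best) best <- v
  }
  best
}

# queue-based flood fill, written independently of the package internals
oracle_flood_fill <- function(ok, seed, connectivity = 26L) {
  d <- dim(ok)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  visited <- array(FALSE, d)
  if (!ok[seed[1], seed[2], seed[3]]) return(visited)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  queue <- list(seed)
  while (length(queue) > 0) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (i in seq_len(nrow(off))) {
      nb <- cur + off[i, ]
      if (all(nb >= 1) && all(nb <= d) &&
          ok[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1L]] <- nb
      }
    }
  }
  visited
}

# Scott's pi for two raters: chance agreement from the pooled marginal
# distribution (the two-rater special case of multi-rater kappa)
oracle_scott_pi <- function(r1, r2) {
  cats <- sort(unique(c(r1, r2)))
  n <- length(r1)
  po <- mean(r1 == r2)
  pj <- (as.vector(table(factor(r1, cats))) +
           as.vector(table(factor(r2, cats)))) / (2 * n)
  pe <- sum(pj^2)
  (po - pe) / (1 - pe)
}

# textbook Kruskal-Wallis H without tie handling (for all-distinct data)
oracle_kw_no_ties <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  rk <- rank(values)
  sizes <- vapply(groups, length, 1L)
  idx <- rep(seq_along(groups), sizes)
  Rj <- tapply(rk, idx, sum)
  12 / (N * (N + 1)) * sum(Rj^2 / sizes) - 3 * (N + 1)
}

# Fleiss kappa from the category-count formulation, written directly
oracle_fleiss <- function(ratings) {
  cats <- sort(unique(as.vector(ratings)))
  N <- nrow(ratings)
  n <- ncol(ratings)
  counts <- t(apply(ratings, 1, function(r) table(factor(r, cats))))
  pj <- colSums(counts) / (N * n)
  pbar <- mean((rowSums(counts^2) - n) / (n * (n - 1)))
  pe <- sum(pj^2)
  (pbar - pe) / (1 - pe)
}
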