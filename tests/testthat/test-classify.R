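test_that("the classification window holds the centre plus 80 surrounding voxels", {
  offs <- expand.grid(dr = -4:4, dc = -4:4)
  expect_equal(nrow(offs), 81L)
  expect_equal(sum(!(offs$dr == 0 & offs$dc == 0)), 80L)
  expect_error(extract_features(rep(0, 80)), "81 values")
})

test_that("a noiseless solid phantom classifies its solid interior to the densest class", {
  # training cohort must hold solid cores wider than the 9x9 window for a
  # pure-solid exemplar to exist; boundary voxels whose windows mix in
  # lung legitimately map to sub-solid classes, so the construction is
  # checked on voxels whose whole window lies inside the nodule
  m <- fixture_solid_model()
  gt <- generate_phantom(phantom_spec(nodule_radius = 6,
                                      solid_core_radius = 6, noise_sd = 0))
  cls <- classify_nodule(gt$volume, gt$nodule_mask, m)
  mask <- gt$nodule_mask$values
  interior <- mask
  for (dr in -4:4) for (dc in -4:4)
    interior <- interior & nodulesig:::shift3d(mask, 0, dr, dc)
  expect_gt(sum(interior), 100)
  densest <- m$labels[which.max(m$features[, "mean"])]
  expect_gte(mean(cls$class_map[interior] == densest), 0.99)
  # and the whole-nodule signature is dominated by the solid classes
  expect_gt(cls$signature$viro_fraction, 0.5)
})

test_that("signatures conserve counts and agree with the class map", {
  m <- fixture_model()
  gt <- fixture_cohort()$phantoms[[2]]
  cls <- classify_nodule(gt$volume, gt$nodule_mask, m)
  sig <- cls$signature
  expect_equal(sum(sig$fractions), 1, tolerance = 1e-9)
  expect_equal(sum(sig$counts), sig$total_classified)
  tallies <- table(factor(cls$class_map[cls$class_map %in% PALETTE],
                          levels = PALETTE))
  expect_identical(as.integer(tallies), unname(sig$counts))
  expect_equal(sig$total_classified + sig$n_unclassified,
               sum(gt$nodule_mask$values))
  expect_equal(sig$viro_fraction + sig$lepidic_fraction +
                 sig$intermediate_fraction, 1, tolerance = 1e-9)
})

test_that("mask voxels without full window support are reported unclassified", {
  m <- fixture_model()
  gt <- fixture_cohort()$phantoms[[1]]
  d <- dim(gt$volume$values)
  # a mask strip touching the column edge: edge voxels lack support
  mask <- array(FALSE, d)
  mask[15, 16:20, 1:12] <- TRUE
  cls <- classify_nodule(gt$volume,
                         voxel_mask(mask, gt$volume$spacing), m)
  expect_equal(cls$signature$n_unclassified, 5L * 4L)
  expect_equal(sum(cls$class_map == "unclassified", na.rm = TRUE), 20L)
  expect_equal(cls$signature$total_classified, 5L * 8L)

  expect_error(classify_nodule(gt$volume,
                               voxel_mask(array(FALSE, d), gt$volume$spacing),
                               m),
               "empty")
})

test_that("VIRO burden sums the four solid-associated class fractions", {
  all_v <- parametric_signature(c(V = 50, I = 0, B = 0, G = 0, Y = 0,
                                  O = 0, R = 0, C = 0, P = 0))
  expect_equal(viro_fraction(all_v), 1.0)

  mixed <- parametric_signature(c(V = 10, I = 10, R = 10, O = 10,
                                  B = 20, G = 20, C = 10, P = 5, Y = 5))
  expect_equal(viro_fraction(mixed), 0.4)

  none <- parametric_signature(c(V = 0, I = 0, R = 0, O = 0,
                                 B = 50, G = 30, C = 10, P = 5, Y = 5))
  expect_equal(viro_fraction(none), 0.0)
})

test_that("risk characterization applies severe-side boundary rules", {
  sig <- function(viro_pct) {
    parametric_signature(c(V = viro_pct, I = 0, R = 0, O = 0,
                           B = 100 - viro_pct, G = 0, C = 0, P = 0, Y = 0))
  }
  rule <- risk_rule()
  expect_identical(risk_characterize(sig(0), rule)$category, "Good")
  expect_identical(risk_characterize(sig(45), rule)$category, "Poor")
  expect_identical(risk_characterize(sig(30), rule)$category, "Intermediate")
  expect_identical(risk_characterize(sig(10), rule)$category, "Intermediate")
  expect_identical(risk_characterize(sig(9), rule)$category, "Good")
  call <- risk_characterize(sig(30), rule)
  expect_equal(call$trace$viro_fraction, 0.30)
  expect_error(risk_rule(0.5, 0.4), "config error")
})

test_that("classification is equivariant under a global HU shift", {
  coh <- fixture_cohort()
  shift <- 100
  shifted_sampler <- function(i, rng_seed = i) {
    s <- small_sampler(i, rng_seed)
    phantom_spec(grid_shape = s$grid_shape, spacing = s$spacing,
                 nodule_center = s$nodule_center,
                 nodule_radius = s$nodule_radius,
                 solid_core_radius = s$solid_core_radius,
                 solid_hu = s$solid_hu + shift, ggo_hu = s$ggo_hu + shift,
                 lung_hu = s$lung_hu + shift, noise_sd = s$noise_sd,
                 vessel_radius = s$vessel_radius, chest_wall = s$chest_wall,
                 rng_seed = s$rng_seed)
  }
  coh2 <- generate_cohort(8, shifted_sampler, seed = 42)
  cfg2 <- feature_config(hu_min = -1024 + shift, hu_max = 200 + shift)
  m1 <- fixture_model()
  m2 <- train_exemplar_model(coh2$phantoms, n_vois = 250, k = 9, seed = 7,
                             config = cfg2)
  gt1 <- coh$phantoms[[3]]
  gt2 <- coh2$phantoms[[3]]
  c1 <- classify_nodule(gt1$volume, gt1$nodule_mask, m1)
  c2 <- classify_nodule(gt2$volume, gt2$nodule_mask, m2)
  agree <- mean(c1$class_map[gt1$nodule_mask$values] ==
                  c2$class_map[gt2$nodule_mask$values])
  expect_gte(agree, 0.999)
  expect_equal(c1$signature$viro_fraction, c2$signature$viro_fraction,
               tolerance = 1e-3)
})

test_that("solidifying the ground-glass shell cannot lower the VIRO burden", {
  m <- fixture_model()
  base <- small_spec(nodule_radius = 4, solid_core_radius = 2, rng_seed = 13L)
  solidified <- small_spec(nodule_radius = 4, solid_core_radius = 2,
                           ggo_hu = base$solid_hu, rng_seed = 13L)
  g1 <- generate_phantom(base)
  g2 <- generate_phantom(solidified)
  v1 <- classify_nodule(g1$volume, g1$nodule_mask, m)$signature$viro_fraction
  v2 <- classify_nodule(g2$volume, g2$nodule_mask, m)$signature$viro_fraction
  expect_gte(v2, v1)
})
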