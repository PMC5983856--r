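test_that("region growing recovers a toy in-plane blob exactly", {
  # 7x7 single-slice grid with a central 3x3 blob of soft tissue
  vals <- array(-850, c(1, 7, 7))
  vals[1, 3:5, 3:5] <- 40
  vol <- ct_volume(vals, spacing = c(1, 1, 1))
  m <- region_grow(vol, c(1, 4, 4))
  expect_equal(sum(m$values), 9L)
  expect_true(all(m$values[1, 3:5, 3:5]))
  # exhaustive flood-fill oracle agrees
  oracle <- oracle_flood_fill(vals >= -750 & vals <= 200, c(1, 4, 4), 26L)
  expect_identical(m$values, oracle)
})

test_that("a uniformly in-threshold volume saturates the VOI box", {
  vol <- ct_volume(array(0, c(20, 20, 20)), spacing = c(1, 1, 1))
  m <- region_grow(vol, c(10, 10, 10),
                   segmentation_params(voi_half_extent = 4))
  idx <- which(m$values, arr.ind = TRUE)
  expect_equal(sum(m$values), 9L^3)
  expect_true(all(idx >= 6 & idx <= 14))
})

test_that("out-of-threshold or out-of-grid seeds are rejected", {
  gt <- generate_phantom(small_spec(noise_sd = 0))
  expect_error(region_grow(gt$volume, c(2, 2, 2)), "seed rejected")
  expect_error(region_grow(gt$volume, c(0, 2, 2)), "bounds")
  expect_error(segmentation_params(hu_low = 10, hu_high = 0), "hu_low")
})

test_that("grown masks are connected and contain the seed", {
  set.seed(31)
  for (conn in c(6L, 26L)) {
    vals <- array(sample(c(-850, 40), 11^3, replace = TRUE, prob = c(.6, .4)),
                  c(11, 11, 11))
    vals[6, 6, 6] <- 40
    vol <- ct_volume(vals, spacing = c(1, 1, 1))
    m <- region_grow(vol, c(6, 6, 6),
                     segmentation_params(connectivity = conn))
    expect_true(m$values[6, 6, 6])
    oracle <- oracle_flood_fill(vals >= -750 & vals <= 200, c(6, 6, 6), conn)
    expect_identical(m$values, oracle)
  }
})

test_that("region growing segments a noiseless solid phantom exactly", {
  gt <- generate_phantom(small_spec(nodule_radius = 3.5,
                                    solid_core_radius = 3.5, noise_sd = 0))
  m <- region_grow(gt$volume, gt$spec$nodule_center)
  expect_equal(as.numeric(dsc(m, gt$nodule_mask)), 1.0)
})

test_that("eraser and exclusion-plane edits remove exactly the hand-counted voxels", {
  # ten voxels along the col axis at 1 mm pitch, centres x = 0..9
  vals <- array(TRUE, c(1, 1, 10))
  m <- voxel_mask(vals, spacing = c(1, 1, 1))
  expect_identical(apply_edits(m, list())$values, m$values)

  erased <- apply_edits(m, list(eraser_sphere(c(0, 0, 1.5), 1.6)))
  expect_equal(sum(erased$values), 6L)   # x = 0,1,2,3 fall inside
  expect_identical(which(erased$values), 5:10)

  far <- apply_edits(m, list(eraser_sphere(c(50, 0, 0), 2)))
  expect_identical(far$values, m$values)

  # strict half-space: the voxel on the plane (x = 5) survives
  cut <- apply_edits(m, list(exclusion_plane(c(0, 0, 5), c(0, 0, 1))))
  expect_identical(which(cut$values), 1:6)

  expect_error(apply_edits(m, list(eraser_sphere(c(0, 0, 4.5), 50))),
               "emptied")
  expect_error(eraser_sphere(c(0, 0, 0), -1), "radius")
  expect_error(exclusion_plane(c(0, 0, 0), c(0, 0, 0)), "normal")
})

test_that("edits only shrink the mask and a zero-radius eraser removes at most one voxel", {
  gt <- generate_phantom(small_spec(noise_sd = 0, solid_core_radius = 3.5))
  m <- region_grow(gt$volume, gt$spec$nodule_center)
  ctr_mm <- (gt$spec$nodule_center - 1) * gt$volume$spacing
  e1 <- apply_edits(m, list(eraser_sphere(ctr_mm, 1.2)))
  expect_true(all(m$values[e1$values]))
  expect_lt(sum(e1$values), sum(m$values))

  e0 <- apply_edits(m, list(eraser_sphere(ctr_mm, 0)))
  expect_equal(sum(m$values) - sum(e0$values), 1L)
})

test_that("sessions replay to the stored result and detect tampering", {
  gt <- generate_phantom(small_spec(noise_sd = 0, solid_core_radius = 3.5))
  ctr_mm <- (gt$spec$nodule_center - 1) * gt$volume$spacing
  edits <- list(eraser_sphere(ctr_mm + c(0, 0, 3), 1),
                exclusion_plane(ctr_mm + c(0, 3, 0), c(0, 1, 0)))
  ses <- segment_nodule(gt$volume, gt$spec$nodule_center, edits = edits)
  expect_identical(replay_session(gt$volume, ses)$values, ses$result$values)
  expect_identical(replay_session(gt$volume, ses)$values,
                   replay_session(gt$volume, ses)$values)

  tampered <- ses
  tampered$edits[[1]]$radius <- 2
  expect_error(replay_session(gt$volume, tampered), "reproducibility error")

  f <- withr::local_tempfile(fileext = ".json")
  write_session(ses, f)
  back <- read_session(f)
  expect_identical(back$result$values, ses$result$values)
  expect_identical(replay_session(gt$volume, back)$values, ses$result$values)
})
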