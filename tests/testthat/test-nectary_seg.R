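test_that("volume of interest selection preserves data and coordinates", {
  arr <- array(seq_len(8 * 5 * 5) %% 50, dim = c(8, 5, 5))
  g <- voxel_grid(arr, 5)
  expect_identical(select_voi(g, 1, 8)$data, g$data)
  one <- select_voi(g, 4, 4)
  expect_identical(dim(one$data), c(1L, 5L, 5L))
  expect_identical(one$z_offset, 3L)
  expect_error(select_voi(g, 5, 4), "z_first")
})

test_that("gland volume is unchanged when measured inside a VOI", {
  spec <- flower_phantom_spec("male", seed = 6)
  ph <- make_flower_phantom(spec)
  zr <- ph$truth$nectary_z
  lb <- inner_box(spec, ph$truth)
  full <- segment_nectary(ph$grid, zr[1], dim(ph$grid$data)[1],
                          lateral_box = lb)
  tight <- segment_nectary(ph$grid, zr[1], zr[2], lateral_box = lb)
  expect_equal(full$volume_mm3, tight$volume_mm3)
})

test_that("thresholding separates tissue from air as specified", {
  ph <- make_flower_phantom(flower_phantom_spec("male", air_intensity = 1000,
                                                tissue_intensity = 30000))
  tis <- threshold_tissue(ph$grid, "otsu")
  expect_identical(tis$data, ph$truth$tissue_mask$data)
  expect_true(tis$threshold > 1000 && tis$threshold <= 30000)
  hi <- threshold_tissue(ph$grid, "fixed", max(ph$grid$data) + 1)
  expect_false(any(hi$data))
  flat <- voxel_grid(array(7L, c(3, 3, 3)), 5)
  expect_error(threshold_tissue(flat, "otsu"), "fixed")
  # noise at 5% of the tissue/air contrast barely degrades the mask
  noisy <- make_flower_phantom(flower_phantom_spec("male", noise_sd = 1250,
                                                   seed = 12))
  tn <- threshold_tissue(noisy$grid, "otsu")
  expect_gte(dice(tn$data, noisy$truth$tissue_mask$data), 0.98)
})

test_that("height projection reports the topmost tissue voxel per column", {
  m <- array(FALSE, c(10, 4, 4))
  m[3:7, 2, 3] <- TRUE
  hm <- height_zproject(binary_mask(m, 5, "tissue"))
  expect_identical(hm$data[2, 3], 7L)
  expect_identical(sum(!is.na(hm$data)), 1L)
  empty <- height_zproject(binary_mask(array(FALSE, c(3, 3, 3)), 5, "tissue"))
  expect_true(all(is.na(empty$data)))
  # dome apex height equals base + dome radius, in original coordinates
  spec <- flower_phantom_spec("male", dome_radius_vox = 20)
  ph <- make_flower_phantom(spec)
  zr <- ph$truth$nectary_z
  voi <- select_voi(ph$grid, zr[1], zr[2])
  hv <- height_zproject(threshold_tissue(voi, "otsu"))
  cc <- ph$truth$center_yx
  expect_equal(as.numeric(hv$data[cc[1], cc[2]]),
               spec$base_height_vox + spec$dome_radius_vox)
})

test_that("watershed compartments match a brute-force flooding oracle", {
  two <- matrix(NA_integer_, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    h <- max(10 - sqrt((i - 6)^2 + (j - 10)^2),
             10 - sqrt((i - 15)^2 + (j - 10)^2))
    if (h > 2) two[i, j] <- as.integer(round(h))
  }
  lab <- watershed_compartments(new_height_map(two), h_min = 2)
  expect_equal(max(lab$data), 2)
  oracle <- ws_flood_oracle(two, list(c(6, 10), c(15, 10)))
  expect_equal(max(oracle), 2)
  # compartments agree up to the ridge line: best-matched Dice >= 0.9
  for (k in 1:2) {
    dices <- sapply(1:2, function(j)
      dice(array(lab$data == k, c(1, 20, 20)),
           array(oracle == j, c(1, 20, 20))))
    expect_gte(max(dices), 0.9)
  }
  # the boundary runs along the valley between the domes (rows 10-11)
  ridge_rows <- unique(which(lab$data == 0 & !is.na(two),
                             arr.ind = TRUE)[, 1])
  expect_true(all(ridge_rows %in% 9:12))
  # single dome and flat plateau each give one compartment
  one <- matrix(NA_integer_, 15, 15)
  for (i in 1:15) for (j in 1:15)
    if (8 - sqrt((i - 8)^2 + (j - 8)^2) > 0)
      one[i, j] <- as.integer(round(8 - sqrt((i - 8)^2 + (j - 8)^2)))
  expect_equal(max(watershed_compartments(new_height_map(one), 2)$data), 1)
  flat <- new_height_map(matrix(5L, 9, 9))
  lab_flat <- watershed_compartments(flat, 2)
  expect_true(all(lab_flat$data == 1))
  allna <- new_height_map(matrix(NA_integer_, 5, 5))
  expect_true(all(watershed_compartments(allna, 2)$data == 0))
})

test_that("compartment selection follows the stated strategies", {
  hm <- matrix(NA_integer_, 25, 25)
  for (i in 1:25) for (j in 1:25) {
    h <- max(9 - sqrt((i - 13)^2 + (j - 13)^2),   # central dome
             5 - sqrt((i - 5)^2 + (j - 20)^2))    # off-centre lobe
    if (h > 1) hm[i, j] <- as.integer(round(h))
  }
  h <- new_height_map(hm)
  lab <- watershed_compartments(h, 2)
  expect_equal(max(lab$data), 2)
  ctr <- select_nectary_compartment(lab, h, "centermost")
  ij <- which(ctr$footprint, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(ij) - 13)), 1)
  big <- select_nectary_compartment(lab, h, "largest")
  expect_identical(big$id, ctr$id)       # central dome is also the largest
  man <- select_nectary_compartment(lab, h, "manual", ids = ctr$id)
  expect_identical(man$footprint, ctr$footprint)
  expect_error(select_nectary_compartment(lab, h, "manual", ids = 99L),
               "absent")
  # contour pixels belong to the footprint and touch its outside
  expect_true(all(ctr$footprint[ctr$contour]))
  empty <- structure(list(data = matrix(0L, 4, 4), spacing_um = 5),
                     class = "label_map")
  expect_error(select_nectary_compartment(empty, h), "empty")
})

test_that("harmonic lower-surface interpolation is exact for flat and planar bases", {
  # gland slab resting on z = 4, footprint 9x9
  m <- array(FALSE, c(10, 11, 11))
  m[4:6, 2:10, 2:10] <- TRUE
  tis <- binary_mask(m, 5, "tissue")
  hm <- height_zproject(tis)
  foot <- !is.na(hm$data)
  contour <- foot & !(rbind(FALSE, foot[-11, ]) & rbind(foot[-1, ], FALSE) &
                        cbind(FALSE, foot[, -11]) & cbind(foot[, -1], FALSE))
  low <- interpolate_lower_surface(contour, tis, hm, foot)
  expect_true(all(low$data[foot] == 4))
  # planar ramp boundary reproduces the plane exactly
  ramp <- array(FALSE, c(30, 13, 13))
  for (y in 2:12) for (x in 2:12) {
    z0 <- y + x  # plane z = y + x
    ramp[z0:(z0 + 3), y, x] <- TRUE
  }
  tr <- binary_mask(ramp, 5, "tissue")
  hr <- height_zproject(tr)
  fr <- !is.na(hr$data)
  cr <- fr & !(rbind(FALSE, fr[-13, ]) & rbind(fr[-1, ], FALSE) &
                 cbind(FALSE, fr[, -13]) & cbind(fr[, -1], FALSE))
  lr <- interpolate_lower_surface(cr, tr, hr, fr)
  for (y in 2:12) for (x in 2:12)
    expect_equal(lr$data[y, x], y + x)
})

test_that("interpolated base of a thick hemispherical shell is close to truth", {
  a <- 14; inner <- 6; b <- 2
  nzd <- b + a + 3; nl <- 2 * a + 7; cc <- a + 4
  m <- array(FALSE, c(nzd, nl, nl))
  r2 <- outer((seq_len(nl) - cc)^2, (seq_len(nl) - cc)^2, "+")
  for (z in (b + 1):(b + a))
    m[z, , ] <- (z - b)^2 + r2 <= a^2 & (z - b)^2 + r2 > inner^2
  tis <- binary_mask(m, 5, "tissue")
  hm <- height_zproject(tis)
  foot <- !is.na(hm$data)
  d2 <- dim(foot)
  cr <- foot & !(rbind(FALSE, foot[-d2[1], ]) & rbind(foot[-1, ], FALSE) &
                   cbind(FALSE, foot[, -d2[2]]) & cbind(foot[, -1], FALSE))
  low <- interpolate_lower_surface(cr, tis, hm, foot)
  # analytic base: z = b + sqrt(inner^2 - r^2) inside the void, else b + 1
  truth <- b + ifelse(r2 < inner^2, sqrt(pmax(inner^2 - r2, 0)), 1)
  mae <- mean(abs(low$data[foot] - truth[foot]))
  expect_lte(mae, 2)
})

test_that("nectary mask construction fills between the two surfaces", {
  foot <- matrix(FALSE, 5, 5); foot[2:4, 2:4] <- TRUE
  up <- new_height_map(ifelse(foot, 3L, NA_integer_))
  lo <- new_height_map(ifelse(foot, 3L, NA_integer_))
  tis <- binary_mask(array(FALSE, c(6, 5, 5)), 5, "tissue")
  slab <- build_nectary_mask(up, lo, foot, tis)
  expect_identical(sum(slab$data), 9L)
  expect_true(all(which(slab$data, arr.ind = TRUE)[, 1] == 3))
  none <- build_nectary_mask(up, lo, matrix(FALSE, 5, 5), tis)
  expect_false(any(none$data))
  bad_lo <- new_height_map(ifelse(foot, 4L, NA_integer_))
  expect_error(build_nectary_mask(up, bad_lo, foot, tis), "exceeds")
})

test_that("voxel-count volume follows the spacing-cubed formula", {
  cube <- make_calibration_solid("cube", 10, spacing_um = 5)
  expect_equal(mask_volume(cube$mask), 1.25e-4)
  expect_equal(mask_volume(binary_mask(array(FALSE, c(3, 3, 3)), 5, "air")), 0)
  sph <- make_calibration_solid("sphere", 20, spacing_um = 5)
  expect_lt(abs(mask_volume(sph$mask) - 4 / 3 * pi * 0.1^3) /
              (4 / 3 * pi * 0.1^3), 0.02)
  # additivity over disjoint masks
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  bb <- array(FALSE, c(4, 4, 4)); bb[4, 1, ] <- TRUE
  expect_equal(mask_volume(a | bb, 5),
               mask_volume(a, 5) + mask_volume(bb, 5))
})

test_that("surface estimators match brute-force face enumeration", {
  cube <- make_calibration_solid("cube", 10, spacing_um = 5)
  expect_equal(as.numeric(mask_surface_area(cube$mask)),
               600 * 25 * 1e-6)  # 6 n^2 faces
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(as.numeric(mask_surface_area(binary_mask(one, 5, "nectary"))),
               6 * 25 * 1e-6)
  # dome phantom: exact agreement with an independent O(N) neighbour scan
  spec <- flower_phantom_spec("male", dome_radius_vox = 8,
                              corolla_outer_radius_vox = 16,
                              corolla_depth_vox = 14, margin_vox = 2)
  ph <- make_flower_phantom(spec)
  nect <- ph$truth$nectary_mask
  tis <- ph$truth$tissue_mask
  got <- as.numeric(mask_surface_area(nect, tis))
  expect_equal(got, brute_face_count(nect$data, !tis$data) * 25 * 1e-6)
  # surface_voxels counts boundary voxels, never more than faces
  sv <- as.numeric(mask_surface_area(nect, tis, "surface_voxels"))
  expect_lte(sv, got)
  expect_gt(sv, 0)
})

test_that("full pipeline recovers the phantom gland and is deterministic", {
  spec <- flower_phantom_spec("male", seed = 7)
  ph <- make_flower_phantom(spec)
  run <- run_pipeline(ph, spec)
  expect_gte(dice(run$model$mask, run$gt), 0.95)
  expect_lt(abs(run$model$volume_mm3 / ph$truth$nectary_volume_mm3 - 1), 0.02)
  expect_equal(run$model$surface_mm2, ph$truth$nectary_surface_mm2,
               tolerance = 0.05)
  again <- run_pipeline(ph, spec)
  expect_identical(run$model$mask$data, again$model$mask$data)
  expect_identical(run$model$volume_mm3, again$model$volume_mm3)
  # female anatomy via the largest-footprint strategy
  fspec <- flower_phantom_spec("female", seed = 8)
  fph <- make_flower_phantom(fspec)
  frun <- run_pipeline(fph, fspec, strategy = "largest")
  expect_gte(dice(frun$model$mask, frun$gt), 0.95)
  expect_lt(abs(frun$model$volume_mm3 / fph$truth$nectary_volume_mm3 - 1),
            0.02)
})

test_that("equal cross-sections can hide a 2.7-fold volume difference", {
  pair <- fold_change_pair(2.7)
  m <- run_pipeline(pair$male, pair$male_spec)
  f <- run_pipeline(pair$female, pair$female_spec, strategy = "largest")
  cs_m <- as.numeric(cross_section_area(m$model$mask))
  cs_f <- as.numeric(cross_section_area(f$model$mask))
  expect_lt(abs(cs_f / cs_m - 1), 0.10)      # 2D proxy: no difference
  ratio <- f$model$volume_mm3 / m$model$volume_mm3
  expect_lt(abs(ratio / 2.7 - 1), 0.05)      # 3D volume: 2.7-fold
})
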