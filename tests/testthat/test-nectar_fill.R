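test_that("voxel volume follows the cubic spacing formula", {
  expect_equal(voxel_volume_ul(5), 1.25e-7)
  expect_equal(voxel_volume_ul(1), 1e-9)
  expect_equal(voxel_volume_ul(10), 1e-6)
  expect_error(voxel_volume_ul(0), "positive")
})

test_that("air mask is the exact complement of tissue on clean contrast", {
  ph <- make_flower_phantom(flower_phantom_spec("male", seed = 3))
  air <- air_mask(ph$grid)
  tis <- threshold_tissue(ph$grid, "otsu")
  expect_identical(air$data, !tis$data)
  expect_false(any(air_mask(ph$grid, threshold = 0)$data))
  noisy <- make_flower_phantom(flower_phantom_spec("male", noise_sd = 1250,
                                                   seed = 13))
  expect_gte(dice(air_mask(noisy$grid)$data, !noisy$truth$tissue_mask$data),
             0.98)
})

# straight 1000-voxel air column inside tissue
column_fixture <- function() {
  arr <- array(30000L, dim = c(1000, 3, 3))
  arr[, 2, 2] <- 1000L
  air_mask(voxel_grid(arr, 5), threshold = 15000)
}

test_that("base-up filling accumulates exactly the required voxels", {
  air <- column_fixture()
  fr <- fill_to_volume(air, 6.25e-5)          # 500 voxels at 5 um
  expect_identical(fr$voxels_used, 500L)
  expect_identical(fr$top_z, 500L)
  expect_true(all(which(fr$nectar_mask$data, arr.ind = TRUE)[, 1] <= 500))
  expect_equal(fr$achieved_ul, 6.25e-5)
  expect_false(fr$truncated)
  # independent oracle: accumulate (z,y,x)-sorted voxels until the target
  idx <- which(air$data, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  k <- 0L
  while (k * voxel_volume_ul(5) < 6.25e-5 * (1 - 1e-12)) k <- k + 1L
  oracle <- idx[ord[seq_len(k)], , drop = FALSE]
  m2 <- array(FALSE, dim(air$data)); m2[oracle] <- TRUE
  expect_identical(fr$nectar_mask$data, m2)
})

test_that("degenerate targets: zero, overfull, partial voxel", {
  air <- column_fixture()
  z <- fill_to_volume(air, 0)
  expect_identical(z$voxels_used, 0L)
  expect_equal(z$achieved_ul, 0)
  over <- fill_to_volume(air, 1)              # far more than available
  expect_true(over$truncated)
  expect_identical(over$voxels_used, 1000L)
  frac <- fill_to_volume(air, 2.6 * voxel_volume_ul(5))
  expect_identical(frac$voxels_used, 3L)      # never under-filled
  expect_error(fill_to_volume(air, -1), ">= 0")
})

test_that("volume conservation and nesting hold across targets", {
  ph <- make_flower_phantom(flower_phantom_spec("male", seed = 2))
  cc <- ph$truth$center_yx
  g <- crop(ph$grid, crop_box(c(1, dim(ph$grid$data)[1]),
                              cc[1] + c(-34, 34), cc[2] + c(-34, 34)))
  air <- air_mask(g)
  vvox <- voxel_volume_ul(5)
  targets <- seq(1e-4, 2e-3, length.out = 10)
  prev <- NULL
  for (t in targets) {
    fr <- fill_to_volume(air, t, base_seed_z = 8)
    if (!fr$truncated) {
      expect_gte(fr$achieved_ul - t, -1e-15)
      expect_lt(fr$achieved_ul - t, vvox)
    }
    if (!is.null(prev)) expect_true(all(fr$nectar_mask$data[prev]))
    prev <- fr$nectar_mask$data
  }
  # idempotence: refilling to an achieved volume reproduces the mask
  fr <- fill_to_volume(air, 7.7e-4, base_seed_z = 8)
  again <- fill_to_volume(air, fr$achieved_ul, base_seed_z = 8)
  expect_identical(again$nectar_mask$data, fr$nectar_mask$data)
  expect_identical(again$voxels_used, fr$voxels_used)
})

test_that("nectar forms a level surface in a convex chamber", {
  ph <- make_flower_phantom(flower_phantom_spec("female", seed = 4))
  cc <- ph$truth$center_yx
  g <- crop(ph$grid, crop_box(c(1, dim(ph$grid$data)[1]),
                              cc[1] + c(-34, 34), cc[2] + c(-34, 34)))
  fr <- fill_to_volume(air_mask(g), 1.5e-3, base_seed_z = 8)
  tops <- apply(fr$nectar_mask$data, c(2, 3),
                function(v) if (any(v)) max(which(v)) else NA)
  expect_lte(diff(range(tops, na.rm = TRUE)), 1)
})

test_that("base-component restriction excludes sealed pockets", {
  arr <- array(30000L, dim = c(30, 5, 5))
  arr[1:10, 2:4, 2:4] <- 1000L       # basal chamber
  arr[20:25, 2:4, 2:4] <- 1000L      # sealed pocket above
  air <- air_mask(voxel_grid(arr, 5), threshold = 15000)
  fr <- fill_to_volume(air, 1, base_seed_z = 1)
  expect_true(fr$truncated)
  expect_identical(fr$voxels_used, 10L * 9L)  # chamber only
  unres <- fill_to_volume(air, 1, restrict_to_base_component = FALSE)
  expect_identical(unres$voxels_used, 10L * 9L + 6L * 9L)
})

test_that("overlay export writes one tinted composite per slice", {
  ph <- make_calibration_solid("cube", 6, spacing_um = 5)
  air <- air_mask(ph$grid, 15000)
  fr <- fill_to_volume(air, 40 * voxel_volume_ul(5),
                       restrict_to_base_component = FALSE)
  out <- file.path(withr::local_tempdir(), "ov")
  overlay_export(ph$grid, fr$nectar_mask, out)
  pngs <- list.files(out, pattern = "^overlay_.*png$")
  expect_identical(length(pngs), dim(ph$grid$data)[1])
  # tinted pixels per slice equal mask voxels per slice
  z <- 3
  img <- png::readPNG(file.path(out, sprintf("overlay_%04d.png", z)))
  grey <- ph$grid$data[z, , ] / 65535
  tinted <- sum(abs(img[, , 1] - grey) > 0.01 | abs(img[, , 3] - grey) > 0.01)
  expect_identical(tinted, sum(fr$nectar_mask$data[z, , ]))
  # empty mask leaves the greyscale untouched
  empty <- binary_mask(array(FALSE, dim(ph$grid$data)), 5, "nectar")
  out2 <- file.path(withr::local_tempdir(), "ov2")
  overlay_export(ph$grid, empty, out2)
  img2 <- png::readPNG(file.path(out2, "overlay_0003.png"))
  expect_equal(img2[, , 2], grey, tolerance = 1e-2)
})
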