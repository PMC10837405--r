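test_that("sphere rasterization agrees exactly with the distance oracle", {
  # 1 cm sphere on a 1 mm grid: continuum volume 523.6 mm^3
  grid <- toy_volume(array(0, dim = c(24, 24, 24)), origin = c(-11, -11, -11))
  sph <- sphere_roi(c(0, 0, 0), diameter = 10)
  mask <- rasterize_sphere(sph, grid)
  oracle <- brute_sphere_mask(c(0, 0, 0), 5, dim(grid$data), grid$affine)
  expect_identical(mask$data, oracle)
  expect_gte(mask$np, 515)
  expect_lte(mask$np, 530)

  # off-center, anisotropic grid
  grid2 <- toy_volume(array(0, dim = c(20, 16, 12)), spacing = c(1.5, 2, 2.5),
                      origin = c(-14, -15, -14))
  sph2 <- sphere_roi(c(2.2, -1.3, 0.7), diameter = 13)
  mask2 <- rasterize_sphere(sph2, grid2)
  expect_identical(mask2$data,
                   brute_sphere_mask(sph2$center, 6.5, dim(grid2$data),
                                     grid2$affine))
})

test_that("doubling grid resolution multiplies sphere voxel count by ~8", {
  coarse <- toy_volume(array(0, dim = c(16, 16, 16)), spacing = c(2, 2, 2),
                       origin = c(-15, -15, -15))
  fine <- toy_volume(array(0, dim = c(32, 32, 32)), origin = c(-15.5, -15.5, -15.5))
  sph <- sphere_roi(c(0, 0, 0), diameter = 20)
  np_c <- rasterize_sphere(sph, coarse)$np
  np_f <- rasterize_sphere(sph, fine)$np
  expect_lt(abs(np_f / np_c - 8), 8 * 0.05)
})

test_that("a sphere missing the grid raises an empty-ROI error", {
  grid <- toy_volume(array(0, dim = c(8, 8, 8)))
  expect_error(rasterize_sphere(sphere_roi(c(100, 100, 100), 10), grid),
               class = "suvhist_empty_roi_error")
})

test_that("reference spheres mirror the lesion centroid across the midline", {
  grid <- toy_volume(array(0, dim = c(80, 40, 40)), spacing = c(2, 2, 2),
                     origin = c(-79, -39, -39))
  lesion <- rasterize_sphere(sphere_roi(c(30, 10, 5), diameter = 16), grid,
                             label = "lesion")
  spheres <- mirror_spheres(lesion, grid, x_mid = 0)
  expect_length(spheres, 3)
  # symmetric voxel sampling around the center keeps the centroid on it
  expect_equal(spheres[[1]]$center, c(-30, 10, 5), tolerance = 1e-6)
  z <- sort(vapply(spheres, function(s) s$center[3], numeric(1)))
  expect_equal(diff(z), c(12, 12), tolerance = 1e-6)
  xy <- unique(t(vapply(spheres, function(s) s$center[1:2], numeric(2))))
  expect_equal(nrow(xy), 1L)

  expect_error(mirror_spheres(binary_mask(array(FALSE, dim = c(8, 8, 8)),
                                          diag(4)), grid),
               class = "suvhist_empty_roi_error")
})

test_that("midline lesions warn; off-grid reflections error", {
  grid <- toy_volume(array(0, dim = c(40, 40, 40)), spacing = c(2, 2, 2),
                     origin = c(-39, -39, -39))
  central <- rasterize_sphere(sphere_roi(c(0, 0, 0), 16), grid)
  expect_warning(mirror_spheres(central, grid, x_mid = 0), "midsagittal")

  lateral <- rasterize_sphere(sphere_roi(c(30, 0, 0), 16), grid)
  expect_error(mirror_spheres(lateral, grid, x_mid = 40),
               class = "suvhist_placement_error")
})

test_that("resampling is the identity on identical grids", {
  grid <- ramp_volume(c(6, 6, 6))
  mask <- rasterize_sphere(sphere_roi(c(2.5, 2.5, 2.5), 4), grid)
  out <- resample_mask(mask, grid)
  expect_identical(out$data, mask$data)
})

test_that("cross-grid resampling only disagrees at the sphere surface", {
  fine <- toy_volume(array(0, dim = c(32, 32, 32)), origin = c(-15.5, -15.5, -15.5))
  coarse <- toy_volume(array(0, dim = c(16, 16, 16)), spacing = c(2, 2, 2),
                       origin = c(-15, -15, -15))
  sph <- sphere_roi(c(0.3, -0.6, 0.2), diameter = 18)
  mask_fine <- rasterize_sphere(sph, fine)
  res <- resample_mask(mask_fine, coarse)

  # oracle: direct world-coordinate membership on the coarse grid
  direct <- rasterize_sphere(sph, coarse)
  differ <- which(res$data != direct$data, arr.ind = TRUE)
  if (nrow(differ) > 0) {
    w <- cbind(differ - 1, 1) %*% t(coarse$affine)
    dist_to_surface <- abs(sqrt(rowSums((w[, 1:3, drop = FALSE] -
      matrix(sph$center, nrow(w), 3, byrow = TRUE))^2)) - sph$diameter / 2)
    # within one voxel layer: half-diagonals of source + target voxels
    expect_true(all(dist_to_surface <= sqrt(3) / 2 * (1 + 2)))
  }
  vol_fine <- mask_fine$np * fine$voxel_volume
  vol_coarse <- res$np * coarse$voxel_volume
  expect_lt(abs(vol_coarse - vol_fine) / vol_fine, 0.25)
})

test_that("resampling onto a disjoint grid raises an empty-ROI error", {
  grid <- toy_volume(array(0, dim = c(8, 8, 8)))
  far <- toy_volume(array(0, dim = c(8, 8, 8)), origin = c(500, 500, 500))
  mask <- rasterize_sphere(sphere_roi(c(3.5, 3.5, 3.5), 5), grid)
  expect_error(resample_mask(mask, far), class = "suvhist_empty_roi_error")
})

test_that("voxel extraction honors mask, order and grid checks", {
  vol <- toy_volume(array(1, dim = c(2, 2, 2)))
  all_true <- binary_mask(array(TRUE, dim = c(2, 2, 2)), vol$affine)
  s <- extract_voxels(vol, all_true)
  expect_identical(s$np, 8L)
  expect_true(all(s$values == 1))
  expect_identical(s$voxel_volume, 0.001)

  ramp <- ramp_volume(c(3, 3, 3))
  one <- array(FALSE, dim = c(3, 3, 3)); one[2, 3, 1] <- TRUE
  s1 <- extract_voxels(ramp, binary_mask(one, ramp$affine))
  expect_identical(s1$values, 8)  # linear index 8 of the ramp

  top3 <- array(FALSE, dim = c(3, 3, 3)); top3[c(25, 26, 27)] <- TRUE
  s3 <- extract_voxels(ramp, binary_mask(top3, ramp$affine))
  expect_identical(s3$values, c(25, 26, 27))  # ascending linear index order

  empty <- binary_mask(array(FALSE, dim = c(3, 3, 3)), ramp$affine)
  expect_error(extract_voxels(ramp, empty), class = "suvhist_empty_roi_error")

  shifted <- binary_mask(one, toy_volume(array(0, dim = c(3, 3, 3)),
                                         origin = c(9, 9, 9))$affine)
  expect_error(extract_voxels(ramp, shifted), class = "suvhist_grid_error")
})

test_that("extraction over a union of disjoint masks is the multiset union", {
  set.seed(41)
  vol <- toy_volume(array(runif(216), dim = c(6, 6, 6)))
  m1 <- array(FALSE, dim = c(6, 6, 6)); m1[1:40] <- TRUE
  m2 <- array(FALSE, dim = c(6, 6, 6)); m2[101:150] <- TRUE
  b1 <- binary_mask(m1, vol$affine); b2 <- binary_mask(m2, vol$affine)
  u <- mask_union(list(b1, b2))
  expect_identical(u$np, b1$np + b2$np)
  su <- extract_voxels(vol, u)
  expect_identical(sort(su$values),
                   sort(c(extract_voxels(vol, b1)$values,
                          extract_voxels(vol, b2)$values)))
})
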