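# Smaller-than-default grids keep these structural tests fast; statistical
# checks at full size live with the phantom-recovery and cohort tests.
small_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 36), voxel_size = c(2, 2, 2),
               lesion = list(center = c(20, 0, 0), radius = 10), ...)
}

test_that("intensity laws know their population skewness in closed form", {
  expect_identical(population_skewness(law_gaussian(1.1, 0.4)), 0)
  expect_equal(population_skewness(law_gamma(4.57, 0.2)), 2 / sqrt(4.57),
               tolerance = 1e-12)
  expect_equal(population_skewness(law_gamma(4, 0.3, shift = 2)), 1)

  # mixture skewness against a large Monte Carlo draw
  mix <- law_mixture(list(law_gaussian(1.2, 0.3), law_gamma(4.57, 0.5 / 4.57)),
                     weights = c(0.6, 0.4))
  big <- withr::with_seed(71, draw_law_for_test(mix, 4e5))
  expect_equal(population_skewness(mix), suv_skewness(big), tolerance = 0.05)
})

test_that("law parameters are validated", {
  expect_error(law_gaussian(1, 0), class = "suvhist_validation_error")
  expect_error(law_gamma(-1, 1), class = "suvhist_validation_error")
  expect_error(law_mixture(list(law_gaussian(1, 1), law_gaussian(2, 1)),
                           c(0.7, 0.7)), class = "suvhist_validation_error")
})

test_that("phantoms are bit-reproducible from their spec", {
  s1 <- make_phantom(small_spec(seed = 5))
  s2 <- make_phantom(small_spec(seed = 5))
  expect_identical(s1$suv_volume$data, s2$suv_volume$data)
  expect_identical(s1$lesion_mask$data, s2$lesion_mask$data)
  s3 <- make_phantom(small_spec(seed = 6))
  expect_false(identical(s1$suv_volume$data, s3$suv_volume$data))
})

test_that("gaussian-law phantom lesions have near-zero sample skewness", {
  s <- make_phantom(phantom_spec(law = law_gaussian(1.1, 0.4), seed = 1))
  series <- extract_voxels(s$suv_volume, s$lesion_mask)
  expect_gt(series$np, 1000)
  expect_lt(abs(suv_skewness(series)), 0.15)  # ~sqrt(6/Np) sampling bound
  expect_identical(s$truth$population_skewness, 0)
})

test_that("gamma-law phantoms carry the non-neoplastic calibration truth", {
  s <- make_phantom(small_spec(law = law_gamma(4.57, 0.9 / 4.57),
                               group = "non-neoplastic", seed = 2))
  expect_equal(s$truth$population_skewness, 0.9356, tolerance = 1e-4)
  series <- extract_voxels(s$suv_volume, s$lesion_mask)
  expect_gt(suv_skewness(series), 0.5)
  expect_gt(suv_tendency(series), 0)
})

test_that("generated subjects satisfy volume invariants and round-trip", {
  s <- make_phantom(small_spec(seed = 9))
  vol <- s$suv_volume
  expect_true(all(is.finite(vol$data)) && all(vol$data >= 0))
  expect_equal(vol$voxel_volume, abs(det(vol$affine[1:3, 1:3])) / 1000)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_suv_volume(vol, f)
  back <- read_volume(f)
  expect_lt(max(abs(back$data - vol$data)), 1e-6)
  expect_identical(back$affine, vol$affine)
})

test_that("a lesion outside the grid is a placement error", {
  spec <- phantom_spec(grid_shape = c(48, 48, 36), voxel_size = c(2, 2, 2),
                       lesion = list(center = c(500, 0, 0), radius = 10),
                       seed = 1)
  expect_error(make_phantom(spec), class = "suvhist_placement_error")
})

test_that("ring + core phantoms split a dual-peaked whole-lesion histogram", {
  spec <- phantom_spec(
    lesion = list(center = c(30, 0, 0), outer_radius = 15, inner_radius = 9),
    ring_law = law_gaussian(1.2, 0.3),
    core_law = law_gamma(4.57, 0.5 / 4.57),
    seed = 12)
  s <- make_phantom(spec)
  expect_named(s$sub_masks, c("ring", "core"))
  expect_identical(s$sub_masks$ring$data | s$sub_masks$core$data,
                   s$lesion_mask$data)
  expect_identical(sum(s$sub_masks$ring$data & s$sub_masks$core$data), 0L)

  ring <- extract_voxels(s$suv_volume, s$sub_masks$ring)
  core <- extract_voxels(s$suv_volume, s$sub_masks$core)
  whole <- extract_voxels(s$suv_volume, s$lesion_mask)
  expect_lt(abs(suv_skewness(ring)), 0.15)
  expect_gt(suv_skewness(core), 0.6)
  expect_gte(count_modes(whole$values), 2)

  # collapse case: identical laws give a single mode
  spec1 <- phantom_spec(
    lesion = list(center = c(30, 0, 0), outer_radius = 15, inner_radius = 9),
    ring_law = law_gaussian(1.2, 0.3), core_law = law_gaussian(1.2, 0.3),
    seed = 12)
  s1 <- make_phantom(spec1)
  expect_identical(count_modes(extract_voxels(s1$suv_volume,
                                              s1$lesion_mask)$values), 1L)

  expect_error(phantom_spec(
    lesion = list(center = c(30, 0, 0), outer_radius = 9, inner_radius = 15),
    ring_law = law_gaussian(1, 0.3), core_law = law_gaussian(1, 0.3)),
    class = "suvhist_validation_error")
})

test_that("default cohorts have the expected size, structure and calibration", {
  co <- make_cohort(seed = 7, grid_shape = c(64, 64, 48))
  expect_length(co$subjects, 21)
  expect_identical(nrow(co$manifest), 21L)
  expect_identical(sum(co$manifest$group == "neoplastic"), 18L)
  expect_identical(sum(co$manifest$group == "non-neoplastic"), 3L)

  co2 <- make_cohort(seed = 7, grid_shape = c(64, 64, 48))
  expect_identical(co2$manifest$seed, co$manifest$seed)
  expect_identical(co2$subjects$S01$suv_volume$data,
                   co$subjects$S01$suv_volume$data)

  stats <- lapply(co$subjects, function(s) {
    v <- extract_voxels(s$suv_volume, s$lesion_mask)
    c(skew = suv_skewness(v), tend = suv_tendency(v))
  })
  skew <- vapply(stats, `[[`, numeric(1), "skew")
  tend <- vapply(stats, `[[`, numeric(1), "tend")
  neo <- co$manifest$group == "neoplastic"
  expect_gt(mean(skew[!neo]), 0.5)
  expect_lt(mean(skew[!neo]), 1.4)
  expect_lt(abs(mean(tend[neo])), 0.05)
})

test_that("written cohorts reproduce the in-memory analysis from disk", {
  dir <- withr::local_tempdir()
  co <- make_cohort(n_neoplastic = 2, n_nonneoplastic = 1, seed = 3,
                    grid_shape = c(48, 48, 36), out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(co$manifest$suv_path)))
  expect_true(all(file.exists(co$manifest$roi_path)))

  roi <- read_roi_set(co$manifest$roi_path[1])
  expect_s3_class(roi$lesion_mask, "binary_mask")
  expect_identical(roi$lesion_mask$data, co$subjects$S01$lesion_mask$data)
  expect_length(roi$reference_spheres, 3)
  expect_equal(roi$reference_spheres[[1]]$center,
               co$subjects$S01$reference_spheres[[1]]$center, tolerance = 1e-9)

  mem <- run_cohort(co)
  disk <- run_cohort(file.path(dir, "manifest.csv"))
  expect_equal(disk$features$skewness, mem$features$skewness, tolerance = 1e-5)
  expect_identical(disk$features$label, mem$features$label)
})
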