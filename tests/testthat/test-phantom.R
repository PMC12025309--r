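test_that("phantom generation is seed-deterministic and seed-sensitive", {
  pc <- phantom_config(shape = c(32, 32, 16), seed = 5)
  a <- generate_phantom(pc)
  b <- generate_phantom(pc)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  c2 <- generate_phantom(pc, seed = 6)
  expect_gt(sum(a$mask$data != c2$mask$data), 0)
})

test_that("mask volume fractions stay inside the configured range", {
  pc <- phantom_config(shape = c(32, 32, 16),
                       synovium_fraction_range = c(0.02, 0.10), seed = 1)
  fr <- vapply(generate_dataset(pc, 50), function(cs) mean(cs$mask$data), 0)
  expect_true(all(fr >= 0.02 & fr <= 0.10))
})

test_that("phantom volumes are bounded and masks binary", {
  pc <- phantom_config(shape = c(24, 24, 12), seed = 2)
  for (cs in generate_dataset(pc, 5)) {
    expect_true(min(cs$volume$data) >= 0 && max(cs$volume$data) <= 1)
    expect_true(all(cs$mask$data %in% c(0, 1)))
  }
})

test_that("synovium is hypoechoic relative to non-shadow background", {
  pc <- phantom_config(shape = c(32, 32, 16), seed = 3)
  ok <- vapply(1:40, function(i) {
    cs <- generate_phantom(pc, seed = i, diagnostics = TRUE)
    rg <- attr(cs, "regions")
    mean(cs$volume$data[cs$mask$data == 1]) <
      mean(cs$volume$data[rg$background]) * (1 + pc$contrast_gap) / 2
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("dataset generation gives unique ids and is reproducible", {
  pc <- phantom_config(shape = c(24, 24, 12), seed = 9)
  d1 <- generate_dataset(pc, 3)
  d2 <- generate_dataset(pc, 3)
  ids <- vapply(d1, `[[`, "", "id")
  expect_length(unique(ids), 3L)
  expect_identical(lapply(d1, `[[`, "volume"), lapply(d2, `[[`, "volume"))
  one <- generate_phantom(pc, seed = swindaf3d:::derive_seed(pc$seed, 1),
                          id = "phantom_0001")
  expect_identical(d1[[1]]$mask$data, one$mask$data)
  expect_error(generate_dataset(pc, 0), ">= 1")
})

test_that("infeasible fraction ranges are rejected", {
  expect_error(phantom_config(shape = c(8, 8, 8),
                              synovium_fraction_range = c(0.001, 0.002)),
               "infeasible")
  expect_error(phantom_config(synovium_fraction_range = c(0.2, 0.1)))
})

test_that("dataset export writes NIfTI pairs and a manifest", {
  dir <- withr::local_tempdir()
  pc <- phantom_config(shape = c(16, 16, 8),
                       synovium_fraction_range = c(0.02, 0.2), seed = 4)
  man <- write_dataset(generate_dataset(pc, 2), dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(man$volume), file.exists(man$mask)))
  back <- read_case(man$volume[1], man$mask[1])
  expect_true(all(back$mask$data %in% c(0, 1)))
})

test_that("augmentation with zero magnitudes and no flips is the identity", {
  pc <- phantom_config(shape = c(16, 16, 8),
                       synovium_fraction_range = c(0.02, 0.2), seed = 7)
  cs <- generate_phantom(pc)
  ac <- augmentation_config(flip_axes = integer(0), rotation_max_deg = 0,
                            brightness_delta = 0, contrast_range = c(1, 1),
                            blur_sigma_range = c(0, 0), noise_std = 0,
                            seed = 11)
  out <- augment_case(cs, ac)
  expect_equal(out$volume$data, cs$volume$data, tolerance = 1e-12)
  expect_identical(out$mask$data, cs$mask$data)
})

test_that("double flip along the same axis is an involution", {
  pc <- phantom_config(shape = c(16, 16, 8),
                       synovium_fraction_range = c(0.02, 0.2), seed = 8)
  cs <- generate_phantom(pc)
  tr <- list(flips = c(2L, 2L), angle = 0, contrast = 1, brightness = 0,
             sigma = 0, noise = 0, noise_seed = 1L)
  out <- apply_augmentation(cs, tr)
  expect_identical(out$volume$data, cs$volume$data)
  expect_identical(out$mask$data, cs$mask$data)
})

test_that("augmentation is deterministic and commutes with mask pairing", {
  pc <- phantom_config(shape = c(16, 16, 8),
                       synovium_fraction_range = c(0.02, 0.2), seed = 12)
  cs <- generate_phantom(pc)
  ac <- augmentation_config(seed = 21, rotation_prob = 1, flip_prob = 1,
                            noise_prob = 1, blur_prob = 1)
  a <- augment_case(cs, ac)
  b <- augment_case(cs, ac)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  # joint augmentation equals applying the same sampled transform per part
  tr <- sample_augmentation(ac)
  joint <- apply_augmentation(cs, tr)
  vol_only <- apply_augmentation(
    us_case("v", cs$volume, us_mask(array(0, dim(cs$volume$data)))), tr)
  mask_only <- apply_augmentation(
    us_case("m", us_volume(array(0.5, dim(cs$mask$data))), cs$mask), tr)
  expect_identical(joint$volume$data, vol_only$volume$data)
  expect_identical(joint$mask$data, mask_only$mask$data)
  expect_true(all(joint$mask$data %in% c(0, 1)))
  expect_true(min(joint$volume$data) >= 0 && max(joint$volume$data) <= 1)
})
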