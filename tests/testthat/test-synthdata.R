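# Phantom generator: determinism, mask invariants, stratified splits and
# lossless PNG round-trips.

test_that("phantoms are bit-identical under the same spec and seed", {
  spec <- phantom_spec()
  a <- generate_phantom(spec, seed = 12)
  b <- generate_phantom(spec, seed = 12)
  expect_identical(a, b)
  c <- generate_phantom(spec, seed = 13)
  expect_false(identical(a$image, c$image))
})

test_that("masks respect label, area range and the lung-field support", {
  spec <- phantom_spec(lesion_prob = 1, lesion_area = c(60, 2000),
                       image_size = 64)
  lungs <- ptxseg:::lung_fields(64)
  for (s in 1:6) {
    ph <- generate_phantom(spec, seed = s)
    expect_equal(ph$label, "PTX")
    area <- sum(ph$mask)
    expect_gte(area, 60); expect_lte(area, 2000)
    expect_true(all(lungs$either[ph$mask == 1]))   # lesion inside a lung
    expect_true(all(ph$image >= 0 & ph$image <= 1))
  }
  none <- generate_phantom(phantom_spec(lesion_prob = 0), seed = 1)
  expect_equal(none$label, "NonPTX")
  expect_equal(sum(none$mask), 0)
})

test_that("spec validation guards infeasible and sub-threshold areas", {
  expect_error(phantom_spec(image_size = 16, lesion_area = c(80, 200)),
               "infeasible")
  expect_error(phantom_spec(lesion_area = c(10, 100)), "50-pixel")
  expect_s3_class(phantom_spec(lesion_area = c(10, 100),
                               sub_threshold = TRUE), "ptx_phantom_spec")
})

test_that("label sequence follows the configured prevalence", {
  set <- generate_phantom_set(200, phantom_spec(), seed = 21)
  share <- mean(set$label == "PTX")
  expect_gt(share, 0.38); expect_lt(share, 0.62)  # ~0.504 +- sampling noise
  # reproducible label sequence
  set2 <- generate_phantom_set(10, phantom_spec(lesion_prob = 0.5),
                               seed = 5)
  set3 <- generate_phantom_set(10, phantom_spec(lesion_prob = 0.5),
                               seed = 5)
  expect_identical(set2$label, set3$label)
})

test_that("dataset writing produces exact stratified splits and a manifest", {
  out <- withr::local_tempdir()
  man <- generate_dataset(100, phantom_spec(image_size = 32,
                                            lesion_area = c(51, 120),
                                            sub_threshold = TRUE),
                          seed = 6, out_dir = out)
  expect_equal(as.integer(table(man$split)[c("train", "val", "test")]),
               c(64L, 16L, 20L))
  expect_named(man, c("image_path", "mask_path", "label", "split"))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  # class ratio in each split within one image of the global ratio
  n1 <- sum(man$label == "PTX")
  for (sp in c("train", "val", "test")) {
    sub <- man[man$split == sp, ]
    expected <- n1 * nrow(sub) / 100
    expect_lte(abs(sum(sub$label == "PTX") - expected), 1)
  }
  # masks exist exactly for lesion images
  expect_equal(man$mask_path != "", man$label == "PTX")
})

test_that("images and masks round-trip losslessly through PNG", {
  out <- withr::local_tempdir()
  spec <- phantom_spec(image_size = 32, lesion_area = c(51, 120),
                       sub_threshold = TRUE, lesion_prob = 1)
  man <- generate_dataset(3, spec, seed = 7, out_dir = out,
                          split_fractions = c(train = 1/3, val = 1/3,
                                              test = 1/3))
  dat <- load_dataset(man, base_dir = out)
  for (i in 1:3) {
    ph <- generate_phantom(spec, seed = 7 * 10000 + i)
    expect_identical(dat$mask[[i]], ph$mask)         # masks exact
    expect_lt(max(abs(dat$image[[i]] - ph$image)), 1 / 255)  # 8-bit image
  }
})

test_that("worked fixtures agree with the implementation they pin", {
  fx <- worked_fixtures()
  expect_equal(compute_weight_map(fx$single_pixel_4x4$mask, 0, "swcel"),
               fx$single_pixel_4x4$weight_map_iter0)
  expect_equal(compute_weight_map(fx$single_pixel_4x4$mask, 1, "swcel"),
               fx$single_pixel_4x4$weight_map_iter1)
  expect_equal(fx$single_pixel_4x4$weight_map_iter0[2, 2],
               fx$single_pixel_4x4$center_weight)
  expect_equal(detect_boundary(fx$block_2x2_4x4$mask),
               fx$block_2x2_4x4$boundary)
  expect_equal(hausdorff(fx$two_point_contour$P, fx$two_point_contour$G),
               fx$two_point_contour$hd)
  expect_equal(dice(fx$dice_4_7$pred, fx$dice_4_7$truth)$dsc1,
               fx$dice_4_7$dsc1)
})
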