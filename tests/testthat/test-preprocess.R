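test_that("zero-plane cropping finds the bounding box and un-crops exactly", {
  img <- array(0, c(4, 10, 10, 10))
  lab <- array(0L, c(10, 10, 10))
  img[, 3:8, 3:8, 3:8] <- 1
  lab[5, 5, 5] <- 4L
  cr <- crop_zero_planes(img, label_map(lab))
  expect_equal(dim(cr$image), c(4, 6, 6, 6))
  expect_equal(cr$crop_record$offset, c(2, 2, 2))
  expect_equal(dim(cr$label$voxels), c(6, 6, 6))

  restored <- uncrop(cr$image, cr$crop_record)
  expect_identical(restored, img)
  expect_identical(uncrop(cr$label, cr$crop_record)$voxels, lab)

  # no zero border planes -> identity
  full <- array(1, c(4, 5, 5, 5))
  cr2 <- crop_zero_planes(full)
  expect_identical(cr2$image, full)
  expect_equal(cr2$crop_record$offset, c(0, 0, 0))

  expect_error(crop_zero_planes(array(0, c(4, 3, 3, 3))), "zero")

  # cropping never removes a non-zero voxel
  cs <- fixture_case
  cr3 <- crop_zero_planes(cs$image, cs$label)
  expect_equal(sum(cr3$image != 0), sum(cs$image != 0))
})

test_that("non-zero z-scoring standardizes with the population sd and guards", {
  v <- array(0, c(1, 3, 1, 3))
  v[1, , 1, 1] <- c(2, 4, 6)
  z <- zscore_nonzero(v)
  expect_equal(sort(z[z != 0]), c(-sqrt(1.5), sqrt(1.5)), tolerance = 1e-12)
  nz <- z[1, , 1, 1]
  expect_equal(mean(nz), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((nz - mean(nz))^2)), 1, tolerance = 1e-12)
  expect_true(all(z[1, , 1, 2:3] == 0))  # background stays exactly zero

  # constant non-zero channel collapses to zero (sd = 0 guard)
  cst <- array(c(5, 5, 5, 0), c(1, 4, 1, 1))
  expect_true(all(zscore_nonzero(cst) == 0))

  # per-channel means/sds over the non-zero set on a real phantom
  z4 <- zscore_nonzero(fixture_case$image)
  for (ch in 1:4) {
    x <- z4[ch, , , ][z4[ch, , , ] != 0]
    expect_equal(mean(x), 0, tolerance = 1e-6)
    expect_equal(sqrt(mean((x - mean(x))^2)), 1, tolerance = 1e-6)
  }

  # idempotent on an already standardized volume (no exact zeros created)
  expect_equal(zscore_nonzero(z4), z4, tolerance = 1e-9)
})

test_that("normalization commutes with cropping on the non-zero set", {
  cs <- fixture_case
  cr <- crop_zero_planes(cs$image, cs$label)
  a <- zscore_nonzero(cr$image)
  b <- crop_zero_planes(zscore_nonzero(cs$image), cs$label)$image
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("patch sampling windows image and reference identically", {
  cs <- fixture_case  # 24^3 volume
  set.seed(1)
  pp <- sample_patch(cs, 16)
  expect_equal(dim(pp$image), c(4, 16, 16, 16))
  expect_equal(dim(pp$ref$channels), c(3, 16, 16, 16))
  expect_true(all(pp$ref$channels %in% c(0, 1)))

  # patch equal to volume size is the whole volume, deterministic
  pp2 <- sample_patch(cs, 24)
  expect_identical(pp2$image, cs$image)

  # smaller volumes are padded symmetrically: 24^3 into 32^3 -> 4-voxel border
  pp3 <- sample_patch(cs, 32)
  expect_equal(dim(pp3$image), c(4, 32, 32, 32))
  expect_identical(pp3$image[, 4 + seq_len(24), 4 + seq_len(24), 4 + seq_len(24)],
                   cs$image)
  expect_equal(sum(pp3$ref$channels[3, , , ]), sum(cs$label$voxels != 0))

  expect_error(sample_patch(cs, 0), "positive")
})

test_that("augmentation preserves binary nesting and per-channel voxel counts", {
  set.seed(2)
  pp <- sample_patch(fixture_case, 16)
  counts <- apply(pp$ref$channels, 1, sum)
  cfg <- augment_config()
  for (i in 1:40) {
    aug <- augment(pp, cfg)
    expect_equal(apply(aug$ref$channels, 1, sum), counts)
    expect_true(all(aug$ref$channels %in% c(0, 1)))
    et <- aug$ref$channels[1, , , ]
    tc <- aug$ref$channels[2, , , ]
    wt <- aug$ref$channels[3, , , ]
    expect_true(all(et <= tc) && all(tc <= wt))
  }
})

test_that("augmentation edge draws behave as configured", {
  set.seed(3)
  pp <- sample_patch(fixture_case, 16)

  # sigma = 0 noise leaves the image unchanged; flips/rotations off
  cfg_id <- augment_config(noise_sd = 0, noise_p = 1, rotation_p = 0, flip_p = 0)
  expect_identical(augment(pp, cfg_id)$image, pp$image)

  # flip-only augmentation is an involution: flipping again restores input
  cfg_flip <- augment_config(noise_p = 0, rotation_p = 0, flip_p = 1)
  a1 <- withr::with_seed(7, augment(pp, cfg_flip))
  a2 <- withr::with_seed(7, augment(a1, cfg_flip))  # same axis draw
  expect_identical(a2$image, pp$image)
  expect_identical(a2$ref$channels, pp$ref$channels)
  expect_false(identical(a1$image, pp$image))
})

test_that("case splitting follows the 4:1 floor rule deterministically", {
  s231 <- split_cases(sprintf("c%03d", 1:231), seed = 42)
  expect_length(s231$train_ids, 185)
  expect_length(s231$val_ids, 46)

  s100 <- split_cases(sprintf("c%03d", 1:100), seed = 42)
  expect_length(s100$val_ids, 20)

  s5 <- split_cases(letters[1:5], seed = 9)
  expect_length(s5$train_ids, 4)
  expect_length(s5$val_ids, 1)

  # n = 2..4 still hold out one case
  expect_length(split_cases(letters[1:2], 1)$val_ids, 1)
  expect_error(split_cases("a", 1), "at least 2")

  # deterministic, disjoint, exhaustive
  again <- split_cases(sprintf("c%03d", 1:231), seed = 42)
  expect_identical(s231, again)
  expect_length(intersect(s231$train_ids, s231$val_ids), 0)
  expect_setequal(c(s231$train_ids, s231$val_ids), sprintf("c%03d", 1:231))
  diff_seed <- split_cases(sprintf("c%03d", 1:231), seed = 43)
  expect_false(identical(s231$val_ids, diff_seed$val_ids))
})
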