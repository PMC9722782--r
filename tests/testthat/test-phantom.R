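cfg0 <- tiny_phantom_cfg()

test_that("case generation is deterministic and geometrically consistent", {
  site <- site_spec("A", 4)
  c1 <- generate_case(cfg0, site, seed = 11)
  c2 <- generate_case(cfg0, site, seed = 11)
  expect_identical(c1, c2)
  c3 <- generate_case(cfg0, site, seed = 12)
  expect_false(identical(c1$image, c3$image))

  # with tumor_presence_prob = 1 all three codes are present
  expect_setequal(unique(as.vector(c1$label$voxels)), c(0L, 1L, 2L, 4L))
  expect_true(validate_label_map(c1$label)$valid)

  # the tumor lies inside the brain's non-zero image support
  brain_mask <- apply(c1$image != 0, c(2, 3, 4), any)
  expect_gt(sum(brain_mask), 0)
  expect_lt(sum(brain_mask), length(brain_mask))
  expect_true(all(brain_mask[c1$label$voxels != 0L]))
})

test_that("noise-free intensities equal the intensity table entries", {
  cfg <- tiny_phantom_cfg(noise_sd = 0)
  site <- site_spec("A", 4)  # identity site effect
  cs <- generate_case(cfg, site, seed = 21)
  it <- cfg$intensity_table
  for (ch in 1:4) {
    vol <- cs$image[ch, , , ]
    expect_equal(unique(vol[cs$label$voxels == 4L]), it["ET", ch])
    expect_equal(unique(vol[cs$label$voxels == 1L]), it["NCR", ch])
    expect_equal(unique(vol[cs$label$voxels == 2L]), it["ED", ch])
  }
  # site shift/scale move the means accordingly
  site2 <- site_spec("B", 4, intensity_shift = 10, intensity_scale = 2)
  cs2 <- generate_case(cfg, site2, seed = 21)
  expect_equal(unique(cs2$image[2, , , ][cs2$label$voxels == 4L]),
               it["ET", 2] * 2 + 10)
})

test_that("enhancing tumor outshines necrosis on T1Gd in noisy phantoms", {
  cs <- generate_case(cfg0, site_spec("A", 4), seed = 33)
  t1gd <- cs$image[2, , , ]
  expect_gt(mean(t1gd[cs$label$voxels == 4L]), mean(t1gd[cs$label$voxels == 1L]))
})

test_that("label corruption modes alter maps as specified", {
  cs <- generate_case(cfg0, site_spec("A", 4), seed = 44, case_id = "A_1")
  n_et <- sum(cs$label$voxels == 4L)
  n_ed <- sum(cs$label$voxels == 2L)

  # fraction = 0 is the identity
  same <- corrupt_site_labels(list(cs), corruption_spec("label_swap", fraction = 0), 1)
  expect_identical(same[[1]], cs)

  # label_swap exchanges ET and ED counts; images untouched
  sw <- corrupt_site_labels(list(cs), corruption_spec("label_swap", fraction = 1), 1)
  expect_equal(sum(sw[[1]]$label$voxels == 4L), n_ed)
  expect_equal(sum(sw[[1]]$label$voxels == 2L), n_et)
  expect_identical(sw[[1]]$image, cs$image)
  expect_true(validate_label_map(sw[[1]]$label)$valid)

  # dilate grows and erode shrinks the whole-tumor extent
  n_wt <- sum(cs$label$voxels != 0L)
  di <- corrupt_site_labels(list(cs), corruption_spec("dilate", 1, magnitude = 2), 1)
  er <- corrupt_site_labels(list(cs), corruption_spec("erode", 1, magnitude = 2), 1)
  expect_gt(sum(di[[1]]$label$voxels != 0L), n_wt)
  expect_lt(sum(er[[1]]$label$voxels != 0L), n_wt)

  # random_flip with p = 1 reassigns every tumor voxel a tumor code
  fl <- corrupt_site_labels(list(cs), corruption_spec("random_flip", 1, magnitude = 1), 7)
  expect_identical(fl[[1]]$label$voxels != 0L, cs$label$voxels != 0L)
  expect_true(all(fl[[1]]$label$voxels[fl[[1]]$label$voxels != 0L] %in% c(1L, 2L, 4L)))

  expect_error(
    corrupt_site_labels(list(cs), corruption_spec("dilate", 1, magnitude = 100), 1),
    "magnitude"
  )
})

test_that("federation realization preserves splits, uniqueness and roles", {
  sites <- list(site_spec("S1", 10), site_spec("S2", 10),
                site_spec("S3", 10, role = "out_of_sample"))
  fd <- generate_federation(sites, cfg0, seed = 5)
  expect_equal(nrow(fd$manifest), 30)
  expect_equal(anyDuplicated(fd$manifest$case_id), 0L)
  for (sid in c("S1", "S2")) {
    expect_length(fd$sites[[sid]]$train_ids, 8)
    expect_length(fd$sites[[sid]]$val_ids, 2)
  }
  # out-of-sample cases never appear in any train split
  oos <- fd$manifest[fd$manifest$role == "out_of_sample", ]
  expect_true(all(oos$split == "val"))
  expect_length(fd$sites[["S3"]]$train_ids, 0)

  # duplicate site ids are rejected
  expect_error(generate_federation(list(site_spec("S1", 4), site_spec("S1", 4)),
                                   cfg0, 5), "duplicate")

  # same seed reproduces the whole federation bit-identically
  fd2 <- generate_federation(sites, cfg0, seed = 5)
  expect_identical(fd, fd2)
})

test_that("public-initial sites participate as ordinary collaborators", {
  reg <- federation_registry(
    list(site_spec("PUB", 10, role = "public_initial"), site_spec("T1", 10)),
    seed = 3
  )
  pub <- reg[reg$role == "public_initial", ]
  expect_equal(sum(pub$split == "train"), 8)
  expect_equal(sum(pub$split == "val"), 2)
})

test_that("NIfTI export/import round-trips a federation case", {
  dir <- withr::local_tempdir()
  fd <- generate_federation(list(site_spec("S1", 2)), cfg0, seed = 9)
  write_federation_nifti(fd, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_brats_case(file.path(dir, "S1", "S1_001"))
  orig <- fd$sites$S1$cases$S1_001
  expect_equal(back$image, orig$image, tolerance = 1e-6)
  expect_identical(back$label$voxels, orig$label$voxels)
})
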