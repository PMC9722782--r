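# CPU-sized configuration used in model unit tests
mini_cfg <- function(...) {
  tiny_model_config(base_filters = 2, patch_size = 8, ...)
}

test_that("initialization is seeded and parameter counts scale as expected", {
  p1 <- init_model(mini_cfg(seed = 5))
  p2 <- init_model(mini_cfg(seed = 5))
  expect_identical(unclass(p1), unclass(p2))
  p3 <- init_model(mini_cfg(seed = 6))
  expect_false(identical(p1[["enc1.conv1.w"]], p3[["enc1.conv1.w"]]))

  n4 <- n_parameters(init_model(tiny_model_config(base_filters = 4)))
  n8 <- n_parameters(init_model(tiny_model_config(base_filters = 8)))
  expect_gt(n8, n4)

  expect_error(model_config(depth = 3, patch_size = 30), "divisible")
})

test_that("parameter count matches a layer-by-layer hand tally", {
  # depth 2, base 2, in 4, out 3:
  #  enc1 (4->2): conv 2*4*27+2, in 2+2, conv 2*2*27+2, in 2+2, proj 2*4+2
  #  enc2 (2->4): conv 4*2*27+4, in 4+4, conv 4*4*27+4, in 4+4, proj 4*2+4
  #  up1  (4->2): 4*2*8+2
  #  dec1 (4->2): conv 2*4*27+2, in 2+2, conv 2*2*27+2, in 2+2, proj 2*4+2
  #  final (2->3): 3*2+3
  hand <- (2 * 4 * 27 + 2 + 4 + 2 * 2 * 27 + 2 + 4 + 10) +
    (4 * 2 * 27 + 4 + 8 + 4 * 4 * 27 + 4 + 8 + 12) +
    (4 * 2 * 8 + 2) +
    (2 * 4 * 27 + 2 + 4 + 2 * 2 * 27 + 2 + 4 + 10) +
    (3 * 2 + 3)
  expect_equal(n_parameters(init_model(mini_cfg())), hand)
})

test_that("forward pass is shape-preserving, sigmoid-bounded and deterministic", {
  p <- init_model(mini_cfg(seed = 2))
  img <- array(rnorm(4 * 8 * 8 * 8), c(4, 8, 8, 8))
  out1 <- forward(p, img)
  expect_s3_class(out1, "region_channels")
  expect_equal(out1$kind, "sigmoid")
  expect_equal(dim(out1$channels), c(3, 8, 8, 8))
  expect_true(all(out1$channels >= 0 & out1$channels <= 1))
  out2 <- forward(p, img)
  expect_identical(out1, out2)

  expect_error(forward(p, array(0, c(3, 8, 8, 8))), "channels")
  expect_error(forward(p, array(0, c(4, 7, 7, 7))), "divisible")

  # odd-size volumes are padded and cropped back by predict_volume
  out3 <- predict_volume(p, array(rnorm(4 * 7 * 9 * 7), c(4, 7, 9, 7)))
  expect_equal(dim(out3$channels), c(3, 7, 9, 7))
})

test_that("backpropagated gradients match finite differences", {
  cfg <- mini_cfg(seed = 11)
  p <- init_model(cfg)
  set.seed(31)
  img <- array(rnorm(4 * 8 * 8 * 8, sd = 0.5), c(4, 8, 8, 8))
  ref <- array(0, c(3, 8, 8, 8))
  ref[1, 4:5, 4:5, 4:5] <- 1; ref[2, 3:6, 3:6, 3:6] <- 1
  ref[3, 2:7, 2:7, 2:7] <- 1

  loss_at <- function(params) {
    pred <- fedsegsim:::net_fwd(params, img, cfg)$pred
    mirrored_dsc_loss(region_channels(ref, "binary"),
                      region_channels(pred, "sigmoid"))
  }
  fw <- fedsegsim:::net_fwd(p, img, cfg, keep_cache = TRUE)
  lg <- fedsegsim:::mirrored_loss_grad(ref, fw$pred)
  grads <- fedsegsim:::net_bwd(p, cfg, fw$cache, lg$gpred)

  eps <- 1e-5
  for (nm in c("enc1.conv1.w", "enc2.conv2.w", "enc2.in1.gamma", "up1.w",
               "dec1.conv1.w", "dec1.proj.w", "final.w", "final.b",
               "enc1.in2.beta")) {
    set.seed(17 + nchar(nm))
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 5e-4,
                   label = paste0("grad ", nm, "[", i, "]"))
    }
  }
})

test_that("a zero learning rate leaves parameters bit-identical", {
  p <- init_model(mini_cfg(seed = 3, lr = 0))
  prep <- fedsegsim:::prep_case(fixture_case)
  res <- train_local_epoch(p, NULL, list(prep), augment_config(), seed = 4)
  expect_identical(unclass(res$params), unclass(p))
  expect_error(train_local_epoch(p, NULL, list(), augment_config(), 1), "empty")
})

test_that("local training is reproducible and reports the mean loss", {
  p <- init_model(mini_cfg(seed = 8, patch_size = 16))
  prep <- fedsegsim:::prep_case(fixture_case)
  cases <- list(prep, prep, prep)
  r1 <- train_local_epoch(p, NULL, cases, augment_config(), seed = 21)
  r2 <- train_local_epoch(p, NULL, cases, augment_config(), seed = 21)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$loss, r2$loss)
  r3 <- train_local_epoch(p, NULL, cases, augment_config(), seed = 22)
  expect_false(identical(r1$params, r3$params))
  expect_true(r1$loss >= 0 && r1$loss <= 1)
})

test_that("repeated epochs on a fixed input descend the training loss", {
  # whole-volume patch and no augmentation so the per-epoch loss is
  # evaluated on the identical input every time
  p <- init_model(tiny_model_config(seed = 12, patch_size = 24))
  prep <- fedsegsim:::prep_case(fixture_case)
  aug_off <- augment_config(flip_p = 0, rotation_p = 0, noise_p = 0)
  losses <- numeric(15)
  opt <- NULL
  for (e in seq_along(losses)) {
    res <- train_local_epoch(p, opt, list(prep), aug_off, seed = 100 + e)
    p <- res$params; opt <- res$opt_state
    losses[e] <- res$loss
  }
  expect_lt(losses[15], losses[1])
  expect_lt(min(losses[8:15]), min(losses[1:3]))
})

test_that("checkpoints round-trip and verify fingerprints", {
  dir <- withr::local_tempdir()
  p <- init_model(mini_cfg(seed = 14))
  path <- file.path(dir, "round_001.rds")
  save_checkpoint(p, path)
  back <- load_checkpoint(path, expect = mini_cfg())
  expect_identical(back, p)
  expect_error(load_checkpoint(path, expect = tiny_model_config()),
               "fingerprint")
})
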