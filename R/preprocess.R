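#' Augmentation configuration
#'
#' Patch-level augmentation drawn once per training patch, applied in the
#' fixed order flip -> rotations -> noise: a flip with probability `flip_p`
#' (axis uniform over sagittal/coronal/axial); 90-degree and 180-degree
#' rotations each with probability `rotation_p`, the rotation axis drawn
#' uniformly and independently per event; additive Gaussian noise
#' `N(noise_mu, noise_sd)` on the image channels only with probability
#' `noise_p`.
#'
#' @param noise_mu,noise_sd,noise_p Noise mean, sd and application
#'   probability (defaults 0, 0.1, 0.2 — intensities are z-scored, so sd is
#'   in standard-deviation units).
#' @param rotation_p Probability of each of the 90- and 180-degree rotation
#'   events (default 0.5).
#' @param flip_p Probability of the flip event (default 1).
#' @return An `augment_config` list.
#' @export
augment_config <- function(noise_mu = 0, noise_sd = 0.1, noise_p = 0.2,
                           rotation_p = 0.5, flip_p = 1) {
  probs <- c(noise_p, rotation_p, flip_p)
  stopifnot(all(probs >= 0 & probs <= 1), noise_sd >= 0)
  structure(list(noise_mu = noise_mu, noise_sd = noise_sd, noise_p = noise_p,
                 rotation_p = rotation_p, flip_p = flip_p),
            class = "augment_config")
}

#' Remove all-zero border planes
#'
#' Strips leading/trailing axial, coronal and sagittal planes that are zero
#' across every image channel (the empty space around a skull-stripped,
#' registered brain), cropping the label map identically.  Only border
#' planes are removed, preserving spatial contiguity; the returned
#' `crop_record` allows exact un-cropping.
#'
#' @param image 4D array `[4, X, Y, Z]`.
#' @param label A [label_map] (or NULL).
#' @return List of `image`, `label`, and `crop_record` (per-axis `offset`
#'   and `original_dim`).
#' @export
crop_zero_planes <- function(image, label = NULL) {
  d <- dim(image)[-1]
  nz <- apply(image != 0, c(2, 3, 4), any)
  if (!any(nz)) {
    abort("image is entirely zero; nothing to crop.")
  }
  rng <- lapply(1:3, function(ax) {
    present <- apply(nz, ax, any)
    range(which(present))
  })
  idx <- lapply(rng, function(r) r[1]:r[2])
  image_c <- image[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  label_c <- if (!is.null(label)) {
    label_map(label$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              spacing = label$spacing)
  }
  list(
    image = image_c, label = label_c,
    crop_record = list(
      offset = vapply(rng, `[`, numeric(1), 1) - 1,
      original_dim = d
    )
  )
}

#' Undo a border crop
#'
#' Restores a cropped volume (image array, label map or 3D array) to its
#' original shape and placement using a `crop_record` from
#' [crop_zero_planes()].
#'
#' @param x Cropped 4D image array, [label_map], or 3D array.
#' @param crop_record Record returned by [crop_zero_planes()].
#' @return Object of the original shape, zero/background padded.
#' @export
uncrop <- function(x, crop_record) {
  off <- crop_record$offset
  d0 <- crop_record$original_dim
  place <- function(arr3, fill = 0) {
    out <- array(fill, d0)
    dc <- dim(arr3)
    out[off[1] + seq_len(dc[1]), off[2] + seq_len(dc[2]),
        off[3] + seq_len(dc[3])] <- arr3
    out
  }
  if (inherits(x, "label_map")) {
    return(label_map(place(x$voxels, 0L), spacing = x$spacing))
  }
  if (length(dim(x)) == 3L) {
    return(place(x))
  }
  out <- array(0, c(dim(x)[1], d0))
  for (ch in seq_len(dim(x)[1])) out[ch, , , ] <- place(x[ch, , , ])
  out
}

#' Z-score the non-zero intensities of each channel
#'
#' Per channel, the non-zero voxels are standardized to mean 0 and
#' (population) standard deviation 1; zero background voxels stay exactly
#' zero.  A degenerate channel whose non-zero voxels are constant has them
#' set to 0.
#'
#' @param image 4D array `[C, X, Y, Z]` (or a 3D array, treated as one
#'   channel).
#' @return Normalized array of the same shape.
#' @export
zscore_nonzero <- function(image) {
  one <- function(v) {
    nz <- v != 0
    if (!any(nz)) return(v)
    x <- v[nz]
    mu <- mean(x)
    sd_pop <- sqrt(mean((x - mu)^2))
    v[nz] <- if (sd_pop == 0) 0 else (x - mu) / sd_pop
    v
  }
  if (length(dim(image)) == 3L) {
    return(one(image))
  }
  out <- image
  for (ch in seq_len(dim(image)[1])) out[ch, , , ] <- one(image[ch, , , ])
  out
}

pad_to <- function(arr3, target, fill = 0) {
  d <- dim(arr3)
  if (all(d >= target)) return(list(x = arr3, before = c(0, 0, 0)))
  before <- pmax(floor((target - d) / 2), 0)
  after <- pmax(target - d - before, 0)
  out <- array(fill, pmax(d, target))
  out[before[1] + seq_len(d[1]), before[2] + seq_len(d[2]),
      before[3] + seq_len(d[3])] <- arr3
  list(x = out, before = before)
}

#' Extract one random training patch from a case
#'
#' Draws a patch corner uniformly over all valid positions and applies the
#' identical spatial window to the image and the reference region channels
#' derived from the label map.  Volumes smaller than the patch are first
#' zero-padded symmetrically (labels padded with background).  Consumes the
#' current RNG stream; seed externally for reproducibility.
#'
#' @param case Case list (`image`, `label`).
#' @param patch_size Integer edge length of the cubic patch.
#' @return A `patch_pair`: list with `image` `[4, p, p, p]` and `ref`
#'   (binary [region_channels] `[3, p, p, p]`).
#' @export
sample_patch <- function(case, patch_size) {
  if (patch_size <= 0) {
    abort("`patch_size` must be positive.")
  }
  p <- as.integer(patch_size)
  d <- dim(case$image)[-1]
  img <- case$image
  lab <- case$label$voxels
  if (any(d < p)) {
    padded <- lapply(seq_len(4), function(ch) pad_to(img[ch, , , ], rep(p, 3)))
    d2 <- dim(padded[[1]]$x)
    img <- array(0, c(4L, d2))
    for (ch in 1:4) img[ch, , , ] <- padded[[ch]]$x
    lab <- pad_to(lab, rep(p, 3), fill = 0L)$x
    d <- d2
  }
  corner <- vapply(d, function(n) sample.int(n - p + 1L, 1L), integer(1))
  ix <- lapply(1:3, function(ax) corner[ax] + seq_len(p) - 1L)
  list(
    image = img[, ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
    ref = derive_region_channels(
      label_map(lab[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
    )
  )
}

rot90_4d <- function(arr, axis, times) {
  # rotate the plane perpendicular to `axis` (1=sagittal, 2=coronal,
  # 3=axial) by times*90 degrees; arr is [C, X, Y, Z]
  times <- times %% 4
  if (times == 0) return(arr)
  plane <- setdiff(1:3, axis) + 1L  # array dims of the rotated plane
  for (i in seq_len(times)) {
    perm <- 1:4
    perm[plane] <- rev(plane)
    arr <- aperm(arr, perm)
    idx <- rep(list(quote(expr = )), 4)
    idx[[plane[1]]] <- rev(seq_len(dim(arr)[plane[1]]))
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  arr
}

flip_4d <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 4)
  idx[[axis + 1L]] <- rev(seq_len(dim(arr)[axis + 1L]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Augment a training patch
#'
#' Applies the augmentation draws of an [augment_config()] in the fixed
#' order flip -> 90-degree rotation -> 180-degree rotation -> noise.
#' Geometric transforms hit image and reference identically; noise is added
#' to image channels only, so the reference stays binary.  Consumes the
#' current RNG stream.
#'
#' @param pp Patch pair from [sample_patch()].
#' @param cfg An [augment_config()].
#' @return Augmented patch pair.
#' @export
augment <- function(pp, cfg) {
  stopifnot(inherits(cfg, "augment_config"))
  img <- pp$image
  ref <- pp$ref$channels
  if (runif(1) < cfg$flip_p) {
    ax <- sample.int(3L, 1L)
    img <- flip_4d(img, ax)
    ref <- flip_4d(ref, ax)
  }
  for (deg in c(1L, 2L)) {  # 90 then 180 degrees, independent draws
    if (runif(1) < cfg$rotation_p) {
      ax <- sample.int(3L, 1L)
      img <- rot90_4d(img, ax, deg)
      ref <- rot90_4d(ref, ax, deg)
    }
  }
  if (runif(1) < cfg$noise_p) {
    img <- img + array(rnorm(length(img), cfg$noise_mu, cfg$noise_sd), dim(img))
  }
  list(image = img, ref = region_channels(ref, "binary"))
}

#' Split case ids 4:1 into training and validation
#'
#' Validation size is `floor(n / 5)` (at least 1), assignment by a seeded
#' uniform shuffle; the same seed always reproduces the same split, which is
#' how per-site splits are preserved for the duration of a federation.
#'
#' @param case_ids Character vector of at least 2 case ids.
#' @param seed Integer seed.
#' @return List with `train_ids` and `val_ids` (disjoint, exhaustive).
#' @export
#' @examples
#' s <- split_cases(sprintf("case_%03d", 1:231), seed = 1)
#' lengths(s)  # 185 train, 46 validation
split_cases <- function(case_ids, seed) {
  n <- length(case_ids)
  if (n < 2) {
    abort("need at least 2 cases to split 4:1.")
  }
  n_val <- max(1L, floor(n / 5))
  perm <- with_seed(seed, sample(case_ids))
  list(train_ids = sort(perm[-seq_len(n_val)]),
       val_ids = sort(perm[seq_len(n_val)]))
}
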