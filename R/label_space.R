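#' @useDynLib fedsegsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom stats rnorm runif setNames
NULL

# BraTS label codes: 0 background, 1 necrotic core (NCR),
# 2 peritumoral edema (ED), 4 enhancing tumor (ET).
BRATS_CODES <- c(0L, 1L, 2L, 4L)
REGIONS <- c("ET", "TC", "WT")

#' Construct a BraTS-convention label map
#'
#' A `label_map` is a 3D integer array of BraTS codes (0 background, 1 NCR,
#' 2 ED, 4 ET) together with voxel spacing and an affine orientation matrix,
#' the package's in-memory form of a segmentation NIfTI.
#'
#' @param voxels 3D integer array with values in \{0, 1, 2, 4\}.
#' @param spacing Numeric length-3 voxel size in mm.
#' @param affine 4x4 orientation/position matrix (default: diagonal from
#'   `spacing`).
#' @return A `label_map` object.
#' @export
label_map <- function(voxels, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.")
  }
  bad <- setdiff(unique(as.integer(voxels)), BRATS_CODES)
  if (length(bad) > 0L) {
    abort(paste0(
      "label map contains codes outside {0,1,2,4}: ",
      paste(sort(bad), collapse = ", ")
    ))
  }
  storage.mode(voxels) <- "integer"
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing), affine = affine),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cts <- table(factor(x$voxels, levels = BRATS_CODES))
  cat("<label_map> ", paste(dim(x$voxels), collapse = "x"),
      " voxels | counts:",
      paste(sprintf("%s=%d", names(cts), cts), collapse = " "), "\n")
  invisible(x)
}

#' Construct a set of nested sub-compartment channels
#'
#' Region channels hold the three nested tumor regions the network predicts,
#' in the fixed order ET (enhancing tumor), TC (tumor core = ET + NCR),
#' WT (whole tumor = TC + ED), as a 4D array `[3, X, Y, Z]`.  `kind` records
#' whether values are hard 0/1 masks or sigmoid activations in (0, 1).
#'
#' @param channels 4D numeric array `[3, X, Y, Z]`.
#' @param kind `"binary"` or `"sigmoid"`.
#' @return A `region_channels` object.
#' @export
region_channels <- function(channels, kind = c("binary", "sigmoid")) {
  kind <- match.arg(kind)
  d <- dim(channels)
  if (length(d) != 4L || d[1] != 3L) {
    abort("`channels` must be a [3, X, Y, Z] array.")
  }
  if (kind == "binary" && !all(channels %in% c(0, 1))) {
    abort("binary region channels must contain only 0/1 values.")
  }
  structure(list(channels = channels, kind = kind), class = "region_channels")
}

#' @export
print.region_channels <- function(x, ...) {
  d <- dim(x$channels)
  cat("<region_channels> kind=", x$kind, " ",
      paste(d[-1], collapse = "x"), " voxels\n", sep = "")
  invisible(x)
}

#' Derive nested region channels from a label map
#'
#' Expands a BraTS label map into the three binary channels the network is
#' trained against: ET = label 4; TC = labels \{1, 4\}; WT = labels
#' \{1, 2, 4\}.  The channels are nested by construction
#' (`ET <= TC <= WT` voxelwise).
#'
#' @param lm A [label_map] (or a bare 3D array of valid codes).
#' @return A binary [region_channels].
#' @export
#' @examples
#' m <- label_map(array(c(0L, 1L, 2L, 4L, 0L, 0L, 0L, 0L), c(2, 2, 2)))
#' rc <- derive_region_channels(m)
#' apply(rc$channels, 1, sum)  # |ET| <= |TC| <= |WT|
derive_region_channels <- function(lm) {
  v <- if (inherits(lm, "label_map")) lm$voxels else {
    lm <- label_map(lm)
    lm$voxels
  }
  d <- dim(v)
  ch <- array(0, c(3L, d))
  ch[1L, , , ] <- as.numeric(v == 4L)
  ch[2L, , , ] <- as.numeric(v == 1L | v == 4L)
  ch[3L, , , ] <- as.numeric(v != 0L)
  rc <- region_channels(ch, "binary")
  rc
}

#' Decode binary region channels back into a label map
#'
#' Inverse of [derive_region_channels()].  Inconsistent channels (a positive
#' ET or TC voxel missing from an enclosing region) are first repaired by
#' upward nesting enforcement (`TC := TC | ET`, `WT := WT | TC`), preserving
#' every positive inner-region prediction; the repaired channels then map to
#' ET -> 4, TC-without-ET -> 1 (NCR), WT-without-TC -> 2 (ED), else 0.
#'
#' @param rc A binary [region_channels].
#' @param spacing,affine Geometry passed to [label_map()].
#' @return A [label_map]; `derive_region_channels()` of the result
#'   reproduces the (nesting-enforced) channels exactly.
#' @export
channels_to_label_map <- function(rc, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(inherits(rc, "region_channels"))
  if (rc$kind != "binary") {
    abort("sigmoid-kind channels must be binarized before decoding (see `binarize()`).")
  }
  d3 <- dim(rc$channels)[-1]
  et <- array(rc$channels[1L, , , ], d3) > 0
  tc <- array(rc$channels[2L, , , ], d3) > 0 | et
  wt <- array(rc$channels[3L, , , ], d3) > 0 | tc
  v <- array(0L, d3)
  v[wt] <- 2L
  v[tc] <- 1L
  v[et] <- 4L
  label_map(v, spacing = spacing, affine = affine)
}

#' Read / write label maps and region masks as NIfTI
#'
#' `write_label_map()` stores the integer codes bit-exactly;
#' `read_label_map()` validates on read.  `write_region_masks()` emits one
#' binary NIfTI per region, suffixed `_et/_tc/_wt`.
#'
#' @param lm A [label_map].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The written path(s) (write) or a [label_map] (read), invisibly
#'   for writers.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  write_volume(lm$voxels, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  v <- read_volume(path)
  label_map(array(as.integer(round(v)), dim(v)))
}

#' @rdname write_label_map
#' @param rc A binary [region_channels].
#' @param prefix Output path prefix for the three per-region masks.
#' @export
write_region_masks <- function(rc, prefix) {
  stopifnot(inherits(rc, "region_channels"))
  if (rc$kind != "binary") {
    abort("binarize before writing region masks.")
  }
  d3 <- dim(rc$channels)[-1]
  paths <- character(3)
  for (i in 1:3) {
    paths[i] <- paste0(prefix, "_", tolower(REGIONS[i]), ".nii.gz")
    write_volume(array(as.integer(rc$channels[i, , , ]), d3), paths[i])
  }
  invisible(paths)
}

#' Validate an integer volume as a BraTS label map
#'
#' Reporting operation for data sanity-checking: tallies voxels per label
#' code and lists any codes outside the \{0, 1, 2, 4\} convention.  Never
#' throws; intended for screening incoming site data.
#'
#' @param voxels 3D integer array (or a [label_map]).
#' @return A list with `valid` (logical), `counts` (named tibble of code and
#'   voxel count) and `offending` (integer vector of invalid codes).
#' @export
validate_label_map <- function(voxels) {
  if (inherits(voxels, "label_map")) voxels <- voxels$voxels
  v <- as.integer(voxels)
  tab <- table(v)
  codes <- as.integer(names(tab))
  offending <- sort(setdiff(codes, BRATS_CODES))
  list(
    valid = length(offending) == 0L,
    counts = tibble::tibble(code = codes, n_voxels = as.integer(tab)),
    offending = offending
  )
}
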