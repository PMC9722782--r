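MRI_CHANNELS <- c("t1", "t1gd", "t2", "flair")

# Default mean intensity per (channel x tissue class), arbitrary units.
# Encodes the radiological contrast the phantoms emulate: ET enhances on
# T1Gd, NCR is dark on T1Gd, ED is brightest on T2-FLAIR.
default_intensity_table <- function() {
  tbl <- rbind(
    brain = c(100, 100, 100, 100),
    NCR   = c(60,   40, 120, 110),
    ET    = c(90,  180, 110, 120),
    ED    = c(80,   90, 140, 170)
  )
  colnames(tbl) <- MRI_CHANNELS
  tbl
}

#' Phantom generation configuration
#'
#' Describes the synthetic mpMRI cases the generator produces: an ellipsoid
#' "brain" of non-zero intensities on a zero background and, with
#' probability `tumor_presence_prob`, a concentric three-compartment tumor
#' (necrotic core inside an enhancing shell inside an edema envelope).
#'
#' @param volume_shape Integer length-3 volume size in voxels (default 48^3,
#'   small enough for CPU-scale federations).
#' @param brain_radius Range (min, max) of the brain ellipsoid semi-axes,
#'   voxels.
#' @param ncr_radius,et_radius,ed_radius Ranges of the tumor compartment
#'   radii, voxels; must satisfy NCR < ET < ED.
#' @param intensity_table Matrix `[tissue class x channel]` of mean
#'   intensities; default [default_intensity_table()].
#' @param noise_sd Additive Gaussian noise standard deviation, intensity
#'   units.
#' @param tumor_presence_prob Probability a case carries a tumor.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(48, 48, 48),
                           brain_radius = c(16, 20),
                           ncr_radius = c(2, 3),
                           et_radius = c(4, 6),
                           ed_radius = c(7, 9),
                           intensity_table = default_intensity_table(),
                           noise_sd = 5,
                           tumor_presence_prob = 1) {
  stopifnot(
    length(volume_shape) == 3L, all(volume_shape >= 8),
    noise_sd >= 0, tumor_presence_prob >= 0, tumor_presence_prob <= 1,
    all(is.finite(intensity_table))
  )
  if (!(max(ncr_radius) < min(et_radius) && max(et_radius) < min(ed_radius))) {
    abort("tumor radii ranges must be strictly increasing: NCR < ET < ED.")
  }
  structure(list(
    volume_shape = as.integer(volume_shape),
    brain_radius = brain_radius, ncr_radius = ncr_radius,
    et_radius = et_radius, ed_radius = ed_radius,
    intensity_table = intensity_table, noise_sd = noise_sd,
    tumor_presence_prob = tumor_presence_prob
  ), class = "phantom_config")
}

#' Site specification for a synthetic federation
#'
#' @param site_id Unique site identifier (string).
#' @param n_cases Number of cases the site contributes (>= 2 so a 4:1
#'   train/validation split is possible).
#' @param intensity_shift Additive per-channel site effect (length 1 or 4).
#' @param intensity_scale Multiplicative per-channel site effect (> 0).
#' @param role `"training"`, `"out_of_sample"` or `"public_initial"`.
#' @param corruption Optional [corruption_spec()] applied to the site's
#'   reference labels.
#' @return A `site_spec` list.
#' @export
site_spec <- function(site_id, n_cases,
                      intensity_shift = 0, intensity_scale = 1,
                      role = c("training", "out_of_sample", "public_initial"),
                      corruption = NULL) {
  role <- match.arg(role)
  stopifnot(n_cases >= 2, all(intensity_scale > 0))
  structure(list(
    site_id = as.character(site_id), n_cases = as.integer(n_cases),
    intensity_shift = rep_len(intensity_shift, 4L),
    intensity_scale = rep_len(intensity_scale, 4L),
    role = role, corruption = corruption
  ), class = "site_spec")
}

#' Annotation corruption specification
#'
#' Emulates site-level data-quality problems in reference segmentations:
#' `label_swap` exchanges the ET and ED codes, `dilate`/`erode` grow or
#' shrink the whole-tumor extent by `magnitude` voxels, `random_flip`
#' reassigns each tumor voxel a uniformly random tumor code with
#' probability `magnitude`.
#'
#' @param mode One of `"label_swap"`, `"dilate"`, `"erode"`, `"random_flip"`.
#' @param fraction Fraction of the site's cases affected, in `[0, 1]`.
#' @param magnitude Voxels (dilate/erode) or probability (random_flip).
#' @return A `corruption_spec` list.
#' @export
corruption_spec <- function(mode = c("label_swap", "dilate", "erode", "random_flip"),
                            fraction = 1, magnitude = 1) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1, magnitude >= 0)
  structure(list(mode = mode, fraction = fraction, magnitude = magnitude),
            class = "corruption_spec")
}

ellipsoid_mask <- function(shape, center, radii) {
  x <- (seq_len(shape[1]) - center[1]) / radii[1]
  y <- (seq_len(shape[2]) - center[2]) / radii[2]
  z <- (seq_len(shape[3]) - center[3]) / radii[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  r2 <= 1
}

#' Generate one synthetic mpMRI case
#'
#' Draws brain/tumor geometry and intensities from `cfg`, applies the
#' site's per-channel intensity shift and scale, and adds Gaussian noise.
#' All randomness comes from the supplied seed, so the same
#' `(cfg, site, seed)` always produces a bit-identical case.
#'
#' @param cfg A [phantom_config()].
#' @param site A [site_spec()].
#' @param seed Integer seed for this case's random stream.
#' @param case_id Optional case identifier carried through evaluation.
#' @return A list with `image` (4D array `[4, X, Y, Z]`), `label`
#'   ([label_map]) and `case_id`.
#' @export
generate_case <- function(cfg, site, seed, case_id = NULL) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(site, "site_spec"))
  with_seed(seed, {
    shp <- cfg$volume_shape
    center <- shp / 2 + runif(3, -1, 1)
    brain_r <- runif(3, cfg$brain_radius[1], cfg$brain_radius[2])
    if (any(brain_r >= shp / 2)) {
      abort("brain radius exceeds volume half-extent; enlarge volume_shape.")
    }
    brain <- ellipsoid_mask(shp, center, brain_r)

    lab <- array(0L, shp)
    has_tumor <- runif(1) < cfg$tumor_presence_prob
    if (has_tumor) {
      r_ncr <- runif(1, cfg$ncr_radius[1], cfg$ncr_radius[2])
      r_et <- runif(1, cfg$et_radius[1], cfg$et_radius[2])
      r_ed <- runif(1, cfg$ed_radius[1], cfg$ed_radius[2])
      if (r_ed >= min(brain_r)) {
        abort("tumor radius exceeds brain radius; shrink ed_radius.")
      }
      # place tumor so its ED envelope stays inside the brain ellipsoid
      margin <- 1 - (r_ed / min(brain_r))
      tc_center <- center + runif(3, -1, 1) * margin * brain_r / 2
      ed_m <- ellipsoid_mask(shp, tc_center, rep(r_ed, 3)) & brain
      et_m <- ellipsoid_mask(shp, tc_center, rep(r_et, 3)) & brain
      ncr_m <- ellipsoid_mask(shp, tc_center, rep(r_ncr, 3)) & brain
      lab[ed_m] <- 2L
      lab[et_m] <- 4L
      lab[ncr_m] <- 1L
    }

    img <- array(0, c(4L, shp))
    tissue <- array("none", shp)
    tissue[brain] <- "brain"
    tissue[lab == 1L] <- "NCR"
    tissue[lab == 4L] <- "ET"
    tissue[lab == 2L] <- "ED"
    for (ch in seq_along(MRI_CHANNELS)) {
      base <- array(0, shp)
      for (cls in rownames(cfg$intensity_table)) {
        base[tissue == cls] <- cfg$intensity_table[cls, ch]
      }
      vals <- base * site$intensity_scale[ch] + site$intensity_shift[ch]
      vals[!brain] <- 0
      if (cfg$noise_sd > 0) {
        noise <- array(rnorm(prod(shp), 0, cfg$noise_sd), shp)
        vals[brain] <- vals[brain] + noise[brain]
      }
      img[ch, , , ] <- vals
    }
    list(image = img, label = label_map(lab), case_id = case_id)
  })
}

#' Corrupt the reference labels of a set of cases
#'
#' Applies a [corruption_spec()] to a site's cases: a seeded draw selects
#' the affected fraction, then each affected case's label map is altered in
#' place (images are untouched and results remain valid label maps).
#'
#' @param cases List of cases from [generate_case()].
#' @param spec A [corruption_spec()].
#' @param seed Integer seed.
#' @return The list of cases with altered label maps.
#' @export
corrupt_site_labels <- function(cases, spec, seed) {
  stopifnot(inherits(spec, "corruption_spec"))
  if (spec$fraction == 0 || length(cases) == 0L) {
    return(cases)
  }
  with_seed(seed, {
    n_hit <- round(spec$fraction * length(cases))
    hit <- sample(seq_along(cases), n_hit)
    for (i in hit) {
      cases[[i]]$label <- corrupt_label_map(cases[[i]]$label, spec)
    }
    cases
  })
}

corrupt_label_map <- function(lm, spec) {
  v <- lm$voxels
  if (spec$mode == "label_swap") {
    et <- v == 4L
    ed <- v == 2L
    v[et] <- 2L
    v[ed] <- 4L
  } else if (spec$mode %in% c("dilate", "erode")) {
    if (spec$magnitude >= min(dim(v))) {
      abort("morphological magnitude exceeds volume extent.")
    }
    wt <- v != 0L
    for (i in seq_len(round(spec$magnitude))) {
      wt <- if (spec$mode == "dilate") dilate6(wt) else erode6(wt)
    }
    if (spec$mode == "dilate") {
      v[wt & v == 0L] <- 2L   # growth joins the edema envelope
    } else {
      v[!wt] <- 0L
    }
  } else { # random_flip
    tum <- which(v != 0L)
    flip <- tum[runif(length(tum)) < spec$magnitude]
    v[flip] <- sample(c(1L, 2L, 4L), length(flip), replace = TRUE)
  }
  label_map(v, spacing = lm$spacing, affine = lm$affine)
}

shift3 <- function(m, axis, by) {
  # shift logical 3D array, padding with FALSE
  out <- array(FALSE, dim(m))
  d <- dim(m)[axis]
  src <- seq_len(d) - by
  ok <- src >= 1 & src <= d
  idx_out <- lapply(dim(m), seq_len)
  idx_in <- idx_out
  idx_out[[axis]] <- which(ok)
  idx_in[[axis]] <- src[ok]
  out[idx_out[[1]], idx_out[[2]], idx_out[[3]]] <-
    m[idx_in[[1]], idx_in[[2]], idx_in[[3]]]
  out
}

dilate6 <- function(m) {
  out <- m
  for (ax in 1:3) {
    out <- out | shift3(m, ax, 1L) | shift3(m, ax, -1L)
  }
  out
}

erode6 <- function(m) {
  out <- m
  for (ax in 1:3) {
    out <- out & shift3(m, ax, 1L) & shift3(m, ax, -1L)
  }
  out
}

#' Build the case registry of a federation without generating volumes
#'
#' Assigns globally unique case ids (`<site>_<index>`) and a preserved 4:1
#' train/validation split to every participating site.  Sites with role
#' `"training"` or `"public_initial"` are split and contribute to training
#' rounds (the data behind the public initial model re-joins the federation
#' as an ordinary collaborator node); `"out_of_sample"` sites are never
#' split into training and serve only for generalizability evaluation.
#'
#' @param sites List of [site_spec()].
#' @param seed Global integer seed; per-site split seeds derive from it via
#'   a stable hash of the site id.
#' @return A manifest tibble (`case_id`, `site_id`, `role`, `split`).
#' @export
federation_registry <- function(sites, seed) {
  ids <- vapply(sites, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate site_id: ", ids[duplicated(ids)][1]))
  }
  purrr::map_dfr(sites, function(site) {
    case_ids <- sprintf("%s_%03d", site$site_id, seq_len(site$n_cases))
    split <- if (site$role %in% c("training", "public_initial")) {
      s <- split_cases(case_ids, derive_seed(seed, "split", site$site_id))
      ifelse(case_ids %in% s$train_ids, "train", "val")
    } else {
      rep("val", length(case_ids))
    }
    tibble::tibble(case_id = case_ids, site_id = site$site_id,
                   role = site$role, split = split)
  })
}

#' Generate a multi-site synthetic federation
#'
#' Realizes every site's cases, applies any per-site label corruption, and
#' records a preserved 4:1 train/validation split for each participating
#' site (see [federation_registry()]).  Case ids are globally unique;
#' per-site seeds derive from the global seed via a stable hash of the site
#' id, so the federation is reproducible independently of site order.
#'
#' @param sites List of [site_spec()]; at least one must have role
#'   `"training"` or `"public_initial"`.
#' @param cfg A [phantom_config()].
#' @param seed Global integer seed.
#' @return A `federation_dataset`: list of realized sites (each with
#'   `spec`, `cases`, `train_ids`, `val_ids`) plus a `manifest` tibble
#'   (case_id, site_id, role, split).
#' @export
generate_federation <- function(sites, cfg, seed) {
  manifest <- federation_registry(sites, seed)
  if (!any(manifest$split == "train")) {
    abort("at least one site must have role 'training' or 'public_initial'.")
  }
  realized <- lapply(sites, function(site) {
    rows <- manifest[manifest$site_id == site$site_id, ]
    cases <- lapply(seq_len(site$n_cases), function(i) {
      generate_case(cfg, site, derive_seed(seed, "case", site$site_id, i),
                    case_id = rows$case_id[i])
    })
    if (!is.null(site$corruption)) {
      cases <- corrupt_site_labels(cases, site$corruption,
                                   derive_seed(seed, "corrupt", site$site_id))
    }
    list(spec = site, cases = setNames(cases, rows$case_id),
         train_ids = rows$case_id[rows$split == "train"],
         val_ids = rows$case_id[rows$split == "val"])
  })
  names(realized) <- vapply(sites, `[[`, character(1), "site_id")
  structure(list(sites = realized, manifest = manifest, seed = seed),
            class = "federation_dataset")
}

#' @export
print.federation_dataset <- function(x, ...) {
  cat("<federation_dataset> ", length(x$sites), " sites, ",
      nrow(x$manifest), " cases\n", sep = "")
  print(dplyr::count(x$manifest, .data$site_id, .data$role, .data$split))
  invisible(x)
}

#' Write a federation to a BraTS-style NIfTI directory layout
#'
#' One directory per site; per case, four image files suffixed
#' `_t1/_t1gd/_t2/_flair` and a `_seg` label file (`.nii.gz`), plus a
#' `manifest.csv` at the root listing case id, site, role and split.
#'
#' @param fd A [generate_federation()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_federation_nifti <- function(fd, dir) {
  stopifnot(inherits(fd, "federation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in fd$sites) {
    sdir <- file.path(dir, s$spec$site_id)
    dir.create(sdir, showWarnings = FALSE)
    for (cid in names(s$cases)) {
      cs <- s$cases[[cid]]
      for (ch in seq_along(MRI_CHANNELS)) {
        write_volume(cs$image[ch, , , ],
                     file.path(sdir, paste0(cid, "_", MRI_CHANNELS[ch], ".nii.gz")))
      }
      write_volume(cs$label$voxels,
                   file.path(sdir, paste0(cid, "_seg.nii.gz")))
    }
  }
  utils::write.csv(fd$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a BraTS-style case from NIfTI files
#'
#' Reads the four modality volumes and the `_seg` label map written by
#' [write_federation_nifti()] (or any BraTS-named case directory).
#'
#' @param prefix Path prefix, e.g. `"<dir>/<site>/<case_id>"`; the reader
#'   appends `_t1/_t1gd/_t2/_flair/_seg` plus `.nii.gz` (or `.nii`).
#' @return A case list (`image`, `label`, `case_id`).
#' @export
read_brats_case <- function(prefix) {
  find <- function(suffix) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- paste0(prefix, "_", suffix, ext)
      if (file.exists(p)) return(p)
    }
    abort(paste0("missing volume: ", prefix, "_", suffix, ".nii[.gz]"))
  }
  vols <- lapply(MRI_CHANNELS, function(ch) read_volume(find(ch)))
  shp <- dim(vols[[1]])
  img <- array(0, c(4L, shp))
  for (ch in 1:4) img[ch, , , ] <- vols[[ch]]
  seg <- read_volume(find("seg"))
  list(image = img, label = label_map(array(as.integer(round(seg)), dim(seg))),
       case_id = basename(prefix))
}

write_volume <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr), path)
}

read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim(v))
}
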