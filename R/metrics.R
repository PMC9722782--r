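#' Generalized Dice similarity coefficient
#'
#' Computes `2 * |RL . PM|_1 / (|RL|_1 + |PM|_1)` where `.` is the
#' componentwise (Hadamard) product and `|x|_1` the sum of absolute values.
#' With binary masks this is the classical DSC; with sigmoid activations it
#' is the "soft" DSC used during training.  When both inputs are entirely
#' empty the score is 1 by convention (perfect agreement on absence, the
#' BraTS community convention); an empty reference against a non-empty
#' prediction scores 0.
#'
#' @param rl Reference values (array or vector), in `[0, 1]`.
#' @param pm Predicted values, same shape.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' a <- c(1, 1, 1, 0, 0, 0, 0, 0)
#' b <- c(1, 1, 0, 1, 1, 1, 0, 0)
#' generalized_dsc(a, b)  # 2*2 / (3+5) = 0.5
generalized_dsc <- function(rl, pm) {
  if (!identical(dim(rl), dim(pm)) || length(rl) != length(pm)) {
    abort("`rl` and `pm` must have identical shapes.")
  }
  denom <- sum(abs(rl)) + sum(abs(pm))
  if (denom == 0) {
    return(1)
  }
  2 * sum(abs(rl * pm)) / denom
}

#' Jaccard index from a Dice score
#'
#' Convenience conversion `jsc = dsc / (2 - dsc)`.
#'
#' @param dsc Dice score(s) in `[0, 1]`.
#' @return Jaccard score(s).
#' @export
dsc_to_jsc <- function(dsc) dsc / (2 - dsc)

#' Threshold sigmoid region channels into binary masks
#'
#' Each channel is thresholded independently with a strict comparison
#' (`value > threshold` maps to 1); exactly-threshold activations map to 0,
#' fixing tie behavior deterministically.  Already-binary channels pass
#' through unchanged (binarization is idempotent).  Nesting is *not*
#' enforced here — see [channels_to_label_map()] for nesting repair at
#' decode time.
#'
#' @param rc A [region_channels].
#' @param threshold Scalar strictly inside (0, 1); default 0.5.
#' @return A binary [region_channels].
#' @export
binarize <- function(rc, threshold = 0.5) {
  stopifnot(inherits(rc, "region_channels"))
  if (rc$kind == "binary") {
    return(rc)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number strictly inside (0, 1).")
  }
  region_channels((rc$channels > threshold) * 1, "binary")
}

#' Mirrored generalized-DSC training loss
#'
#' The training loss is the mean, over the three sub-compartments, of
#' `1 - DSC(1 - ref_c, 1 - pred_c)`: the generalized DSC evaluated on the
#' *absolute complement* of each region, with floating-point (sigmoid)
#' predictions.  Scoring the complement weights small structures more
#' evenly, so no per-region penalty weights are needed.  A degenerate
#' channel whose reference and prediction complements are both all-zero
#' contributes a loss term of 0.
#'
#' @param ref Binary [region_channels] reference.
#' @param pred Sigmoid (or binary) [region_channels] prediction.
#' @param include_region Also score each region directly and average the
#'   region and complement terms (default FALSE: the training loss uses
#'   the complement alone).  Provided for comparing the two formulations.
#' @return Loss in `[0, 1]`; 0 iff prediction equals reference exactly.
#' @export
mirrored_dsc_loss <- function(ref, pred, include_region = FALSE) {
  stopifnot(inherits(ref, "region_channels"), inherits(pred, "region_channels"))
  if (!identical(dim(ref$channels), dim(pred$channels))) {
    abort("reference and prediction shapes differ.")
  }
  term <- function(a, p) {
    if (sum(a) + sum(p) == 0) 0 else 1 - generalized_dsc(a, p)
  }
  terms <- vapply(1:3, function(c) {
    r <- ref$channels[c, , , ]
    q <- pred$channels[c, , , ]
    mirrored <- term(1 - r, 1 - q)
    if (include_region) (mirrored + term(r, q)) / 2 else mirrored
  }, numeric(1))
  mean(terms)
}

#' Per-case region scores from whole-volume inference
#'
#' Runs a predictor over a full case volume, binarizes the sigmoid output
#' at 0.5, and scores each nested region against the channels derived from
#' the reference label map.
#'
#' @param predict_fn Function `(image 4D array [4, X, Y, Z]) ->`
#'   [region_channels] (sigmoid or binary).
#' @param case A list with `image` (4D array) and `label` ([label_map]),
#'   as produced by [generate_case()].
#' @return A one-row tibble with `case_id`, `dsc_et`, `dsc_tc`, `dsc_wt`.
#' @export
evaluate_case <- function(predict_fn, case) {
  pred <- tryCatch(
    predict_fn(case$image),
    error = function(e) {
      abort(paste0("inference failed on case '", case$case_id %||% "?",
                   "': ", conditionMessage(e)))
    }
  )
  if (pred$kind == "sigmoid") pred <- binarize(pred, 0.5)
  ref <- derive_region_channels(case$label)
  scores <- vapply(1:3, function(c) {
    generalized_dsc(ref$channels[c, , , ], pred$channels[c, , , ])
  }, numeric(1))
  tibble::tibble(
    case_id = case$case_id %||% NA_character_,
    dsc_et = scores[1], dsc_tc = scores[2], dsc_wt = scores[3]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
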