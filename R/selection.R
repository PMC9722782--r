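#' Score every federated round from per-case validation results
#'
#' Computes, per round, the collective score (per-case mean over the three
#' regions, then the mean across all cases of all sites) and the pooled
#' per-region means.  These are the quantities singlet and triplet
#' selection rank.
#'
#' @param case_scores Per-case tibble with `round`, `dsc_et`, `dsc_tc`,
#'   `dsc_wt` (the `case_scores` element of a [run_federation()] result).
#' @return Tibble with one row per round: `round`, `collective`, `dsc_et`,
#'   `dsc_tc`, `dsc_wt`.
#' @export
score_rounds <- function(case_scores) {
  stopifnot(nrow(case_scores) > 0)
  case_scores |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(
      collective = mean((.data$dsc_et + .data$dsc_tc + .data$dsc_wt) / 3),
      dsc_et = mean(.data$dsc_et),
      dsc_tc = mean(.data$dsc_tc),
      dsc_wt = mean(.data$dsc_wt),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$round)
}

top_rounds <- function(scores, column, k) {
  # ties broken toward the earlier round
  ord <- order(-scores[[column]], scores$round)
  scores$round[ord[seq_len(k)]]
}

#' Select singlet and triplet consensus models
#'
#' A *singlet* is a single round's consensus model ranked by the collective
#' validation score; a *triplet* is one specialist round per region (ET,
#' TC, WT), each ranked by that region's pooled validation score.  Ties
#' break toward the earlier round.
#'
#' @param case_scores Per-case validation tibble (see [score_rounds()]).
#' @param k Number of candidates of each kind (default 5).
#' @return A `selection_result`: list with `singlets` (integer rounds,
#'   best first) and `triplets` (tibble with `rank`, `round_et`,
#'   `round_tc`, `round_wt`).
#' @export
select_models <- function(case_scores, k = 5) {
  scores <- score_rounds(case_scores)
  if (k > nrow(scores)) {
    abort(paste0("k = ", k, " exceeds the ", nrow(scores),
                 " available rounds."))
  }
  singlets <- top_rounds(scores, "collective", k)
  triplets <- tibble::tibble(
    rank = seq_len(k),
    round_et = top_rounds(scores, "dsc_et", k),
    round_tc = top_rounds(scores, "dsc_tc", k),
    round_wt = top_rounds(scores, "dsc_wt", k)
  )
  structure(list(singlets = singlets, triplets = triplets, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> singlet rounds:",
      paste(x$singlets, collapse = ", "), "\n")
  print(x$triplets)
  invisible(x)
}

#' Predict with a singlet, triplet or ensemble of consensus models
#'
#' * `singlet`: one model's sigmoid output, thresholded at 0.5.
#' * `triplet`: three specialist models in region order (ET, TC, WT); each
#'   region channel is taken from its specialist's sigmoid output before a
#'   single thresholding pass (exactly 3 forward passes per case).
#' * `ensemble`: the voxelwise mean of all members' sigmoid outputs,
#'   thresholded at 0.5 (how single-site-model ensembles are combined).
#'
#' @param models A `model_params` or list of them (1 for singlet, exactly 3
#'   for triplet, >= 1 for ensemble).
#' @param image 4D image array `[4, X, Y, Z]`.
#' @param mode `"singlet"`, `"triplet"` or `"ensemble"`.
#' @param threshold Binarization threshold (default 0.5).
#' @return A binary [region_channels].
#' @export
predict_segmentation <- function(models, image,
                                 mode = c("singlet", "triplet", "ensemble"),
                                 threshold = 0.5) {
  mode <- match.arg(mode)
  if (inherits(models, "model_params")) models <- list(models)
  n <- length(models)
  if (mode == "singlet" && n != 1L) {
    abort("singlet mode needs exactly 1 model.")
  }
  if (mode == "triplet" && n != 3L) {
    abort("triplet mode needs exactly 3 models (ET, TC, WT specialists).")
  }
  if (mode == "ensemble" && n < 1L) {
    abort("ensemble mode needs at least 1 model.")
  }
  sig <- switch(mode,
    singlet = predict_volume(models[[1]], image)$channels,
    triplet = {
      out <- NULL
      for (r in 1:3) {
        ch <- predict_volume(models[[r]], image)$channels
        if (is.null(out)) out <- ch
        out[r, , , ] <- ch[r, , , ]
      }
      out
    },
    ensemble = {
      acc <- predict_volume(models[[1]], image)$channels
      for (i in seq_along(models)[-1]) {
        acc <- acc + predict_volume(models[[i]], image)$channels
      }
      acc / n
    }
  )
  binarize(region_channels(sig, "sigmoid"), threshold)
}
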