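#' Federation run configuration
#'
#' @param max_rounds Number of federated rounds to run (>= 1).
#' @param plateau_window,plateau_eps Optional early stopping: stop once the
#'   best pooled collective validation score in the last `plateau_window`
#'   rounds improves on the best before them by less than `plateau_eps`.
#'   `NULL` window disables plateau detection (the default; a fixed round
#'   budget with post-hoc model selection is the primary protocol).
#' @param seed Global seed; per-site per-round streams derive from it via
#'   [derive_seed()], so results are independent of site iteration order.
#' @param aug_cfg An [augment_config()].
#' @param reset_optimizer Reset each site's Adam state at the start of
#'   every round (default TRUE).  Optimizer moments are never aggregated
#'   either way — only model parameters are.  After a broadcast, moments
#'   persisted from the previous round describe the site's *old* parameter
#'   trajectory, and with the short local epochs of a desk-scale
#'   federation that stale momentum measurably degrades the consensus, so
#'   a fresh optimizer per round is the default; set FALSE to persist
#'   local state across rounds instead.
#' @return A `federation_config` list.
#' @export
federation_config <- function(max_rounds = 10, plateau_window = NULL,
                              plateau_eps = 0, seed = 1,
                              aug_cfg = augment_config(),
                              reset_optimizer = TRUE) {
  stopifnot(max_rounds >= 1, plateau_eps >= 0)
  structure(list(max_rounds = as.integer(max_rounds),
                 plateau_window = plateau_window, plateau_eps = plateau_eps,
                 seed = as.integer(seed), aug_cfg = aug_cfg,
                 reset_optimizer = isTRUE(reset_optimizer)),
            class = "federation_config")
}

#' Federated averaging of model parameters
#'
#' The consensus parameters are the weighted elementwise mean of the
#' collaborators' parameters, weights proportional to each collaborator's
#' contributing (training) data.  Weights are normalized to sum to one
#' before averaging, so aggregation is invariant to their scale and a
#' single-update aggregation is exactly the identity.
#'
#' @param updates List of `model_params` with matching fingerprints.
#' @param weights Positive numeric weights, one per update.
#' @return Consensus `model_params`.
#' @export
#' @examples
#' # weighted mean: weights (1, 3) on values (0, 4) -> 3
fedavg <- function(updates, weights) {
  stopifnot(length(updates) >= 1, length(weights) == length(updates),
            all(weights > 0))
  fps <- vapply(updates, attr, character(1), "fingerprint")
  if (length(unique(fps)) > 1L) {
    bad <- which(fps != fps[1])[1]
    abort(paste0("cannot aggregate: update 1 has fingerprint '", fps[1],
                 "' but update ", bad, " has '", fps[bad], "'."))
  }
  if (length(updates) == 1L) {
    return(updates[[1]])
  }
  w <- weights / sum(weights)
  out <- updates[[1]]
  for (nm in names(out)) {
    acc <- w[1] * updates[[1]][[nm]]
    for (i in seq_along(updates)[-1]) {
      acc <- acc + w[i] * updates[[i]][[nm]]
    }
    out[[nm]] <- acc
  }
  out
}

prep_case <- function(case) {
  cr <- crop_zero_planes(case$image, case$label)
  list(image = zscore_nonzero(cr$image), label = cr$label,
       case_id = case$case_id)
}

training_sites <- function(dataset) {
  keep <- vapply(dataset$sites, function(s) {
    s$spec$role %in% c("training", "public_initial")
  }, logical(1))
  dataset$sites[keep]
}

#' Initialize federation state
#'
#' Preprocesses every case once (zero-plane crop + non-zero z-score; these
#' are deterministic per case), and sets up consensus parameters and
#' per-site optimizer state.
#'
#' @param cfg A [federation_config()].
#' @param dataset A [generate_federation()] result.
#' @param initial_params Starting `model_params` (a fresh [init_model()] or
#'   a pre-trained public-initial-model stand-in).
#' @return A `federation_state` list.
#' @export
federation_init <- function(cfg, dataset, initial_params) {
  stopifnot(inherits(cfg, "federation_config"),
            inherits(dataset, "federation_dataset"),
            inherits(initial_params, "model_params"))
  sites <- training_sites(dataset)
  if (length(sites) == 0L) {
    abort("dataset has no training sites.")
  }
  prepped <- lapply(dataset$sites, function(s) {
    lapply(s$cases, prep_case)
  })
  structure(list(
    cfg = cfg, dataset = dataset, prepped = prepped,
    consensus = initial_params,
    opt_states = setNames(vector("list", length(sites)), names(sites)),
    round = 0L
  ), class = "federation_state")
}

site_validation_scores <- function(params, state, round_idx) {
  purrr::map_dfr(names(state$dataset$sites), function(sid) {
    s <- state$dataset$sites[[sid]]
    if (!s$spec$role %in% c("training", "public_initial") ||
        length(s$val_ids) == 0L) {
      return(tibble::tibble())
    }
    purrr::map_dfr(s$val_ids, function(cid) {
      sc <- evaluate_case(function(img) predict_volume(params, img),
                          state$prepped[[sid]][[cid]])
      dplyr::mutate(sc, site_id = sid, round = round_idx, .before = 1)
    })
  })
}

round_record <- function(case_scores, train_losses, round_idx) {
  per_site <- case_scores |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("dsc"), mean),
                     n_cases = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(round = round_idx,
                  train_loss = unname(train_losses[.data$site_id]))
  pooled <- tibble::tibble(
    round = round_idx,
    dsc_et = mean(case_scores$dsc_et),
    dsc_tc = mean(case_scores$dsc_tc),
    dsc_wt = mean(case_scores$dsc_wt),
    collective = mean((case_scores$dsc_et + case_scores$dsc_tc +
                         case_scores$dsc_wt) / 3),
    n_cases = nrow(case_scores)
  )
  list(per_site = per_site, pooled = pooled)
}

#' Execute one federated round
#'
#' Broadcast the consensus model to every training site; each site trains
#' one local epoch on its training split (seeded by site id and round);
#' updates are aggregated with [fedavg()] weighted by training-case counts;
#' the new consensus is then evaluated on every site's local validation
#' split.
#'
#' @param state A `federation_state` from [federation_init()].
#' @return Updated state, with `$last_record` (list of `per_site` and
#'   `pooled` tibbles) describing the round.
#' @export
run_round <- function(state) {
  stopifnot(inherits(state, "federation_state"))
  r <- state$round + 1L
  sites <- training_sites(state$dataset)
  updates <- list()
  weights <- numeric(0)
  losses <- numeric(0)
  for (sid in names(sites)) {
    s <- sites[[sid]]
    train_cases <- state$prepped[[sid]][s$train_ids]
    opt <- if (state$cfg$reset_optimizer) NULL else state$opt_states[[sid]]
    res <- tryCatch(
      train_local_epoch(state$consensus, opt, train_cases,
                        state$cfg$aug_cfg,
                        derive_seed(state$cfg$seed, "round", sid, r)),
      error = function(e) {
        abort(paste0("round ", r, " aborted: site '", sid, "' failed: ",
                     conditionMessage(e)))
      }
    )
    updates[[sid]] <- res$params
    weights <- c(weights, length(train_cases))
    losses <- c(losses, setNames(res$loss, sid))
    state$opt_states[[sid]] <- res$opt_state
  }
  state$consensus <- fedavg(updates, weights)
  state$round <- r
  scores <- site_validation_scores(state$consensus, state, r)
  state$last_case_scores <- scores
  state$last_record <- round_record(scores, losses, r)
  state
}

#' Detect a validation plateau
#'
#' TRUE once the best pooled collective score within the last `window`
#' rounds exceeds the best score before them by less than `eps` (i.e., the
#' last `window` rounds brought no meaningful change).  Always FALSE while
#' fewer than `window + 1` rounds exist.
#'
#' @param collective Numeric vector of pooled collective scores, one per
#'   round so far.
#' @param window Number of trailing rounds that must fail to improve.
#' @param eps Minimum improvement that counts as meaningful.
#' @return Logical.
#' @export
plateau_reached <- function(collective, window, eps) {
  n <- length(collective)
  if (n <= window) {
    return(FALSE)
  }
  best_recent <- max(collective[(n - window + 1):n])
  best_before <- max(collective[1:(n - window)])
  (best_recent - best_before) < eps
}

#' Run a full federation
#'
#' Runs federated rounds until `max_rounds` (or an optional validation
#' plateau), checkpointing every round's consensus model — round-wise
#' checkpoints are what singlet/triplet model selection searches over.
#'
#' @param cfg A [federation_config()].
#' @param dataset A [generate_federation()] result.
#' @param initial_params Starting `model_params`.
#' @param checkpoint_dir Optional directory; if given, each round's
#'   consensus is also serialized to `round_<r>.rds`.
#' @param quiet Suppress per-round progress messages.
#' @return A `federation_run`: list with `history` (round x site tibble),
#'   `pooled` (round-level tibble), `case_scores` (per-case per-round
#'   tibble), `checkpoints` (list of `model_params` by round), `consensus`
#'   (final), and `config`.
#' @export
run_federation <- function(cfg, dataset, initial_params,
                           checkpoint_dir = NULL, quiet = TRUE) {
  state <- federation_init(cfg, dataset, initial_params)
  history <- list()
  pooled <- list()
  case_scores <- list()
  checkpoints <- list()
  for (r in seq_len(cfg$max_rounds)) {
    state <- run_round(state)
    history[[r]] <- state$last_record$per_site
    pooled[[r]] <- state$last_record$pooled
    case_scores[[r]] <- state$last_case_scores
    checkpoints[[r]] <- state$consensus
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(state$consensus,
              file.path(checkpoint_dir, sprintf("round_%03d.rds", r)))
    }
    if (!quiet) {
      message(sprintf("round %d | collective DSC %.3f", r,
                      pooled[[r]]$collective))
    }
    if (!is.null(cfg$plateau_window) &&
        plateau_reached(vapply(pooled, `[[`, numeric(1), "collective"),
                        cfg$plateau_window, cfg$plateau_eps)) {
      break
    }
  }
  structure(list(
    history = dplyr::bind_rows(history),
    pooled = dplyr::bind_rows(pooled),
    case_scores = dplyr::bind_rows(case_scores),
    checkpoints = checkpoints,
    consensus = state$consensus,
    config = cfg
  ), class = "federation_run")
}

#' @export
print.federation_run <- function(x, ...) {
  n <- nrow(x$pooled)
  cat("<federation_run> ", n, " rounds, ",
      length(unique(x$history$site_id)), " sites | final collective DSC ",
      sprintf("%.3f", x$pooled$collective[n]), "\n", sep = "")
  invisible(x)
}

#' Save / load a consensus-model checkpoint
#'
#' A checkpoint is the named parameter arrays plus the architecture
#' fingerprint; loading verifies the fingerprint when `expect` is given.
#'
#' @param params A `model_params` object.
#' @param path File path (conventionally `round_<r>.rds`).
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: the
#'   `model_params`.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect Optional fingerprint (or `model_config`) the checkpoint
#'   must match.
#' @export
load_checkpoint <- function(path, expect = NULL) {
  params <- readRDS(path)
  if (!inherits(params, "model_params")) {
    abort(paste0("'", path, "' is not a model checkpoint."))
  }
  if (!is.null(expect)) {
    fp <- if (inherits(expect, "model_config")) expect$fingerprint else expect
    if (!identical(attr(params, "fingerprint"), fp)) {
      abort(paste0("checkpoint fingerprint '", attr(params, "fingerprint"),
                   "' does not match expected '", fp, "'."))
    }
  }
  params
}

#' Centralized training baseline
#'
#' Trains the same network on a pooled set of cases for `epochs` epochs
#' (one optimizer step per case per epoch), using the same per-epoch
#' seed-derivation scheme as a federated site.  A 1-site federation and a
#' centralized run over that site's training split with `site_id` equal to
#' the site's id are bit-identical in deterministic mode.
#'
#' @param initial_params Starting `model_params`.
#' @param cases List of raw cases (preprocessed internally like federation
#'   sites).
#' @param epochs Number of epochs.
#' @param aug_cfg An [augment_config()].
#' @param seed Global seed.
#' @param site_id Stream tag (default `"centralized"`).
#' @return List with `params`, `loss_history`.
#' @export
train_centralized <- function(initial_params, cases, epochs,
                              aug_cfg = augment_config(), seed = 1,
                              site_id = "centralized") {
  prepped <- lapply(cases, prep_case)
  params <- initial_params
  opt <- NULL
  losses <- numeric(epochs)
  for (r in seq_len(epochs)) {
    res <- train_local_epoch(params, opt, prepped, aug_cfg,
                             derive_seed(seed, "round", site_id, r))
    params <- res$params
    opt <- res$opt_state
    losses[r] <- res$loss
  }
  list(params = params, loss_history = losses)
}

#' Pooled validation DSC of a model over a dataset
#'
#' Evaluates a parameter set on every training-site validation case and
#' returns the pooled per-region and collective means ("across all cases
#' of all sites").
#'
#' @param params `model_params`.
#' @param dataset A [generate_federation()] result.
#' @return One-row tibble (`dsc_et`, `dsc_tc`, `dsc_wt`, `collective`,
#'   `n_cases`).
#' @export
pooled_validation_dsc <- function(params, dataset) {
  scores <- purrr::map_dfr(dataset$sites, function(s) {
    if (!s$spec$role %in% c("training", "public_initial")) {
      return(tibble::tibble())
    }
    purrr::map_dfr(s$val_ids, function(cid) {
      evaluate_case(function(img) predict_volume(params, img),
                    prep_case(s$cases[[cid]]))
    })
  })
  tibble::tibble(
    dsc_et = mean(scores$dsc_et), dsc_tc = mean(scores$dsc_tc),
    dsc_wt = mean(scores$dsc_wt),
    collective = mean((scores$dsc_et + scores$dsc_tc + scores$dsc_wt) / 3),
    n_cases = nrow(scores)
  )
}
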