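#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (the standard convention).  With at most
#' 25 remaining pairs and no ties among the absolute differences the exact
#' signed-rank null distribution is used; otherwise the normal
#' approximation with continuity correction (and tie correction of the
#' variance).  If every difference is zero the sample is degenerate and
#' `p = 1` is returned with a note.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return List with `p_value`, `statistic` (signed-rank V), `n_effective`
#'   (pairs after dropping zeros), `method`, and `degenerate` flag.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(0, 1, 2, 3, 4))$p_value  # 0.0625
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    abort("`x` and `y` must be non-empty and of equal length.")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(v, n),
                 stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(p_value = p, statistic = v, n_effective = n, method = method,
       degenerate = FALSE)
}

#' Paired comparison of two segmentation models
#'
#' Scores both predictors on every case, reports per-region means, the
#' relative improvement of B over A (`(mean_B - mean_A) / mean_A * 100` %),
#' and a paired two-sided Wilcoxon signed-rank p-value per region.  An
#' all-zero baseline mean yields an undefined (NA) improvement rather than
#' an infinite one.
#'
#' @param predict_a,predict_b Functions `(image) -> region_channels`.
#' @param cases List of cases (`image`, `label`, `case_id`).
#' @return A `comparison_report` tibble: one row per region with columns
#'   `region`, `mean_a`, `mean_b`, `improvement_pct`, `p_value`,
#'   `n_cases`; per-case scores attached as attribute `"case_scores"`.
#' @export
compare_models_paired <- function(predict_a, predict_b, cases) {
  stopifnot(length(cases) >= 1)
  sa <- purrr::map_dfr(cases, function(cs) evaluate_case(predict_a, cs))
  sb <- purrr::map_dfr(cases, function(cs) evaluate_case(predict_b, cs))
  rows <- purrr::map_dfr(seq_along(REGIONS), function(i) {
    col <- c("dsc_et", "dsc_tc", "dsc_wt")[i]
    ma <- mean(sa[[col]])
    mb <- mean(sb[[col]])
    tibble::tibble(
      region = REGIONS[i],
      mean_a = ma, mean_b = mb,
      improvement_pct = if (ma == 0) NA_real_ else (mb - ma) / ma * 100,
      p_value = wilcoxon_signed_rank(sb[[col]], sa[[col]])$p_value,
      n_cases = length(cases)
    )
  })
  attr(rows, "case_scores") <- list(a = sa, b = sb)
  class(rows) <- c("comparison_report", class(rows))
  rows
}

#' Scan one site's validation history for data-quality anomalies
#'
#' Mirrors the monitoring that exposed low-quality annotations at a
#' collaborating site: for each region, the site's round-wise mean
#' validation DSC is paired with the federation-wide round-wise mean
#' (pooled across all cases of all sites) and tested with a two-sided
#' Wilcoxon signed-rank test.  A site is flagged when the test is
#' significant at `alpha` *and* its mean sits at least `min_effect` below
#' the federation mean — consistently low scores indicate the consensus
#' model is not gaining knowledge from (or validating well against) that
#' site's data.
#'
#' The minimum-effect guard exists because a paired rank test is
#' magnitude-blind: a site whose fixed validation cases happen to be
#' marginally harder than average sits consistently below the federation
#' mean every round and reaches arbitrarily small p-values at a deficit
#' of a few hundredths of a DSC point.  Deficits of that size are within
#' typical inter-rater variability for these structures and are not a
#' data-quality signal, hence the 0.05-DSC default; set `min_effect = 0`
#' to flag on significance and direction alone.
#'
#' @param run A [run_federation()] result (or its `case_scores` tibble).
#' @param site_id Site to scan.
#' @param alpha Significance level (default 0.05).
#' @param min_effect Minimum DSC deficit below the federation mean for a
#'   significant site to be flagged (default 0.05).
#' @return An `anomaly_report` tibble: per region, `p_value`, `site_mean`,
#'   `federation_mean`, `flagged`; round-wise series attached as attribute
#'   `"series"`.
#' @export
site_anomaly_scan <- function(run, site_id, alpha = 0.05, min_effect = 0.05) {
  cs <- if (inherits(run, "federation_run")) run$case_scores else run
  if (!site_id %in% cs$site_id) {
    abort(paste0("unknown site '", site_id, "'."))
  }
  if (length(unique(cs$round)) < 2) {
    abort("need at least 2 rounds to scan for anomalies.")
  }
  fed <- cs |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("dsc"), mean),
                     .groups = "drop")
  site <- cs |>
    dplyr::filter(.data$site_id == !!site_id) |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("dsc"), mean),
                     .groups = "drop")
  rows <- purrr::map_dfr(seq_along(REGIONS), function(i) {
    col <- c("dsc_et", "dsc_tc", "dsc_wt")[i]
    w <- wilcoxon_signed_rank(site[[col]], fed[[col]])
    sm <- mean(site[[col]])
    fm <- mean(fed[[col]])
    tibble::tibble(
      site_id = site_id, region = REGIONS[i],
      p_value = w$p_value, site_mean = sm, federation_mean = fm,
      flagged = w$p_value < alpha && sm < fm - min_effect
    )
  })
  attr(rows, "series") <- list(site = site, federation = fed)
  class(rows) <- c("anomaly_report", class(rows))
  rows
}

#' Scan every site of a run
#'
#' @inheritParams site_anomaly_scan
#' @param bonferroni Add a Bonferroni-adjusted p-value column across sites
#'   (reported alongside the raw values; flagging uses raw p).
#' @return Tibble of per-site per-region anomaly rows.
#' @export
scan_all_sites <- function(run, alpha = 0.05, min_effect = 0.05,
                           bonferroni = FALSE) {
  cs <- if (inherits(run, "federation_run")) run$case_scores else run
  sites <- unique(cs$site_id)
  out <- purrr::map_dfr(sites, function(s) {
    site_anomaly_scan(cs, s, alpha, min_effect)
  })
  if (bonferroni) {
    out$p_bonferroni <- pmin(1, out$p_value * length(sites))
  }
  out
}

#' Write run summary files
#'
#' Emits the round-curve table (one row per round per site plus a pooled
#' row per round), any model-comparison tables, and an anomaly table, as
#' CSV files under `dir`.  Every number is re-derivable from the per-case
#' scores, which are written alongside.
#'
#' @param run A [run_federation()] result.
#' @param dir Output directory.
#' @param comparisons Named list of `comparison_report` objects (optional).
#' @param anomalies An anomaly tibble from [scan_all_sites()] (optional).
#' @return Invisible character vector of written paths.
#' @export
summarize_run <- function(run, dir, comparisons = list(), anomalies = NULL) {
  stopifnot(inherits(run, "federation_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pooled_rows <- run$pooled |>
    dplyr::transmute(.data$round, site_id = "POOLED", .data$dsc_et,
                     .data$dsc_tc, .data$dsc_wt, .data$n_cases)
  curve <- dplyr::bind_rows(
    dplyr::select(run$history, "round", "site_id", "dsc_et", "dsc_tc",
                  "dsc_wt", "n_cases"),
    pooled_rows
  ) |> dplyr::arrange(.data$round, .data$site_id)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(curve, "round_curves.csv")
  w(run$case_scores, "case_scores.csv")
  w(tibble::tibble(
    key = c("seed", "max_rounds", "rounds_run", "reset_optimizer"),
    value = c(run$config$seed, run$config$max_rounds, nrow(run$pooled),
              as.integer(run$config$reset_optimizer))
  ), "run_manifest.csv")
  for (nm in names(comparisons)) {
    w(as.data.frame(comparisons[[nm]]), paste0("comparison_", nm, ".csv"))
  }
  if (!is.null(anomalies)) w(as.data.frame(anomalies), "anomalies.csv")
  invisible(paths)
}
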