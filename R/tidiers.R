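#' Tidy a federation run into a long per-round table
#'
#' One row per round, site and region (plus pooled rows with
#' `site_id = "POOLED"`), ready for plotting or dplyr summaries.
#'
#' @param x A [run_federation()] result.
#' @param ... Unused.
#' @return A tibble with `round`, `site_id`, `region`, `dsc`.
#' @method tidy federation_run
#' @export
tidy.federation_run <- function(x, ...) {
  pooled <- x$pooled |>
    dplyr::transmute(.data$round, site_id = "POOLED", .data$dsc_et,
                     .data$dsc_tc, .data$dsc_wt)
  dplyr::bind_rows(
    dplyr::select(x$history, "round", "site_id", "dsc_et", "dsc_tc",
                  "dsc_wt"),
    pooled
  ) |>
    tidyr::pivot_longer(dplyr::starts_with("dsc"), names_to = "region",
                        values_to = "dsc", names_prefix = "dsc_") |>
    dplyr::mutate(region = toupper(.data$region))
}

#' One-row summary of a federation run
#'
#' @param x A [run_federation()] result.
#' @param ... Unused.
#' @return Tibble with rounds run, sites, and final pooled scores.
#' @method glance federation_run
#' @export
glance.federation_run <- function(x, ...) {
  last <- x$pooled[nrow(x$pooled), ]
  tibble::tibble(
    n_rounds = nrow(x$pooled),
    n_sites = length(unique(x$history$site_id)),
    n_val_cases = last$n_cases,
    final_dsc_et = last$dsc_et, final_dsc_tc = last$dsc_tc,
    final_dsc_wt = last$dsc_wt, final_collective = last$collective,
    best_collective = max(x$pooled$collective),
    best_round = x$pooled$round[which.max(x$pooled$collective)]
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot per-site validation curves of a federation run
#'
#' Round-wise mean validation DSC per site (thin lines) with the pooled
#' federation mean (thick line), faceted by region — the standard
#' monitoring view in which a site with corrupted annotations stands out
#' below the federation mean.
#'
#' @param object A [run_federation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot federation_run
#' @export
autoplot.federation_run <- function(object, ...) {
  df <- tidy(object)
  pooled <- dplyr::filter(df, .data$site_id == "POOLED")
  sites <- dplyr::filter(df, .data$site_id != "POOLED")
  ggplot2::ggplot(sites, ggplot2::aes(.data$round, .data$dsc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$site_id,
                                    colour = .data$site_id), alpha = 0.7) +
    ggplot2::geom_line(data = pooled, linewidth = 1.1, colour = "black") +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "federated round", y = "mean validation DSC",
                  colour = "site") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
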