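test_that("wilcoxon handles degenerate and textbook cases", {
  w_eq <- wilcoxon_signed_rank(1:5, 1:5)
  expect_equal(w_eq$p_value, 1)
  expect_true(w_eq$degenerate)

  # n = 5, all differences positive (ties-free): two-sided exact p = 2 / 2^5
  x <- c(1.1, 2.3, 3.7, 4.9, 5.2)
  y <- x - c(0.5, 0.4, 0.3, 0.2, 0.1)
  w5 <- wilcoxon_signed_rank(x, y)
  expect_equal(w5$p_value, 2 * (1 / 2^5))
  expect_equal(w5$method, "exact")

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact branch agrees with full sign-assignment enumeration", {
  set.seed(12)
  for (n in 4:12) {
    for (rep in 1:3) {
      x <- round(rnorm(n), 3)
      y <- round(rnorm(n), 3)
      d <- x - y
      if (any(d == 0) || anyDuplicated(abs(d[d != 0]))) next
      w <- wilcoxon_signed_rank(x, y)
      expect_equal(w$p_value, wilcoxon_enum_p(x, y), tolerance = 1e-12,
                   label = paste0("n=", n, " rep=", rep))
      # and with R's reference implementation
      expect_equal(w$p_value,
                   suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                       exact = TRUE)$p.value),
                   tolerance = 1e-12)
    }
  }
})

test_that("large samples fall back to the corrected normal approximation", {
  set.seed(13)
  x <- rnorm(40, 0.2)
  y <- rnorm(40)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
})

make_fixed_predictor <- function(per_case) {
  # returns the stored binary channels for whichever case is being scored
  function(img) {
    key <- paste(dim(img)[-1], collapse = "x")
    per_case[[key]]
  }
}

test_that("paired model comparison reports means, improvements and p-values", {
  # three 6^3 cases with different tumor sizes
  cases <- lapply(1:3, function(i) {
    lab <- array(0L, c(6, 6, 6) + i)
    lab[1:(2 + i), 1, 1] <- 4L
    list(image = array(1, c(4, dim(lab))), label = label_map(lab),
         case_id = paste0("h", i))
  })
  # baseline over-segments ET by one voxel; "perfect" matches the reference
  baseline <- function(img) {
    d <- dim(img)[-1]
    lab <- array(0L, d)
    lab[1:(d[1] - 3), 1, 1] <- 4L
    derive_region_channels(label_map(lab))
  }
  perfect <- function(img) {
    d <- dim(img)[-1]
    lab <- array(0L, d)
    lab[1:(d[1] - 4), 1, 1] <- 4L
    derive_region_channels(label_map(lab))
  }
  rep_ab <- compare_models_paired(baseline, perfect, cases)
  expect_s3_class(rep_ab, "comparison_report")
  expect_equal(nrow(rep_ab), 3)
  expect_equal(rep_ab$n_cases, rep(3L, 3))
  et <- rep_ab[rep_ab$region == "ET", ]
  expect_equal(et$mean_b, 1)
  expect_lt(et$mean_a, 1)
  expect_equal(et$improvement_pct, (et$mean_b - et$mean_a) / et$mean_a * 100)

  # identical models: zero improvement, degenerate p = 1
  rep_aa <- compare_models_paired(perfect, perfect, cases)
  expect_true(all(rep_aa$improvement_pct == 0))
  expect_true(all(rep_aa$p_value == 1))

  # swapped orientation flips the sign of the absolute gain
  rep_ba <- compare_models_paired(perfect, baseline, cases)
  expect_equal(rep_ba$mean_a, rep_ab$mean_b)
  expect_equal(rep_ba$mean_b - rep_ba$mean_a,
               -(rep_ab$mean_b - rep_ab$mean_a))

  # all-zero baseline yields an undefined improvement, not infinity
  zero <- function(img) {
    region_channels(array(0, c(3, dim(img)[-1])), "binary")
  }
  rep_z <- compare_models_paired(zero, perfect, cases)
  expect_true(all(is.na(rep_z$improvement_pct)))
})

test_that("relative improvement reproduces the 0.62 -> 0.8246 = +33% arithmetic", {
  expect_equal(round((0.8246 - 0.62) / 0.62 * 100), 33)
})

test_that("anomaly scanning flags only significantly low sites", {
  # synthetic per-case history: 3 sites x 12 rounds x 4 cases
  set.seed(20)
  mk <- function(site, shift) {
    purrr::map_dfr(1:12, function(r) {
      tibble::tibble(
        site_id = site, round = r, case_id = paste0(site, "_", 1:4),
        dsc_et = pmin(1, pmax(0, 0.7 + shift + rnorm(4, 0, 0.015))),
        dsc_tc = pmin(1, pmax(0, 0.75 + shift + rnorm(4, 0, 0.015))),
        dsc_wt = pmin(1, pmax(0, 0.8 + shift + rnorm(4, 0, 0.015)))
      )
    })
  }
  hist <- dplyr::bind_rows(mk("good", 0), mk("bad", -0.25), mk("high", +0.05))
  rep_bad <- site_anomaly_scan(hist, "bad")
  expect_true(all(rep_bad$flagged))
  expect_true(all(rep_bad$site_mean < rep_bad$federation_mean))

  # a site uniformly above the federation mean is never flagged
  rep_high <- site_anomaly_scan(hist, "high")
  expect_false(any(rep_high$flagged))

  # a site that matches the federation mean exactly is degenerate, p = 1
  fed_mean <- hist |>
    dplyr::group_by(round) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("dsc"), mean))
  clone <- purrr::map_dfr(1:12, function(r) {
    tibble::tibble(site_id = "clone", round = r, case_id = "clone_1",
                   dsc_et = fed_mean$dsc_et[r], dsc_tc = fed_mean$dsc_tc[r],
                   dsc_wt = fed_mean$dsc_wt[r])
  })
  # clone shifts the pooled mean slightly; rebuild with clone included
  hist2 <- dplyr::bind_rows(hist, clone)
  rep_clone <- site_anomaly_scan(hist2, "clone")
  expect_false(any(rep_clone$flagged))

  expect_error(site_anomaly_scan(hist, "nope"), "unknown")

  all_sites <- scan_all_sites(hist, bonferroni = TRUE)
  expect_equal(sort(unique(all_sites$site_id[all_sites$flagged])), "bad")
  expect_true(all(all_sites$p_bonferroni >= all_sites$p_value))
})

test_that("run summaries are re-derivable from the per-case scores", {
  run <- make_mini_run()
  dir <- withr::local_tempdir()
  summarize_run(run, dir)
  curve <- utils::read.csv(file.path(dir, "round_curves.csv"))
  n_sites <- length(unique(run$history$site_id))
  expect_equal(nrow(curve), nrow(run$pooled) * (n_sites + 1))
  per_case <- utils::read.csv(file.path(dir, "case_scores.csv"))
  for (r in unique(curve$round)) {
    pooled_row <- curve[curve$round == r & curve$site_id == "POOLED", ]
    cases_r <- per_case[per_case$round == r, ]
    expect_equal(pooled_row$dsc_et, mean(cases_r$dsc_et), tolerance = 1e-9)
    expect_equal(pooled_row$dsc_wt, mean(cases_r$dsc_wt), tolerance = 1e-9)
  }
})

test_that("the minimum-effect guard keeps marginal sites unflagged", {
  # a site consistently but trivially below the federation mean: the rank
  # test is maximally significant, yet the deficit is not meaningful
  set.seed(21)
  mk2 <- function(site, shift) {
    purrr::map_dfr(1:12, function(r) {
      tibble::tibble(site_id = site, round = r, case_id = paste0(site, 1:4),
                     dsc_et = 0.7 + shift + rnorm(4, 0, 0.002),
                     dsc_tc = 0.7 + shift + rnorm(4, 0, 0.002),
                     dsc_wt = 0.7 + shift + rnorm(4, 0, 0.002))
    })
  }
  hist <- dplyr::bind_rows(mk2("lowish", -0.02), mk2("ok1", 0.01), mk2("ok2", 0.01))
  rep_low <- site_anomaly_scan(hist, "lowish")
  expect_true(all(rep_low$p_value < 0.05))          # significant ...
  expect_false(any(rep_low$flagged))                # ... but not meaningful
  rep_low0 <- site_anomaly_scan(hist, "lowish", min_effect = 0)
  expect_true(all(rep_low0$flagged))                # bare rule would flag
})
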