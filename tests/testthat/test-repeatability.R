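test_that("within-subject SD matches the worked pair set by both routes", {
  pairs <- data.frame(value_1 = c(0.1, 0.3), value_2 = c(0.2, 0.3))
  sw <- within_subject_sd(pairs)
  expect_equal(sw, 0.05)  # sqrt((0.01 + 0) / 4)

  # independent route: one-way ANOVA within-subject mean square
  long <- data.frame(subject = factor(rep(1:2, each = 2)),
                     value = c(0.1, 0.2, 0.3, 0.3))
  fit <- stats::aov(value ~ subject, data = long)
  ms_within <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  expect_equal(sw, sqrt(ms_within))

  # shift invariance and degenerate zero
  shifted <- pairs + 0.17
  expect_equal(within_subject_sd(shifted), sw)
  expect_identical(within_subject_sd(data.frame(value_1 = c(0.2, 0.4),
                                                value_2 = c(0.2, 0.4))), 0)
  expect_error(within_subject_sd(pairs[1, ]), "at least 2")
  expect_warning(
    within_subject_sd(data.frame(value_1 = c(0.1, 0.3, NA),
                                 value_2 = c(0.2, 0.3, 0.1))),
    "incomplete")
})

test_that("repeatability coefficient and CV follow their definitions", {
  expect_identical(repeatability_coefficient(0), 0)
  expect_equal(repeatability_coefficient(0.05) / 0.05, 1.96 * sqrt(2))
  expect_error(repeatability_coefficient(-0.1), ">= 0")

  expect_identical(coefficient_of_variation(0, 0.2), 0)
  expect_equal(coefficient_of_variation(0.05, 0.25), 0.2)
  expect_error(coefficient_of_variation(0.05, 0), "> 0")
  # scale invariance: scaling all measurements scales sw and mean alike
  pairs <- data.frame(value_1 = c(0.1, 0.3), value_2 = c(0.2, 0.25))
  cv1 <- coefficient_of_variation(within_subject_sd(pairs),
                                  mean(unlist(pairs)))
  cv2 <- coefficient_of_variation(within_subject_sd(pairs * 3),
                                  mean(unlist(pairs * 3)))
  expect_equal(cv1, cv2)
})

test_that("Sw confidence intervals behave like an SD interval should", {
  expect_equal(sw_confidence_interval(0, 10), c(0, 0))
  ci <- sw_confidence_interval(0.05, 50)
  expect_equal(ci, c(0.05 * (1 - 1.96 / 10), 0.05 * (1 + 1.96 / 10)),
               tolerance = 1e-4)
  # width -> 0 as n grows
  wide <- diff(sw_confidence_interval(0.05, 10))
  narrow <- diff(sw_confidence_interval(0.05, 1e6))
  expect_lt(narrow, 0.003 * 0.05)
  expect_lt(narrow, wide)
  # chi-squared variant brackets the point estimate too
  ci2 <- sw_confidence_interval(0.05, 50, method = "chisq")
  expect_true(ci2[1] < 0.05 && 0.05 < ci2[2])
  expect_error(sw_confidence_interval(0.05, 1), ">= 2")
})

test_that("normal-approximation CI has near-nominal coverage at study scale", {
  # 200 simulated cohorts at the study's scale: n = 47, sigma_w = 0.02,
  # mean density 0.22; empirical coverage must sit in [90%, 98%]
  sw_true <- 0.02
  covered <- vapply(1:200, function(s) {
    sim <- generate_paired_scans(paired_scan_config(
      n_subjects = 47, true_density_mean = 0.22,
      within_subject_sd = sw_true, seed = s))
    ci <- sw_confidence_interval(within_subject_sd(sim), 47)
    ci[1] <= sw_true && sw_true <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.98)
})

test_that("paired mean-difference test matches the textbook t formula", {
  pairs <- data.frame(value_1 = c(0.11, 0.22, 0.33, 0.44),
                      value_2 = c(0.10, 0.20, 0.30, 0.40))
  res <- mean_difference_test(pairs)
  d <- pairs$value_1 - pairs$value_2   # 0.01 0.02 0.03 0.04
  tstat <- mean(d) / (sd(d) / sqrt(4))
  p_ref <- 2 * stats::pt(-abs(tstat), df = 3)
  expect_equal(res$p_value, p_ref)
  expect_equal(res$mean_difference, mean(d))
  half <- stats::qt(0.975, 3) * sd(d) / sqrt(4)
  expect_equal(res$ci, c(mean(d) - half, mean(d) + half))

  # two-sided symmetry under swapping the scans
  swapped <- data.frame(value_1 = pairs$value_2, value_2 = pairs$value_1)
  expect_equal(mean_difference_test(swapped)$p_value, res$p_value)

  # degenerate: identical pairs
  same <- data.frame(value_1 = c(0.2, 0.3), value_2 = c(0.2, 0.3))
  res0 <- mean_difference_test(same)
  expect_identical(res0$mean_difference, 0)
  expect_identical(res0$ci, c(0, 0))
  expect_identical(res0$p_value, 1)
  expect_true(res0$degenerate)
})

make_cohort <- function(seed = 7, n = 30, scan_type = "macula") {
  segs <- segment_labels(scan_type)
  regions <- c("segment", "superior", "inferior", "nasal", "temporal")
  grid <- expand.grid(region = regions, segment_label = segs,
                      eye = c("OD", "OS"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- generate_paired_scans(paired_scan_config(n_subjects = n,
                                                    seed = seed + i))
    cbind(grid[rep(i, n), ], sim[, c("subject_id", "value_1", "value_2")],
          scan_type = scan_type, row.names = NULL)
  })
  do.call(rbind, rows)
}

test_that("repeatability report has full deterministic structure", {
  pairs <- make_cohort()
  rep <- suppressMessages(repeatability_report(pairs))
  expect_identical(nrow(rep), 40L)   # 2 eyes x 4 segments x 5 regions
  expect_identical(rep$eye, rep(c("OD", "OS"), each = 20))
  expect_identical(rep$region[1:5], c("segment", "superior", "inferior",
                                      "nasal", "temporal"))
  # definitional identity, exact
  expect_equal(rep$repeatability, 1.96 * sqrt(2) * rep$sw)
  expect_equal(rep$cv, rep$sw / rep$overall_mean)
  # CIs contain their point estimates
  expect_true(all(rep$sw_lo <= rep$sw & rep$sw <= rep$sw_hi))
  expect_true(all(rep$mean_difference_lo <= rep$mean_difference &
                    rep$mean_difference <= rep$mean_difference_hi))
  # CV decreases when all measurements shift upward
  shifted <- pairs
  shifted$value_1 <- shifted$value_1 + 0.3
  shifted$value_2 <- shifted$value_2 + 0.3
  rep2 <- suppressMessages(repeatability_report(shifted))
  expect_true(all(rep2$cv < rep$cv))
  # optional BH column
  rep3 <- suppressMessages(repeatability_report(pairs, adjust = TRUE))
  expect_true(all(rep3$p_adjusted >= rep3$p_value))
})

test_that("report keeps under-filled groups as NA rows and recovers sigma_w", {
  pairs <- make_cohort(n = 20)
  # knock one group down to a single subject
  drop <- pairs$eye == "OD" & pairs$segment_label == "deep_retina" &
    pairs$region == "nasal" & pairs$subject_id != "S001"
  pairs <- pairs[!drop, ]
  rep <- suppressMessages(repeatability_report(pairs))
  expect_identical(nrow(rep), 40L)   # row emitted, not dropped
  na_row <- rep[rep$eye == "OD" & rep$segment_label == "deep_retina" &
                  rep$region == "nasal", ]
  expect_true(is.na(na_row$sw))
  expect_identical(na_row$n, 1L)

  # sigma_w recovery on a large simulated group (chi-squared band, df = n)
  sim <- generate_paired_scans(paired_scan_config(n_subjects = 500,
                                                  within_subject_sd = 0.02,
                                                  seed = 99))
  sim$eye <- "OD"; sim$segment_label <- "deep_retina"
  sim$region <- "segment"; sim$scan_type <- "macula"
  r1 <- suppressMessages(repeatability_report(sim))
  lo <- 0.02 * sqrt(qchisq(0.025, 500) / 500)
  hi <- 0.02 * sqrt(qchisq(0.975, 500) / 500)
  expect_true(r1$sw >= lo && r1$sw <= hi)
})
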