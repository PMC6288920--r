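#' Within-subject standard deviation for two replicates
#'
#' The Bland-Altman two-replicate estimator: with per-subject differences
#' `d_i = value_1i - value_2i`, `Sw = sqrt(sum(d_i^2) / (2 n))`. This equals
#' the square root of the one-way within-subject mean square, so it is the
#' standard companion of the repeatability coefficient `1.96 sqrt(2) Sw`.
#'
#' @param pairs Data frame with columns `value_1` and `value_2`; rows with a
#'   missing member are excluded with a warning.
#' @return The non-negative estimate `sw`.
#' @examples
#' within_subject_sd(data.frame(value_1 = c(0.1, 0.3),
#'                              value_2 = c(0.2, 0.3)))  # 0.05
#' @export
within_subject_sd <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("value_1", "value_2") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("value_1", "value_2")])
  if (any(!ok))
    warning(sum(!ok), " subject(s) with an incomplete pair excluded")
  d <- pairs$value_1[ok] - pairs$value_2[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  sqrt(sum(d^2) / (2 * n))
}

#' Repeatability coefficient
#'
#' `1.96 * sqrt(2) * sw`: the value below which the absolute difference
#' between two repeated measurements on the same subject falls with 95%
#' probability.
#'
#' @param sw Within-subject standard deviation (>= 0).
#' @return The repeatability coefficient, on the scale of `sw`.
#' @examples
#' round(repeatability_coefficient(0.008), 3)  # 0.022
#' @export
repeatability_coefficient <- function(sw) {
  if (any(sw < 0)) stop("`sw` must be >= 0", call. = FALSE)
  1.96 * sqrt(2) * sw
}

#' Within-subject coefficient of variation
#'
#' `CV = sw / overall_mean`, where the overall mean is taken over both
#' scans' values across subjects. Stored as a fraction; display layers
#' multiply by 100.
#'
#' @param sw Within-subject standard deviation.
#' @param overall_mean Mean of all measurements (> 0).
#' @return The CV as a fraction.
#' @export
coefficient_of_variation <- function(sw, overall_mean) {
  if (any(overall_mean <= 0))
    stop("`overall_mean` must be > 0", call. = FALSE)
  sw / overall_mean
}

#' Confidence interval for the within-subject SD
#'
#' `method = "normal"` (default) uses the large-sample approximation for an
#' SD with `n (m - 1) = n` degrees of freedom at `m = 2` replicates:
#' `sw * (1 -+ 1.96 / sqrt(2 n))`, floored at 0. `method = "chisq"` uses
#' the exact pivot `n sw^2 / sigma^2 ~ chi-squared(n)`. CIs for the CV and
#' the repeatability coefficient are obtained by applying their linear
#' transforms to these bounds.
#'
#' @param sw Within-subject standard deviation (>= 0).
#' @param n Number of subjects (>= 2).
#' @param level Confidence level (default 0.95).
#' @param method `"normal"` or `"chisq"`.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' sw_confidence_interval(0.05, 50)  # c(0.0402, 0.0598)
#' @export
sw_confidence_interval <- function(sw, n, level = 0.95,
                                   method = c("normal", "chisq")) {
  method <- match.arg(method)
  if (sw < 0) stop("`sw` must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (method == "normal") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    half <- z / sqrt(2 * n)
    c(max(0, sw * (1 - half)), sw * (1 + half))
  } else {
    a <- (1 - level) / 2
    # df = n(m-1) with m = 2 replicates
    c(sw * sqrt(n / qchisq(1 - a, n)), sw * sqrt(n / qchisq(a, n)))
  }
}

#' Paired-difference test between first and repeat scan
#'
#' Mean of the per-subject differences `d_i = value_1i - value_2i`, its 95%
#' t-interval, and the two-sided paired t-test p-value on `n - 1` degrees
#' of freedom. When every difference is zero the result is degenerate:
#' mean 0, interval (0, 0), p-value 1, `degenerate = TRUE`. (Differences
#' that are constant but non-zero are likewise flagged, with a p-value of
#' 0.)
#'
#' @param pairs Data frame with columns `value_1`, `value_2`.
#' @param level Confidence level for the interval (default 0.95).
#' @return List with `mean_difference`, `ci` (length 2), `p_value`,
#'   `degenerate`, `n`.
#' @export
mean_difference_test <- function(pairs, level = 0.95) {
  stopifnot(is.data.frame(pairs),
            all(c("value_1", "value_2") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("value_1", "value_2")])
  d <- pairs$value_1[ok] - pairs$value_2[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (sd(d) == 0) {
    m <- mean(d)
    return(list(mean_difference = m, ci = c(m, m),
                p_value = if (m == 0) 1 else 0,
                degenerate = TRUE, n = n))
  }
  tt <- t.test(d, conf.level = level)
  list(mean_difference = unname(tt$estimate),
       ci = as.numeric(tt$conf.int),
       p_value = tt$p.value,
       degenerate = FALSE, n = n)
}

#' Test-retest repeatability report per region
#'
#' Groups paired measurements by (eye, segment, region) and computes, per
#' group: the overall mean over both scans, the mean scan difference with
#' its 95% CI and paired t-test p-value, the within-subject SD `Sw` with
#' CI, the coefficient of variation `CV = Sw / overall mean` with CI, and
#' the repeatability coefficient `1.96 sqrt(2) Sw` with CI. Groups with
#' fewer than two usable pairs are emitted with `NA` statistics rather
#' than silently dropped. Row order is deterministic: eye (OD, OS), then
#' the canonical segment order, then segment, superior, inferior, nasal,
#' temporal.
#'
#' @param pairs Data frame with columns `subject_id`, `eye`,
#'   `segment_label`, `region`, `value_1`, `value_2`, and optionally
#'   `scan_type` (used to pick the canonical segment order).
#' @param ci_method CI construction for `Sw`; see
#'   [sw_confidence_interval()].
#' @param adjust Add a Benjamini-Hochberg adjusted p-value column
#'   (`p_adjusted`) across the report's paired tests (off by default, as
#'   repeatability studies conventionally report unadjusted paired tests).
#' @return A data frame, one row per (eye, segment, region), with columns
#'   `eye`, `segment_label`, `region`, `n`, `overall_mean`,
#'   `mean_difference`, `mean_difference_lo`, `mean_difference_hi`,
#'   `p_value`, `sw`, `sw_lo`, `sw_hi`, `cv`, `cv_lo`, `cv_hi`,
#'   `repeatability`, `repeatability_lo`, `repeatability_hi`.
#' @export
repeatability_report <- function(pairs, ci_method = c("normal", "chisq"),
                                 adjust = FALSE) {
  ci_method <- match.arg(ci_method)
  needed <- c("subject_id", "eye", "segment_label", "region",
              "value_1", "value_2")
  stopifnot(is.data.frame(pairs), all(needed %in% names(pairs)))
  scan_type <- if ("scan_type" %in% names(pairs))
    unique(pairs$scan_type)[1] else NULL
  seg_order <- if (!is.null(scan_type) &&
                   scan_type %in% c("macula", "disc")) {
    segment_labels(scan_type)
  } else {
    c(segment_labels("macula"), segment_labels("disc"))
  }
  seg_levels <- c(intersect(seg_order, unique(pairs$segment_label)),
                  setdiff(unique(pairs$segment_label), seg_order))
  eye_levels <- intersect(c("OD", "OS"), unique(pairs$eye))
  reg_levels <- intersect(region_order, unique(pairs$region))
  groups <- expand.grid(region = reg_levels, segment_label = seg_levels,
                        eye = eye_levels, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  groups <- groups[, c("eye", "segment_label", "region")]
  groups <- groups[order(match(groups$eye, eye_levels),
                         match(groups$segment_label, seg_levels),
                         match(groups$region, reg_levels)), ]
  used <- 0L
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- pairs[pairs$eye == g$eye &
                   pairs$segment_label == g$segment_label &
                   pairs$region == g$region, ]
    sub <- sub[stats::complete.cases(sub[, c("value_1", "value_2")]), ]
    base <- data.frame(eye = g$eye, segment_label = g$segment_label,
                       region = g$region, n = nrow(sub),
                       stringsAsFactors = FALSE)
    if (nrow(sub) < 2L) {
      na <- NA_real_
      return(cbind(base, data.frame(
        overall_mean = na, mean_difference = na, mean_difference_lo = na,
        mean_difference_hi = na, p_value = na, sw = na, sw_lo = na,
        sw_hi = na, cv = na, cv_lo = na, cv_hi = na, repeatability = na,
        repeatability_lo = na, repeatability_hi = na)))
    }
    used <<- used + nrow(sub)
    overall_mean <- mean(c(sub$value_1, sub$value_2))
    sw <- within_subject_sd(sub)
    sw_ci <- sw_confidence_interval(sw, nrow(sub), method = ci_method)
    md <- mean_difference_test(sub)
    rc <- repeatability_coefficient(sw)
    rc_ci <- repeatability_coefficient(sw_ci)
    cv <- coefficient_of_variation(sw, overall_mean)
    cv_ci <- coefficient_of_variation(sw_ci, overall_mean)
    cbind(base, data.frame(
      overall_mean = overall_mean,
      mean_difference = md$mean_difference,
      mean_difference_lo = md$ci[1], mean_difference_hi = md$ci[2],
      p_value = md$p_value,
      sw = sw, sw_lo = sw_ci[1], sw_hi = sw_ci[2],
      cv = cv, cv_lo = cv_ci[1], cv_hi = cv_ci[2],
      repeatability = rc, repeatability_lo = rc_ci[1],
      repeatability_hi = rc_ci[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  message(sprintf(
    "repeatability audit: %d input pairs -> %d rows (%d with >= 2 pairs)",
    used, nrow(out), sum(!is.na(out$sw))))
  out
}
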