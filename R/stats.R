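# Cohort-level descriptive and inferential statistics for embolic-event
# analyses: medians with inverse-ECDF quartiles, paired left-vs-right
# comparison, procedure-group rank-sum comparison, and bubble-size
# distribution summaries.

#' Median and interquartile range (inverse-ECDF quartiles)
#'
#' The median is the standard sample median (mean of the central pair for
#' even n). Quartiles are the order statistics at positions `ceil(0.25 n)`
#' and `ceil(0.75 n)` (inverse empirical-CDF convention), the convention
#' under which clinical count tables typically report IQRs.
#'
#' @param values Numeric vector, length >= 1.
#' @param round_half_up Round the median half-up to an integer, as done when
#'   reporting event counts (default FALSE).
#' @return Named vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(c(502, 349, 2785, 409, 2080, 480, 674, 196, 950, 284))
#' @export
median_iqr <- function(values, round_half_up = FALSE) {
  if (length(values) < 1 || any(!is.finite(values))) {
    stop("values must be a non-empty finite numeric vector", call. = FALSE)
  }
  s <- sort(values)
  n <- length(s)
  med <- stats::median(s)
  if (round_half_up) med <- floor(med + 0.5)
  c(median = med,
    q1 = s[ceiling(0.25 * n)],
    q3 = s[ceiling(0.75 * n)])
}

#' Paired t-test statistic
#'
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` with `n - 1` degrees of freedom
#' and a two-sided p-value. Swapping the arguments negates `t`. Zero
#' variance of the differences leaves the statistic undefined and raises an
#' error.
#'
#' @param a,b Paired numeric vectors of equal length, n >= 2.
#' @return Named list `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  stopifnot("a and b must have equal length" = length(a) == length(b),
            "need n >= 2 pairs" = length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("differences have zero variance; paired t is undefined",
         call. = FALSE)
  }
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Wilcoxon rank-sum z statistic (normal approximation)
#'
#' Midranks for ties, tie-corrected variance, no continuity correction. The
#' statistic is signed with the first group's rank-sum deficit:
#' `z = (mu_W - W1) / sigma_W`, where `W1` is the first group's rank sum and
#' `mu_W` its null expectation, so a first group with systematically larger
#' values yields a negative z. The z value is invariant under any strictly
#' monotone transform of the pooled data.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return Named list `z`, `p` (two-sided, normal approximation).
#' @export
ranksum_z <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  if (v == 0) return(list(z = 0, p = 1))
  z <- (mu - w1) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Summarise a bubble-size distribution
#'
#' Median and inverse-ECDF quartiles of the diameters, the fractions below /
#' above the clinically quoted thresholds (strictly less than 100 um;
#' strictly greater than 500 um and 1 mm), and optional per-stage medians.
#'
#' @param sized Data frame with a `diameter_um` column (e.g. from
#'   [size_stream()] or [invert_mebr()]); an optional `stage` column yields
#'   per-stage medians.
#' @return A list of class `size_distribution_summary`.
#' @export
size_distribution <- function(sized) {
  d <- sized$diameter_um
  d <- d[is.finite(d)]
  if (length(d) < 1) stop("no finite diameters", call. = FALSE)
  mq <- median_iqr(d)
  out <- list(
    n = length(d),
    median_um = unname(mq["median"]),
    q1_um = unname(mq["q1"]),
    q3_um = unname(mq["q3"]),
    frac_below_100um = mean(d < 100),
    frac_above_500um = mean(d > 500),
    frac_above_1mm = mean(d > 1000),
    stage_medians_um = if (!is.null(sized$stage)) {
      tapply(sized$diameter_um, sized$stage, stats::median)
    } else NULL
  )
  class(out) <- "size_distribution_summary"
  out
}

#' Cohort report: totals, group comparison and left-right symmetry
#'
#' Computes per-patient totals (left + right), the cohort minimum / maximum
#' / medians with IQRs (inverse-ECDF convention, count medians rounded
#' half-up), the left-vs-right paired t-test, and the intra-cardiac versus
#' CABG-only rank-sum comparison. Group "means" are reported alongside group
#' medians because small-cohort summaries sometimes label medians as means.
#'
#' @param cohort Data frame with one row per patient and columns `id`,
#'   `procedure` (containing `"MVR"`/`"AVR"` marks intra-cardiac),
#'   `n_left`, `n_right`, and optionally `total_volume_ml`.
#' @return A list of class `cohort_report`.
#' @export
cohort_report <- function(cohort) {
  stopifnot(nrow(cohort) >= 1,
            all(c("id", "procedure", "n_left", "n_right") %in% names(cohort)))
  totals <- cohort$n_left + cohort$n_right
  intra <- grepl("MVR|AVR|valve|combined", cohort$procedure,
                 ignore.case = TRUE)
  out <- list(
    n_patients = nrow(cohort),
    totals = stats::setNames(totals, cohort$id),
    min_total = min(totals),
    max_total = max(totals),
    left = median_iqr(cohort$n_left, round_half_up = TRUE),
    right = median_iqr(cohort$n_right, round_half_up = TRUE),
    left_vs_right = if (nrow(cohort) >= 2 &&
                          stats::sd(cohort$n_left - cohort$n_right) > 0) {
      paired_t(cohort$n_left, cohort$n_right)
    } else NULL,
    group_comparison = if (any(intra) && any(!intra)) {
      c(list(intra_median = unname(median_iqr(totals[intra])["median"]),
             intra_mean = mean(totals[intra]),
             cabg_median = unname(median_iqr(totals[!intra])["median"]),
             cabg_mean = mean(totals[!intra])),
        ranksum_z(totals[intra], totals[!intra]))
    } else NULL,
    volume_range_ml = if (!is.null(cohort$total_volume_ml)) {
      range(cohort$total_volume_ml)
    } else NULL
  )
  class(out) <- "cohort_report"
  out
}

#' Built-in reference cohort
#'
#' Per-patient bilateral embolic counts, procedures and total air volumes
#' for a ten-patient cardiac-surgery monitoring cohort, shipped as a
#' plain-text example dataset for the cohort statistics.
#'
#' @return Data frame with columns `id`, `procedure`, `mca_left_mm`,
#'   `mca_right_mm`, `n_left`, `n_right`, `total_volume_ml`.
#' @examples
#' cohort_report(reference_cohort())
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv",
                      package = "mcaemboli", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
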