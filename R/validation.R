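# Evaluation arithmetic for a dosing-protocol audit: measured-vs-predicted
# agreement, per-group dose summaries, patient-flow accounting, the
# two-analyst LVEF agreement rule, reading averaging, and paravenous
# flagging.

#' Straight-line agreement between measured and predicted count rate
#'
#' Ordinary least-squares fit of `y` on `x` with the squared Pearson
#' correlation as R-squared — the standard calibration check for a
#' count-rate prediction algorithm (ideal agreement: slope 1, intercept 0).
#'
#' @param x predicted count rates (kcps).
#' @param y measured count rates (kcps).
#' @return A list of class `erna_regression` with `slope`, `intercept`
#'   (kcps), `r_squared`, and `n`.
#' @examples
#' linear_fit(c(1, 2, 3), c(3, 5, 7))  # slope 2, intercept 1, R^2 1
#' @export
linear_fit <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::var(x) == 0) stop("x is degenerate (no variance)", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 n = length(x)),
            class = "erna_regression")
}

#' @export
print.erna_regression <- function(x, ...) {
  cat(sprintf("linear fit (n = %d): slope %.4f, intercept %.4f kcps, R^2 %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Summarise planned doses for a group
#'
#' Mean, sample SD (n - 1 denominator), and SEE = SD / sqrt(n) of the
#' planned activity; floor usage; and mean predicted (and, when supplied,
#' measured) count rates — the per-group summary layout of a dosing audit
#' table. A single-plan group reports SD 0 with `degenerate = TRUE`.
#'
#' @param plans an `erna_dose_plan` data frame from [plan_dose()].
#' @param measured_kcps optional vector of measured count rates aligned with
#'   `plans`.
#' @return A list of class `erna_dose_summary`.
#' @export
summarize_doses <- function(plans, measured_kcps = NULL) {
  if (is.null(plans) || nrow(plans) == 0)
    stop("no plans to summarise", call. = FALSE)
  n <- nrow(plans)
  doses <- plans$planned_dose_MBq
  degenerate <- n < 2
  sd_dose <- if (degenerate) 0 else stats::sd(doses)
  structure(list(
    n = n,
    mean_dose_MBq = mean(doses),
    sd_dose_MBq = sd_dose,
    see_dose_MBq = sd_dose / sqrt(n),
    floor_count = sum(plans$floor_applied),
    floor_fraction = mean(plans$floor_applied),
    mean_predicted_kcps = mean(plans$predicted_count_rate_kcps, na.rm = TRUE),
    mean_measured_kcps = if (is.null(measured_kcps)) NA_real_
                         else mean(measured_kcps, na.rm = TRUE),
    degenerate = degenerate
  ), class = "erna_dose_summary")
}

#' Patient-flow accounting for a multi-group study
#'
#' Conservation identity of a referral flow table: per group and in total,
#' `individualized = referred - exclusions - standard_dose`, with
#' `included = individualized + standard_dose` (patients actually scanned on
#' the study protocol). Negative remainders are an accounting error.
#'
#' @param referred patients referred, per group.
#' @param excluded_fdg,excluded_nai_spect,excluded_nai_planar,excluded_dose_mismatch
#'   exclusion counts per group (recycled if scalar).
#' @param standard_dose patients scanned at the standard activity, per group.
#' @param group_labels optional group names.
#' @return A list of class `erna_flow` with a per-group data frame and the
#'   totals `referred`, `excluded`, `standard_dose`, `individualized`,
#'   `included`.
#' @export
cohort_flow <- function(referred,
                        excluded_fdg = 0, excluded_nai_spect = 0,
                        excluded_nai_planar = 0, excluded_dose_mismatch = 0,
                        standard_dose = 0,
                        group_labels = NULL) {
  k <- length(referred)
  tab <- data.frame(
    group = if (is.null(group_labels)) as.character(seq_len(k)) else group_labels,
    referred = referred,
    excluded_fdg = rep_len(excluded_fdg, k),
    excluded_nai_spect = rep_len(excluded_nai_spect, k),
    excluded_nai_planar = rep_len(excluded_nai_planar, k),
    excluded_dose_mismatch = rep_len(excluded_dose_mismatch, k),
    standard_dose = rep_len(standard_dose, k)
  )
  counts <- tab[-1]
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("flow counts must be non-negative integers", call. = FALSE)
  excl <- tab$excluded_fdg + tab$excluded_nai_spect +
    tab$excluded_nai_planar + tab$excluded_dose_mismatch
  tab$individualized <- tab$referred - excl - tab$standard_dose
  if (any(tab$individualized < 0))
    stop("inconsistent flow counts: exclusions and standard doses exceed referrals",
         call. = FALSE)
  tab$included <- tab$individualized + tab$standard_dose
  structure(list(
    per_group = tab,
    referred = sum(tab$referred),
    excluded = sum(excl),
    standard_dose = sum(tab$standard_dose),
    individualized = sum(tab$individualized),
    included = sum(tab$included)
  ), class = "erna_flow")
}

#' Mean of the three on-screen count-rate readings
#'
#' An acquisition's count rate is taken as the arithmetic mean of three
#' readings (beginning, middle, end of the acquisition).
#'
#' @param readings numeric vector of exactly 3 positive count rates (kcps).
#' @return The mean count rate (kcps).
#' @export
mean_count_rate <- function(readings) {
  if (length(readings) != 3L)
    stop("exactly 3 readings are required", call. = FALSE)
  if (any(is.na(readings)) || any(readings <= 0))
    stop("readings must be strictly positive", call. = FALSE)
  mean(readings)
}

#' Two-analyst LVEF agreement rule
#'
#' Two independent LVEF analyses agree sufficiently when they differ by no
#' more than the tolerance (default 2 percentage points); a difference of
#' exactly the tolerance still counts as sufficient ("more than" is strict).
#' Insufficient agreement triggers further analyses in clinical practice.
#'
#' @param lvef_a,lvef_b LVEF values in percent, each in \[0, 100\].
#' @param tolerance_pp agreement tolerance in percentage points.
#' @return `"sufficient"` or `"insufficient"` (vectorised).
#' @export
lvef_agreement <- function(lvef_a, lvef_b, tolerance_pp = 2) {
  if (any(c(lvef_a, lvef_b) < 0) || any(c(lvef_a, lvef_b) > 100))
    stop("LVEF must lie in [0, 100] percent", call. = FALSE)
  ifelse(abs(lvef_a - lvef_b) <= tolerance_pp, "sufficient", "insufficient")
}

#' Flag a suspected paravenous injection
#'
#' A measured count rate far below prediction suggests the tracer infiltrated
#' tissue at the injection site instead of the vein. Flags acquisitions whose
#' measured/predicted ratio falls strictly below the threshold. The default
#' threshold 0.5 keeps the false-flag rate of ordinary measurement noise well
#' under 1%.
#'
#' @param measured_kcps,predicted_kcps strictly positive count rates
#'   (vectorised).
#' @param ratio_threshold flag when `measured / predicted <` this value.
#' @return Logical vector.
#' @export
flag_paravenous <- function(measured_kcps, predicted_kcps, ratio_threshold = 0.5) {
  if (any(measured_kcps <= 0) || any(predicted_kcps <= 0))
    stop("count rates must be strictly positive", call. = FALSE)
  measured_kcps / predicted_kcps < ratio_threshold
}
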