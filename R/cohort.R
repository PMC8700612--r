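# Synthetic patient cohorts and the count-rate measurement noise model.
# Cohorts emulate the published per-target-count-rate group marginals
# (female fraction; mean/SD of age, height, weight); measured count rates are
# simulated as predicted * exp(eps) with eps ~ N(0, sigma^2), sigma
# calibrated so the straight-line fit of measured on predicted attains a
# requested R^2.

#' Parameters of a synthetic patient cohort
#'
#' Marginal distributions for cohort generation: sex is Bernoulli in the
#' female fraction; age, height, and weight are drawn independently from
#' normal distributions truncated to the plausibility bounds.
#'
#' @param n number of patients.
#' @param female_fraction probability of drawing a female patient.
#' @param age_mean,age_sd years.
#' @param height_mean,height_sd cm.
#' @param weight_mean,weight_sd kg.
#' @param bounds truncation bounds, defaulting to [patient_bounds()].
#' @param seed optional integer seed; [generate_cohort()] uses it when no
#'   explicit seed is passed.
#' @return An object of class `erna_cohort_params`.
#' @export
cohort_parameters <- function(n, female_fraction,
                              age_mean, age_sd,
                              height_mean, height_sd,
                              weight_mean, weight_sd,
                              bounds = patient_bounds(),
                              seed = NULL) {
  stopifnot(n >= 1, female_fraction >= 0, female_fraction <= 1,
            age_sd >= 0, height_sd >= 0, weight_sd >= 0)
  means <- c(age_years = age_mean, height_cm = height_mean,
             weight_kg = weight_mean)
  sds <- c(age_years = age_sd, height_cm = height_sd, weight_kg = weight_sd)
  for (v in names(means)) {
    lo <- bounds[[v]][1]; hi <- bounds[[v]][2]
    if (sds[[v]] > 0 &&
        (means[[v]] < lo - 5 * sds[[v]] || means[[v]] > hi + 5 * sds[[v]]))
      stop(sprintf("infeasible truncation for %s: mean %g lies > 5 SD outside [%g, %g]",
                   v, means[[v]], lo, hi), call. = FALSE)
    if (sds[[v]] == 0 && (means[[v]] < lo || means[[v]] > hi))
      stop(sprintf("degenerate %s mean %g outside bounds", v, means[[v]]),
           call. = FALSE)
  }
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 bounds = bounds, seed = seed),
            class = "erna_cohort_params")
}

#' Packaged cohort presets for the published target-count-rate groups
#'
#' One preset per study group, carrying the group's size, female fraction,
#' and anthropometric means/SDs, together with the group's target count rate
#' and the weight threshold in force during that period (the earliest,
#' highest-target group was dosed with the weight-squared equation alone, so
#' its threshold is 0; the standard-dose group has no target and is planned
#' at the 550 MBq reference activity).
#'
#' @param name one of `"1.0"`, `"1.5"`, `"1.7"`, `"2.0"`, `"2.7"`,
#'   `"standard"`.
#' @return A list with elements `params` (an `erna_cohort_params`),
#'   `target_count_rate_kcps` (`NA` for `"standard"`) and
#'   `weight_threshold_kg`.
#' @examples
#' cohort_preset("1.7")$params$n  # 432
#' @export
cohort_preset <- function(name = c("1.0", "1.5", "1.7", "2.0", "2.7", "standard")) {
  name <- match.arg(as.character(name), c("1.0", "1.5", "1.7", "2.0", "2.7", "standard"))
  tab <- list(
    "1.0"      = list(n = 314, f = 0.685, a = c(59.6, 15.1), h = c(168.9, 8.9), w = c(74.8, 16.0), crt = 1.0, thr = 73),
    "1.5"      = list(n = 286, f = 0.664, a = c(61.0, 14.5), h = c(169.2, 8.6), w = c(74.7, 16.8), crt = 1.5, thr = 73),
    "1.7"      = list(n = 432, f = 0.697, a = c(61.0, 14.2), h = c(168.5, 8.7), w = c(73.5, 14.9), crt = 1.7, thr = 73),
    "2.0"      = list(n = 285, f = 0.656, a = c(60.6, 14.8), h = c(169.5, 8.6), w = c(75.7, 16.6), crt = 2.0, thr = 73),
    "2.7"      = list(n = 250, f = 0.652, a = c(61.4, 13.9), h = c(169.2, 8.9), w = c(75.1, 17.2), crt = 2.7, thr = 0),
    "standard" = list(n = 83,  f = 0.651, a = c(61.2, 14.3), h = c(170.0, 9.2), w = c(74.3, 14.9), crt = NA_real_, thr = 73)
  )[[name]]
  list(
    params = cohort_parameters(tab$n, tab$f, tab$a[1], tab$a[2],
                               tab$h[1], tab$h[2], tab$w[1], tab$w[2]),
    target_count_rate_kcps = tab$crt,
    weight_threshold_kg = tab$thr
  )
}

# inverse-CDF sampler for a normal truncated to [lo, hi]
rtruncated_normal <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the seed: the same seed yields an identical cohort.
#' Age, height, and weight are independent truncated normals; sex is
#' Bernoulli. For n >= 100 the empirical moments land within a few standard
#' errors of the targets.
#'
#' @param params an [cohort_parameters()] object (or the `params` element of
#'   a [cohort_preset()]).
#' @param seed integer seed; defaults to the seed stored in `params`.
#' @param id_prefix prefix for the generated patient ids.
#' @return An `erna_patients` data frame with `params$n` rows.
#' @export
generate_cohort <- function(params, seed = params$seed, id_prefix = "syn") {
  stopifnot(inherits(params, "erna_cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  b <- params$bounds
  sex <- ifelse(stats::runif(n) < params$female_fraction, "female", "male")
  age <- rtruncated_normal(n, params$age_mean, params$age_sd,
                           b$age_years[1], b$age_years[2])
  height <- rtruncated_normal(n, params$height_mean, params$height_sd,
                              b$height_cm[1], b$height_cm[2])
  weight <- rtruncated_normal(n, params$weight_mean, params$weight_sd,
                              b$weight_kg[1], b$weight_kg[2])
  as_patients(data.frame(
    id = sprintf("%s%04d", id_prefix, seq_len(n)),
    sex = sex, age_years = age, height_cm = height, weight_kg = weight
  ), bounds = b)
}

#' Measurement noise model for simulated count rates
#'
#' Multiplicative log-normal noise on the predicted count rate, plus a rare
#' paravenous-injection branch that attenuates the measured rate by a fixed
#' factor (tracer infiltrating tissue at the injection site produces a far
#' lower count rate than predicted). The default paravenous probability,
#' 10/1650, matches the observed clinical frequency; the attenuation factor
#' is a configurable model choice.
#'
#' @param sigma_log SD of the log-scale noise (dimensionless, natural log).
#' @param paravenous_probability per-acquisition probability of a paravenous
#'   event.
#' @param paravenous_attenuation multiplicative factor in (0, 1) applied to
#'   affected acquisitions.
#' @return An object of class `erna_noise_model`.
#' @export
noise_model <- function(sigma_log,
                        paravenous_probability = 10 / 1650,
                        paravenous_attenuation = 0.5) {
  stopifnot(sigma_log >= 0,
            paravenous_probability >= 0, paravenous_probability <= 1,
            paravenous_attenuation > 0, paravenous_attenuation < 1)
  structure(list(sigma_log = sigma_log,
                 paravenous_probability = paravenous_probability,
                 paravenous_attenuation = paravenous_attenuation),
            class = "erna_noise_model")
}

# Large-sample R^2 of the straight-line fit of x*exp(eps) on x,
# eps ~ N(0, sigma^2), for a sample x with the given mean and variance:
#   rho^2 = s / ((s + mu^2) * e - mu^2),  e = exp(sigma^2), s = Var(x).
expected_fit_r2 <- function(sigma, x_mean, x_var) {
  e <- exp(sigma^2)
  x_var / ((x_var + x_mean^2) * e - x_mean^2)
}

#' Calibrate the log-noise SD to a target agreement R-squared
#'
#' Finds the `sigma_log` such that, in large samples, the squared Pearson
#' correlation between predicted rates `x` and noisy measurements
#' `x * exp(eps)` equals `target_r2`. The expected R-squared is a strictly
#' decreasing function of sigma, so the value is located by monotone
#' root-finding (bisection via [stats::uniroot()]) on the closed large-sample
#' expression evaluated at the sample moments of `predicted_rates`.
#'
#' @param target_r2 requested R-squared, in (0, 1).
#' @param predicted_rates the predicted count rates (kcps) of the cohort to
#'   be simulated; at least two distinct values are required.
#' @param tol root-finding tolerance on sigma.
#' @return `sigma_log`, reproducible to `tol`.
#' @examples
#' x <- c(1.0, 1.5, 1.7, 2.0, 2.7, 4.0)
#' calibrate_noise_sigma(0.8, x)
#' @export
calibrate_noise_sigma <- function(target_r2, predicted_rates, tol = 1e-8) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  x <- predicted_rates[!is.na(predicted_rates)]
  if (length(unique(x)) < 2)
    stop("predicted rates carry no variance; noise cannot be calibrated",
         call. = FALSE)
  mu <- mean(x); s <- stats::var(x)
  f <- function(sig) expected_fit_r2(sig, mu, s) - target_r2
  upper <- 1
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

#' Simulate measured acquisition count rates
#'
#' Draws `measured = predicted * exp(eps)`, `eps ~ N(0, sigma_log^2)`; with
#' the configured probability an acquisition is additionally attenuated by
#' the paravenous factor and tagged.
#'
#' @param predicted_kcps strictly positive predicted count rates.
#' @param noise an [noise_model()] object.
#' @param seed optional integer seed.
#' @return Data frame with columns `measured_kcps` and `paravenous`.
#' @export
simulate_measured_count_rate <- function(predicted_kcps, noise, seed = NULL) {
  stopifnot(inherits(noise, "erna_noise_model"))
  if (any(is.na(predicted_kcps)) || any(predicted_kcps <= 0))
    stop("predicted_kcps must be strictly positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(predicted_kcps)
  eps <- stats::rnorm(n, 0, noise$sigma_log)
  paravenous <- stats::runif(n) < noise$paravenous_probability
  measured <- predicted_kcps * exp(eps)
  measured[paravenous] <- measured[paravenous] * noise$paravenous_attenuation
  data.frame(measured_kcps = measured, paravenous = paravenous)
}

#' Simulate a full multi-group study cohort
#'
#' Generates every requested preset group, plans each patient's activity with
#' the group's target count rate and weight threshold, and (optionally)
#' simulates measured count rates. This is the harness behind the package's
#' cohort-level validation statistics: with all six presets it reconstitutes
#' a 1650-patient mixed cohort.
#'
#' @param presets character vector of [cohort_preset()] names.
#' @param seed integer seed governing generation and noise.
#' @param noise an [noise_model()], or `NULL` to skip measurement simulation.
#' @param config base [dose_config()]; each group's target count rate and
#'   weight threshold override it.
#' @return Data frame: patient columns, `group`, `target_count_rate_kcps`,
#'   plan columns, and when noise is simulated `measured_kcps` +
#'   `paravenous`.
#' @export
simulate_study <- function(presets = c("1.0", "1.5", "1.7", "2.0", "2.7", "standard"),
                           seed = 1, noise = NULL,
                           config = dose_config()) {
  set.seed(seed)
  groups <- lapply(presets, function(nm) {
    ps <- cohort_preset(nm)
    cohort <- generate_cohort(ps$params,
                              seed = sample.int(.Machine$integer.max, 1),
                              id_prefix = paste0("g", gsub("[.]", "", nm), "_"))
    cfg <- config
    cfg$target_count_rate_kcps <- ps$target_count_rate_kcps
    cfg$weight_threshold_kg <- ps$weight_threshold_kg
    plan <- suppressMessages(plan_dose(cohort, cfg))
    out <- cbind(as.data.frame(cohort), group = nm,
                 target_count_rate_kcps = ps$target_count_rate_kcps,
                 as.data.frame(plan)[-1])
    out
  })
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  if (!is.null(noise)) {
    sim <- simulate_measured_count_rate(out$predicted_count_rate_kcps, noise,
                                        seed = sample.int(.Machine$integer.max, 1))
    out <- cbind(out, sim)
  }
  out
}
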