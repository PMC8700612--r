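# Worklist / plan / report readers and writers, plus YAML configuration
# loading. Worklists are plain CSV with a header; timestamps are ISO-8601;
# the decimal separator is "." with no locale handling.

worklist_required_cols <- c("id", "sex", "age_years", "height_cm", "weight_kg",
                            "target_count_rate_kcps", "scheduled_time",
                            "actual_time")

#' Read a patient worklist
#'
#' Comma-separated with a header row and columns `id`, `sex` (m/f),
#' `age_years`, `height_cm`, `weight_kg`, `target_count_rate_kcps`,
#' `scheduled_time`, `actual_time` (ISO-8601; `actual_time` may be empty).
#' Extra columns — e.g. simulated `measured_kcps` — are carried through.
#' Height/weight may be empty on a row (the standard-dose fallback applies at
#' planning time); any other invalid field is reported with its row number.
#' By default all row errors are collected into one message; `strict = TRUE`
#' aborts on the first.
#'
#' @param path CSV file path.
#' @param bounds plausibility bounds, see [patient_bounds()].
#' @param strict abort on the first invalid row instead of collecting all.
#' @return A data frame of class `erna_worklist`.
#' @export
read_worklist <- function(path, bounds = patient_bounds(), strict = FALSE) {
  if (!file.exists(path)) stop("worklist file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  miss <- setdiff(worklist_required_cols, names(raw))
  if (length(miss))
    stop("worklist is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0) {
    wl <- raw
    class(wl) <- c("erna_worklist", "data.frame")
    return(wl)
  }
  if (anyDuplicated(raw$id))
    stop("duplicate patient id(s): ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)

  errs <- character(0)
  note <- function(row, field, msg) {
    e <- sprintf("row %d, %s: %s", row, field, msg)
    if (strict) stop(e, call. = FALSE)
    errs <<- c(errs, e)
  }
  num_field <- function(col, required) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    blank <- is.na(raw[[col]]) | trimws(raw[[col]]) == ""
    for (i in seq_len(nrow(raw))) {
      if (blank[i]) {
        if (required) note(i, col, "missing value")
      } else if (is.na(vals[i])) {
        note(i, col, sprintf("not a number: '%s'", raw[[col]][i]))
      }
    }
    vals
  }
  out <- raw
  out$age_years <- num_field("age_years", required = TRUE)
  out$height_cm <- num_field("height_cm", required = FALSE)
  out$weight_kg <- num_field("weight_kg", required = FALSE)
  out$target_count_rate_kcps <- num_field("target_count_rate_kcps",
                                          required = FALSE)
  for (i in seq_len(nrow(out))) {
    s <- try(normalize_sex(out$sex[i]), silent = TRUE)
    if (inherits(s, "try-error")) note(i, "sex",
                                       sprintf("unrecognised: '%s'", out$sex[i]))
    else out$sex[i] <- s
  }
  check_bound <- function(col) {
    v <- out[[col]]
    bad <- !is.na(v) & (v < bounds[[col]][1] | v > bounds[[col]][2])
    for (i in which(bad))
      note(i, col, sprintf("%g outside [%g, %g]", v[i],
                           bounds[[col]][1], bounds[[col]][2]))
  }
  for (col in c("age_years", "height_cm", "weight_kg")) check_bound(col)
  for (col in c("scheduled_time", "actual_time")) {
    blank <- is.na(out[[col]]) | trimws(out[[col]]) == ""
    parsed <- parse_iso8601(out[[col]])
    for (i in which(!blank & is.na(parsed)))
      note(i, col, sprintf("unparseable ISO-8601 timestamp: '%s'", out[[col]][i]))
  }
  if (length(errs))
    stop("invalid worklist rows:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  if ("measured_kcps" %in% names(out))
    out$measured_kcps <- suppressWarnings(as.numeric(out$measured_kcps))
  class(out) <- c("erna_worklist", "data.frame")
  out
}

parse_iso8601 <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    todo <- is.na(out) & !is.na(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
  }
  out
}

#' Write a worklist to CSV
#'
#' @param worklist a worklist data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_worklist <- function(worklist, path) {
  utils::write.csv(as.data.frame(worklist), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Plan every row of a worklist
#'
#' Applies [plan_dose()] with each row's own target count rate, then adjusts
#' each planned activity for the delay between scheduled and actual injection
#' time (rows without an actual time are taken as injected on schedule) and
#' converts the adjusted activity to an effective dose.
#'
#' @param worklist an `erna_worklist` from [read_worklist()].
#' @param config an [dose_config()].
#' @return Data frame with columns `id`, `planned_dose_MBq`,
#'   `equation_used`, `floor_applied`, `cap_applied`,
#'   `reference_count_rate_kcps`, `predicted_count_rate_kcps`,
#'   `decay_adjusted_dose_MBq`, `effective_dose_mSv`.
#' @export
plan_worklist <- function(worklist, config = dose_config()) {
  patients <- as_patients(worklist[c("id", "sex", "age_years", "height_cm",
                                     "weight_kg")], allow_missing = TRUE)
  plans <- plan_dose(patients, config,
                     target_kcps = worklist$target_count_rate_kcps)
  sched <- parse_iso8601(worklist$scheduled_time)
  actual <- parse_iso8601(worklist$actual_time)
  delay <- as.numeric(difftime(actual, sched, units = "mins"))
  delay[is.na(delay)] <- 0
  adj <- decay_adjusted_dose(plans$planned_dose_MBq, delay, config)
  data.frame(
    id = plans$patient_id,
    planned_dose_MBq = plans$planned_dose_MBq,
    equation_used = plans$equation_used,
    floor_applied = plans$floor_applied,
    cap_applied = plans$cap_applied,
    reference_count_rate_kcps = plans$reference_count_rate_kcps,
    predicted_count_rate_kcps = plans$predicted_count_rate_kcps,
    decay_adjusted_dose_MBq = adj,
    effective_dose_mSv = effective_dose(adj, config),
    stringsAsFactors = FALSE
  )
}

#' Read a dose-algorithm configuration file
#'
#' Flat YAML key-value file whose keys mirror the [dose_config()] arguments
#' one-to-one; any key may be omitted and takes its documented default. The
#' `floor_policy` key is a mapping with `crt_min` and `floor_MBq` lists, and
#' `sex_coding` a mapping with `male` and `female` codes.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return An [dose_config()] object.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(dose_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(dose_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$floor_policy))
    raw$floor_policy <- as.data.frame(
      lapply(raw$floor_policy, function(v) as.numeric(unlist(v))))
  if (!is.null(raw$sex_coding))
    raw$sex_coding <- unlist(raw$sex_coding)
  do.call(dose_config, raw)
}
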