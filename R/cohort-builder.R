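# Cohort construction: eligibility filtering, disease-status labelling and
# covariate-matched undersampling into the three classification scenarios.

DEFAULT_KOA_CODES <- c("M17", "M17.0", "M17.1", "M17.9")

#' Apply the eligibility filters
#'
#' Removes participants with (in this order of precedence) any missing or
#' non-finite hourly value, any hourly value strictly greater than
#' `anomaly_max`, or BMI below `bmi_min` (missing BMI fails this rule).
#' Boundary semantics: a reading of exactly `anomaly_max` is kept
#' (rejection requires *exceeding* the threshold); BMI equal to `bmi_min`
#' is kept (inclusive cutoff). Survivor order is preserved and every
#' rejection is logged with the first rule it triggered.
#'
#' @param records Cohort data frame with columns `h00`..`h23` and `bmi`.
#' @param anomaly_max Anomalous-reading threshold (default 1000).
#' @param bmi_min Inclusive BMI cutoff (default 29).
#'
#' @return A list with `kept` (the surviving rows) and `rejections`
#'   (data frame of `id` and `reason`:
#'   `"missing_hourly"`, `"anomalous_reading"` or `"low_bmi"`).
#' @export
filter_valid <- function(records, anomaly_max = 1000, bmi_min = 29) {
  if (nrow(records) == 0) {
    return(list(kept = records,
                rejections = data.frame(id = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE)))
  }
  h <- as.matrix(records[, HOUR_COLS])
  bad_missing <- rowSums(!is.finite(h)) > 0
  bad_anom <- !bad_missing & rowSums(h > anomaly_max) > 0
  bad_bmi <- !bad_missing & !bad_anom &
    (!is.finite(records$bmi) | records$bmi < bmi_min)
  reason <- rep(NA_character_, nrow(records))
  reason[bad_bmi] <- "low_bmi"
  reason[bad_anom] <- "anomalous_reading"
  reason[bad_missing] <- "missing_hourly"
  keep <- is.na(reason)
  list(
    kept = records[keep, , drop = FALSE],
    rejections = data.frame(id = records$id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}

#' Label disease status from ICD-10 codes and diagnosis timing
#'
#' A participant qualifies as a KOA case when any of their ICD-10 codes
#' prefix-matches one of `koa_codes`. Status is `healthy` without a
#' qualifying code; `diagnosed` when the diagnosis offset is at or before
#' the recording (offset <= 0); `prodromal` when the diagnosis falls within
#' `prodromal_window` years after recording (`within_5y` marks offsets
#' within `early_window` years); and `beyond_window` when a qualifying
#' diagnosis falls later than `prodromal_window` years after recording
#' (a case for the healthy-vs-KOA contrast, but outside the prodromal
#' definition).
#'
#' @param records Cohort data frame with `icd10` (semicolon-separable code
#'   string) and `diagnosis_offset_years` columns.
#' @param koa_codes Qualifying code prefixes.
#' @param prodromal_window,early_window Windows in years;
#'   `prodromal_window >= early_window > 0` required.
#'
#' @return Data frame with columns `status` (factor with levels `healthy`,
#'   `diagnosed`, `prodromal`, `beyond_window`) and `within_5y` (logical,
#'   `TRUE` only for prodromal cases inside `early_window`).
#' @export
classify_status <- function(records,
                            koa_codes = DEFAULT_KOA_CODES,
                            prodromal_window = 10,
                            early_window = 5) {
  stopifnot(prodromal_window >= early_window, early_window > 0)
  codes <- strsplit(ifelse(is.na(records$icd10), "", records$icd10), ";")
  has_code <- vapply(codes, function(cs) {
    cs <- trimws(cs)
    cs <- cs[nzchar(cs)]
    any(vapply(koa_codes,
               function(k) any(startsWith(cs, k)), logical(1)))
  }, logical(1))
  offset <- records$diagnosis_offset_years
  if (any(has_code & is.na(offset))) {
    stop("data integrity: qualifying KOA code with missing diagnosis offset",
         call. = FALSE)
  }
  status <- rep("healthy", nrow(records))
  status[has_code & offset <= 0] <- "diagnosed"
  status[has_code & offset > 0 & offset <= prodromal_window] <- "prodromal"
  status[has_code & offset > prodromal_window] <- "beyond_window"
  within <- status == "prodromal" & !is.na(offset) & offset <= early_window
  data.frame(
    status = factor(status, levels = c("healthy", "diagnosed",
                                       "prodromal", "beyond_window")),
    within_5y = within
  )
}

#' Standardized mean difference between two groups
#'
#' Between-group mean difference divided by the pooled standard deviation;
#' the standard balance diagnostic for matching.
#'
#' @param x_case,x_control Numeric vectors.
#' @return The (signed) SMD; 0 when the pooled SD is 0.
#' @export
compute_smd <- function(x_case, x_control) {
  s <- sqrt((stats::var(x_case) + stats::var(x_control)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (mean(x_case) - mean(x_control)) / s
}

balance_table <- function(cases, controls) {
  data.frame(
    variable = c("age", "bmi", "male_fraction"),
    smd = c(compute_smd(cases$age, controls$age),
            compute_smd(cases$bmi, controls$bmi),
            mean(cases$sex == "male") - mean(controls$sex == "male"))
  )
}

#' Covariate-matched undersampling of controls
#'
#' Selects exactly `nrow(cases)` controls without replacement, with
#' sampling weights proportional to the case/control density ratio on the
#' balance variables: sex is a stratum, age and BMI enter through binned
#' counts (5-year and 2-unit bins). Cell counts are Laplace-smoothed
#' (`alpha = 0.5`) so strata where cases outnumber available controls
#' borrow from neighbouring cells rather than fail; a warning reports
#' case strata with no controls at all. Fully determined by `seed`.
#'
#' @param controls,cases Cohort data frames (after [filter_valid()]).
#' @param seed Integer seed for the weighted draw.
#' @param age_bin,bmi_bin Bin widths for the density ratio.
#'
#' @return A subset of `controls` with `nrow(cases)` rows, fields
#'   untouched.
#' @export
matched_undersample <- function(controls, cases, seed,
                                age_bin = 5, bmi_bin = 2) {
  n_cases <- nrow(cases)
  if (n_cases < 1) stop("`cases` must contain at least one record",
                        call. = FALSE)
  if (nrow(controls) < n_cases) {
    stop("infeasible: fewer controls (", nrow(controls),
         ") than cases (", n_cases, ")", call. = FALSE)
  }
  bin_of <- function(x, w) as.integer(floor(x / w))
  cell_key <- function(d) {
    paste(d$sex, bin_of(d$age, age_bin), bin_of(d$bmi, bmi_bin), sep = "|")
  }
  ctrl_cells <- cell_key(controls)
  case_cells <- cell_key(cases)
  ctrl_tab <- table(ctrl_cells)
  case_tab <- table(case_cells)
  orphan <- setdiff(names(case_tab), names(ctrl_tab))
  if (length(orphan)) {
    warning(length(orphan), " case stratum/strata without controls; ",
            "their weight is redistributed to neighbouring cells via ",
            "smoothing", call. = FALSE)
  }
  alpha <- 0.5
  n_case_cell <- as.numeric(case_tab[ctrl_cells])
  n_case_cell[is.na(n_case_cell)] <- 0
  n_ctrl_cell <- as.numeric(ctrl_tab[ctrl_cells])
  w <- (n_case_cell + alpha) / (n_ctrl_cell + alpha)
  sel <- withr::with_seed(seed,
                          sample(nrow(controls), n_cases, prob = w))
  controls[sel, , drop = FALSE]
}

#' Assemble one of the three classification scenarios
#'
#' Scenario 1 contrasts healthy controls (label 0) with all KOA cases --
#' diagnosed, prodromal, or diagnosed beyond the prodromal window --
#' (label 1), with controls matched-undersampled to a 1:1 ratio.
#' Scenario 2 contrasts prodromal (label 0) with already-diagnosed
#' (label 1) cases, retaining all eligible participants with no balancing.
#' Scenario 3 contrasts healthy controls (label 0) with prodromal cases
#' diagnosed within the early window (label 1), again matched 1:1.
#'
#' @param records Cohort data frame that already passed [filter_valid()].
#' @param scenario Integer 1, 2 or 3.
#' @param seed Seed for the matched undersampling.
#' @param prodromal_window,early_window Passed to [classify_status()].
#'
#' @return A `scenario_dataset`: list with `scenario`, `data` (records in
#'   label order, controls first), `labels` (integer 0/1), and
#'   `provenance` (named counts plus a pre/post matching balance table).
#' @export
build_scenario <- function(records, scenario, seed,
                           prodromal_window = 10, early_window = 5) {
  stopifnot(scenario %in% 1:3)
  cls <- classify_status(records,
                         prodromal_window = prodromal_window,
                         early_window = early_window)
  healthy <- records[cls$status == "healthy", , drop = FALSE]
  diagnosed <- records[cls$status == "diagnosed", , drop = FALSE]
  prodromal <- records[cls$status == "prodromal", , drop = FALSE]
  beyond <- records[cls$status == "beyond_window", , drop = FALSE]
  prodromal_5y <- records[cls$status == "prodromal" & cls$within_5y, ,
                          drop = FALSE]
  counts <- c(input = nrow(records), healthy = nrow(healthy),
              diagnosed = nrow(diagnosed), prodromal = nrow(prodromal),
              prodromal_within_5y = nrow(prodromal_5y),
              beyond_window = nrow(beyond))

  fail_empty <- function(what) {
    stop("scenario ", scenario, ": empty class (", what, ")", call. = FALSE)
  }
  if (scenario == 1) {
    cases <- rbind(diagnosed, prodromal, beyond)
    if (nrow(cases) == 0) fail_empty("KOA cases")
    if (nrow(healthy) == 0) fail_empty("healthy controls")
    ctrl <- matched_undersample(healthy, cases, seed)
    dat <- rbind(ctrl, cases)
    labels <- c(rep(0L, nrow(ctrl)), rep(1L, nrow(cases)))
    bal <- list(pre = balance_table(cases, healthy),
                post = balance_table(cases, ctrl))
  } else if (scenario == 2) {
    if (nrow(prodromal) == 0) fail_empty("prodromal")
    if (nrow(diagnosed) == 0) fail_empty("diagnosed")
    dat <- rbind(prodromal, diagnosed)
    labels <- c(rep(0L, nrow(prodromal)), rep(1L, nrow(diagnosed)))
    bal <- list(pre = balance_table(diagnosed, prodromal), post = NULL)
  } else {
    if (nrow(prodromal_5y) == 0) fail_empty("prodromal within early window")
    if (nrow(healthy) == 0) fail_empty("healthy controls")
    ctrl <- matched_undersample(healthy, prodromal_5y, seed)
    dat <- rbind(ctrl, prodromal_5y)
    labels <- c(rep(0L, nrow(ctrl)), rep(1L, nrow(prodromal_5y)))
    bal <- list(pre = balance_table(prodromal_5y, healthy),
                post = balance_table(prodromal_5y, ctrl))
  }
  rownames(dat) <- NULL
  structure(
    list(scenario = scenario,
         data = dat,
         labels = labels,
         provenance = list(counts = counts, balance = bal, seed = seed)),
    class = "scenario_dataset"
  )
}

#' @export
print.scenario_dataset <- function(x, ...) {
  cat("scenario_dataset (scenario ", x$scenario, "): ",
      sum(x$labels == 0), " vs ", sum(x$labels == 1), " records\n",
      sep = "")
  invisible(x)
}
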