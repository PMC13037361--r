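# Synthetic wrist-actigraphy cohorts.
#
# The generator emulates processed hourly mean-acceleration summaries:
# a diurnal template with a nocturnal plateau, a mid-morning (10:00) peak
# and an evening decline; seasonal modulation (winter low, summer high);
# BMI-linked attenuation of waking activity; and a small multiplicative
# daytime attenuation for disease cases that controls class separability.

HOUR_COLS <- sprintf("h%02d", 0:23)

#' Configuration of the synthetic actigraphy cohort generator
#'
#' Bundles every generative parameter of [generate_population()] with its
#' seed, so that a cohort is a pure function of its configuration.
#'
#' @param n_participants Number of participants to simulate.
#' @param case_fraction Probability that a participant is a KOA case.
#' @param daytime_attenuation Multiplicative reduction, in `[0, 1)`, applied
#'   to case activity during hours 9--16 before noise is added. This is the
#'   single knob controlling class separability; see
#'   [calibrate_attenuation()] for choosing it from a target AUC.
#' @param seasonal_amplitude Peak-to-mean amplitude, in `[0, 1)`, of the
#'   cosine month modulation (July maximal, January minimal).
#' @param noise_sd Standard deviation (milli-gravity units) of the
#'   independent per-hour Gaussian noise; profiles are truncated at 0.
#' @param night_level,peak_level Expected acceleration (milli-gravity units)
#'   of the nocturnal plateau (hours 0--5) and the 10:00 peak.
#' @param age_mean,age_sd Normal age distribution, years.
#' @param male_fraction Proportion of male participants.
#' @param bmi_mean,bmi_sd Normal BMI distribution, kg/m^2.
#' @param bmi_activity_coef Fractional reduction of waking activity per BMI
#'   unit above 25 (0 disables the BMI-activity coupling).
#' @param prodromal_lag_range Length-2 interval, years, of uniform
#'   post-recording diagnosis offsets for prodromal cases.
#' @param prediagnosed_fraction,prodromal_fraction Split of cases into
#'   already-diagnosed (negative offset) and prodromal (positive offset);
#'   must sum to 1.
#' @param seed Integer seed; the same configuration always regenerates a
#'   byte-identical cohort.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_participants = 2000,
                             case_fraction = 0.12,
                             daytime_attenuation = 0.11,
                             seasonal_amplitude = 0.15,
                             noise_sd = 12,
                             night_level = 5,
                             peak_level = 40,
                             age_mean = 65.5,
                             age_sd = 4.5,
                             male_fraction = 0.46,
                             bmi_mean = 31.5,
                             bmi_sd = 2.5,
                             bmi_activity_coef = 0.0075,
                             prodromal_lag_range = c(0, 10),
                             prediagnosed_fraction = 0.566,
                             prodromal_fraction = 0.434,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    case_fraction = case_fraction,
    daytime_attenuation = daytime_attenuation,
    seasonal_amplitude = seasonal_amplitude,
    noise_sd = noise_sd,
    night_level = night_level,
    peak_level = peak_level,
    age_mean = age_mean,
    age_sd = age_sd,
    male_fraction = male_fraction,
    bmi_mean = bmi_mean,
    bmi_sd = bmi_sd,
    bmi_activity_coef = bmi_activity_coef,
    prodromal_lag_range = as.numeric(prodromal_lag_range),
    prediagnosed_fraction = prediagnosed_fraction,
    prodromal_fraction = prodromal_fraction,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_participants <= 0L) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  if (cfg$case_fraction < 0 || cfg$case_fraction > 1) {
    stop("`case_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$daytime_attenuation < 0 || cfg$daytime_attenuation >= 1) {
    stop("`daytime_attenuation` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$seasonal_amplitude < 0 || cfg$seasonal_amplitude >= 1) {
    stop("`seasonal_amplitude` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$noise_sd <= 0 || cfg$night_level <= 0 || cfg$peak_level <= 0) {
    stop("`noise_sd`, `night_level` and `peak_level` must be > 0",
         call. = FALSE)
  }
  if (cfg$night_level >= cfg$peak_level) {
    stop("`night_level` must be smaller than `peak_level`", call. = FALSE)
  }
  if (length(cfg$prodromal_lag_range) != 2 ||
      cfg$prodromal_lag_range[1] < 0 ||
      diff(cfg$prodromal_lag_range) <= 0) {
    stop("`prodromal_lag_range` must be an increasing non-negative interval",
         call. = FALSE)
  }
  if (abs(cfg$prediagnosed_fraction + cfg$prodromal_fraction - 1) > 1e-8) {
    stop("`prediagnosed_fraction` + `prodromal_fraction` must equal 1",
         call. = FALSE)
  }
  invisible(cfg)
}

# Base (un-modulated) diurnal shape: nocturnal plateau over hours 0-5, a
# linear rise from 6 to the 10:00 peak, then a linear decline back towards
# the nocturnal level at hour 23.
template_base <- function(hour, config) {
  night <- config$night_level
  peak <- config$peak_level
  ifelse(hour <= 5, night,
         ifelse(hour <= 10,
                night + (peak - night) * (hour - 5) / 5,
                peak - (peak - night) * (hour - 10) / 13))
}

#' Expected diurnal activity at a given hour and month
#'
#' Noiseless expected hourly mean acceleration of the generator: a nocturnal
#' plateau at `night_level` (hours 0--5), a monotone rise to the maximum
#' `peak_level` at hour 10, a monotone decline thereafter, all multiplied by
#' the seasonal factor `1 + seasonal_amplitude * cos(2 * pi * (month - 7) / 12)`
#' (July maximal, January minimal).
#'
#' @param hour Integer hour(s) of day in 0--23.
#' @param month Integer month(s) in 1--12.
#' @param config A [synthetic_config()].
#'
#' @return Expected acceleration (same units as `peak_level`), vectorised
#'   over `hour` and `month`.
#' @export
diurnal_template <- function(hour, month, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(!is.finite(hour)) || any(hour != floor(hour)) ||
      any(hour < 0) || any(hour > 23)) {
    stop("`hour` must be an integer in 0..23", call. = FALSE)
  }
  if (any(!is.finite(month)) || any(month != floor(month)) ||
      any(month < 1) || any(month > 12)) {
    stop("`month` must be an integer in 1..12", call. = FALSE)
  }
  season <- 1 + config$seasonal_amplitude * cos(2 * pi * (month - 7) / 12)
  template_base(hour, config) * season
}

#' Generate a synthetic participant cohort
#'
#' Draws `n_participants` records. Demographics come from the configured
#' distributions (weight is derived from BMI and a sex-specific height
#' draw); the wear month is uniform over 1--12; the 24-hour profile is the
#' diurnal template times the seasonal factor, attenuated on waking hours
#' (6--23) by the BMI coupling, attenuated on hours 9--16 by
#' `daytime_attenuation` for cases, plus independent Gaussian noise
#' truncated at zero. Cases carry an ICD-10 M17.x code; already-diagnosed
#' cases get a negative diagnosis offset (uniform on -10..0 years),
#' prodromal cases a positive offset uniform on `prodromal_lag_range`.
#'
#' @param config A [synthetic_config()].
#'
#' @return A data frame with one row per participant and columns `id`,
#'   `h00`..`h23`, `month`, `sex`, `age`, `weight`, `bmi`, `icd10`,
#'   `diagnosis_offset_years` (`NA` for controls).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  n <- config$n_participants

  withr::with_seed(config$seed, {
    sex <- factor(ifelse(stats::runif(n) < config$male_fraction,
                         "male", "female"),
                  levels = c("female", "male"))
    age <- stats::rnorm(n, config$age_mean, config$age_sd)
    # Sex-specific heights at typical UK adult means.
    height_cm <- ifelse(sex == "male",
                        stats::rnorm(n, 175.6, 6.9),
                        stats::rnorm(n, 162.1, 6.3))
    bmi <- pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 15)
    weight <- bmi * (height_cm / 100)^2
    month <- sample.int(12, n, replace = TRUE)

    is_case <- stats::runif(n) < config$case_fraction
    offset <- rep(NA_real_, n)
    icd10 <- rep("", n)
    case_idx <- which(is_case)
    if (length(case_idx)) {
      pre <- stats::runif(length(case_idx)) < config$prediagnosed_fraction
      offset[case_idx[pre]] <- stats::runif(sum(pre), -10, 0)
      offset[case_idx[!pre]] <- stats::runif(sum(!pre),
                                             config$prodromal_lag_range[1],
                                             config$prodromal_lag_range[2])
      icd10[case_idx] <- sample(c("M17", "M17.0", "M17.1", "M17.9"),
                                length(case_idx), replace = TRUE)
    }

    base <- matrix(template_base(0:23, config), n, 24, byrow = TRUE)
    season <- 1 + config$seasonal_amplitude * cos(2 * pi * (month - 7) / 12)
    prof <- base * season
    # BMI-linked decrement of waking activity (hours 6-23).
    wake_cols <- 7:24
    bmi_factor <- 1 - config$bmi_activity_coef * pmax(bmi - 25, 0)
    prof[, wake_cols] <- prof[, wake_cols] * bmi_factor
    # Case daytime attenuation, hours 9-16.
    day_cols <- 10:17
    if (any(is_case)) {
      prof[is_case, day_cols] <-
        prof[is_case, day_cols] * (1 - config$daytime_attenuation)
    }
    prof <- pmax(prof + matrix(stats::rnorm(n * 24, 0, config$noise_sd),
                               n, 24), 0)
    colnames(prof) <- HOUR_COLS

    out <- data.frame(
      id = sprintf("P%06d", seq_len(n)),
      prof,
      month = month,
      sex = sex,
      age = age,
      weight = weight,
      bmi = bmi,
      icd10 = icd10,
      diagnosis_offset_years = offset,
      stringsAsFactors = FALSE
    )
    out
  })
}

#' Closed-form attenuation for a target daytime-mean AUC
#'
#' Under the generator's Gaussian noise, a univariate discriminant on the
#' daytime mean (hours 9--16) of cases vs controls has theoretical
#' `AUC = pnorm(d / sqrt(2))` with standardized separation
#' `d = delta * mu_day / sigma_day`. This inverts that relation:
#' `delta = sqrt(2) * qnorm(target_auc) * sigma_day / mu_day`.
#'
#' @param target_auc Target AUC in `[0.5, 1)`.
#' @param mu_day Expected control daytime mean.
#' @param sigma_day Standard deviation of the daytime mean.
#'
#' @return The daytime attenuation `delta` in `[0, 1)`.
#' @export
attenuation_from_auc <- function(target_auc, mu_day, sigma_day) {
  if (!is.finite(target_auc) || target_auc < 0.5 || target_auc >= 1) {
    stop("`target_auc` must lie in [0.5, 1)", call. = FALSE)
  }
  stopifnot(mu_day > 0, sigma_day > 0)
  delta <- sqrt(2) * stats::qnorm(target_auc) * sigma_day / mu_day
  if (delta >= 1) {
    stop("target AUC ", target_auc, " is unattainable: it requires an ",
         "attenuation >= 1 given the configured noise", call. = FALSE)
  }
  delta
}

# Moments of the (noiseless) daytime-mean statistic implied by a
# configuration: seasonal factor moments over the 12 equiprobable months,
# BMI-factor moments from the normal-excess closed form, Gaussian noise
# averaged over the 8 daytime hours. Truncation at zero is ignored
# (negligible at daytime activity levels).
daytime_moments <- function(config) {
  hrs <- 9:16
  mu_t <- mean(template_base(hrs, config))
  s <- 1 + config$seasonal_amplitude * cos(2 * pi * ((1:12) - 7) / 12)
  es <- mean(s)
  es2 <- mean(s^2)
  z <- (config$bmi_mean - 25) / config$bmi_sd
  eg <- (config$bmi_mean - 25) * stats::pnorm(z) +
    config$bmi_sd * stats::dnorm(z)
  eg2 <- ((config$bmi_mean - 25)^2 + config$bmi_sd^2) * stats::pnorm(z) +
    (config$bmi_mean - 25) * config$bmi_sd * stats::dnorm(z)
  b <- config$bmi_activity_coef
  ea <- 1 - b * eg
  ea2 <- 1 - 2 * b * eg + b^2 * eg2
  var_sa <- es2 * ea2 - (es * ea)^2
  list(
    mu_day = es * ea * mu_t,
    sigma_day = sqrt(mu_t^2 * var_sa + config$noise_sd^2 / length(hrs))
  )
}

#' Calibrate the case attenuation to a target discriminability
#'
#' Computes the `daytime_attenuation` at which the univariate daytime-mean
#' discriminant (mean activity over hours 9--16) separates cases from
#' controls with the requested theoretical AUC under `config`'s noise,
#' seasonal and BMI-coupling structure. See [attenuation_from_auc()] for
#' the closed form; the daytime-mean moments are derived analytically from
#' the configuration (month uniform over 12 values, normal BMI, Gaussian
#' hourly noise averaged over the 8 daytime hours).
#'
#' @param target_auc Target AUC in `[0.5, 1)`; 0.5 returns 0.
#' @param config A [synthetic_config()] supplying the noise, seasonal and
#'   BMI parameters (its own `daytime_attenuation` is ignored).
#'
#' @return The calibrated attenuation, a proportion in `[0, 1)`.
#' @export
calibrate_attenuation <- function(target_auc, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.finite(target_auc) || target_auc < 0.5 || target_auc >= 1) {
    stop("`target_auc` must lie in [0.5, 1)", call. = FALSE)
  }
  if (target_auc == 0.5) {
    return(0)
  }
  mom <- daytime_moments(config)
  attenuation_from_auc(target_auc, mom$mu_day, mom$sigma_day)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes one row per participant (`id`, `h00`..`h23`,
#' `month`, `sex`, `age`, `weight`, `bmi`, `icd10`,
#' `diagnosis_offset_years`, empty for controls) as CSV and, when `config`
#' is supplied, a YAML sidecar `<path basename>_config.yaml` capturing all
#' generator parameters including the seed.
#'
#' @param cohort A cohort data frame from [generate_population()].
#' @param path Output CSV path.
#' @param config Optional [synthetic_config()] to record alongside.
#'
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), "_config.yaml")
    yaml::write_yaml(unclass(config), sidecar)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$sex <- factor(out$sex, levels = c("female", "male"))
  if (!"icd10" %in% names(out)) out$icd10 <- ""
  out$icd10[is.na(out$icd10)] <- ""
  out
}
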