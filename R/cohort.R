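#' Analyzed brain regions
#'
#' Canonical names (and CSV column names) of the regions whose per-subject
#' median delta-T1 the pipeline reports: global cerebral cortex, the four
#' cortical lobes, cerebellar cortex, cerebral and cerebellar white matter,
#' basal-ganglia perivascular spaces, and choroid plexus.
#'
#' @return Character vector of region names.
#' @export
cohort_regions <- function() {
  c("cerebral_cortex", "frontal_cortex", "parietal_cortex",
    "temporal_cortex", "occipital_cortex", "cerebellar_cortex",
    "cerebral_white_matter", "cerebellar_white_matter",
    "bg_pvs", "choroid_plexus")
}

#' Assign day/night scan period from clock time
#'
#' Day and night follow the clinical-shift definition: daytime is
#' 06:00-17:59 and nighttime 18:00-05:59, with clock time given in minutes
#' since midnight.
#'
#' @param scan_clock minutes since midnight, in `[0, 1439]`; vectorized.
#' @return Character vector of `"day"` / `"night"`.
#' @export
assign_scan_period <- function(scan_clock) {
  if (!is.numeric(scan_clock) || any(!is.finite(scan_clock))) {
    stop("`scan_clock` must be finite minutes since midnight", call. = FALSE)
  }
  if (any(scan_clock < 0 | scan_clock > 1439)) {
    stop("`scan_clock` out of range: clock times must lie in [0, 1439] minutes",
         call. = FALSE)
  }
  ifelse(scan_clock >= 360 & scan_clock <= 1079, "day", "night")
}

#' Default generative parameters for the synthetic cohort
#'
#' Encodes the study cohort this package emulates: 447 subjects (307 day,
#' 140 night), age ~ truncated Normal(63.0, 13.3^2) on [18, 95], sex and
#' diagnosis proportions per period taken from the observed
#' period-stratified counts, contrast delay ~ lognormal matched to median
#' 5.9 min (IQR 5.5-6.5), and a per-region linear model of delta-T1:
#' period-specific median level `mu` at the reference age, a period-specific
#' age slope `beta_age` (ms per year), optional sex/diagnosis offsets
#' (0 by default), and Gaussian between-subject noise `subject_sd`.
#'
#' @return A list of class `t1gad_params` with components `n_day`, `n_night`,
#'   `age` (mean, sd, lower, upper), `sex_p_male` (per period),
#'   `diagnosis_p` (per period, named proportions), `delay` (meanlog, sdlog),
#'   `reference_age`, `sex_offset`, `diagnosis_offsets`, and `regions` (one
#'   entry per [cohort_regions()] name with `mu_day`, `mu_night`,
#'   `beta_age_day`, `beta_age_night`, `subject_sd`).
#' @export
default_generative_params <- function() {
  # region, mu day/night (ms), age slope day/night (ms/yr), subject sd (ms)
  reg <- list(
    cerebral_cortex         = c(-166.4, -160.9, -0.47, -0.34, 22),
    frontal_cortex          = c(-147.5, -144.0, -0.34, -0.04, 22),
    parietal_cortex         = c(-169.0, -163.3, -0.39, -0.44, 22),
    temporal_cortex         = c(-170.2, -166.7, -0.55, -0.37, 22),
    occipital_cortex        = c(-229.3, -223.1, -0.94, -1.09, 33),
    cerebellar_cortex       = c(-174.6, -165.0,  0.02,  0.09, 22),
    cerebral_white_matter   = c( -39.3,  -38.4, -0.15, -0.16,  9),
    cerebellar_white_matter = c( -50.4,  -50.3, -0.16, -0.11, 11),
    bg_pvs                  = c( -87.2,  -88.5, -0.51, -0.29, 20),
    choroid_plexus          = c(-869.7, -869.2, -0.90, -1.66, 108)
  )
  regions <- lapply(reg, function(v) {
    list(mu_day = v[1], mu_night = v[2],
         beta_age_day = v[3], beta_age_night = v[4], subject_sd = v[5])
  })
  diagnoses <- c("IPD", "ET", "MSA", "PSP", "VaP", "Other")
  p <- list(
    n_day = 307L,
    n_night = 140L,
    age = list(mean = 63.0, sd = 13.3, lower = 18, upper = 95),
    sex_p_male = c(day = 140 / 307, night = 59 / 140),
    diagnosis_p = list(
      day   = stats::setNames(c(84, 64, 39, 10, 7, 103) / 307, diagnoses),
      night = stats::setNames(c(64, 17, 13, 3, 3, 40) / 140, diagnoses)
    ),
    # lognormal matched to median 5.9 and IQR [5.5, 6.5] minutes
    delay = list(meanlog = log(5.9),
                 sdlog = (log(6.5) - log(5.5)) / (2 * stats::qnorm(0.75))),
    reference_age = 63,
    sex_offset = 0,
    diagnosis_offsets = stats::setNames(numeric(6), diagnoses),
    regions = regions
  )
  class(p) <- "t1gad_params"
  p
}

validate_params <- function(params) {
  if (!inherits(params, "t1gad_params")) {
    stop("`params` must come from default_generative_params() (or a modified copy)",
         call. = FALSE)
  }
  unknown <- setdiff(names(params$regions), cohort_regions())
  if (length(unknown)) {
    stop("unknown region name(s) in params: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sds <- vapply(params$regions, `[[`, numeric(1), "subject_sd")
  if (any(sds < 0)) stop("subject_sd must be >= 0", call. = FALSE)
  for (per in c("day", "night")) {
    pr <- params$diagnosis_p[[per]]
    if (abs(sum(pr) - 1) > 1e-8) {
      stop("diagnosis proportions must sum to 1 within each period", call. = FALSE)
    }
  }
  invisible(params)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

sample_period_covariates <- function(n, period, params, id_offset) {
  a <- params$age
  age <- rtruncnorm(n, a$mean, a$sd, a$lower, a$upper)
  sex <- ifelse(stats::runif(n) < params$sex_p_male[[period]], "male", "female")
  dp <- params$diagnosis_p[[period]]
  diagnosis <- sample(names(dp), n, replace = TRUE, prob = dp)
  # clock times uniform within the period's shift window
  scan_clock <- if (period == "day") {
    sample(360:1079, n, replace = TRUE)
  } else {
    sample(c(1080:1439, 0:359), n, replace = TRUE)
  }
  delay <- stats::rlnorm(n, params$delay$meanlog, params$delay$sdlog)
  data.frame(
    subject_id = sprintf("S%04d", id_offset + seq_len(n)),
    age = age,
    sex = sex,
    diagnosis = diagnosis,
    scan_clock = as.integer(scan_clock),
    scan_period = assign_scan_period(scan_clock),
    contrast_delay = delay,
    stringsAsFactors = FALSE
  )
}

#' Sample a synthetic cohort (covariates only)
#'
#' Draws subject-level covariates (age, sex, diagnosis, scan clock time,
#' derived day/night period, contrast delay) with the marginals configured
#' in `params`. Deterministic given `seed`.
#'
#' @param params generative parameters, see [default_generative_params()].
#' @param n_day,n_night number of daytime / nighttime subjects (default: the
#'   configured study sizes, 307 and 140).
#' @param seed integer RNG seed.
#' @return A data.frame with one row per subject.
#' @export
sample_cohort <- function(params = default_generative_params(),
                          n_day = params$n_day, n_night = params$n_night,
                          seed = 1L) {
  validate_params(params)
  if (n_day < 0 || n_night < 0) stop("cohort sizes must be >= 0", call. = FALSE)
  set.seed(seed)
  parts <- list()
  if (n_day > 0) parts$day <- sample_period_covariates(n_day, "day", params, 0L)
  if (n_night > 0) {
    parts$night <- sample_period_covariates(n_night, "night", params, n_day)
  }
  if (!length(parts)) {
    return(sample_period_covariates(0L, "day", params, 0L))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate regional delta-T1 values for a cohort
#'
#' Fills one column per analyzed region with
#' `mu(period) + beta_age(period) * (age - reference_age) + sex/diagnosis
#' offsets + Normal(0, subject_sd)`. With `subject_sd = 0` the value is the
#' deterministic linear predictor. The day/night level difference is encoded
#' as period-specific `mu`, additive with the age effect (the generative
#' model carries no age-by-period interaction by default; slopes may still
#' differ per period via `beta_age_day` / `beta_age_night`).
#'
#' @param cohort covariate table from [sample_cohort()].
#' @param params generative parameters.
#' @param seed integer RNG seed for the subject-level noise.
#' @return `cohort` with one numeric delta-T1 column (ms) appended per region.
#' @export
simulate_regional_delta_t1 <- function(cohort,
                                       params = default_generative_params(),
                                       seed = 1L) {
  validate_params(params)
  req <- c("age", "scan_period", "sex", "diagnosis")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) {
    stop("cohort is missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(cohort)
  is_day <- cohort$scan_period == "day"
  off <- ifelse(cohort$sex == "male", params$sex_offset, 0) +
    params$diagnosis_offsets[cohort$diagnosis]
  for (rn in names(params$regions)) {
    r <- params$regions[[rn]]
    mu <- ifelse(is_day, r$mu_day, r$mu_night)
    beta <- ifelse(is_day, r$beta_age_day, r$beta_age_night)
    vals <- mu + beta * (cohort$age - params$reference_age) + off
    if (r$subject_sd > 0) vals <- vals + stats::rnorm(n, 0, r$subject_sd)
    cohort[[rn]] <- as.numeric(vals)
  }
  cohort
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [sample_cohort()] followed by
#' [simulate_regional_delta_t1()], each seeded deterministically from `seed`.
#'
#' @inheritParams sample_cohort
#' @return A cohort data.frame with covariates and regional delta-T1 columns.
#' @export
simulate_cohort <- function(params = default_generative_params(),
                            n_day = params$n_day, n_night = params$n_night,
                            seed = 1L) {
  cov <- sample_cohort(params, n_day, n_night, seed = seed)
  simulate_regional_delta_t1(cov, params, seed = seed + 1000L)
}

#' Write / read a cohort table as CSV
#'
#' Plain CSV with a header row; the column order is subject covariates
#' followed by one delta-T1 column per region.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
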