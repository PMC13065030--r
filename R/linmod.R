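#' Ordinary least-squares fit with Wald t-tests
#'
#' QR-based least squares of `response` on the columns of `design`, with
#' per-coefficient standard errors, t statistics and two-sided p-values.
#' A rank-deficient design is rejected, naming the aliased columns.
#'
#' @param design numeric design matrix (including any intercept column).
#' @param response numeric response vector.
#' @return List of class `t1gad_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `df_residual`, `sigma2`
#'   (residual variance), `fitted`, `residuals`.
#' @export
fit_linear_model <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  n <- nrow(design)
  p <- ncol(design)
  if (length(response) != n) {
    stop("design and response lengths differ", call. = FALSE)
  }
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(p))
  }
  qr_d <- qr(design)
  if (qr_d$rank < p) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):p]]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n <= p) stop("need more observations than parameters", call. = FALSE)

  beta <- qr.coef(qr_d, response)
  fitted <- as.numeric(design %*% beta)
  res <- response - fitted
  df <- n - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_d))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  pval <- 2 * stats::pt(-abs(tval), df)

  structure(list(
    coefficients = data.frame(term = colnames(design), estimate = as.numeric(beta),
                              se = se, t = tval, p = pval,
                              stringsAsFactors = FALSE, row.names = NULL),
    df_residual = df, sigma2 = sigma2, fitted = fitted, residuals = res
  ), class = "t1gad_fit")
}

#' @export
print.t1gad_fit <- function(x, ...) {
  cat(sprintf("<t1gad_fit> df = %d, residual variance = %.6g\n",
              x$df_residual, x$sigma2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

coef_row <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("coefficient not found: ", term, call. = FALSE)
  fit$coefficients[i, ]
}

# Cohort design matrix builder. Treatment coding: sex reference female,
# diagnosis reference "Other", period reference day.
cohort_design <- function(cohort, terms) {
  stopifnot(nrow(cohort) > 0)
  cols <- list("(Intercept)" = rep(1, nrow(cohort)))
  add_factor <- function(cols, values, levels_all, prefix) {
    f <- factor(values, levels = levels_all)
    f <- droplevels(f)
    for (lv in levels(f)[-1L]) {
      cols[[paste0(prefix, lv)]] <- as.numeric(f == lv)
    }
    cols
  }
  for (tm in terms) {
    cols <- switch(tm,
      age = { cols$age <- cohort$age; cols },
      period = add_factor(cols, cohort$scan_period, c("day", "night"), "period"),
      sex = add_factor(cols, cohort$sex, c("female", "male"), "sex"),
      diagnosis = add_factor(cols, cohort$diagnosis,
                             c("Other", "IPD", "ET", "MSA", "PSP", "VaP"),
                             "diagnosis"),
      "age:period" = {
        cols[["age:periodnight"]] <-
          cohort$age * as.numeric(cohort$scan_period == "night")
        cols
      },
      stop("unknown model term: ", tm, call. = FALSE))
  }
  do.call(cbind, cols)
}

check_region_column <- function(cohort, region) {
  if (!region %in% names(cohort)) {
    stop("region column not found in cohort: ", region, call. = FALSE)
  }
  if (!region %in% cohort_regions()) {
    stop("unknown region name: ", region, call. = FALSE)
  }
}

#' Covariate-adjusted day/night contrast (ANCOVA)
#'
#' Fits `deltaT1 ~ period + age + sex + diagnosis` by least squares
#' (treatment coding; day, female, and "Other" as references) and reports
#' the Wald t-test of the night-vs-day coefficient — the adjusted group
#' comparison of enhancement between daytime and nighttime scans.
#'
#' @param cohort cohort data.frame with covariates and region columns.
#' @param region region column name (see [cohort_regions()]).
#' @return List: `p_value`, `estimate` (night minus day, ms), `se`, `fit`.
#' @export
ancova_group_pvalue <- function(cohort, region) {
  check_region_column(cohort, region)
  if (length(unique(cohort$scan_period)) < 2L) {
    stop("both day and night scans are required for the group contrast",
         call. = FALSE)
  }
  X <- cohort_design(cohort, c("period", "age", "sex", "diagnosis"))
  fit <- fit_linear_model(X, cohort[[region]])
  row <- coef_row(fit, "periodnight")
  list(p_value = row$p, estimate = row$estimate, se = row$se, fit = fit)
}

#' Age slope of regional delta-T1 within one scan period
#'
#' Linear regression `deltaT1 ~ age + sex + diagnosis` restricted to the
#' daytime or nighttime stratum; the age coefficient is the change in ms of
#' delta-T1 per one-year increase in age.
#'
#' @inheritParams ancova_group_pvalue
#' @param period `"day"` or `"night"`.
#' @return List: `beta` (ms/year), `p_value`, `se`, `n`, `fit`.
#' @export
age_slope_by_period <- function(cohort, region, period = c("day", "night")) {
  period <- match.arg(period)
  check_region_column(cohort, region)
  sub <- cohort[cohort$scan_period == period, , drop = FALSE]
  if (nrow(sub) < 10L) {
    stop("stratum too small (need at least 10 subjects): ", period,
         call. = FALSE)
  }
  X <- cohort_design(sub, c("age", "sex", "diagnosis"))
  fit <- fit_linear_model(X, sub[[region]])
  row <- coef_row(fit, "age")
  list(beta = row$estimate, p_value = row$p, se = row$se, n = nrow(sub),
       fit = fit)
}

#' Age-by-scan-time interaction test
#'
#' Fits `deltaT1 ~ age * period + sex + diagnosis` and reports the Wald
#' p-value of the `age:period` product term — whether the age-related slope
#' of enhancement differs between daytime and nighttime scans.
#'
#' @inheritParams ancova_group_pvalue
#' @return List: `p_value`, `estimate` (slope difference, night minus day),
#'   `se`, `fit`.
#' @export
interaction_pvalue <- function(cohort, region) {
  check_region_column(cohort, region)
  if (length(unique(cohort$scan_period)) < 2L) {
    stop("both day and night scans are required for the interaction test",
         call. = FALSE)
  }
  X <- cohort_design(cohort, c("age", "period", "age:period", "sex",
                               "diagnosis"))
  fit <- fit_linear_model(X, cohort[[region]])
  row <- coef_row(fit, "age:periodnight")
  list(p_value = row$p, estimate = row$estimate, se = row$se, fit = fit)
}

#' Region-by-region statistical summary of a cohort
#'
#' Runs the adjusted day/night ANCOVA contrast, the stratified age-slope
#' regressions, and the age-by-period interaction test for every region
#' column present, returning a tidy table.
#'
#' @param cohort cohort data.frame.
#' @param regions region columns to analyze (default: all present).
#' @return data.frame with one row per region: group contrast estimate/p,
#'   day and night age slopes with p-values, and interaction p.
#' @export
analyze_cohort <- function(cohort, regions = intersect(cohort_regions(),
                                                       names(cohort))) {
  rows <- lapply(regions, function(rn) {
    grp <- ancova_group_pvalue(cohort, rn)
    day <- age_slope_by_period(cohort, rn, "day")
    night <- age_slope_by_period(cohort, rn, "night")
    inter <- interaction_pvalue(cohort, rn)
    data.frame(region = rn,
               group_estimate = grp$estimate, group_p = grp$p_value,
               beta_day = day$beta, p_day = day$p_value,
               beta_night = night$beta, p_night = night$p_value,
               interaction_p = inter$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
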