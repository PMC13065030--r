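test_that("least squares matches a direct normal-equations solve", {
  set.seed(21)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(20), x2 = runif(20))
  y <- 2 - 0.5 * X[, 2] + 1.3 * X[, 3] + rnorm(20, 0, 0.3)
  fit <- fit_linear_model(X, y)

  # independent oracle: solve the normal equations directly
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-10)
  res <- y - X %*% beta_oracle
  s2 <- sum(res^2) / (20 - 3)
  se_oracle <- sqrt(diag(solve(t(X) %*% X)) * s2)
  expect_equal(fit$coefficients$se, as.numeric(se_oracle), tolerance = 1e-10)

  # exact data: coefficients to machine precision, zero residual variance
  y0 <- 1 + 2 * X[, 2] - 3 * X[, 3]
  fit0 <- fit_linear_model(X, y0)
  expect_equal(fit0$coefficients$estimate, c(1, 2, -3), tolerance = 1e-10)
  expect_lt(fit0$sigma2, 1e-20)

  # intercept-only model returns the sample mean
  fit1 <- fit_linear_model(matrix(1, 20, 1), y)
  expect_equal(fit1$coefficients$estimate, mean(y))

  Xbad <- cbind(X, dup = X[, 2])
  expect_error(fit_linear_model(Xbad, y), "dup")
})

test_that("period-only model reproduces the pooled two-sample t-test", {
  set.seed(22)
  p <- flat_params(mu_day = -160, mu_night = -150, sd = 15)
  coh <- simulate_cohort(p, n_day = 40L, n_night = 30L, seed = 8L)
  X <- cbind(`(Intercept)` = 1,
             periodnight = as.numeric(coh$scan_period == "night"))
  fit <- fit_linear_model(X, coh$cerebral_cortex)
  tt <- t.test(cerebral_cortex ~ scan_period, data = coh, var.equal = TRUE)
  p_model <- fit$coefficients$p[fit$coefficients$term == "periodnight"]
  expect_equal(p_model, tt$p.value, tolerance = 1e-6)
})

test_that("ANCOVA contrast equals the Wald test of its period coefficient", {
  coh <- simulate_cohort(n_day = 60L, n_night = 40L, seed = 12L)
  res <- ancova_group_pvalue(coh, "cerebral_cortex")
  X <- coh |> (\(d) cbind(
    `(Intercept)` = 1,
    periodnight = as.numeric(d$scan_period == "night"),
    age = d$age,
    sexmale = as.numeric(d$sex == "male"),
    sapply(c("IPD", "ET", "MSA", "PSP", "VaP"),
           function(l) as.numeric(d$diagnosis == l))
  ))()
  # independent check through R's lm on the same model
  df <- data.frame(y = coh$cerebral_cortex, period = coh$scan_period,
                   age = coh$age, sex = coh$sex,
                   diagnosis = factor(coh$diagnosis,
                                      levels = c("Other", "IPD", "ET", "MSA",
                                                 "PSP", "VaP")))
  lmfit <- summary(lm(y ~ period + age + sex + diagnosis, data = df))
  expect_equal(res$p_value, lmfit$coefficients["periodnight", 4],
               tolerance = 1e-10)
  expect_equal(res$estimate, lmfit$coefficients["periodnight", 1],
               tolerance = 1e-10)

  only_day <- coh[coh$scan_period == "day", ]
  expect_error(ancova_group_pvalue(only_day, "cerebral_cortex"),
               "both day and night")
})

test_that("stratified age slopes and interaction agree with lm oracles", {
  p <- flat_params(mu_day = -160, mu_night = -150, beta_day = -0.5,
                   beta_night = -0.2, sd = 10)
  coh <- simulate_cohort(p, n_day = 120L, n_night = 80L, seed = 14L)
  day <- age_slope_by_period(coh, "cerebral_cortex", "day")
  df <- coh[coh$scan_period == "day", ]
  df$diagnosis <- factor(df$diagnosis, levels = c("Other", "IPD", "ET", "MSA",
                                                  "PSP", "VaP"))
  lmfit <- summary(lm(cerebral_cortex ~ age + sex + diagnosis, data = df))
  expect_equal(day$beta, lmfit$coefficients["age", 1], tolerance = 1e-10)
  expect_equal(day$p_value, lmfit$coefficients["age", 4], tolerance = 1e-10)

  inter <- interaction_pvalue(coh, "cerebral_cortex")
  df2 <- coh
  df2$diagnosis <- factor(df2$diagnosis, levels = c("Other", "IPD", "ET",
                                                    "MSA", "PSP", "VaP"))
  lmfit2 <- summary(lm(cerebral_cortex ~ age * scan_period + sex + diagnosis,
                       data = df2))
  expect_equal(inter$p_value, lmfit2$coefficients["age:scan_periodnight", 4],
               tolerance = 1e-10)
  # generative slope difference (night - day) is recovered in the estimate
  expect_equal(inter$estimate, 0.3, tolerance = 3 * inter$se)

  expect_error(age_slope_by_period(coh[1:5, ], "cerebral_cortex", "day"),
               "too small")
})

test_that("noiseless equal slopes give a zero interaction coefficient", {
  p <- flat_params(mu_day = -160, mu_night = -150, beta_day = -0.4,
                   beta_night = -0.4, sd = 0)
  coh <- simulate_cohort(p, n_day = 40L, n_night = 30L, seed = 16L)
  inter <- interaction_pvalue(coh, "cerebral_cortex")
  expect_equal(inter$estimate, 0, tolerance = 1e-10)
})

test_that("p-values are invariant under relabeling of diagnosis classes", {
  coh <- simulate_cohort(n_day = 80L, n_night = 60L, seed = 18L)
  base <- ancova_group_pvalue(coh, "cerebral_cortex")
  relab <- c(IPD = "ET", ET = "MSA", MSA = "PSP", PSP = "VaP", VaP = "Other",
             Other = "IPD")
  coh2 <- coh
  coh2$diagnosis <- unname(relab[coh$diagnosis])
  perm <- ancova_group_pvalue(coh2, "cerebral_cortex")
  expect_equal(perm$p_value, base$p_value, tolerance = 1e-10)
  expect_equal(perm$estimate, base$estimate, tolerance = 1e-10)
})

test_that("day/night contrast has power against the observed cortical gap", {
  # day-night gap of 5.5 ms (cortical medians) at study size, subject SD 22
  p <- flat_params(mu_day = -166.4, mu_night = -160.9, sd = 22)
  hits <- vapply(1:60, function(i) {
    coh <- simulate_cohort(p, seed = 3000L + i)
    ancova_group_pvalue(coh, "cerebral_cortex")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("interaction test detects a 1 ms/year slope difference", {
  p <- flat_params(mu_day = -160, mu_night = -160, beta_day = -0.5,
                   beta_night = -1.5, sd = 22)
  hits <- vapply(1:40, function(i) {
    coh <- simulate_cohort(p, seed = 4000L + i)
    interaction_pvalue(coh, "cerebral_cortex")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("Mann-Whitney U: exact enumeration, ties, and separation", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(2.0, 6.3, 1.1, 4.0, 3.3)
  res <- mann_whitney_u(x, y)
  expect_equal(res$method, "exact")
  # independent oracle for the tie-free case
  expect_equal(res$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)

  set.seed(30)
  big_x <- rnorm(30)
  same_big <- mann_whitney_u(big_x, big_x)
  expect_equal(same_big$method, "normal")
  expect_gte(same_big$p_value, 0.99)

  sep <- mann_whitney_u(rnorm(25), rnorm(25) + 100)
  expect_lt(sep$p_value, 1e-8)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("chi-square test matches the closed-form oracle and handles margins", {
  tbl <- rbind(c(30, 10), c(20, 40))
  res <- chi_square_pvalue(tbl)  # Yates by default on 2x2
  oracle <- suppressWarnings(chisq.test(tbl, correct = TRUE))
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)

  # proportional table: statistic exactly 0, p = 1
  prop <- outer(c(10, 20), c(3, 7)) / 10
  res0 <- chi_square_pvalue(prop, yates = FALSE)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(chi_square_pvalue(rbind(c(0, 0), c(5, 5))), "zero margin")
  expect_error(chi_square_pvalue(matrix(1, 3, 3), yates = TRUE), "2x2")
})

test_that("Fisher exact p equals exhaustive hypergeometric enumeration", {
  set.seed(33)
  for (i in 1:8) {
    m <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ours <- fisher_exact_2x2(m)$p_value
    expect_equal(ours, fisher.test(m)$p.value, tolerance = 1e-9)
    # independent enumeration oracle: sum dhyper over no-more-probable tables
    k <- max(0, sum(m[, 1]) - sum(m[2, ])):min(sum(m[1, ]), sum(m[, 1]))
    probs <- dhyper(k, sum(m[1, ]), sum(m[2, ]), sum(m[, 1]))
    p_obs <- dhyper(m[1, 1], sum(m[1, ]), sum(m[2, ]), sum(m[, 1]))
    expect_equal(ours, sum(probs[probs <= p_obs * (1 + 1e-7)]),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p_value, 1)
})

test_that("pairwise Fisher comparisons are Bonferroni-adjusted over all pairs", {
  tbl <- rbind(IPD = c(84, 64), ET = c(64, 17), MSA = c(39, 13))
  out <- pairwise_fisher_bonferroni(tbl)
  expect_equal(nrow(out), 3L)
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 3))
  ipd_et <- out[out$row1 == "IPD" & out$row2 == "ET", ]
  expect_equal(ipd_et$p_raw, fisher_exact_2x2(tbl[1:2, ])$p_value)
  expect_error(pairwise_fisher_bonferroni(matrix(1, 1, 2)), ">= 2 rows")
})
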