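test_that("complete-case filter reports and warns at the 5% threshold", {
  d <- toy_cohort(matrix(1, 20, 2))
  f <- complete_case_filter(d)
  expect_identical(nrow(f$cohort), 20L)
  expect_identical(f$n_excluded, 0L)

  d$bmi[1] <- NA
  expect_warning(f1 <- complete_case_filter(d), "5.0%")
  expect_identical(nrow(f1$cohort), 19L)
  expect_equal(f1$pct_excluded, 5)

  d2 <- toy_cohort(matrix(1, 20, 2))
  d2$smoking[1:2] <- NA
  expect_warning(complete_case_filter(d2), "10.0%")
  d3 <- toy_cohort(matrix(1, 50, 2))
  d3$smoking[1] <- NA
  expect_silent(f3 <- complete_case_filter(d3))
  expect_equal(f3$pct_excluded, 2)
})

test_that("reference cluster is the lowest-impact cluster", {
  mk_row <- function(cl, n, gp, hosp, meds, m5) {
    data.frame(cluster = cl, n = n, pct = 0, died_2yr_pct = 0,
               died_5yr_pct = m5, gp_consults_mean = gp,
               gp_consults_median = gp, gp_consults_q1 = 0,
               gp_consults_q3 = 0, hospitalisations_mean = hosp,
               hospitalisations_median = 0, hospitalisations_q1 = 0,
               hospitalisations_q3 = 0, regular_meds_mean = meds,
               regular_meds_median = 0, regular_meds_q1 = 0,
               regular_meds_q3 = 0)
  }
  # cluster 3 lowest on every outcome
  s <- rbind(mk_row("1", 100, 12, 0.6, 4, 10),
             mk_row("2", 80, 15, 0.8, 6, 14),
             mk_row("3", 60, 8, 0.3, 2, 5))
  expect_identical(choose_reference_cluster(s), 3L)

  # constructed rank-sum tie: sizes decide (100 vs 50)
  s2 <- rbind(mk_row("1", 100, 8, 0.8, 2, 14),
              mk_row("2", 50, 15, 0.3, 6, 5))
  expect_identical(choose_reference_cluster(s2), 1L)

  expect_error(choose_reference_cluster(s[1, ]), "at least two")

  # planted low-use class is chosen across seeded replicates
  hits <- 0L
  for (r in 1:20) {
    set.seed(800 + r)
    n <- 600
    a <- sample(1:3, n, TRUE)
    mu <- c(8, 8, 2)[a]
    d <- toy_cohort(matrix(1, n, 2),
                    gp = rpois(n, mu), hosp = rpois(n, mu / 8),
                    meds = rpois(n, mu / 2),
                    died5 = rbinom(n, 1, c(0.2, 0.2, 0.02)[a]))
    ref <- choose_reference_cluster(cluster_outcome_summary(a, d))
    if (ref == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("design matrix uses the documented coding and column order", {
  d <- toy_cohort(matrix(1, 6, 2),
                  age = c(50L, 60L, 70L, 55L, 65L, 75L),
                  gender = c("F", "M", "F", "M", "F", "F"),
                  imd = c(1L, 2L, 3L, 4L, 5L, 3L),
                  smoking = c("never", "current", "ex", "never",
                              "never", "current"),
                  bmi = c(24, 27, 30, 22, 26, 31))
  a <- c(1L, 1L, 2L, 2L, 3L, 3L)
  des <- build_design(d, a, reference_cluster = 1L)
  # columns: intercept + (K-1) cluster + gender + 2 smoking + imd + bmi + age
  expect_identical(colnames(des$X),
                   c("(Intercept)", "cluster_2", "cluster_3",
                     "gender_M", "smoking_current", "smoking_ex",
                     "imd", "bmi", "age"))
  # a reference-cluster never-smoking female has all indicators at 0
  expect_equal(unname(des$X[1, c("cluster_2", "cluster_3", "gender_M",
                                 "smoking_current", "smoking_ex")]),
               rep(0, 5))
  expect_equal(unname(des$X[, "imd"]), as.numeric(d$imd))

  # full column rank on a simulated cohort
  truth <- default_simulation_truth(n_scale = 0.02)
  sim <- simulate_cohort(truth)
  cc <- suppressWarnings(complete_case_filter(sim$cohort))
  lab <- sim$truth_labels$true_class[
    match(cc$cohort$patient_id, sim$truth_labels$patient_id)]
  st <- age_stratum(cc$cohort$age) == "65-84"
  des2 <- build_design(cc$cohort[st, ], lab[st], 1L)
  expect_identical(qr(des2$X)$rank, ncol(des2$X))

  d_na <- d; d_na$bmi[2] <- NA
  expect_error(build_design(d_na, a, 1L), "complete cases")
  expect_error(build_design(d, a, 9L), "no members")
  expect_warning(build_design(d, c(1L, 1L, 1L, 2L, 2L, 3L), 1L),
                 "< 2 members")
})

test_that("two-group count model reproduces the ratio of group means exactly", {
  X <- cbind(`(Intercept)` = rep(1, 40), group = rep(c(0, 1), each = 20))
  y <- c(rep(2L, 20), rep(4L, 20))
  fit <- fit_count_glm(y, X, family = "poisson")
  irr <- fit$coefficients$ratio[fit$coefficients$term == "group"]
  expect_equal(irr, 2, tolerance = 1e-6)

  # identical counts across groups: aIRR exactly 1
  fit0 <- fit_count_glm(rep(3L, 40), X, family = "poisson")
  expect_equal(fit0$coefficients$ratio[2], 1, tolerance = 1e-8)

  # NB and Poisson agree on equidispersed data
  set.seed(81)
  y2 <- rpois(500, exp(1 + 0.5 * rep(c(0, 1), 250)))
  X2 <- cbind(1, rep(c(0, 1), 250))
  colnames(X2) <- c("(Intercept)", "group")
  fp <- fit_count_glm(y2, X2, family = "poisson")
  fnb <- fit_count_glm(y2, X2, family = "negative_binomial")
  expect_equal(fnb$coefficients$estimate, fp$coefficients$estimate,
               tolerance = 1e-4)
  expect_lt(fnb$dispersion, 0.05)

  # permutation invariance
  perm <- sample(40)
  fitp <- fit_count_glm(y[perm], X[perm, ], family = "poisson")
  expect_equal(fitp$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-8)

  expect_error(fit_count_glm(y, X[, c(1, 1, 2)]), "rank deficient")
  expect_error(fit_count_glm(c(y[-1], -1), X), "non-negative")
})

test_that("logistic model reproduces the 2x2 cross-product odds ratio", {
  X <- cbind(`(Intercept)` = rep(1, 200),
             exposed = rep(c(1, 0), each = 100))
  y <- c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95))
  fit <- fit_mortality_glm(y, X)
  or <- fit$coefficients$ratio[fit$coefficients$term == "exposed"]
  expect_equal(or, (10 * 95) / (90 * 5), tolerance = 1e-6)
  expect_true(all(fit$coefficients$ci_lower <=
                    fit$coefficients$estimate &
                  fit$coefficients$estimate <=
                    fit$coefficients$ci_upper))

  # balanced null: OR exactly 1
  y0 <- rep(c(1, 0, 1, 0), each = 50)
  expect_equal(fit_mortality_glm(y0, X)$coefficients$ratio[2], 1,
               tolerance = 1e-8)

  # complete separation is refused with the column named
  ysep <- X[, "exposed"]
  expect_error(fit_mortality_glm(ysep, X), "separation.*exposed")
  expect_error(fit_mortality_glm(rep(1, 200), X), "both outcome levels")
})

test_that("full outcome-model wrapper ties the stages together", {
  truth <- default_simulation_truth(n_scale = 0.05)
  sim <- simulate_cohort(truth)
  st <- age_stratum(sim$cohort$age) == "65-84"
  d <- sim$cohort[st, ]
  attr(d, "condition_registry") <- attr(sim$cohort, "condition_registry")
  lab <- sim$truth_labels$true_class[st]
  res <- suppressWarnings(
    cluster_outcome_models(d, lab, family = "poisson"))
  expect_s3_class(res$models$gp_consults, "outcome_glm")
  expect_identical(res$models$gp_consults$family, "poisson")
  # reference cluster is the hypertension-led lowest-impact class
  expect_identical(res$reference_cluster, 1L)
  irr <- res$models$gp_consults$coefficients
  expect_true(all(irr$ratio > 0))
  expect_true(all(irr$ratio_lower <= irr$ratio &
                  irr$ratio <= irr$ratio_upper))
})
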