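test_that("condition simulator honours degenerate and seeded contracts", {
  # K = 1 with rho = 0 everywhere yields an all-zero matrix
  p0 <- lca_params(1, matrix(0, 1, 4))
  s0 <- simulate_conditions(p0, 25, seed = 1)
  expect_true(all(s0$data == 0))
  expect_true(all(s0$class == 1L))

  # identical seeds give bit-identical draws
  p <- two_class_params()
  a <- simulate_conditions(p, 500, seed = 42)
  b <- simulate_conditions(p, 500, seed = 42)
  expect_identical(a$data, b$data)
  expect_identical(a$class, b$class)

  expect_error(simulate_conditions(p, 0), "n must be")
})

test_that("simulated prevalences converge to the mixture marginals", {
  # symmetric 0.9/0.1 mixture: marginal prevalence 0.5 per condition
  p <- two_class_params(J = 5)
  s <- simulate_conditions(p, 10000, seed = 7)
  mc_sd <- sqrt(0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(s$data) - 0.5) < 3 * mc_sd))

  # asymmetric mixture at larger n: within 4 binomial SDs of
  # sum_k pi_k rho_kj
  p2 <- block_params(K = 3, J = 6, hi = 0.7, lo = 0.05,
                     pi = c(0.5, 0.3, 0.2))
  s2 <- simulate_conditions(p2, 100000, seed = 8)
  expected <- as.numeric(p2$pi %*% p2$rho)
  tol <- 4 * sqrt(expected * (1 - expected) / 100000)
  expect_true(all(abs(colMeans(s2$data) - expected) < tol))
})

test_that("outcome simulator matches its stated generative model", {
  n <- 50000
  classes <- rep(c(1L, 2L), length.out = n)
  cov <- data.frame(age = rep(60, n), gender = rep("F", n),
                    imd = rep(3L, n), smoking = rep("never", n),
                    bmi = rep(27, n))
  # null model: all coefficients zero, Poisson counts -> mean exp(0)=1
  mk_truth <- function(cls_gp) simulation_truth(
    list(stratum_spec("45-64", 10, c(45, 64),
                      two_class_params(J = 4))),
    outcome_coefficients = list(
      gp_consults = list(intercept = 0,
                         class_effects = list("45-64" = cls_gp)),
      hospitalisations = list(class_effects = list("45-64" = c(0, 0))),
      regular_meds = list(class_effects = list("45-64" = c(0, 0))),
      died_2yr = list(intercept = -1,
                      class_effects = list("45-64" = c(0, 0))),
      died_5yr = list(intercept = 0,
                      class_effects = list("45-64" = c(0, 0)))),
    dispersion = list(), seed = 5L)

  out <- simulate_outcomes(classes, cov, mk_truth(c(0, 0)), "45-64",
                           seed = 9)
  expect_lt(abs(mean(out$gp_consults) - 1), 3 * sqrt(1 / n))

  # planted class effect log(2) on counts: class mean ratio ~ 2
  out2 <- simulate_outcomes(classes, cov, mk_truth(c(0, log(2))),
                            "45-64", seed = 10)
  ratio <- mean(out2$gp_consults[classes == 2L]) /
    mean(out2$gp_consults[classes == 1L])
  expect_lt(abs(ratio - 2), 0.1)

  # monotone mortality: certain 2-year death forces 5-year death
  tr3 <- mk_truth(c(0, 0))
  tr3$outcome_coefficients$died_2yr$intercept <- 40
  out3 <- simulate_outcomes(classes[1:500], cov[1:500, ], tr3,
                            "45-64", seed = 11)
  expect_true(all(out3$died_2yr == 1))
  expect_true(all(out3$died_5yr == 1))

  expect_error(simulate_outcomes(classes[1:10], cov, mk_truth(c(0, 0)),
                                 "45-64"), "different lengths")
})

test_that("cohort simulator respects stratum structure and missingness", {
  truth <- default_simulation_truth()   # study sizes scaled by 1/100
  sim <- simulate_cohort(truth)
  counts <- table(age_stratum(sim$cohort$age))
  expect_identical(as.integer(counts), c(153L, 361L, 495L, 123L))
  st <- age_strata()
  f <- age_stratum(sim$cohort$age)
  for (i in seq_len(nrow(st))) {
    ages <- sim$cohort$age[f == st$label[i]]
    expect_true(all(ages >= st$lower[i] & ages < st$upper[i]))
  }
  # labels live in a side table, not in the cohort
  expect_false("true_class" %in% names(sim$cohort))
  expect_identical(sim$truth_labels$patient_id, sim$cohort$patient_id)
  # hierarchical mortality is monotone for every patient
  expect_true(all(sim$cohort$died_5yr >= sim$cohort$died_2yr))
  # reproducibility
  sim2 <- simulate_cohort(truth)
  expect_identical(sim$cohort, sim2$cohort)

  # zero missingness leaves no missing fields
  spec <- stratum_spec("18-44", 200, c(18, 44),
                       two_class_params(J = 4),
                       smoking_missing = 0, bmi_missing = 0)
  tr <- default_simulation_truth()
  tr$strata_specs <- list("18-44" = spec)
  sim3 <- simulate_cohort(tr)
  expect_false(anyNA(sim3$cohort$smoking))
  expect_false(anyNA(sim3$cohort$bmi))
})

test_that("simulation truth validates probability vectors and rates", {
  expect_error(stratum_spec("a", 10, c(18, 44), two_class_params(4),
                            imd_probs = c(0.3, 0.3, 0.3, 0.05, 0.06)),
               "sum to 1")
  expect_error(stratum_spec("a", 10, c(18, 44), two_class_params(4),
                            bmi_missing = 1.2), "missingness")
  expect_error(stratum_spec("a", 0, c(18, 44), two_class_params(4)),
               "n_patients")
})

test_that("built-in contingency fixtures reproduce the printed margins", {
  f <- builtin_fixtures()
  # male multimorbid cell follows by subtraction: 113,211 - 63,072
  expect_identical(f$gender_mm["M", "multimorbid"], 50139)
  expect_identical(sum(f$gender_mm), 391669)
  expect_identical(sum(f$gender_mm[, "multimorbid"]), 113211)
  expect_identical(unname(rowSums(f$gender_mm)), c(192929, 198740))
  expect_identical(sum(f$imd_mm[, "multimorbid"]), 113211)
  expect_identical(unname(rowSums(f$imd_mm)),
                   c(90730, 87734, 81569, 71424, 60212))
})
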