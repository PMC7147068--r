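test_that("morbidity count and the two-condition threshold", {
  cond <- rbind(c(0, 0, 0, 0),
                c(1, 0, 0, 0),
                c(1, 1, 0, 0),
                c(1, 1, 1, 1))
  d <- toy_cohort(cond)
  expect_identical(morbidity_count(d), c(0L, 1L, 2L, 4L))
  expect_identical(is_multimorbid(d), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("age stratification partitions the cohort at the documented bounds", {
  ages <- c(18L, 44L, 45L, 64L, 65L, 84L, 85L, 99L)
  f <- age_stratum(ages)
  expect_identical(as.character(f),
                   c("18-44", "18-44", "45-64", "45-64",
                     "65-84", "65-84", "85+", "85+"))
  expect_error(age_stratum(c(17L, 30L)), ">= 18")

  d <- toy_cohort(matrix(0, 50, 3), age = sample(18:95, 50, TRUE))
  parts <- stratify_by_age(d)
  expect_identical(sum(vapply(parts, nrow, 0L)), nrow(d))
  expect_identical(sort(unname(unlist(lapply(parts, `[[`,
                                             "patient_id")))),
                   sort(d$patient_id))
})

test_that("stratified split takes floor(fraction * n) per stratum, reproducibly", {
  ages <- rep(c(30L, 50L, 70L, 90L), times = c(153, 361, 495, 123))
  d <- toy_cohort(matrix(0, length(ages), 3), age = ages)
  sp <- split_train_test(d, 0.8, seed = 3)
  tr_sizes <- table(age_stratum(sp$train$age))
  expect_identical(as.integer(tr_sizes), c(122L, 288L, 396L, 98L))
  # disjoint and exhaustive
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  d$patient_id)
  # same seed, same membership
  sp2 <- split_train_test(d, 0.8, seed = 3)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)

  d10 <- toy_cohort(matrix(0, 10, 3), age = rep(30L, 10))
  w <- capture_warnings(sp10 <- split_train_test(d10, 0.8, seed = 1))
  expect_length(w, 3)          # the three unpopulated strata
  expect_match(w, "empty", all = TRUE)
  expect_identical(nrow(sp10$train), 8L)
  expect_identical(nrow(sp10$test), 2L)

  expect_error(split_train_test(d, 1.2), "train_fraction")
})

test_that("demographic summaries use linear-interpolation quartiles", {
  cond <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                c(1, 1, 1, 0), c(1, 1, 1, 1))
  d <- toy_cohort(cond, imd = c(5L, 5L, 5L, 5L),
                  gender = c("F", "M", "F", "F"))
  s <- summarize_demographics(d)
  # counts {2,2,3,4}: median 2.5, Q1 2, Q3 3.25 under type-7 quantiles
  expect_equal(s$morbidity_median, 2.5)
  expect_equal(s$morbidity_q1, 2)
  expect_equal(s$morbidity_q3, 3.25)
  expect_equal(s$pct_multimorbid, 100)
  expect_equal(s$pct_greater_deprivation, 100)
  expect_equal(s$pct_female, 75)

  s1 <- summarize_demographics(d[3, , drop = FALSE])
  expect_equal(s1$morbidity_median, 3)
  expect_equal(s1$morbidity_q1, 3)
  expect_equal(s1$morbidity_q3, 3)

  expect_error(summarize_demographics(d, "nope"), "unknown grouping")

  by_g <- summarize_demographics(d, "gender")
  expect_identical(by_g$group, c("F", "M"))
  expect_identical(sum(by_g$n), 4L)
})

test_that("chi-square independence matches a brute-force cell loop", {
  f <- builtin_fixtures()
  g <- chisq_independence(f$gender_mm)
  expect_equal(g$statistic, naive_chisq(f$gender_mm, yates = TRUE),
               tolerance = 1e-10)
  expect_identical(g$df, 1L)
  i <- chisq_independence(f$imd_mm)
  expect_equal(i$statistic, naive_chisq(f$imd_mm, yates = FALSE),
               tolerance = 1e-10)
  expect_identical(i$df, 4L)

  # property: random tables agree with the double loop; Yates for 2x2
  set.seed(14)
  for (rep in 1:10) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(sample(5:200, r * cc, TRUE), r, cc)
    res <- chisq_independence(tab)
    expect_equal(res$statistic,
                 naive_chisq(tab, yates = r == 2 && cc == 2),
                 tolerance = 1e-10)
    expect_identical(res$df, (r - 1L) * (cc - 1L))
  }

  # identical row proportions -> exact independence, statistic 0
  tab0 <- rbind(c(30, 70), c(60, 140), c(90, 210))
  expect_equal(chisq_independence(tab0)$statistic, 0)

  expect_error(chisq_independence(rbind(c(0, 0), c(3, 4))),
               "zero row or column")
  expect_error(chisq_independence(rbind(c(-1, 2), c(3, 4))),
               "non-negative")
  expect_error(chisq_independence(matrix(1:3, 1)), "at least 2x2")
})

test_that("combination frequencies count exact multisets with stable ties", {
  cond <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 1))
  d <- toy_cohort(cond)
  cf <- combination_frequencies(d)
  expect_identical(cf$count, c(2L, 1L))
  expect_identical(cf$combination[1], "cond_01+cond_02")
  expect_identical(cf$combination[2], "cond_01+cond_03")
  expect_identical(sum(cf$count), nrow(d))

  # all patients share one combination -> single 100% entry
  d1 <- toy_cohort(matrix(rep(c(1, 0, 1), 5), 5, 3, byrow = TRUE))
  cf1 <- combination_frequencies(d1)
  expect_identical(nrow(cf1), 1L)
  expect_equal(cf1$pct, 100)

  # two point-mass classes -> exactly two combinations
  pm <- lca_params(c(0.5, 0.5), rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  s <- simulate_conditions(pm, 200, seed = 5)
  cf2 <- combination_frequencies(toy_cohort(s$data))
  expect_identical(nrow(cf2), 2L)
  expect_identical(sum(cf2$count), 200L)

  # tie-break: equal counts ordered lexicographically by indices
  cond3 <- rbind(c(1, 0, 1), c(1, 1, 0))
  cf3 <- combination_frequencies(toy_cohort(cond3))
  expect_identical(cf3$combination,
                   c("cond_01+cond_02", "cond_01+cond_03"))
})
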