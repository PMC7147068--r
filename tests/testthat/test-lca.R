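test_that("parameter container enforces its invariants", {
  expect_error(lca_params(c(0.6, 0.5), matrix(0.5, 2, 3)), "sum to 1")
  expect_error(lca_params(c(0.5, 0.5), matrix(1.5, 2, 3)), "\\[0, 1\\]")
  expect_error(lca_params(c(0.5, 0.5), matrix(0.5, 3, 2)),
               "one row per class")
  p <- lca_params(c(0.7, 0.3), matrix(0.4, 2, 5))
  expect_identical(p$K, 2L)
  expect_identical(p$J, 5L)
})

test_that("log-likelihood matches closed forms and the naive oracle", {
  # K=1, J=1, y = (1,1,0,0), rho = 0.5: 4 * ln 0.5
  p1 <- lca_params(1, matrix(0.5, 1, 1))
  y1 <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(log_likelihood(p1, y1), 4 * log(0.5), tolerance = 1e-10)

  # degenerate mixture pi = (1, 0) equals the K=1 likelihood
  set.seed(21)
  y <- matrix(rbinom(18, 1, 0.5), 6, 3)
  p_deg <- lca_params(c(1, 0), rbind(rep(0.3, 3), rep(0.8, 3)))
  p_one <- lca_params(1, matrix(0.3, 1, 3))
  expect_equal(log_likelihood(p_deg, y), log_likelihood(p_one, y),
               tolerance = 1e-10)

  # random small instances agree with naive per-patient summation
  for (rep in 1:5) {
    p <- lca_params(as.numeric(prop.table(runif(2))),
                    matrix(runif(6, 0.05, 0.95), 2, 3))
    y <- matrix(rbinom(18, 1, 0.5), 6, 3)
    expect_equal(log_likelihood(p, y), naive_loglik(p, y),
                 tolerance = 1e-10)
  }

  expect_error(log_likelihood(p1, matrix(2, 3, 1)), "0/1")
  expect_error(log_likelihood(p1, matrix(0, 3, 2)), "expect")
})

test_that("E-step posteriors match Bayes rule and its symmetries", {
  p1 <- lca_params(1, matrix(0.4, 1, 3))
  y <- rbind(c(1, 0, 1), c(0, 0, 0))
  expect_true(all(e_step(p1, y) == 1))

  # symmetric parameters: complementary patterns swap their posteriors
  ps <- two_class_params(J = 3, hi = 0.8, lo = 0.2)
  pat <- rbind(c(1, 1, 0), c(0, 0, 1))
  post <- e_step(ps, pat)
  expect_equal(post[1, ], rev(post[2, ]), tolerance = 1e-12)

  set.seed(22)
  for (rep in 1:5) {
    p <- lca_params(as.numeric(prop.table(runif(2))),
                    matrix(runif(6, 0.05, 0.95), 2, 3))
    y <- matrix(rbinom(18, 1, 0.5), 6, 3)
    expect_equal(e_step(p, y), naive_posterior(p, y),
                 tolerance = 1e-12)
    expect_equal(rowSums(e_step(p, y)), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("M-step recovers weighted prevalences and class fractions", {
  y <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 1))
  onehot <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  p <- m_step(onehot, y)
  expect_equal(p$pi, c(0.5, 0.5))
  expect_equal(unname(p$rho[1, ]), c(1 - 1e-6, 0.5, 1e-6))
  expect_equal(unname(p$rho[2, ]), c(1e-6, 0.5, 1 - 1e-6))

  # uniform posteriors collapse both classes to the overall prevalence
  unif <- matrix(0.5, 4, 2)
  pu <- m_step(unif, y)
  expect_equal(unname(pu$rho[1, ]), colMeans(y))
  expect_equal(unname(pu$rho[2, ]), colMeans(y))

  # random soft posteriors match direct weighted means
  set.seed(23)
  w <- matrix(runif(8), 4, 2); w <- w / rowSums(w)
  pw <- m_step(w, y)
  for (k in 1:2)
    expect_equal(unname(pw$rho[k, ]),
                 colSums(w[, k] * y) / sum(w[, k]), tolerance = 1e-12)

  expect_warning(m_step(cbind(rep(1, 4), rep(0, 4)), y),
                 "zero posterior mass")
})

test_that("EM fits are deterministic, monotone and label-stable", {
  p <- two_class_params(J = 10)
  s <- simulate_conditions(p, 2000, seed = 31)
  f1 <- fit_em(s$data, 2, n_restarts = 5, seed = 7)
  f2 <- fit_em(s$data, 2, n_restarts = 5, seed = 7)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$pi, f2$params$pi)
  expect_identical(f1$assignment, f2$assignment)

  # monotone log-likelihood trace within the winning run
  expect_true(all(diff(f1$ll_trace) > -1e-6))
  # posterior rows on the simplex; assignment is the row argmax
  expect_equal(rowSums(f1$posterior), rep(1, f1$N), tolerance = 1e-8)
  expect_identical(f1$assignment,
                   max.col(f1$posterior, ties.method = "first"))
  # classes ordered by descending mixing proportion
  expect_true(all(diff(f1$params$pi) <= 0))
  expect_lte(f1$loglik, 0)

  # parameter recovery on well-separated classes
  m <- matched_mae(p, f1$params)
  expect_lt(m$pi, 0.03)
  expect_lt(m$rho, 0.05)

  # row permutation leaves the fitted model unchanged (same seed)
  perm <- sample(nrow(s$data))
  f3 <- fit_em(s$data[perm, ], 2, n_restarts = 5, seed = 7)
  expect_equal(f3$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f3$params$pi, f1$params$pi, tolerance = 1e-4)
  expect_equal(f3$params$rho, f1$params$rho, tolerance = 1e-3)
})

test_that("single-class fit is the closed-form prevalence model", {
  set.seed(33)
  y <- matrix(rbinom(200, 1, 0.3), 50, 4)
  f <- fit_em(y, 1, n_restarts = 1, seed = 1)
  expect_equal(f$params$pi, 1)
  expect_equal(unname(f$params$rho[1, ]), colMeans(y),
               tolerance = 1e-9)
  expect_identical(f$n_params, 4)
  expect_true(all(f$posterior == 1))
})

test_that("EM guards its preconditions", {
  y <- matrix(rbinom(20, 1, 0.5), 5, 4)
  expect_error(fit_em(y, 5), "more observations than classes")
  expect_error(fit_em(y, 0), "K must be")
  y2 <- matrix(rep(c(0, 1), each = 20), 40, 1)
  expect_warning(fit_em(y2, 3, n_restarts = 2, seed = 1),
                 "distinct response patterns")
})
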