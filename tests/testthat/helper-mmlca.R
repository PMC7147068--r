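# shared test fixtures, all generated in code

# well-separated two-class parameters on J indicators
two_class_params <- function(J = 10, hi = 0.9, lo = 0.1,
                             pi = c(0.5, 0.5)) {
  lca_params(pi, rbind(rep(hi, J), rep(lo, J)))
}

# block-structured K-class parameters: class k has prevalence `hi` on
# its own block of conditions and `lo` elsewhere
block_params <- function(K = 3, J = 20, hi = 0.8, lo = 0.1,
                         pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / K, K)
  rho <- matrix(lo, K, J)
  block <- floor(J / K)
  for (k in seq_len(K))
    rho[k, ((k - 1) * block + 1):(k * block)] <- hi
  lca_params(pi / sum(pi), rho)
}

# minimal valid cohort data frame wrapping a condition matrix
toy_cohort <- function(cond, age = NULL, gender = NULL, imd = NULL,
                       smoking = NULL, bmi = NULL, gp = NULL,
                       hosp = NULL, meds = NULL, died2 = NULL,
                       died5 = NULL) {
  n <- nrow(cond)
  cond_df <- as.data.frame(cond)
  names(cond_df) <- sprintf("cond_%02d", seq_len(ncol(cond)))
  d <- cbind(
    data.frame(patient_id = sprintf("t%04d", seq_len(n)),
               age = age %||% rep(50L, n),
               gender = gender %||% rep("F", n),
               imd = imd %||% rep(3L, n),
               smoking = smoking %||% rep("never", n),
               bmi = bmi %||% rep(27, n)),
    cond_df,
    data.frame(gp_consults = gp %||% rep(0L, n),
               hospitalisations = hosp %||% rep(0L, n),
               regular_meds = meds %||% rep(0L, n),
               died_2yr = died2 %||% rep(0L, n),
               died_5yr = died5 %||% rep(0L, n)))
  attr(d, "condition_registry") <- names(cond_df)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive log-likelihood oracle: per-patient product over classes,
# no log-space tricks
naive_loglik <- function(params, y) {
  ll <- 0
  for (i in seq_len(nrow(y))) {
    tot <- 0
    for (k in seq_len(params$K)) {
      f <- params$pi[k]
      for (j in seq_len(params$J)) {
        f <- f * (if (y[i, j] == 1) params$rho[k, j]
                  else 1 - params$rho[k, j])
      }
      tot <- tot + f
    }
    ll <- ll + log(tot)
  }
  ll
}

# naive posterior oracle via direct Bayes rule
naive_posterior <- function(params, y) {
  post <- matrix(NA_real_, nrow(y), params$K)
  for (i in seq_len(nrow(y))) {
    f <- numeric(params$K)
    for (k in seq_len(params$K)) {
      f[k] <- params$pi[k]
      for (j in seq_len(params$J))
        f[k] <- f[k] * (if (y[i, j] == 1) params$rho[k, j]
                        else 1 - params$rho[k, j])
    }
    post[i, ] <- f / sum(f)
  }
  post
}

# brute-force Pearson chi-square with optional Yates correction
naive_chisq <- function(tab, yates) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    d <- abs(tab[i, j] - E[i, j])
    if (yates) d <- max(d - 0.5, 0)
    stat <- stat + d^2 / E[i, j]
  }
  stat
}

# mean absolute rho error after best class matching (small K only)
matched_mae <- function(true, est) {
  K <- true$K
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  best <- Inf; best_pi <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    mae <- mean(abs(true$rho - est$rho[p, , drop = FALSE]))
    if (mae < best) {
      best <- mae
      best_pi <- mean(abs(true$pi - est$pi[p]))
    }
  }
  list(rho = best, pi = best_pi)
}
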