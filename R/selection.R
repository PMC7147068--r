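#' Information criteria for a latent class fit
#'
#' `bic()` is the Bayesian information criterion
#' `-2 * loglik + p * log(N)`; `abic()` is the sample-size-adjusted
#' variant that replaces `log(N)` with `log((N + 2) / 24)`. The
#' parameter count is `p = (K - 1) + K * J`.
#'
#' @param fit An `lca_fit` object.
#' @return A scalar criterion value (smaller is better).
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "lca_fit"))
  if (fit$N <= 0) stop("fit has non-positive sample size")
  -2 * fit$loglik + fit$n_params * log(fit$N)
}

#' @rdname bic
#' @export
abic <- function(fit) {
  stopifnot(inherits(fit, "lca_fit"))
  if (fit$N <= 0) stop("fit has non-positive sample size")
  -2 * fit$loglik + fit$n_params * log((fit$N + 2) / 24)
}

#' Relative entropy of the classification
#'
#' Scaled measure of how cleanly the posterior separates patients into
#' classes:
#' \deqn{E = 1 + \frac{\sum_i \sum_k p_{ik} \log p_{ik}}{N \log K},}
#' with the convention `0 * log(0) = 0`. `E = 1` indicates perfect
#' (one-hot) classification, `E = 0` uniform posteriors; a single-class
#' model is defined to have `E = 1`.
#'
#' @param fit An `lca_fit` object, or a bare `N x K` posterior matrix.
#' @return A scalar in `[0, 1]`.
#' @export
relative_entropy <- function(fit) {
  post <- if (inherits(fit, "lca_fit")) fit$posterior else as.matrix(fit)
  K <- ncol(post)
  if (K == 1L) return(1)
  plogp <- post * log(post)
  plogp[!is.finite(plogp)] <- 0
  1 + sum(plogp) / (nrow(post) * log(K))
}

#' Parametric bootstrap likelihood-ratio test for K vs K + 1 classes
#'
#' The naive likelihood-ratio statistic `-2 * (loglik_null -
#' loglik_alt)` has no standard chi-square reference distribution for
#' mixtures, so the null distribution is built by parametric bootstrap:
#' `B` datasets are simulated from the fitted `K_null`-class model and
#' both models are refitted to each. The p-value is
#' `(1 + #\{boot >= observed\}) / (B + 1)`. The alternative fit always
#' includes one warm start that splits a null class in two, which
#' guarantees a non-negative observed statistic.
#'
#' @param data Binary `N x J` matrix.
#' @param K_null Null number of classes.
#' @param K_alt Alternative number of classes; must equal `K_null + 1`.
#' @param B Number of bootstrap replicates (default 19).
#' @param seed Optional integer seed.
#' @param n_restarts Restarts per fit (default 5; bootstrap refits are
#'   many, so a lighter setting than [fit_em]'s default is used).
#' @param ... Further arguments passed to [fit_em].
#' @return List with `statistic`, `p_value`, `boot_stats`, `fit_null`,
#'   `fit_alt`.
#' @export
bootstrap_lrt <- function(data, K_null, K_alt = K_null + 1, B = 19,
                          seed = NULL, n_restarts = 5, ...) {
  if (K_alt != K_null + 1)
    stop("bootstrap LRT compares adjacent models: K_alt must be K_null + 1")
  if (B < 1) stop("B must be >= 1")
  data <- check_binary_matrix(data)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(2147483646L, B + 2L)

  fit_pair <- function(y, s) {
    f0 <- fit_em(y, K_null, n_restarts = n_restarts, seed = s, ...)
    warm <- split_class_init(f0$params)
    f1 <- fit_em(y, K_alt, n_restarts = n_restarts, seed = s + 1L,
                 init = list(warm), ...)
    list(f0 = f0, f1 = f1,
         stat = max(0, -2 * (f0$loglik - f1$loglik)))
  }

  obs <- fit_pair(data, seeds[1L])
  boot_stats <- numeric(B)
  for (b in seq_len(B)) {
    sim <- simulate_conditions(obs$f0$params, nrow(data),
                               seed = seeds[b + 2L])
    boot_stats[b] <- fit_pair(sim$data, seeds[b + 2L])$stat
  }
  list(statistic = obs$stat,
       p_value = (1 + sum(boot_stats >= obs$stat)) / (B + 1),
       boot_stats = boot_stats,
       fit_null = obs$f0, fit_alt = obs$f1)
}

# warm start for K+1 classes: duplicate the largest class with its
# mixing mass split in half, leaving the likelihood of the null optimum
# attainable at iteration zero
split_class_init <- function(params) {
  k <- which.max(params$pi)
  pi <- c(params$pi, params$pi[k] / 2)
  pi[k] <- pi[k] / 2
  rho <- rbind(params$rho, params$rho[k, ])
  list(pi = pi / sum(pi), rho = pmin(pmax(rho, 1e-3), 1 - 1e-3))
}

#' Scan the number of latent classes and select one
#'
#' Fits the model for every `K` in `k_range` and tabulates
#' log-likelihood, parameter count, BIC, sample-size-adjusted BIC,
#' relative entropy and (optionally) the parametric bootstrap LRT
#' against `K - 1`. The default selection rule minimises aBIC among
#' fits whose relative entropy reaches `entropy_floor`; when no fit
#' does, the overall aBIC minimiser is chosen and flagged. The full
#' table is always returned so the statistical evidence can be weighed
#' alongside clinical judgement.
#'
#' @param data Binary `N x J` matrix.
#' @param k_range Integer vector of candidate class counts.
#' @param n_restarts Restarts per fit (default 20).
#' @param entropy_floor Minimum relative entropy for a fit to be
#'   eligible under the default rule (default 0.8).
#' @param bootstrap_B Bootstrap LRT replicates per adjacent pair; 0
#'   (default) skips the test.
#' @param seed Optional integer seed; per-K seeds are derived from it.
#' @param ... Further arguments passed to [fit_em].
#' @return An object of class `lca_selection`: `table` (one row per K),
#'   `chosen_K`, `rule`, `entropy_floor_met`, and `fits` (named list of
#'   `lca_fit` objects).
#' @export
select_k <- function(data, k_range, n_restarts = 20,
                     entropy_floor = 0.8, bootstrap_B = 0,
                     seed = NULL, ...) {
  if (length(k_range) < 1L) stop("k_range must be non-empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1L) stop("k_range entries must be >= 1")
  data <- check_binary_matrix(data)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)

  fits <- list()
  rows <- list()
  for (K in k_range) {
    s <- if (is.null(base_seed)) NULL else
      (base_seed + 7919L * K) %% 2147483647L
    fit <- fit_em(data, K, n_restarts = n_restarts, seed = s, ...)
    fits[[as.character(K)]] <- fit
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = fit$loglik, n_params = fit$n_params,
      bic = bic(fit), abic = abic(fit),
      entropy = relative_entropy(fit),
      lrt_stat = NA_real_, lrt_p = NA_real_,
      n_restarts = fit$n_restarts_used, converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  if (bootstrap_B > 0) {
    for (i in seq_along(k_range)[-1L]) {
      if (k_range[i] != k_range[i - 1L] + 1L) next
      s <- if (is.null(base_seed)) NULL else
        (base_seed + 104729L * k_range[i]) %% 2147483647L
      lrt <- bootstrap_lrt(data, k_range[i - 1L], k_range[i],
                           B = bootstrap_B, seed = s,
                           n_restarts = min(n_restarts, 5L), ...)
      tab$lrt_stat[i] <- lrt$statistic
      tab$lrt_p[i] <- lrt$p_value
    }
  }

  eligible <- tab$entropy >= entropy_floor
  floor_met <- any(eligible)
  pool <- if (floor_met) which(eligible) else seq_len(nrow(tab))
  chosen <- tab$K[pool[which.min(tab$abic[pool])]]
  structure(list(
    table = tab, chosen_K = chosen,
    rule = paste0("minimum aBIC among fits with relative entropy >= ",
                  entropy_floor,
                  if (!floor_met) " (no fit met the floor; overall aBIC minimiser chosen)"),
    entropy_floor_met = floor_met,
    fits = fits), class = "lca_selection")
}

#' @export
print.lca_selection <- function(x, ...) {
  cat("Latent class model selection (chosen K =", x$chosen_K, ")\n")
  cat("  rule:", x$rule, "\n")
  print(x$table, digits = 6)
  invisible(x)
}
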