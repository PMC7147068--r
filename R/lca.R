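#' Latent class model parameters for binary indicators
#'
#' Container for the parameters of a `K`-class latent class model over
#' `J` binary condition indicators: mixing proportions `pi` (prior class
#' probabilities) and item-response probabilities `rho`, where
#' `rho[k, j]` is the probability that condition `j` is present given
#' membership of class `k`.
#'
#' @param pi Numeric vector of `K >= 1` non-negative mixing proportions
#'   summing to 1 (tolerance `1e-10`).
#' @param rho Numeric `K x J` matrix of probabilities in `[0, 1]`.
#'   Column names, when present, are carried as the condition registry.
#' @return An object of class `lca_params` with elements `K`, `J`, `pi`,
#'   `rho`.
#' @export
#' @examples
#' lca_params(c(0.6, 0.4), rbind(rep(0.9, 3), rep(0.1, 3)))
lca_params <- function(pi, rho) {
  if (!is.numeric(pi) || length(pi) < 1L || anyNA(pi))
    stop("`pi` must be a numeric vector of length >= 1 without NAs")
  if (any(pi < 0)) stop("`pi` entries must be non-negative")
  if (abs(sum(pi) - 1) > 1e-10)
    stop("`pi` must sum to 1 (got ", format(sum(pi)), ")")
  rho <- as.matrix(rho)
  if (nrow(rho) != length(pi))
    stop("`rho` must have one row per class: nrow(rho) = ", nrow(rho),
         ", length(pi) = ", length(pi))
  if (!is.numeric(rho) || anyNA(rho) || any(rho < 0) || any(rho > 1))
    stop("`rho` entries must be probabilities in [0, 1]")
  structure(list(K = length(pi), J = ncol(rho),
                 pi = as.numeric(pi), rho = rho),
            class = "lca_params")
}

#' @export
print.lca_params <- function(x, ...) {
  cat("Latent class parameters:", x$K, "classes,", x$J, "indicators\n")
  cat("  pi:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

# validate a binary data matrix against expected number of indicators
check_binary_matrix <- function(data, J = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data))
    stop("data must be a numeric binary matrix without NAs")
  if (!all(data %in% c(0, 1)))
    stop("data must contain only 0/1 entries")
  if (!is.null(J) && ncol(data) != J)
    stop("data has ", ncol(data), " columns but parameters expect ", J)
  data
}

# N x K matrix of per-class log pattern densities plus log prior
class_log_densities <- function(params, data) {
  eps <- 1e-12
  lr <- log(pmin(pmax(params$rho, eps), 1 - eps))
  lrc <- log(pmin(pmax(1 - params$rho, eps), 1 - eps))
  lf <- data %*% t(lr) + (1 - data) %*% t(lrc)
  sweep(lf, 2L, log(pmax(params$pi, eps)), "+")
}

#' Log-likelihood of a binary latent class model
#'
#' Total observed-data log-likelihood
#' \deqn{\ell = \sum_i \log \sum_k \pi_k \prod_j
#'   \rho_{kj}^{y_{ij}} (1-\rho_{kj})^{1-y_{ij}},}
#' evaluated in log space with a log-sum-exp over classes.
#'
#' @param params An [lca_params] object.
#' @param data Binary `N x J` matrix (0/1 entries).
#' @return A finite scalar log-likelihood.
#' @export
log_likelihood <- function(params, data) {
  stopifnot(inherits(params, "lca_params"))
  data <- check_binary_matrix(data, params$J)
  lf <- class_log_densities(params, data)
  m <- do.call(pmax, c(as.data.frame(lf), list(na.rm = FALSE)))
  sum(m + log(rowSums(exp(lf - m))))
}

#' E-step: posterior class membership probabilities
#'
#' Bayes-rule posteriors
#' \eqn{p_{ik} = \pi_k f_k(y_i) / \sum_m \pi_m f_m(y_i)}, computed via
#' log-space normalisation so extreme patterns do not underflow.
#'
#' @inheritParams log_likelihood
#' @return `N x K` matrix; each row lies on the simplex.
#' @export
e_step <- function(params, data) {
  stopifnot(inherits(params, "lca_params"))
  data <- check_binary_matrix(data, params$J)
  lf <- class_log_densities(params, data)
  m <- do.call(pmax, c(as.data.frame(lf), list(na.rm = FALSE)))
  w <- exp(lf - m)
  w / rowSums(w)
}

#' M-step: update parameters from posteriors
#'
#' Closed-form maximisers of the expected complete-data log-likelihood:
#' `pi[k] = mean_i p_ik` and
#' `rho[k, j] = sum_i p_ik y_ij / sum_i p_ik`, with `rho` clamped to
#' `[eps, 1 - eps]` to keep subsequent log-densities finite. A class
#' with zero posterior mass has its response probabilities re-seeded
#' uniformly at random (with a warning).
#'
#' @param posterior `N x K` matrix of class membership probabilities
#'   (rows on the simplex).
#' @param data Binary `N x J` matrix.
#' @param eps Clamping bound for `rho` (default `1e-6`).
#' @return An [lca_params] object.
#' @export
m_step <- function(posterior, data, eps = 1e-6) {
  posterior <- as.matrix(posterior)
  data <- check_binary_matrix(data)
  if (nrow(posterior) != nrow(data))
    stop("posterior and data row counts differ")
  if (any(abs(rowSums(posterior) - 1) > 1e-8))
    stop("posterior rows must sum to 1")
  K <- ncol(posterior); J <- ncol(data)
  mass <- colSums(posterior)
  rho <- matrix(NA_real_, K, J, dimnames = list(NULL, colnames(data)))
  for (k in seq_len(K)) {
    if (mass[k] <= 0) {
      warning("class ", k, " has zero posterior mass; re-seeding rho")
      rho[k, ] <- runif(J, 0.05, 0.95)
    } else {
      rho[k, ] <- colSums(posterior[, k] * data) / mass[k]
    }
  }
  rho <- pmin(pmax(rho, eps), 1 - eps)
  lca_params(mass / sum(mass), rho)
}

#' Fit a binary latent class model by EM with random restarts
#'
#' Runs the EM algorithm from `n_restarts` random initialisations
#' (`pi` from a symmetric Dirichlet(1), `rho` entries from
#' Uniform(0.05, 0.95)) and keeps the restart with the highest final
#' log-likelihood. Within every run the log-likelihood is checked to be
#' non-decreasing. Convergence is declared when the relative
#' log-likelihood change falls below `tol`. Classes are relabelled in
#' descending `pi` order so labels are stable across runs; each patient
#' is then given a modal assignment (posterior argmax, ties to the
#' lowest class index).
#'
#' @param data Binary `N x J` matrix of condition indicators.
#' @param K Number of latent classes (`>= 1`, `< N`).
#' @param n_restarts Number of random initialisations (default 20).
#' @param max_iter Maximum EM iterations per restart (default 1000).
#' @param tol Relative log-likelihood convergence tolerance
#'   (default `1e-8`).
#' @param seed Optional integer seed; when given the fit is fully
#'   reproducible.
#' @param eps Clamping bound for `rho` (default `1e-6`).
#' @param init Optional list of extra initialisations, each a list with
#'   elements `pi` and `rho`, run in addition to the random restarts
#'   (used e.g. to warm-start from a nested model).
#' @return An object of class `lca_fit`: `params` ([lca_params]),
#'   `loglik`, `n_params` (`(K-1) + K*J`), `posterior`, `assignment`,
#'   `converged`, `n_iterations`, `n_restarts_used`, `ll_trace` (winning
#'   restart), `seed`, `N`.
#' @export
#' @examples
#' truth <- lca_params(c(0.5, 0.5), rbind(rep(0.9, 6), rep(0.1, 6)))
#' sim <- simulate_conditions(truth, 300, seed = 1)
#' fit <- fit_em(sim$data, K = 2, n_restarts = 5, seed = 2)
#' fit$params$pi
fit_em <- function(data, K, n_restarts = 20, max_iter = 1000,
                   tol = 1e-8, seed = NULL, eps = 1e-6, init = NULL) {
  data <- check_binary_matrix(data)
  N <- nrow(data); J <- ncol(data)
  if (K < 1) stop("K must be >= 1")
  if (N <= K) stop("need more observations than classes (N = ", N,
                   ", K = ", K, ")")
  n_distinct <- nrow(unique(data))
  if (K > n_distinct)
    warning("K = ", K, " exceeds the ", n_distinct,
            " distinct response patterns; the model is likely ",
            "unidentifiable")
  if (!is.null(seed)) set.seed(seed)

  inits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    pi0 <- rgamma(K, 1); pi0 <- pi0 / sum(pi0)
    inits[[r]] <- list(pi = pi0,
                       rho = matrix(runif(K * J, 0.05, 0.95), K, J))
  }
  inits <- c(inits, init)

  best <- NULL
  for (r in seq_along(inits)) {
    run <- .em_run_cpp(data, inits[[r]]$pi,
                       matrix(inits[[r]]$rho, K, J), tol,
                       as.integer(max_iter), eps)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  ord <- order(best$pi, decreasing = TRUE)
  pi <- as.numeric(best$pi)[ord]
  rho <- best$rho[ord, , drop = FALSE]
  colnames(rho) <- colnames(data)
  posterior <- best$posterior[, ord, drop = FALSE]
  params <- lca_params(pi / sum(pi), rho)
  structure(list(
    params = params,
    loglik = best$loglik,
    n_params = (K - 1) + K * J,
    posterior = posterior,
    assignment = max.col(posterior, ties.method = "first"),
    converged = isTRUE(best$converged),
    n_iterations = best$n_iterations,
    n_restarts_used = length(inits),
    ll_trace = as.numeric(best$trace),
    seed = seed,
    N = N, J = J), class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("Latent class fit: K =", x$params$K, ", N =", x$N,
      ", J =", x$J, "\n")
  cat("  log-likelihood:", format(x$loglik), "(",
      if (x$converged) "converged" else "NOT converged", "in",
      x$n_iterations, "iterations )\n")
  cat("  class sizes:",
      paste(table(factor(x$assignment, levels = seq_len(x$params$K))),
            collapse = " "), "\n")
  invisible(x)
}

#' Serialise a latent class fit to JSON
#'
#' Writes `{K, pi, rho, condition_registry, loglik, N, seed}` plus any
#' supplied selection statistics, in a stable layout suitable for
#' re-loading and for pipeline provenance.
#'
#' @param fit An `lca_fit` object.
#' @param path Output file path.
#' @param selection Optional named list of selection statistics to embed.
#' @return `path`, invisibly.
#' @export
write_lca_fit <- function(fit, path, selection = NULL) {
  stopifnot(inherits(fit, "lca_fit"))
  obj <- list(K = fit$params$K,
              pi = fit$params$pi,
              rho = lapply(seq_len(fit$params$K), function(k)
                as.numeric(fit$params$rho[k, ])),
              condition_registry = colnames(fit$params$rho),
              loglik = fit$loglik, n_params = fit$n_params,
              N = fit$N, seed = fit$seed,
              converged = fit$converged,
              selection = selection)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Exhaustive grid-search log-likelihood for a two-class model
#'
#' Brute-force maximisation of the two-class latent class
#' log-likelihood over a dense parameter grid: `pi_1` and every entry
#' of both item-response vectors range over
#' `{step, 2*step, ..., 1-step}` independently. Intended as an
#' independent validator for [fit_em] on tiny instances (the grid grows
#' as `((1-2*step)/step + 1)^(2*J)`); the observed patterns are
#' collapsed to unique rows first.
#'
#' @param data Binary `N x J` matrix with small `J` (guarded at
#'   roughly `J <= 5` for the default step).
#' @param step Grid resolution (default 0.05).
#' @return The maximum grid log-likelihood (a scalar).
#' @export
exhaustive_loglik_k2 <- function(data, step = 0.05) {
  data <- check_binary_matrix(data)
  key <- apply(data, 1L, paste, collapse = "")
  cnt <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(cnt), ""), as.integer))
  .grid_loglik_k2_cpp(pats, as.numeric(cnt), step)
}
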