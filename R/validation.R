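#' Jensen-Shannon distance between two disease profiles
#'
#' Both prevalence vectors are first normalised to probability
#' distributions. The Jensen-Shannon divergence with base-2 logarithms
#' is `D = H(M) - (H(P) + H(Q)) / 2` where `M = (P + Q) / 2` and `H`
#' is Shannon entropy in bits; the distance is `sqrt(D)`. With base-2
#' logs the distance is bounded by 1, is symmetric, vanishes iff the
#' normalised profiles coincide, and satisfies the triangle inequality.
#'
#' @param p,q Non-negative vectors of equal length with positive sums
#'   (e.g. within-cluster condition prevalences).
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' jsd(c(1, 0), c(0.5, 0.5))
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (anyNA(p) || anyNA(q) || any(p < 0) || any(q < 0))
    stop("p and q must be non-negative and non-missing")
  if (sum(p) <= 0 || sum(q) <= 0)
    stop("p and q must each have a positive sum")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  h <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  d <- h(m) - (h(p) + h(q)) / 2
  sqrt(max(d, 0))
}

#' Pearson correlation between two disease profiles
#'
#' Standard Pearson correlation on the raw (un-normalised) prevalence
#' vectors. A constant vector has no defined correlation; `NA` is
#' returned with a warning.
#'
#' @param p,q Numeric vectors of equal length `>= 2`.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` if either
#'   vector is constant.
#' @export
profile_correlation <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (length(p) < 2) stop("profiles must have length >= 2")
  if (sd(p) == 0 || sd(q) == 0) {
    warning("constant profile: correlation undefined")
    return(NA_real_)
  }
  cor(p, q)
}

#' Match test clusters to training clusters
#'
#' For every test cluster independently, finds the training cluster at
#' minimum Jensen-Shannon distance and the one at maximum Pearson
#' profile correlation, and records whether the two criteria agree.
#' The matching is deliberately not forced one-to-one: several test
#' clusters may share a training partner. Ties go to the lowest
#' training cluster index.
#'
#' @param train_profiles,test_profiles [prevalence_profile] objects
#'   (or bare `K x J` prevalence matrices) over the same condition
#'   registry.
#' @return An object of class `cluster_match`: `jsd_matrix` and
#'   `corr_matrix` (train x test), `jsd_match` and `corr_match`
#'   (named integer maps test -> train), `agreement` (logical per test
#'   cluster).
#' @export
match_clusters <- function(train_profiles, test_profiles) {
  get_mat <- function(x) {
    if (inherits(x, "cluster_profile")) x$within else as.matrix(x)
  }
  tr <- get_mat(train_profiles); te <- get_mat(test_profiles)
  if (ncol(tr) != ncol(te))
    stop("profiles use different condition registries")
  if (!is.null(colnames(tr)) && !is.null(colnames(te)) &&
      !identical(colnames(tr), colnames(te)))
    stop("profiles use different condition registries")
  nt <- nrow(tr); ne <- nrow(te)
  jm <- matrix(NA_real_, nt, ne,
               dimnames = list(rownames(tr), rownames(te)))
  cm <- jm
  for (i in seq_len(nt)) for (j in seq_len(ne)) {
    jm[i, j] <- jsd(tr[i, ], te[j, ])
    cm[i, j] <- suppressWarnings(profile_correlation(tr[i, ], te[j, ]))
  }
  jsd_match <- apply(jm, 2L, which.min)
  corr_match <- apply(cm, 2L, which.max)
  structure(list(jsd_matrix = jm, corr_matrix = cm,
                 jsd_match = jsd_match, corr_match = corr_match,
                 agreement = jsd_match == corr_match),
            class = "cluster_match")
}

#' @export
print.cluster_match <- function(x, ...) {
  cat("Cluster match:", ncol(x$jsd_matrix), "test vs",
      nrow(x$jsd_matrix), "train clusters;",
      sum(x$agreement), "of", length(x$agreement),
      "agree across criteria\n")
  invisible(x)
}

#' Refit on the held-out split and match clusters
#'
#' Fits a fresh latent class model to the test data with the number of
#' classes fixed to the training fit's `K`, computes within-cluster
#' prevalence profiles on both splits from modal assignments, matches
#' test clusters to training clusters, and records the relative
#' entropy of both classifications (expected to be similar when the
#' solution is stable).
#'
#' @param train_fit `lca_fit` from the training split.
#' @param train_data Binary condition matrix of the training split.
#' @param test_data Binary condition matrix of the held-out split
#'   (same registry).
#' @param seed Optional integer seed for the test-set fit.
#' @param ... Further arguments passed to [fit_em] (e.g.
#'   `n_restarts`).
#' @return List with `test_fit`, `match` ([match_clusters] result),
#'   `entropy_train`, `entropy_test`, `train_profile`, `test_profile`.
#' @export
replicate_on_test <- function(train_fit, train_data, test_data,
                              seed = NULL, ...) {
  stopifnot(inherits(train_fit, "lca_fit"))
  K <- train_fit$params$K
  test_data <- check_binary_matrix(test_data, train_fit$J)
  if (nrow(test_data) <= K) {
    warning("test split smaller than the number of classes (",
            nrow(test_data), " <= ", K, "); replication skipped")
    return(list(test_fit = NULL, match = NULL,
                entropy_train = relative_entropy(train_fit),
                entropy_test = NA_real_,
                train_profile = prevalence_profile(train_fit$assignment,
                                                   train_data),
                test_profile = NULL))
  }
  test_fit <- fit_em(test_data, K, seed = seed, ...)
  train_profile <- prevalence_profile(train_fit$assignment, train_data)
  test_profile <- prevalence_profile(test_fit$assignment, test_data)
  list(test_fit = test_fit,
       match = match_clusters(train_profile, test_profile),
       entropy_train = relative_entropy(train_fit),
       entropy_test = relative_entropy(test_fit),
       train_profile = train_profile, test_profile = test_profile)
}
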