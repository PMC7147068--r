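#' Complete-case filter on smoking and BMI
#'
#' Drops patients whose last-recorded smoking status or BMI is
#' missing, as done ahead of the outcome regressions. A warning is
#' emitted when the exclusion reaches 5% of the cohort, the level at
#' which a complete-case analysis stops being obviously innocuous.
#'
#' @param cohort Cohort data frame.
#' @return List with `cohort` (filtered), `n_total`, `n_excluded`,
#'   `pct_excluded`.
#' @export
complete_case_filter <- function(cohort) {
  drop <- is.na(cohort$smoking) | is.na(cohort$bmi)
  pct <- 100 * mean(drop)
  if (pct >= 5)
    warning(sprintf("complete-case filter excludes %.1f%% of patients",
                    pct))
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "condition_registry") <- attr(cohort, "condition_registry")
  list(cohort = out, n_total = nrow(cohort),
       n_excluded = sum(drop), pct_excluded = pct)
}

#' Choose the reference cluster for outcome models
#'
#' The reference is the cluster with the lowest overall impact on the
#' outcomes: each cluster is ranked on mean GP consultations, mean
#' hospitalisations, mean regular medications and 5-year mortality,
#' and the cluster with the smallest rank sum wins. Ties go to the
#' larger cluster (a more stable reference).
#'
#' @param outcome_summary Data frame from [cluster_outcome_summary]
#'   (any `non-multimorbid` row is ignored).
#' @return The chosen cluster id (same type as the `cluster` column
#'   values, converted back to integer when possible).
#' @export
choose_reference_cluster <- function(outcome_summary) {
  s <- outcome_summary[outcome_summary$cluster != "non-multimorbid", ,
                       drop = FALSE]
  if (nrow(s) < 2)
    stop("need at least two clusters to choose a reference")
  rank_sum <- rank(s$gp_consults_mean) +
    rank(s$hospitalisations_mean) + rank(s$regular_meds_mean) +
    rank(s$died_5yr_pct)
  best <- which(rank_sum == min(rank_sum))
  if (length(best) > 1) best <- best[which.max(s$n[best])]
  id <- s$cluster[best]
  if (!is.na(suppressWarnings(as.integer(id)))) as.integer(id) else id
}

#' Build the regression design matrix
#'
#' Indicator coding with the documented column order: intercept,
#' cluster indicators (reference cluster omitted), `gender_M`
#' (reference female), `smoking_current` and `smoking_ex` (reference
#' never-smoker), `imd` as a single ordinal 1-5 numeric term, `bmi`
#' and `age` continuous. Requires complete cases; clusters with fewer
#' than two members are dropped (their rows removed) with a warning.
#'
#' @param cohort Complete-case cohort data frame.
#' @param assignments Integer cluster assignments aligned with cohort
#'   rows.
#' @param reference_cluster Cluster id to use as reference.
#' @return List with `X` (design matrix), `rows` (indices of cohort
#'   rows retained), `reference_cluster`, `dropped_clusters`.
#' @export
build_design <- function(cohort, assignments, reference_cluster) {
  if (length(assignments) != nrow(cohort))
    stop("assignments and cohort rows differ in length")
  if (anyNA(cohort$smoking) || anyNA(cohort$bmi))
    stop("design requires complete cases; run complete_case_filter() first")
  if (!reference_cluster %in% assignments)
    stop("reference cluster ", reference_cluster, " has no members")
  sizes <- table(assignments)
  small <- as.integer(names(sizes)[sizes < 2])
  if (length(small)) {
    warning("dropping cluster(s) with < 2 members: ",
            paste(small, collapse = ", "))
  }
  rows <- which(!assignments %in% small)
  d <- cohort[rows, , drop = FALSE]
  a <- assignments[rows]
  others <- setdiff(sort(unique(a)), reference_cluster)
  X <- matrix(1, nrow(d), 1)
  for (k in others) X <- cbind(X, as.numeric(a == k))
  colnames(X) <- c("(Intercept)", paste0("cluster_", others))
  X <- cbind(X,
             gender_M = as.numeric(d$gender == "M"),
             smoking_current = as.numeric(d$smoking == "current"),
             smoking_ex = as.numeric(d$smoking == "ex"),
             imd = as.numeric(d$imd),
             bmi = as.numeric(d$bmi),
             age = as.numeric(d$age))
  list(X = X, rows = rows, reference_cluster = reference_cluster,
       dropped_clusters = small)
}

# Wald coefficient table with exponentiated estimates
wald_table <- function(fit, ratio_name, n_used, family, dispersion,
                       n_excluded = 0L) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  term <- sub("^X", "", names(est))
  tab <- data.frame(term = term, estimate = unname(est),
                    se = unname(se),
                    ci_lower = unname(est - z * se),
                    ci_upper = unname(est + z * se))
  tab$ratio <- exp(tab$estimate)
  tab$ratio_lower <- exp(tab$ci_lower)
  tab$ratio_upper <- exp(tab$ci_upper)
  structure(list(coefficients = tab, family = family,
                 ratio_name = ratio_name, n_used = n_used,
                 n_excluded_missing = n_excluded,
                 dispersion = dispersion,
                 converged = isTRUE(fit$converged) ||
                   is.null(fit$converged)),
            class = "outcome_glm")
}

#' @export
print.outcome_glm <- function(x, ...) {
  cat("Outcome GLM (", x$family, "), n =", x$n_used, "\n")
  tab <- x$coefficients
  tab[[x$ratio_name]] <- sprintf("%.3f [%.3f-%.3f]", tab$ratio,
                                 tab$ratio_lower, tab$ratio_upper)
  print(tab[, c("term", "estimate", "se", x$ratio_name)], digits = 4)
  invisible(x)
}

#' Count-outcome GLM with adjusted incidence rate ratios
#'
#' Log-link count regression fitted by maximum likelihood (iteratively
#' reweighted least squares; for the negative binomial the dispersion
#' is estimated by maximum likelihood alongside the coefficients).
#' Exponentiated coefficients are adjusted incidence rate ratios
#' (aIRR) with Wald 95% confidence intervals.
#'
#' @param response Non-negative integer counts.
#' @param design A [build_design] result, or a bare design matrix
#'   whose first column is the intercept.
#' @param family `"negative_binomial"` (default) or `"poisson"`.
#' @return An `outcome_glm` object; `dispersion` is the estimated
#'   negative-binomial `alpha = 1/theta` (0 for Poisson).
#' @export
fit_count_glm <- function(response,
                          design,
                          family = c("negative_binomial", "poisson")) {
  family <- match.arg(family)
  X <- if (is.list(design)) design$X else as.matrix(design)
  if (length(response) != nrow(X))
    stop("response length does not match design rows")
  if (anyNA(response) || any(response < 0))
    stop("counts must be non-negative and non-missing")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  if (family == "poisson") {
    fit <- glm(response ~ 0 + X, family = poisson(),
               control = list(maxit = 100, epsilon = 1e-8))
    if (!fit$converged)
      stop("Poisson GLM failed to converge in 100 iterations")
    return(wald_table(fit, "aIRR", length(response), family, 0))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(response ~ 0 + X,
                                  control = stats::glm.control(
                                    maxit = 100, epsilon = 1e-8))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # theta diverges on (near-)equidispersed data; the NB limit as
    # alpha -> 0 is exactly the Poisson fit, so fall back when the
    # Pearson dispersion confirms there is no overdispersion
    pfit <- glm(response ~ 0 + X, family = poisson(),
                control = list(maxit = 100, epsilon = 1e-8))
    pearson_disp <- sum(residuals(pfit, "pearson")^2) / pfit$df.residual
    if (pfit$converged && pearson_disp < 1.1)
      return(wald_table(pfit, "aIRR", length(response), family, 0))
    stop("negative binomial GLM failed: ", conditionMessage(fit))
  }
  if (!fit$converged)
    stop("negative binomial GLM failed to converge in 100 iterations")
  wald_table(fit, "aIRR", length(response), family, 1 / fit$theta)
}

#' Logistic GLM for binary mortality with odds ratios
#'
#' Logistic regression fitted by maximum likelihood (iteratively
#' reweighted least squares); exponentiated coefficients are odds
#' ratios with Wald 95% confidence intervals. Complete separation is
#' detected (fitted probabilities pinned at 0/1 alongside a diverging
#' coefficient) and raised as an error naming the offending columns.
#'
#' @param response 0/1 outcome with both levels present.
#' @param design A [build_design] result or bare design matrix.
#' @return An `outcome_glm` object.
#' @export
fit_mortality_glm <- function(response, design) {
  X <- if (is.list(design)) design$X else as.matrix(design)
  if (length(response) != nrow(X))
    stop("response length does not match design rows")
  if (!all(response %in% c(0, 1)))
    stop("response must be 0/1")
  if (length(unique(response)) < 2)
    stop("response must include both outcome levels")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  fit <- suppressWarnings(glm(response ~ 0 + X, family = binomial(),
                              control = list(maxit = 100,
                                             epsilon = 1e-8)))
  if (!fit$converged)
    stop("logistic GLM failed to converge in 100 iterations")
  big <- abs(coef(fit)) > 15
  mu <- fit$fitted.values
  if (any(big) && (any(mu > 1 - 1e-8) || any(mu < 1e-8)))
    stop("complete or quasi-complete separation involving: ",
         paste(sub("^X", "", names(coef(fit))[big]), collapse = ", "))
  wald_table(fit, "OR", length(response), "logistic", NA_real_)
}

#' Fit all outcome models for one stratum
#'
#' Convenience wrapper running the published outcome-model sequence
#' for a fitted stratum: complete-case filter, per-cluster outcome
#' summary, reference-cluster choice (lowest impact), design
#' construction, count GLMs for GP consultations, hospitalisations
#' and regular medications, and logistic GLMs for 2- and 5-year
#' mortality.
#'
#' @param cohort Stratum cohort data frame (multimorbid patients).
#' @param assignments Integer cluster assignments aligned with cohort
#'   rows.
#' @param family Count family passed to [fit_count_glm].
#' @param reference_cluster Optional override; default chooses by
#'   [choose_reference_cluster].
#' @return List with `models` (named list of `outcome_glm`),
#'   `reference_cluster`, `exclusions`, `summary`.
#' @export
cluster_outcome_models <- function(cohort, assignments,
                                   family = "negative_binomial",
                                   reference_cluster = NULL) {
  cc <- complete_case_filter(cohort)
  a <- assignments[match(cc$cohort$patient_id, cohort$patient_id)]
  summ <- cluster_outcome_summary(a, cc$cohort)
  ref <- reference_cluster %||% choose_reference_cluster(summ)
  des <- build_design(cc$cohort, a, ref)
  d <- cc$cohort[des$rows, , drop = FALSE]
  models <- list(
    gp_consults = fit_count_glm(d$gp_consults, des, family),
    hospitalisations = fit_count_glm(d$hospitalisations, des, family),
    regular_meds = fit_count_glm(d$regular_meds, des, family),
    died_2yr = tryCatch(fit_mortality_glm(d$died_2yr, des),
                        error = function(e) e),
    died_5yr = tryCatch(fit_mortality_glm(d$died_5yr, des),
                        error = function(e) e))
  for (nm in names(models))
    if (inherits(models[[nm]], "outcome_glm"))
      models[[nm]]$n_excluded_missing <- cc$n_excluded
  list(models = models, reference_cluster = ref,
       exclusions = cc[c("n_total", "n_excluded", "pct_excluded")],
       summary = summ)
}
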