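#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis. Stage seeds are
#' derived deterministically from the master seed, so a pipeline run
#' is reproducible and individual stages can be re-run in isolation.
#'
#' @param output_dir Directory for result files (created if needed).
#' @param cohort_path Optional cohort CSV path (alternatively pass the
#'   cohort directly to [run_pipeline]).
#' @param conditions Condition registry.
#' @param train_fraction Training proportion of the stratified split.
#' @param k_range Candidate class counts: either one integer vector
#'   used for every stratum or a named list keyed by stratum label.
#' @param n_restarts,max_iter,tol EM settings (see [fit_em]).
#' @param entropy_floor,bootstrap_B Selection settings (see
#'   [select_k]).
#' @param glm_family Count-outcome family
#'   (`"negative_binomial"`/`"poisson"`).
#' @param reference_cluster Optional fixed reference cluster id for
#'   the outcome models; default chooses the lowest-impact cluster
#'   per stratum.
#' @param seed Integer master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(output_dir, cohort_path = NULL,
                            conditions = mm_conditions(),
                            train_fraction = 0.8, k_range = 1:6,
                            n_restarts = 20, max_iter = 1000,
                            tol = 1e-8, entropy_floor = 0.8,
                            bootstrap_B = 0,
                            glm_family = "negative_binomial",
                            reference_cluster = NULL, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)")
  kr <- if (is.list(k_range)) unlist(k_range) else k_range
  if (min(kr) < 1) stop("k_range entries must be >= 1")
  if (is.null(seed)) stop("a master seed is required")
  structure(list(output_dir = output_dir, cohort_path = cohort_path,
                 conditions = conditions,
                 train_fraction = train_fraction, k_range = k_range,
                 n_restarts = n_restarts, max_iter = max_iter,
                 tol = tol, entropy_floor = entropy_floor,
                 bootstrap_B = bootstrap_B, glm_family = glm_family,
                 reference_cluster = reference_cluster,
                 seed = as.integer(seed)), class = "pipeline_config")
}

stage_seed <- function(master, stage, stratum = 0L) {
  as.integer((as.numeric(master) + 104729 * stage + 7919 * stratum) %%
               2147483647)
}

stratum_tag <- function(label) {
  gsub("-", "_", sub("\\+", "plus", label))
}

pipeline_log <- function(quiet, ...) {
  if (!quiet) message("[mmlca] ", ...)
}

#' Run the full age-stratified clustering pipeline
#'
#' Executes the published analysis sequence on a cohort: filter to
#' multimorbid patients (two or more conditions), stratify by age,
#' split 80/20 within strata, select and fit a latent class model per
#' stratum on the training split, profile and label the clusters,
#' refit on the held-out split and match clusters across splits, and
#' fit the outcome GLMs. All tables, model JSON files and a Markdown
#' report are written under `config$output_dir`; numeric outputs are
#' byte-identical across runs with the same master seed.
#'
#' @param config A [pipeline_config] object.
#' @param cohort Optional cohort data frame (otherwise read from
#'   `config$cohort_path`).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return An `mm_pipeline` object (per-stratum results plus the
#'   config), invisibly.
#' @export
run_pipeline <- function(config, cohort = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    if (is.null(config$cohort_path))
      stop("stage read_cohort: no cohort supplied and no cohort_path configured")
    cohort <- read_cohort(config$cohort_path, config$conditions)
  }
  pipeline_log(quiet, "cohort: ", nrow(cohort), " patients, seed ",
               config$seed)

  mm_flag <- is_multimorbid(cohort)
  if (!any(mm_flag))
    stop("stage multimorbid_filter: cohort contains no multimorbid patients")
  mm <- cohort[mm_flag, , drop = FALSE]
  nonmm <- cohort[!mm_flag, , drop = FALSE]
  attr(mm, "condition_registry") <- attr(cohort, "condition_registry")

  split <- split_train_test(mm, config$train_fraction,
                            seed = stage_seed(config$seed, 1L))
  train_strata <- stratify_by_age(split$train)
  test_strata <- stratify_by_age(split$test)
  nonmm_strata <- if (nrow(nonmm)) stratify_by_age(nonmm) else NULL

  results <- list()
  for (i in seq_along(train_strata)) {
    label <- names(train_strata)[i]
    tag <- stratum_tag(label)
    tr <- train_strata[[label]]
    te <- test_strata[[label]]
    if (!nrow(tr)) {
      warning("stage fit: training stratum ", label, " is empty; skipped")
      next
    }
    kr <- if (is.list(config$k_range)) config$k_range[[label]]
          else config$k_range
    kr <- kr[kr < nrow(tr)]
    if (!length(kr))
      stop("stage select_k (", label, "): stratum too small for k_range")
    y_tr <- condition_matrix(tr)
    pipeline_log(quiet, label, ": selecting K over {",
                 paste(kr, collapse = ","), "} on n=", nrow(tr))
    sel <- select_k(y_tr, kr, n_restarts = config$n_restarts,
                    entropy_floor = config$entropy_floor,
                    bootstrap_B = config$bootstrap_B,
                    seed = stage_seed(config$seed, 2L, i),
                    max_iter = config$max_iter, tol = config$tol)
    fit <- sel$fits[[as.character(sel$chosen_K)]]

    profile <- prevalence_profile(fit$assignment, y_tr)
    kc <- key_conditions(profile)
    labels <- cluster_labels(profile)
    demo <- summarize_demographics(tr, factor(fit$assignment))
    outs <- cluster_outcome_summary(
      fit$assignment, tr,
      nonmultimorbid = nonmm_strata[[label]])

    replication <- NULL
    if (nrow(te) > sel$chosen_K) {
      replication <- replicate_on_test(
        fit, y_tr, condition_matrix(te),
        seed = stage_seed(config$seed, 3L, i),
        n_restarts = config$n_restarts, max_iter = config$max_iter,
        tol = config$tol)
    } else {
      warning("stage replicate (", label,
              "): test split too small; replication skipped")
    }

    outcome_models <- NULL
    if (sel$chosen_K >= 2) {
      outcome_models <- tryCatch(
        cluster_outcome_models(tr, fit$assignment,
                               family = config$glm_family,
                               reference_cluster =
                                 config$reference_cluster),
        error = function(e) {
          warning("stage outcomes (", label, "): ",
                  conditionMessage(e))
          NULL
        })
    }

    res <- list(label = label, n_train = nrow(tr), n_test = nrow(te),
                selection = sel, fit = fit, profile = profile,
                key_conditions = kc, labels = labels,
                demographics = demo, outcome_summary = outs,
                replication = replication,
                outcome_models = outcome_models)
    results[[label]] <- res
    write_stratum_outputs(res, tag, config)
  }
  if (!length(results))
    stop("stage fit: no stratum could be fitted")

  out <- structure(list(results = results, config = config,
                        n_cohort = nrow(cohort),
                        n_multimorbid = nrow(mm)),
                   class = "mm_pipeline")
  write_pipeline_report(out)
  write_pipeline_summary(out)
  pipeline_log(quiet, "done; outputs in ", config$output_dir)
  invisible(out)
}

write_stratum_outputs <- function(res, tag, config) {
  odir <- config$output_dir
  write.csv(res$selection$table,
            file.path(odir, paste0("selection_", tag, ".csv")),
            row.names = FALSE)
  write_lca_fit(res$fit,
                file.path(odir, paste0("model_", tag, ".json")),
                selection = list(
                  chosen_K = res$selection$chosen_K,
                  rule = res$selection$rule,
                  entropy = relative_entropy(res$fit)))
  prof <- res$profile
  long <- data.frame(
    cluster = rep(prof$clusters, each = ncol(prof$within)),
    condition = rep(colnames(prof$within) %||%
                      condition_cols(ncol(prof$within)),
                    times = nrow(prof$within)),
    within_prevalence = as.vector(t(prof$within)),
    stratum_prevalence = rep(prof$overall, times = nrow(prof$within)))
  write.csv(long, file.path(odir, paste0("profiles_", tag, ".csv")),
            row.names = FALSE)
  write.csv(res$key_conditions,
            file.path(odir, paste0("labels_", tag, ".csv")),
            row.names = FALSE)
  write.csv(res$outcome_summary,
            file.path(odir, paste0("outcome_summary_", tag, ".csv")),
            row.names = FALSE)
  if (!is.null(res$replication)) {
    m <- res$replication$match
    jsonlite::write_json(
      list(jsd_match = as.list(m$jsd_match),
           corr_match = as.list(m$corr_match),
           agreement = as.list(m$agreement),
           entropy_train = res$replication$entropy_train,
           entropy_test = res$replication$entropy_test),
      file.path(odir, paste0("match_", tag, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mats <- rbind(
      data.frame(matrix = "jsd",
                 train_cluster = rep(rownames(m$jsd_matrix),
                                     ncol(m$jsd_matrix)),
                 test_cluster = rep(colnames(m$jsd_matrix),
                                    each = nrow(m$jsd_matrix)),
                 value = as.vector(m$jsd_matrix)),
      data.frame(matrix = "pearson",
                 train_cluster = rep(rownames(m$corr_matrix),
                                     ncol(m$corr_matrix)),
                 test_cluster = rep(colnames(m$corr_matrix),
                                    each = nrow(m$corr_matrix)),
                 value = as.vector(m$corr_matrix)))
    write.csv(mats,
              file.path(odir, paste0("match_matrices_", tag, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(res$outcome_models)) {
    rows <- list()
    for (nm in names(res$outcome_models$models)) {
      mod <- res$outcome_models$models[[nm]]
      if (!inherits(mod, "outcome_glm")) next
      tab <- mod$coefficients
      tab$outcome <- nm
      tab$family <- mod$family
      tab$reference_cluster <- res$outcome_models$reference_cluster
      rows[[nm]] <- tab
    }
    if (length(rows))
      write.csv(do.call(rbind, rows),
                file.path(odir, paste0("outcomes_", tag, ".csv")),
                row.names = FALSE)
  }
}

write_pipeline_summary <- function(x) {
  strata <- lapply(x$results, function(r) list(
    label = r$label, n_train = r$n_train, n_test = r$n_test,
    chosen_K = r$selection$chosen_K,
    entropy = relative_entropy(r$fit),
    entropy_test = if (!is.null(r$replication))
      r$replication$entropy_test else NULL,
    match_agreement = if (!is.null(r$replication))
      mean(r$replication$match$agreement) else NULL,
    reference_cluster = if (!is.null(r$outcome_models))
      r$outcome_models$reference_cluster else NULL))
  jsonlite::write_json(
    list(seed = x$config$seed, n_cohort = x$n_cohort,
         n_multimorbid = x$n_multimorbid,
         multimorbid_pct = 100 * x$n_multimorbid / x$n_cohort,
         strata = strata),
    file.path(x$config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_pipeline_report <- function(x) {
  L <- c("# Age-stratified multimorbidity clustering report", "",
         sprintf("- Cohort: %d patients; %d (%.1f%%) multimorbid.",
                 x$n_cohort, x$n_multimorbid,
                 100 * x$n_multimorbid / x$n_cohort),
         sprintf("- Master seed: %d; train fraction: %.2f.",
                 x$config$seed, x$config$train_fraction),
         sprintf("- Count-outcome family: %s.", x$config$glm_family),
         "")
  for (r in x$results) {
    L <- c(L, sprintf("## Age stratum %s", r$label), "",
           sprintf("Training n = %d, test n = %d; selected K = %d (%s).",
                   r$n_train, r$n_test, r$selection$chosen_K,
                   r$selection$rule), "")
    L <- c(L, "| Cluster | n | % | Key conditions |",
           "|---|---|---|---|")
    sizes <- r$profile$sizes
    ord <- order(-sizes)
    for (j in ord)
      L <- c(L, sprintf("| %s | %d | %.0f%% | %s |",
                        r$profile$clusters[j], sizes[j],
                        100 * sizes[j] / r$n_train, r$labels[j]))
    L <- c(L, "")
    if (!is.null(r$replication)) {
      m <- r$replication$match
      L <- c(L, sprintf(paste0(
        "Hold-out replication: entropy %.3f (train) vs %.3f (test); ",
        "%d of %d test clusters matched identically under JSD and ",
        "correlation."),
        r$replication$entropy_train, r$replication$entropy_test,
        sum(m$agreement), length(m$agreement)), "")
    }
    if (!is.null(r$outcome_models)) {
      L <- c(L, sprintf(
        "Outcome models: reference cluster %s; %d patients excluded (%.1f%%) for missing smoking/BMI.",
        r$outcome_models$reference_cluster,
        r$outcome_models$exclusions$n_excluded,
        r$outcome_models$exclusions$pct_excluded), "")
    }
  }
  L <- c(L,
         "Counts are modelled as negative binomial by default; the",
         "generating family for real consultation data is unknown, so",
         "Poisson results are available as a sensitivity via the",
         "`glm_family` setting.", "")
  writeLines(L, file.path(x$config$output_dir, "report.md"))
}

#' @export
print.mm_pipeline <- function(x, ...) {
  cat("mmlca pipeline:", x$n_multimorbid, "multimorbid of",
      x$n_cohort, "patients;", length(x$results), "strata\n")
  for (r in x$results)
    cat(sprintf("  %s: K = %d (train n = %d, test n = %d)\n",
                r$label, r$selection$chosen_K, r$n_train, r$n_test))
  invisible(x)
}
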