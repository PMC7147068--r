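fmt_q <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                type = 7)
  list(q1 = q[1], median = q[2], q3 = q[3])
}

#' Descriptive demographic summary by group
#'
#' Produces one row per group with: n, percent of total, median and
#' quartiles (linear-interpolation convention) of the morbidity count,
#' percent multimorbid, percent female, percent current smoker (among
#' recorded), percent living in the most deprived 40% of areas (IMD
#' quintiles 4-5), BMI median and quartiles, and smoking/BMI
#' missingness percentages.
#'
#' @param cohort Cohort data frame.
#' @param grouping Either `"overall"`, the name of a categorical cohort
#'   column (e.g. `"gender"`, `"imd"`), `"age_stratum"`, or a factor
#'   vector aligned with the cohort rows (e.g. cluster assignments).
#' @return Data frame, one row per group.
#' @export
summarize_demographics <- function(cohort, grouping = "overall") {
  if (is.character(grouping) && length(grouping) == 1L) {
    g <- switch(grouping,
      overall = factor(rep("all", nrow(cohort))),
      age_stratum = age_stratum(cohort$age),
      {
        if (!grouping %in% names(cohort))
          stop("unknown grouping field: ", grouping)
        factor(cohort[[grouping]])
      })
  } else {
    if (length(grouping) != nrow(cohort))
      stop("grouping vector must align with cohort rows")
    g <- factor(grouping)
  }
  mc <- morbidity_count(cohort)
  total <- nrow(cohort)
  rows <- lapply(levels(g), function(l) {
    i <- which(g == l)
    d <- cohort[i, , drop = FALSE]
    mq <- fmt_q(mc[i]); bq <- fmt_q(d$bmi)
    smoked <- d$smoking[!is.na(d$smoking)]
    data.frame(
      group = l, n = length(i), pct = 100 * length(i) / total,
      morbidity_median = mq$median, morbidity_q1 = mq$q1,
      morbidity_q3 = mq$q3,
      pct_multimorbid = 100 * mean(mc[i] >= 2),
      pct_female = 100 * mean(d$gender == "F"),
      pct_current_smoker =
        if (length(smoked)) 100 * mean(smoked == "current") else NA_real_,
      pct_greater_deprivation = 100 * mean(d$imd >= 4),
      bmi_median = bq$median, bmi_q1 = bq$q1, bmi_q3 = bq$q3,
      pct_smoking_missing = 100 * mean(is.na(d$smoking)),
      pct_bmi_missing = 100 * mean(is.na(d$bmi)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson chi-square on an `r x c` contingency table of
#' counts, with Yates continuity correction applied to 2x2 tables only
#' (the convention under which the published gender-by-multimorbidity
#' statistic of 1573.4 reproduces). Delegates to [stats::chisq.test]
#' after validating the table.
#'
#' @param table Matrix of non-negative counts, at least 2x2, with no
#'   zero row or column margin.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_independence(builtin_fixtures()$gender_mm)
chisq_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("table must be at least 2x2")
  if (anyNA(table) || any(table < 0))
    stop("counts must be non-negative and non-missing")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has a zero row or column margin")
  yates <- nrow(table) == 2 && ncol(table) == 2
  ht <- suppressWarnings(chisq.test(table, correct = yates))
  list(statistic = unname(ht$statistic),
       df = as.integer(unname(ht$parameter)),
       p_value = unname(ht$p.value))
}

#' Frequencies of distinct condition combinations
#'
#' Counts the distinct full condition vectors in the cohort (an exact
#' multiset count, not pairwise co-occurrence), ranked by frequency;
#' ties are broken lexicographically on the sorted condition indices.
#'
#' @param cohort Cohort data frame.
#' @param min_size Drop combinations held by fewer patients than this
#'   (default 1 keeps all).
#' @return Data frame with `combination` (`+`-separated condition
#'   names; `"none"` for the all-zero vector), `n_conditions`, `count`
#'   and `pct` of the cohort.
#' @export
combination_frequencies <- function(cohort, min_size = 1L) {
  cm <- condition_matrix(cohort)
  registry <- attr(cohort, "condition_registry") %||%
    colnames(cm) %||% condition_cols(ncol(cm))
  # zero-padded keys make string order match lexicographic order on
  # the condition index sequences (the documented tie-break)
  key <- apply(cm, 1L, function(r)
    paste(sprintf("%02d", which(r == 1)), collapse = ","))
  cnt <- table(key)
  lab <- vapply(names(cnt), function(k) {
    if (k == "") return("none")
    paste(registry[as.integer(strsplit(k, ",")[[1]])], collapse = "+")
  }, "")
  nc <- vapply(names(cnt), function(k)
    if (k == "") 0L else length(strsplit(k, ",")[[1]]), 0L)
  out <- data.frame(combination = lab, n_conditions = nc,
                    count = as.integer(cnt),
                    pct = 100 * as.integer(cnt) / nrow(cohort))
  out <- out[order(-out$count, names(cnt)), , drop = FALSE]
  rownames(out) <- NULL
  out[out$count >= min_size, , drop = FALSE]
}
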