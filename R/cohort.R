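#' Age strata definition
#'
#' The four closed-open age strata used throughout:
#' `[18, 45)`, `[45, 65)`, `[65, 85)`, `[85, Inf)`, labelled
#' `18-44`, `45-64`, `65-84`, `85+`. Together they partition ages
#' `>= 18`.
#'
#' @return Data frame with columns `label`, `lower`, `upper`.
#' @export
age_strata <- function() {
  data.frame(label = c("18-44", "45-64", "65-84", "85+"),
             lower = c(18, 45, 65, 85),
             upper = c(45, 65, 85, Inf))
}

#' Assign ages to age strata
#'
#' @param age Integer vector of ages (all `>= 18`).
#' @return Factor with levels `18-44`, `45-64`, `65-84`, `85+`.
#' @export
age_stratum <- function(age) {
  if (anyNA(age) || any(age < 18))
    stop("all ages must be >= 18 and non-missing")
  st <- age_strata()
  cut(age, breaks = c(st$lower, Inf), labels = st$label, right = FALSE)
}

#' Extract the binary condition matrix from a cohort
#'
#' @param cohort Cohort data frame with `cond_*` columns.
#' @return Numeric 0/1 matrix, one row per patient, columns in
#'   registry order and named from the cohort's condition registry
#'   when one is attached.
#' @export
condition_matrix <- function(cohort) {
  cols <- grep("^cond_[0-9]+$", names(cohort), value = TRUE)
  if (!length(cols)) stop("cohort has no cond_* columns")
  m <- as.matrix(cohort[, cols[order(cols)], drop = FALSE])
  registry <- attr(cohort, "condition_registry")
  if (!is.null(registry) && length(registry) == ncol(m))
    colnames(m) <- registry
  m
}

#' Morbidity count and multimorbidity indicator
#'
#' `morbidity_count()` sums each patient's condition flags;
#' `is_multimorbid()` flags patients with two or more long-term
#' conditions (the standard multimorbidity definition).
#'
#' @param cohort Cohort data frame with `cond_*` columns.
#' @return Integer vector (counts) or logical vector, one per patient.
#' @export
morbidity_count <- function(cohort) {
  as.integer(rowSums(condition_matrix(cohort)))
}

#' @rdname morbidity_count
#' @export
is_multimorbid <- function(cohort) morbidity_count(cohort) >= 2L

#' Split a cohort into age strata
#'
#' @param cohort Cohort data frame with an `age` column (all ages
#'   `>= 18`).
#' @return Named list of cohort data frames, one per stratum, in
#'   stratum order; every patient appears in exactly one.
#' @export
stratify_by_age <- function(cohort) {
  f <- age_stratum(cohort$age)
  out <- lapply(levels(f), function(l) {
    part <- cohort[f == l, , drop = FALSE]
    attr(part, "condition_registry") <- attr(cohort, "condition_registry")
    part
  })
  names(out) <- levels(f)
  out
}

#' Stratified train/test split
#'
#' Samples independently within each age stratum: each stratum
#' contributes `floor(train_fraction * stratum size)` patients to the
#' training set and the rest to the test set, so the split is
#' age-stratified, disjoint and exhaustive.
#'
#' @param cohort Cohort data frame.
#' @param train_fraction Proportion in `(0, 1)` (default 0.8).
#' @param seed Optional integer seed for reproducible membership.
#' @return List with `train` and `test` cohort data frames.
#' @export
split_train_test <- function(cohort, train_fraction = 0.8,
                             seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  f <- age_stratum(cohort$age)
  train_idx <- integer(0)
  for (l in levels(f)) {
    idx <- which(f == l)
    if (!length(idx)) {
      warning("age stratum ", l, " is empty")
      next
    }
    n_train <- floor(train_fraction * length(idx))
    train_idx <- c(train_idx, sort(sample(idx, n_train)))
  }
  keep_attrs <- function(d) {
    attr(d, "condition_registry") <- attr(cohort, "condition_registry")
    d
  }
  list(train = keep_attrs(cohort[sort(train_idx), , drop = FALSE]),
       test = keep_attrs(cohort[setdiff(seq_len(nrow(cohort)),
                                        train_idx), , drop = FALSE]))
}

cohort_required_cols <- function(n_cond = 38L) {
  c("patient_id", "age", "gender", "imd", "smoking", "bmi",
    condition_cols(n_cond), "gp_consults", "hospitalisations",
    "regular_meds", "died_2yr", "died_5yr")
}

#' Read and validate a cohort CSV
#'
#' Expects the documented schema: `patient_id`, `age`, `gender`
#' (`M`/`F`), `imd` (1-5), `smoking` (`current`/`never`/`ex`, may be
#' empty), `bmi` (kg/m^2, may be empty), `cond_01` ... `cond_NN`
#' (0/1), `gp_consults`, `hospitalisations`, `regular_meds`
#' (non-negative counts), `died_2yr`, `died_5yr` (0/1).
#'
#' @param path CSV file path.
#' @param conditions Condition registry to attach; its length must
#'   match the number of `cond_*` columns.
#' @return Validated cohort data frame with attribute
#'   `condition_registry`.
#' @export
read_cohort <- function(path, conditions = mm_conditions()) {
  cohort <- read.csv(path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  n_cond <- length(conditions)
  missing_cols <- setdiff(cohort_required_cols(n_cond), names(cohort))
  if (length(missing_cols))
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  cm <- condition_matrix(cohort)
  bad <- which(!(cm %in% c(0, 1) & !is.na(cm)), arr.ind = FALSE)
  if (length(bad)) {
    rows <- sort(unique(((bad - 1) %% nrow(cm)) + 1))
    stop("non-binary condition values in row(s): ",
         paste(head(rows, 10), collapse = ", "))
  }
  if (anyNA(cohort$age) || any(cohort$age < 18))
    stop("ages must be >= 18 and non-missing")
  if (!all(cohort$gender %in% c("M", "F")))
    stop("gender must be 'M' or 'F'")
  if (!all(cohort$imd %in% 1:5))
    stop("imd must be a quintile in 1..5")
  bad_smoke <- !(is.na(cohort$smoking) |
                   cohort$smoking %in% c("current", "never", "ex"))
  if (any(bad_smoke))
    stop("invalid smoking value(s) in row(s): ",
         paste(head(which(bad_smoke), 10), collapse = ", "))
  for (cc in c("gp_consults", "hospitalisations", "regular_meds"))
    if (anyNA(cohort[[cc]]) || any(cohort[[cc]] < 0))
      stop(cc, " must be non-negative and non-missing")
  for (cc in c("died_2yr", "died_5yr"))
    if (!all(cohort[[cc]] %in% c(0, 1)))
      stop(cc, " must be 0/1")
  if (any(cohort$died_2yr == 1 & cohort$died_5yr == 0))
    stop("died_2yr = 1 implies died_5yr = 1; inconsistent rows present")
  attr(cohort, "condition_registry") <- conditions
  cohort
}

#' Write a cohort data frame as CSV
#'
#' Missing smoking/BMI values are written as empty fields, matching
#' what [read_cohort] expects.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
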