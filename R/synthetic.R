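#' Simulate binary condition indicators from a latent class model
#'
#' Draws each patient's class from the mixing proportions and then each
#' condition flag independently from the class's item-response
#' probability: `z_i ~ Categorical(pi)`,
#' `y_ij | z_i = k ~ Bernoulli(rho[k, j])`.
#'
#' @param params An [lca_params] object (generating truth).
#' @param n Number of patients (`>= 1`).
#' @param seed Optional integer seed; the same seed reproduces the
#'   output bit for bit.
#' @return List with `data` (`n x J` 0/1 matrix, columns named from
#'   `colnames(params$rho)` when present) and `class` (length-`n`
#'   integer vector of true class labels in `1..K`).
#' @export
simulate_conditions <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "lca_params"))
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  z <- sample.int(params$K, n, replace = TRUE, prob = params$pi)
  p <- params$rho[z, , drop = FALSE]
  y <- matrix(rbinom(n * params$J, 1L, p), n, params$J,
              dimnames = list(NULL, colnames(params$rho)))
  list(data = y, class = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linear predictor for one outcome given class labels and covariates;
# covariate effects are centred at age 60, IMD 3, BMI 27 so the
# intercept is interpretable as a reference-patient rate
outcome_linpred <- function(co, class_labels, covariates, stratum) {
  eff <- co$class_effects[[stratum]]
  if (is.null(eff))
    stop("no class effects defined for stratum ", stratum)
  if (max(class_labels) > length(eff))
    stop("class label exceeds class-effect vector for stratum ", stratum)
  (co$intercept %||% 0) + eff[class_labels] +
    (co$age %||% 0) * (covariates$age - 60) +
    (co$imd %||% 0) * (covariates$imd - 3) +
    (co$bmi %||% 0) * (covariates$bmi - 27) +
    (co$gender_m %||% 0) * (covariates$gender == "M") +
    (co$smoking_current %||% 0) * (covariates$smoking == "current") +
    (co$smoking_ex %||% 0) * (covariates$smoking == "ex")
}

#' Simulate service-use and mortality outcomes
#'
#' Counts (GP consultations, hospitalisations, regular medications) are
#' drawn from a negative binomial with log-link mean
#' `exp(linear predictor)` and the per-outcome overdispersion given in
#' `truth$dispersion` (variance `mu + alpha * mu^2`; `alpha` `NULL` or 0
#' gives Poisson). Two-year death is Bernoulli on the logistic scale;
#' five-year death is generated hierarchically - certain when the
#' patient died within two years, otherwise a second Bernoulli draw on
#' the conditional linear predictor - so `died_2yr == 1` always implies
#' `died_5yr == 1`.
#'
#' @param class_labels Integer vector of true class memberships.
#' @param covariates Data frame with columns `age`, `gender`, `imd`,
#'   `smoking`, `bmi`, aligned row-for-row with `class_labels`.
#' @param truth A [simulation_truth] object supplying
#'   `outcome_coefficients` and `dispersion`.
#' @param stratum Age stratum label keying the class-effect vectors.
#' @param seed Optional integer seed.
#' @return Data frame with columns `gp_consults`, `hospitalisations`,
#'   `regular_meds`, `died_2yr`, `died_5yr`.
#' @export
simulate_outcomes <- function(class_labels, covariates, truth,
                              stratum, seed = NULL) {
  if (length(class_labels) != nrow(covariates))
    stop("class_labels and covariates have different lengths")
  if (!is.null(seed)) set.seed(seed)
  n <- length(class_labels)
  cf <- truth$outcome_coefficients
  draw_count <- function(name) {
    mu <- exp(outcome_linpred(cf[[name]], class_labels, covariates,
                              stratum))
    alpha <- truth$dispersion[[name]]
    if (is.null(alpha) || alpha == 0) rpois(n, mu)
    else rnbinom(n, size = 1 / alpha, mu = mu)
  }
  gp <- draw_count("gp_consults")
  hosp <- draw_count("hospitalisations")
  meds <- draw_count("regular_meds")
  p2 <- plogis(outcome_linpred(cf$died_2yr, class_labels, covariates,
                               stratum))
  died2 <- rbinom(n, 1L, p2)
  p5c <- plogis(outcome_linpred(cf$died_5yr, class_labels, covariates,
                                stratum))
  died5 <- ifelse(died2 == 1L, 1L, rbinom(n, 1L, p5c))
  data.frame(gp_consults = gp, hospitalisations = hosp,
             regular_meds = meds, died_2yr = died2, died_5yr = died5)
}

#' Specification of one simulated age stratum
#'
#' @param label Stratum label, e.g. `"18-44"`.
#' @param n_patients Number of patients to simulate (`>= 1`).
#' @param age_range Integer vector `c(lower, upper)`; ages are uniform
#'   on the closed integer range.
#' @param params Generating [lca_params] for the condition indicators.
#' @param female_prop Proportion female.
#' @param imd_probs Length-5 probability vector over IMD quintiles.
#' @param smoking_probs Length-3 probability vector over
#'   (current, never, ex).
#' @param bmi_mean,bmi_sd BMI distribution in kg/m^2.
#' @param smoking_missing,bmi_missing Missingness rates in `[0, 1]`.
#' @return A `stratum_spec` list.
#' @export
stratum_spec <- function(label, n_patients, age_range, params,
                         female_prop = 0.56,
                         imd_probs = rep(0.2, 5),
                         smoking_probs = c(0.19, 0.49, 0.32),
                         bmi_mean = 27, bmi_sd = 5,
                         smoking_missing = 0, bmi_missing = 0) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  stopifnot(inherits(params, "lca_params"))
  for (p in list(imd_probs, smoking_probs))
    if (abs(sum(p) - 1) > 1e-12)
      stop("probability vectors must sum to 1 within 1e-12")
  for (m in c(smoking_missing, bmi_missing))
    if (m < 0 || m > 1) stop("missingness rates must lie in [0, 1]")
  structure(list(label = label, n_patients = as.integer(n_patients),
                 age_range = as.integer(age_range), params = params,
                 female_prop = female_prop, imd_probs = imd_probs,
                 smoking_probs = smoking_probs, bmi_mean = bmi_mean,
                 bmi_sd = bmi_sd, smoking_missing = smoking_missing,
                 bmi_missing = bmi_missing), class = "stratum_spec")
}

#' Ground truth for a simulated multimorbid cohort
#'
#' Bundles per-stratum generating specifications, outcome model
#' coefficients (log scale for counts, logit scale for mortality, keyed
#' by class and covariates), per-count-outcome overdispersion, and the
#' master seed.
#'
#' @param strata_specs List of [stratum_spec] objects.
#' @param outcome_coefficients Named list (one entry per outcome) of
#'   coefficient lists; see [simulate_outcomes].
#' @param dispersion Named list of overdispersion parameters for the
#'   count outcomes (`NULL` entries mean Poisson).
#' @param seed Integer master seed.
#' @return A `simulation_truth` object.
#' @export
simulation_truth <- function(strata_specs, outcome_coefficients,
                             dispersion = list(), seed = 1L) {
  stopifnot(length(strata_specs) >= 1,
            all(vapply(strata_specs, inherits, TRUE, "stratum_spec")))
  labels <- vapply(strata_specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("stratum labels must be unique")
  names(strata_specs) <- labels
  structure(list(strata_specs = strata_specs,
                 outcome_coefficients = outcome_coefficients,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "simulation_truth")
}

# rho builder: background prevalence everywhere, overwritten by the
# named (condition -> prevalence) profile of each class
profile_rho <- function(class_profiles, conditions, background) {
  K <- length(class_profiles)
  rho <- matrix(background, K, length(conditions),
                dimnames = list(NULL, conditions))
  for (k in seq_len(K)) {
    pr <- class_profiles[[k]]
    miss <- setdiff(names(pr), conditions)
    if (length(miss)) stop("unknown condition(s): ",
                           paste(miss, collapse = ", "))
    rho[k, names(pr)] <- pr
  }
  rho
}

#' Default simulation truth emulating a CPRD-like multimorbid cohort
#'
#' Four age strata (18-44, 45-64, 65-84, 85+) whose sizes are the
#' study-scale multimorbid stratum sizes (15,306 / 36,097 / 49,494 /
#' 12,314) multiplied by `n_scale`; the default `n_scale = 0.01` gives
#' 153 / 361 / 495 / 123 patients. Each stratum carries a generating
#' latent class model whose classes mirror the published cluster
#' structure (lead condition at high prevalence, two key conditions at
#' moderate prevalence, a low age-increasing background elsewhere),
#' demographic distributions matching the published stratum summaries,
#' and outcome coefficients reproducing the published per-cluster mean
#' service use and 2/5-year mortality gradients.
#'
#' @param n_scale Multiplier on the study-scale stratum sizes.
#' @param conditions Condition registry (default [mm_conditions()]).
#' @param seed Master seed stored in the truth object.
#' @return A [simulation_truth] object.
#' @export
default_simulation_truth <- function(n_scale = 0.01,
                                     conditions = mm_conditions(),
                                     seed = 20120101L) {
  pr <- function(...) c(...)
  strata <- list(
    list(label = "18-44", n = 15306, age = c(18, 44), base = 0.02,
         pi = c(0.32, 0.23, 0.20, 0.18, 0.07),
         prof = list(
           pr(depression = 1.00, anxiety = 0.41, pain = 0.31),
           pr(pain = 0.36, hearing_loss = 0.30, hypertension = 0.23),
           pr(asthma = 1.00, irritable_bowel_syndrome = 0.26,
              depression = 0.20),
           pr(irritable_bowel_syndrome = 1.00, depression = 0.29,
              hearing_loss = 0.21),
           pr(psychoactive_substance_misuse = 0.75,
              alcohol_problems = 0.42, depression = 0.24)),
         female = 0.62, imd = c(17, 18, 19, 22, 24) / 100,
         smoking = c(0.37, 0.45, 0.18), bmi = c(26, 6),
         miss = c(smoking = 0.004, bmi = 0.10),
         gp = c(14.5, 11.9, 11.3, 10.6, 10.7),
         hosp = c(0.4, 0.6, 0.4, 0.4, 0.4),
         meds = c(2.4, 2.5, 1.9, 1.2, 1.3),
         mort2 = c(0.9, 1.0, 0.2, 0.2, 1.8) / 100,
         mort5 = c(1.8, 2.7, 0.6, 0.4, 3.9) / 100),
    list(label = "45-64", n = 36097, age = c(45, 64), base = 0.04,
         pi = c(0.37, 0.24, 0.22, 0.12, 0.05),
         prof = list(
           pr(hypertension = 0.76, diabetes = 0.37, pain = 0.25),
           pr(irritable_bowel_syndrome = 0.40, hearing_loss = 0.29,
              pain = 0.28),
           pr(depression = 0.93, pain = 0.53, anxiety = 0.31),
           pr(asthma = 1.00, pain = 0.24, copd = 0.16),
           pr(alcohol_problems = 0.62,
              psychoactive_substance_misuse = 0.42, pain = 0.28)),
         female = 0.55, imd = c(20, 21, 20, 19, 19) / 99,
         smoking = c(0.25, 0.47, 0.28), bmi = c(28, 6),
         miss = c(smoking = 0.0013, bmi = 0.04),
         gp = c(11.5, 10.5, 16.7, 12.6, 10.7),
         hosp = c(0.5, 0.5, 0.6, 0.4, 0.5),
         meds = c(4.1, 2.0, 5.1, 3.4, 2.4),
         mort2 = c(1.6, 1.3, 2.4, 1.0, 4.5) / 100,
         mort5 = c(4.4, 3.0, 5.8, 2.7, 12.5) / 100),
    list(label = "65-84", n = 49494, age = c(65, 84), base = 0.06,
         pi = c(0.41, 0.22, 0.14, 0.10, 0.08, 0.05),
         prof = list(
           pr(hypertension = 1.00, diabetes = 0.31, pain = 0.27),
           pr(hearing_loss = 0.40, prostate_disorders = 0.21,
              irritable_bowel_syndrome = 0.10),
           pr(depression = 0.56, pain = 0.56, anxiety = 0.23),
           pr(coronary_heart_disease = 0.54, diabetes = 0.32,
              atrial_fibrillation = 0.29),
           pr(copd = 0.57, asthma = 0.49, pain = 0.33),
           pr(pain = 0.81, coronary_heart_disease = 0.53,
              depression = 0.45)),
         female = 0.52, imd = c(24, 24, 21, 17, 14) / 100,
         smoking = c(0.12, 0.49, 0.39), bmi = c(27, 5),
         miss = c(smoking = 0.0008, bmi = 0.03),
         gp = c(12.4, 13.2, 17.3, 16.8, 15.7, 26.3),
         hosp = c(0.6, 0.7, 0.8, 1.1, 0.8, 1.6),
         meds = c(4.5, 3.3, 5.9, 5.9, 5.5, 10.7),
         mort2 = c(4.7, 4.4, 8.4, 11.3, 9.2, 16.2) / 100,
         mort5 = c(13.2, 11.1, 20.9, 28.8, 25.5, 39.2) / 100),
    list(label = "85+", n = 12314, age = c(85, 99), base = 0.08,
         pi = c(0.58, 0.23, 0.11, 0.08),
         prof = list(
           pr(hypertension = 0.72, hearing_loss = 0.39,
              diabetes = 0.18),
           pr(pain = 0.64, depression = 0.41, constipation = 0.24),
           pr(coronary_heart_disease = 0.61,
              atrial_fibrillation = 0.53, heart_failure = 0.49),
           pr(asthma = 0.48, copd = 0.48, pain = 0.44)),
         female = 0.65, imd = c(24, 24, 22, 17, 13) / 100,
         smoking = c(0.05, 0.59, 0.35) / 0.99,
         bmi = c(25, 4),
         miss = c(smoking = 0.006, bmi = 0.10),
         gp = c(13.0, 17.3, 21.9, 19.6),
         hosp = c(0.8, 0.8, 1.5, 1.1),
         meds = c(4.1, 6.7, 8.0, 6.9),
         mort2 = c(20.9, 31.1, 37.7, 28.0) / 100,
         mort5 = c(49.5, 62.9, 70.8, 56.5) / 100))

  specs <- lapply(strata, function(s)
    stratum_spec(s$label, max(1L, round(s$n * n_scale)), s$age,
                 lca_params(s$pi / sum(s$pi),
                            profile_rho(s$prof, conditions, s$base)),
                 female_prop = s$female, imd_probs = s$imd,
                 smoking_probs = s$smoking, bmi_mean = s$bmi[1],
                 bmi_sd = s$bmi[2], smoking_missing = s$miss["smoking"],
                 bmi_missing = s$miss["bmi"]))

  eff <- function(field, base) lapply(
    setNames(strata, vapply(strata, `[[`, "", "label")),
    function(s) log(s[[field]] / base))
  logit_eff <- function(rates) qlogis(pmin(pmax(rates, 1e-4), 0.999))
  mort2_eff <- lapply(setNames(strata, vapply(strata, `[[`, "", "label")),
                      function(s) logit_eff(s$mort2) + 4)
  # five-year effects are on the conditional (survived 2 years) scale
  mort5_eff <- lapply(setNames(strata, vapply(strata, `[[`, "", "label")),
                      function(s) {
                        p5c <- (s$mort5 - s$mort2) / (1 - s$mort2)
                        logit_eff(p5c) + 4
                      })
  coefs <- list(
    gp_consults = list(intercept = log(10), age = 0.004, imd = 0.02,
                       bmi = 0.004, gender_m = -0.05,
                       smoking_current = 0.05,
                       class_effects = eff("gp", 10)),
    hospitalisations = list(intercept = log(0.5), age = 0.006,
                            imd = 0.03, smoking_current = 0.08,
                            class_effects = eff("hosp", 0.5)),
    regular_meds = list(intercept = log(3), age = 0.006, imd = 0.02,
                        bmi = 0.006,
                        class_effects = eff("meds", 3)),
    died_2yr = list(intercept = -4, age = 0.015, imd = 0.05,
                    gender_m = 0.2, smoking_current = 0.3,
                    class_effects = mort2_eff),
    died_5yr = list(intercept = -4, age = 0.015, imd = 0.05,
                    gender_m = 0.2, smoking_current = 0.3,
                    class_effects = mort5_eff))

  simulation_truth(specs, coefs,
                   dispersion = list(gp_consults = 0.3,
                                     hospitalisations = 1.0,
                                     regular_meds = 0.5),
                   seed = seed)
}

#' Simulate a full multimorbid cohort
#'
#' Concatenates per-stratum patients: class labels and condition flags
#' from the stratum's latent class model, ages uniform on the stratum's
#' integer range, demographics from the stated distributions, outcomes
#' from the truth's outcome models, and finally smoking/BMI values
#' blanked at the stated missingness rates. True class labels are
#' returned in a separate table so the cohort itself has exactly the
#' fields a real extract would.
#'
#' @param truth A [simulation_truth] object; `truth$seed` drives all
#'   randomness (per-stratum and per-stage seeds are derived from it).
#' @return List with `cohort` (data frame in the cohort CSV schema,
#'   with the condition registry attached as attribute
#'   `condition_registry`) and `truth_labels` (data frame
#'   `patient_id`, `stratum`, `true_class`).
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  out <- list(); labs <- list()
  offset <- 0L
  for (i in seq_along(truth$strata_specs)) {
    sp <- truth$strata_specs[[i]]
    s0 <- (truth$seed + 1009L * i) %% 2147483647L
    sim <- simulate_conditions(sp$params, sp$n_patients, seed = s0)
    n <- sp$n_patients
    set.seed((s0 + 1L) %% 2147483647L)
    cov <- data.frame(
      age = sample(seq(sp$age_range[1], sp$age_range[2]), n,
                   replace = TRUE),
      gender = ifelse(rbinom(n, 1, sp$female_prop) == 1L, "F", "M"),
      imd = sample.int(5L, n, replace = TRUE, prob = sp$imd_probs),
      smoking = sample(c("current", "never", "ex"), n, replace = TRUE,
                       prob = sp$smoking_probs),
      bmi = round(stats::rnorm(n, sp$bmi_mean, sp$bmi_sd), 1))
    cov$bmi <- pmax(cov$bmi, 13)
    outc <- simulate_outcomes(sim$class, cov, truth, sp$label,
                              seed = (s0 + 2L) %% 2147483647L)
    set.seed((s0 + 3L) %% 2147483647L)
    cov$smoking[runif(n) < sp$smoking_missing] <- NA
    cov$bmi[runif(n) < sp$bmi_missing] <- NA
    ids <- sprintf("p%07d", offset + seq_len(n))
    offset <- offset + n
    cond <- as.data.frame(sim$data)
    names(cond) <- condition_cols(ncol(sim$data))
    out[[i]] <- cbind(data.frame(patient_id = ids), cov, cond, outc)
    labs[[i]] <- data.frame(patient_id = ids, stratum = sp$label,
                            true_class = sim$class)
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  attr(cohort, "condition_registry") <-
    colnames(truth$strata_specs[[1]]$params$rho)
  list(cohort = cohort, truth_labels = do.call(rbind, labs))
}

#' Write simulation ground truth as JSON
#'
#' @param truth A [simulation_truth] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_simulation_truth <- function(truth, path) {
  obj <- list(
    seed = truth$seed,
    dispersion = truth$dispersion,
    strata = lapply(truth$strata_specs, function(sp) list(
      label = sp$label, n_patients = sp$n_patients,
      age_range = sp$age_range, pi = sp$params$pi,
      rho = lapply(seq_len(sp$params$K),
                   function(k) as.numeric(sp$params$rho[k, ])))),
    outcome_coefficients = truth$outcome_coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Contingency tables reconstructed from published population counts
#'
#' Small built-in fixtures: (a) the 2x2 gender-by-multimorbidity table
#' and (b) the 5x2 IMD-quintile-by-multimorbidity table for a
#' 391,669-patient English primary-care population with 113,211
#' multimorbid patients. Cell counts are reconstructed exactly from the
#' published marginal and multimorbid counts.
#'
#' @return Named list with integer matrices `gender_mm` (rows M/F) and
#'   `imd_mm` (rows quintiles 1-5), columns
#'   `multimorbid`/`not_multimorbid`.
#' @export
#' @examples
#' builtin_fixtures()$gender_mm
builtin_fixtures <- function() {
  male_total <- 192929; female_total <- 198740
  female_mm <- 63072; total_mm <- 113211
  male_mm <- total_mm - female_mm
  gender <- matrix(c(male_mm, male_total - male_mm,
                     female_mm, female_total - female_mm),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("M", "F"),
                                   c("multimorbid", "not_multimorbid")))
  imd_total <- c(90730, 87734, 81569, 71424, 60212)
  imd_mm <- c(24624, 25027, 23700, 20934, 18926)
  imd <- cbind(multimorbid = imd_mm,
               not_multimorbid = imd_total - imd_mm)
  rownames(imd) <- paste0("imd_", 1:5)
  list(gender_mm = gender, imd_mm = imd)
}
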