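#' Default long-term condition registry
#'
#' Ordered names for the 38 binary long-term-condition indicators used
#' throughout the package. The list follows the primary-care taxonomy of
#' chronic conditions commonly used in UK electronic-health-record
#' multimorbidity research. Cohort CSV columns `cond_01` ... `cond_38`
#' map positionally onto this registry.
#'
#' @return Character vector of 38 unique condition names.
#' @export
#' @examples
#' length(mm_conditions())
mm_conditions <- function() {
  c("hypertension", "depression", "pain", "asthma",
    "irritable_bowel_syndrome", "hearing_loss", "diabetes",
    "coronary_heart_disease", "copd", "anxiety", "alcohol_problems",
    "psychoactive_substance_misuse", "atrial_fibrillation",
    "heart_failure", "constipation", "prostate_disorders", "cancer",
    "chronic_kidney_disease", "stroke_tia", "epilepsy", "dementia",
    "schizophrenia_bipolar", "thyroid_disorders",
    "rheumatoid_arthritis", "osteoporosis",
    "peripheral_vascular_disease", "diverticular_disease",
    "inflammatory_bowel_disease", "psoriasis_eczema", "blindness",
    "glaucoma", "bronchiectasis", "chronic_sinusitis", "dyspepsia",
    "anorexia_bulimia", "migraine", "multiple_sclerosis",
    "learning_disability")
}

# names of the condition flag columns in a cohort table
condition_cols <- function(n = 38L) sprintf("cond_%02d", seq_len(n))
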