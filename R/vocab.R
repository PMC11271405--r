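#' Controlled vocabularies for the cohort data model
#'
#' Character constants enumerating the legal values of every categorical
#' column in the four cohort tables. These are the single source of truth:
#' the readers, the validator and the synthetic generator all reference them.
#'
#' @name vocab
#' @keywords internal
NULL

DIAGNOSIS_GROUPS <- c("CNS", "SOLID", "HM")

ENROLLMENT_STATUSES <- c("DIAGNOSIS", "FIRST_RELAPSE", "GE2_RELAPSE")

TIERS <- c("T1", "T2", "T3", "T4", "T5")

ABERRATION_CLASSES <- c("FUSION_SV", "SNV", "CNV", "HIGH_RNA_ONLY", "OTHER")

THERAPY_TYPES <- c("TARGETED_MONO", "TARGETED_DUAL", "TARGETED_PLUS_CHEMO",
                   "CHEMO")

COURSE_CATEGORIES <- c("PGT", "UGT", "SOC", "OTHER")

BASELINE_STATES <- c("MEASURABLE", "NONMEASURABLE_EVALUABLE", "NED")

MODALITIES <- c("RECIST", "RANO", "PERCIST", "LEUKEMIA")

NONMEASURABLE_STATUSES <- c("DISAPPEARED", "PERSISTS", "UNEQUIVOCAL_PROGRESSION")

RESPONSE_CATEGORIES <- c("CR", "PR", "SD", "PD", "NON_CR_NON_PD", "NE")

# ordering used when taking the best response over a course; smaller is better
RESPONSE_RANK <- c(CR = 1L, PR = 2L, SD = 3L, NON_CR_NON_PD = 3L, PD = 4L)

OCB_VALUES <- c("YES", "NO", "NE")

OS_GROUPS <- c("PGT", "UGT", "SOC", "OTHER")
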