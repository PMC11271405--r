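#' @section Data model:
#' A cohort is four tables, linked by opaque string keys:
#'
#' * `patients` — one row per enrolled patient: diagnosis group (CNS tumor,
#'   non-CNS solid tumor, hematologic malignancy), enrollment status, the day
#'   the molecular tumor board (MTB) discussed the case, vital status and the
#'   ordered days of disease-progression events since enrollment.
#' * `recommendations` — one row per MTB therapeutic option with its evidence
#'   tier (T1 strongest to T5), molecular target and aberration class.
#' * `courses` — one row per administered treatment course (PGT, UGT, SOC or
#'   other) with start/stop days, baseline disease state and assessment
#'   modality; the unit of the progression-free-survival analysis.
#' * `assessments` — one row per time-stamped disease evaluation: lesion sums
#'   for imaging modalities, blast counts for leukemia, new-lesion flags.
#'
#' All times are integer day offsets from study start; 4 weeks = 28 days,
#' 6 weeks = 42 days, 24 weeks = 168 days, 2 years = 730 days. The data
#' cutoff day is a configuration parameter and all censoring uses
#' `min(cutoff_day, last_followup_day)`.
#' @keywords internal
"_PACKAGE"

# ---- configuration ---------------------------------------------------------

#' Analysis configuration
#'
#' @param cutoff_day integer day offset of the data cutoff; every censoring
#'   time is `min(cutoff_day, last_followup_day)`.
#' @param thresholds `"paper"` for the published waterfall bands (progression
#'   at +25% for all imaging modalities) or `"recist11"` to use +20% for
#'   RECIST-assessed courses.
#' @param sd_min_day minimum day (from course start, inclusive) at which a
#'   stable-disease finding becomes countable; default 42 (6 weeks).
#' @param min_duration_day evaluability threshold on treatment duration and
#'   early progression; default 28 (4 weeks).
#' @param ocb_day disease-control duration required for objective clinical
#'   benefit; default 168 (24 weeks).
#' @param path optional path to a JSON file whose top-level keys override the
#'   arguments above.
#' @return a list of class `pgt_config`.
#' @export
pgt_config <- function(cutoff_day = 1750L, thresholds = c("paper", "recist11"),
                       sd_min_day = 42L, min_duration_day = 28L,
                       ocb_day = 168L, path = NULL) {
  thresholds <- match.arg(thresholds)
  cfg <- list(cutoff_day = as.integer(cutoff_day), thresholds = thresholds,
              sd_min_day = as.integer(sd_min_day),
              min_duration_day = as.integer(min_duration_day),
              ocb_day = as.integer(ocb_day))
  if (!is.null(path)) {
    override <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in intersect(names(override), names(cfg))) cfg[[k]] <- override[[k]]
  }
  structure(cfg, class = "pgt_config")
}

# ---- schemas ---------------------------------------------------------------

cohort_schema <- function() {
  list(
    patients = list(
      cols = c(patient_id = "character", diagnosis_group = "character",
               enrollment_day = "integer", enrollment_status = "character",
               mtb_day = "integer", death_day = "integer",
               last_followup_day = "integer", progression_days = "character"),
      optional = "death_day"),
    recommendations = list(
      cols = c(recommendation_id = "character", patient_id = "character",
               tier = "character", target_gene = "character",
               aberration_class = "character", therapy_type = "character"),
      optional = character()),
    courses = list(
      cols = c(course_id = "character", patient_id = "character",
               category = "character", recommendation_id = "character",
               start_day = "integer", stop_day = "integer",
               baseline_state = "character",
               n_progressions_before_start = "integer",
               modality = "character", pre_mtb = "logical"),
      optional = "recommendation_id"),
    assessments = list(
      cols = c(course_id = "character", day = "integer",
               target_sum = "double", nonmeasurable_status = "character",
               new_lesions = "logical", marrow_blast_pct = "double",
               circulating_blast_abs = "double", extramedullary = "logical"),
      optional = c("target_sum", "nonmeasurable_status", "marrow_blast_pct",
                   "circulating_blast_abs", "extramedullary"))
  )
}

coerce_table <- function(df, name) {
  sch <- cohort_schema()[[name]]
  missing <- setdiff(names(sch$cols), names(df))
  if (length(missing))
    abort("table '", name, "' is missing column(s): ",
          paste(missing, collapse = ", "))
  if ("progression_days" %in% names(df))
    df$progression_days[is.na(df$progression_days)] <- ""
  for (col in names(sch$cols)) {
    df[[col]] <- switch(sch$cols[[col]],
      character = as.character(df[[col]]),
      integer   = as.integer(df[[col]]),
      double    = as.numeric(df[[col]]),
      logical   = as.logical(df[[col]]))
  }
  df[names(sch$cols)]
}

# ---- progression-day list encoding ----------------------------------------

#' Encode / decode progression-day lists
#'
#' `progression_days` is stored in the patients table as a `;`-separated
#' string of strictly increasing integer days (empty string = no events),
#' keeping the table flat and the CSV round-trip lossless.
#'
#' @param x for `encode_days`, a list of integer vectors; for `decode_days`,
#'   a character vector.
#' @return the other representation.
#' @export
encode_days <- function(x) {
  vapply(x, function(v) paste(as.integer(v), collapse = ";"), character(1))
}

#' @rdname encode_days
#' @export
decode_days <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) integer() else as.integer(strsplit(s, ";")[[1]])
  })
}

# ---- validation ------------------------------------------------------------

validate_cohort <- function(cohort) {
  p <- cohort$patients; r <- cohort$recommendations
  co <- cohort$courses; a <- cohort$assessments

  chk_enum <- function(x, vocab, what) {
    bad <- !is.na(x) & !(x %in% vocab)
    if (any(bad))
      abort("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "))
  }
  chk_enum(p$diagnosis_group, DIAGNOSIS_GROUPS, "diagnosis_group")
  chk_enum(p$enrollment_status, ENROLLMENT_STATUSES, "enrollment_status")
  chk_enum(r$tier, TIERS, "tier")
  chk_enum(r$aberration_class, ABERRATION_CLASSES, "aberration_class")
  chk_enum(r$therapy_type, THERAPY_TYPES, "therapy_type")
  chk_enum(co$category, COURSE_CATEGORIES, "course category")
  chk_enum(co$baseline_state, BASELINE_STATES, "baseline_state")
  chk_enum(co$modality, MODALITIES, "modality")
  chk_enum(a$nonmeasurable_status, NONMEASURABLE_STATUSES,
           "nonmeasurable_status")

  if (anyDuplicated(p$patient_id))
    abort("duplicate patient_id in patients table")
  if (anyDuplicated(co$course_id))
    abort("duplicate course_id in courses table")

  # referential integrity: name the offending row
  bad <- which(!(r$patient_id %in% p$patient_id))
  if (length(bad))
    abort("unknown patient_id '", r$patient_id[bad[1]],
          "' in recommendations row ", bad[1])
  bad <- which(!(co$patient_id %in% p$patient_id))
  if (length(bad))
    abort("unknown patient_id '", co$patient_id[bad[1]],
          "' in courses row ", bad[1])
  bad <- which(!is.na(co$recommendation_id) &
                 !(co$recommendation_id %in% r$recommendation_id))
  if (length(bad))
    abort("unknown recommendation_id '", co$recommendation_id[bad[1]],
          "' in courses row ", bad[1])
  bad <- which(!(a$course_id %in% co$course_id))
  if (length(bad))
    abort("unknown course_id '", a$course_id[bad[1]],
          "' in assessments row ", bad[1])

  # patient timeline invariants
  if (any(p$enrollment_day > p$mtb_day))
    abort("enrollment_day later than mtb_day for patient ",
          p$patient_id[which(p$enrollment_day > p$mtb_day)[1]])
  if (any(p$mtb_day > p$last_followup_day))
    abort("mtb_day later than last_followup_day for patient ",
          p$patient_id[which(p$mtb_day > p$last_followup_day)[1]])
  bad <- which(!is.na(p$death_day) & p$death_day != p$last_followup_day)
  if (length(bad))
    abort("death_day must equal last_followup_day for patient ",
          p$patient_id[bad[1]])
  for (i in seq_len(nrow(p))) {
    d <- decode_days(p$progression_days[i])[[1]]
    if (length(d) > 1 && any(diff(d) <= 0))
      abort("progression_days not strictly increasing for patient ",
            p$patient_id[i])
  }

  # course invariants
  if (any(co$start_day >= co$stop_day))
    abort("start_day >= stop_day for course ",
          co$course_id[which(co$start_day >= co$stop_day)[1]])
  bad <- which(co$category == "PGT" & is.na(co$recommendation_id))
  if (length(bad))
    abort("PGT course without recommendation_id: ", co$course_id[bad[1]])
  mtb <- p$mtb_day[match(co$patient_id, p$patient_id)]
  bad <- which(!co$pre_mtb & co$start_day < mtb)
  if (length(bad))
    abort("course ", co$course_id[bad[1]],
          " starts before MTB without pre_mtb flag")

  # assessment invariants
  start <- co$start_day[match(a$course_id, co$course_id)]
  if (any(a$day < start))
    abort("assessment before course start for course ",
          a$course_id[which(a$day < start)[1]])
  mod <- co$modality[match(a$course_id, co$course_id)]
  bad <- which(mod == "LEUKEMIA" & is.na(a$marrow_blast_pct))
  if (length(bad))
    abort("leukemia assessment without marrow_blast_pct for course ",
          a$course_id[bad[1]])
  if (any(!is.na(a$target_sum) & a$target_sum < 0))
    abort("negative target_sum")
  # measurable imaging courses need a baseline target-lesion sum
  meas <- co$course_id[co$baseline_state == "MEASURABLE" &
                         co$modality != "LEUKEMIA"]
  if (length(meas)) {
    ao <- a[order(a$course_id, a$day), ]
    first <- ao[!duplicated(ao$course_id), ]
    hit <- match(meas, first$course_id)
    bad <- is.na(hit) | is.na(first$target_sum[hit])
    if (any(bad))
      abort("measurable course ", meas[which(bad)[1]],
            " lacks a baseline target_sum")
  }
  invisible(cohort)
}

#' Assemble and validate a cohort object
#'
#' @param patients,recommendations,courses,assessments data frames following
#'   the shipped data dictionary (`system.file("extdata",
#'   "data_dictionary.json", package = "pgtkit")`).
#' @return a validated list of class `pgt_cohort`.
#' @export
as_cohort <- function(patients, recommendations, courses, assessments) {
  cohort <- structure(
    list(patients = coerce_table(patients, "patients"),
         recommendations = coerce_table(recommendations, "recommendations"),
         courses = coerce_table(courses, "courses"),
         assessments = coerce_table(assessments, "assessments")),
    class = "pgt_cohort")
  validate_cohort(cohort)
}

#' @export
print.pgt_cohort <- function(x, ...) {
  cat("<pgt_cohort>", nrow(x$patients), "patients,",
      nrow(x$recommendations), "recommendations,",
      nrow(x$courses), "courses,",
      nrow(x$assessments), "assessments\n")
  invisible(x)
}

# ---- i/o -------------------------------------------------------------------

#' Read a cohort from four CSV tables
#'
#' @param dir directory containing `patients.csv`, `recommendations.csv`,
#'   `courses.csv` and `assessments.csv`; alternatively pass the four paths
#'   via `paths` as a named character vector.
#' @param paths optional named character vector with names `patients`,
#'   `recommendations`, `courses`, `assessments`.
#' @param quiet suppress the row-count message.
#' @return a validated `pgt_cohort`.
#' @export
read_cohort <- function(dir = NULL, paths = NULL, quiet = FALSE) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- file.path(dir, paste0(names(cohort_schema()), ".csv"))
    names(paths) <- names(cohort_schema())
  }
  for (pp in paths) if (!file.exists(pp)) abort("file not found: ", pp)
  tabs <- lapply(names(cohort_schema()), function(nm) {
    utils::read.csv(paths[[nm]], colClasses = "character",
                    na.strings = c("NA", ""))
  })
  names(tabs) <- names(cohort_schema())
  cohort <- as_cohort(tabs$patients, tabs$recommendations, tabs$courses,
                      tabs$assessments)
  if (!quiet)
    message(sprintf("read cohort: %d patients / %d recommendations / %d courses / %d assessments",
                    nrow(cohort$patients), nrow(cohort$recommendations),
                    nrow(cohort$courses), nrow(cohort$assessments)))
  cohort
}

#' Write a cohort to four CSV tables
#'
#' Inverse of [read_cohort()]; the round trip is lossless.
#'
#' @param cohort a `pgt_cohort`.
#' @param dir output directory (created if absent).
#' @return the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pgt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(cohort_schema()), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(cohort[[nm]], p, row.names = FALSE, na = "")
    p
  }, character(1))
  invisible(paths)
}

# ---- aberration classification --------------------------------------------

#' Classify a molecular aberration from its evidence flags
#'
#' A targeted gene may carry several kinds of supporting evidence. The class
#' is assigned by fixed precedence `FUSION_SV > SNV > CNV`; high RNA
#' expression yields `HIGH_RNA_ONLY` only when it is the sole evidence —
#' a target with any structural, sequence or copy-number evidence is never
#' classed as high-RNA-only.
#'
#' @param flags character vector, a non-empty subset of
#'   `c("FUSION_SV", "SNV", "CNV", "HIGH_RNA")`.
#' @return one of `"FUSION_SV"`, `"SNV"`, `"CNV"`, `"HIGH_RNA_ONLY"`.
#' @export
#' @examples
#' classify_aberration(c("FUSION_SV", "HIGH_RNA"))  # "FUSION_SV"
#' classify_aberration("HIGH_RNA")                  # "HIGH_RNA_ONLY"
classify_aberration <- function(flags) {
  valid <- c("FUSION_SV", "SNV", "CNV", "HIGH_RNA")
  if (length(flags) == 0) abort("empty evidence-flag set")
  if (!all(flags %in% valid))
    abort("unknown evidence flag: ",
          paste(setdiff(flags, valid), collapse = ", "))
  for (cl in c("FUSION_SV", "SNV", "CNV")) if (cl %in% flags) return(cl)
  "HIGH_RNA_ONLY"
}
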