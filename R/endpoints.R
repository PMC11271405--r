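# Endpoint derivation: analysis-set filters with reason-coded audit trail,
# per-course PFS, objective clinical benefit, intra-patient PFS ratio,
# overall-survival grouping, and the favorable-factor score.

first_pd_day <- function(course, responses) {
  sel <- responses$course_id == course$course_id &
    responses$category == "PD"
  if (!any(sel)) NA_integer_ else min(responses$day[sel])
}

#' Evaluability of a treatment course
#'
#' A course enters the outcome analysis when all three hold: treatment
#' duration of 28 days (4 weeks) or longer; no disease progression within the
#' first 28 days of treatment; and at least one response evaluation exists.
#'
#' @param course one row of the courses table.
#' @param responses adjudicated assessments ([adjudicate()] output).
#' @param config a [pgt_config()].
#' @return list with `evaluable` (logical) and `reason` (`"ok"`,
#'   `"duration<4wk"`, `"early PD"`, `"no evaluation"`).
#' @export
is_evaluable <- function(course, responses, config = pgt_config()) {
  min_d <- config$min_duration_day
  if (course$stop_day - course$start_day < min_d)
    return(list(evaluable = FALSE, reason = "duration<4wk"))
  pd <- first_pd_day(course, responses)
  if (!is.na(pd) && pd - course$start_day < min_d)
    return(list(evaluable = FALSE, reason = "early PD"))
  has_eval <- any(responses$course_id == course$course_id) ||
    course$baseline_state == "NED"
  if (!has_eval)
    return(list(evaluable = FALSE, reason = "no evaluation"))
  list(evaluable = TRUE, reason = "ok")
}

#' Progression-free survival for a course
#'
#' Time from the start of the specific treatment to the first disease
#' progression on that treatment or death from any cause, whichever occurs
#' first; censored at `min(cutoff_day, last_followup_day)` when neither
#' occurs.
#'
#' @param course one row of the courses table.
#' @param responses adjudicated assessments.
#' @param patient the matching row of the patients table.
#' @param config a [pgt_config()].
#' @return list with `days` (integer) and `event` (logical).
#' @export
compute_pfs <- function(course, responses, patient, config = pgt_config()) {
  pd <- first_pd_day(course, responses)
  if (!is.na(pd) && pd < course$start_day)
    abort("progression recorded before course start for ", course$course_id)
  death <- patient$death_day
  event_day <- suppressWarnings(min(pd, death, na.rm = TRUE))
  if (is.finite(event_day)) {
    list(days = as.integer(event_day - course$start_day), event = TRUE)
  } else {
    cens <- min(config$cutoff_day, patient$last_followup_day)
    list(days = as.integer(cens - course$start_day), event = FALSE)
  }
}

#' Objective clinical benefit for a course
#'
#' Three branches, by baseline disease state:
#' * measurable: best response CR/PR/SD with disease control sustained for
#'   168 days (24 weeks) or longer;
#' * non-measurable: CR or non-CR/non-PD sustained 168 days or longer;
#' * no evidence of disease at start: disease-free for 168 days or longer.
#'
#' Disease control is measured from the course start to the first
#' progression or the treatment stop, whichever ends observation. A course
#' whose best response is stable disease but which stopped before 168 days
#' while still in SD cannot be assessed and returns `"NE"`.
#'
#' @inheritParams compute_pfs
#' @param best the course's [best_response()].
#' @return `"YES"`, `"NO"` or `"NE"`.
#' @export
compute_ocb <- function(course, responses, best, config = pgt_config()) {
  pd <- first_pd_day(course, responses)
  control_end <- if (!is.na(pd)) min(pd, course$stop_day) else course$stop_day
  control <- control_end - course$start_day
  sustained <- control >= config$ocb_day

  if (course$baseline_state == "NED")
    return(if (is.na(pd) && sustained) "YES" else "NO")
  if (best == "NE") return("NE")
  controlled <- best %in% c("CR", "PR", "SD", "NON_CR_NON_PD")
  if (controlled && sustained) return("YES")
  # stopped early while still in disease control without progression:
  # the 24-week clock cannot be adjudicated
  if (best %in% c("SD", "NON_CR_NON_PD") && is.na(pd) && !sustained)
    return("NE")
  "NO"
}

#' Intra-patient PFS ratio for a molecularly guided course
#'
#' Compares PFS on the guided treatment (PFS2) with PFS on the most recent
#' previous treatment on which the patient experienced progression (PFS1).
#' Eligibility requires all five of:
#' 1. no progression within the first 28 days of the guided course;
#' 2. if the guided course has not progressed at cutoff, its (censored) PFS
#'    must be at least as long as the comparator's;
#' 3. the comparator ended in progression;
#' 4. the comparator was given for relapsed/refractory disease;
#' 5. both treatment durations were 28 days or longer.
#'
#' Clinical benefit: PFS2/PFS1 > 1.3 and PFS2 - PFS1 >= 28 days.
#'
#' @param pgt_pfs,prior_pfs lists from [compute_pfs()] for the guided course
#'   and the comparator.
#' @param pgt_course,prior_course the respective course rows; pass
#'   `prior_course = NULL` when no progressed comparator exists.
#' @param config a [pgt_config()].
#' @return list with `eligible`, `reason`, and (when eligible) `ratio` and
#'   `benefit`.
#' @export
pfs_ratio <- function(pgt_pfs, prior_pfs, pgt_course, prior_course,
                      config = pgt_config()) {
  inel <- function(reason) list(eligible = FALSE, reason = reason,
                                ratio = NA_real_, benefit = NA)
  if (is.null(prior_course)) return(inel("no comparator"))
  min_d <- config$min_duration_day
  if (pgt_pfs$event && pgt_pfs$days < min_d) return(inel("early PD"))
  if (!pgt_pfs$event && pgt_pfs$days < prior_pfs$days)
    return(inel("censored before comparator duration"))
  if (!prior_pfs$event) return(inel("comparator did not progress"))
  if (prior_course$n_progressions_before_start < 1)
    return(inel("comparator not for relapsed/refractory disease"))
  if (pgt_course$stop_day - pgt_course$start_day < min_d ||
      prior_course$stop_day - prior_course$start_day < min_d)
    return(inel("duration<4wk"))
  ratio <- pgt_pfs$days / prior_pfs$days
  list(eligible = TRUE, reason = "ok", ratio = ratio,
       benefit = ratio > 1.3 && (pgt_pfs$days - prior_pfs$days) >= min_d)
}

# most recent course before `start_day` on which the patient progressed;
# `courses` should already be restricted to the patient's courses
find_comparator <- function(courses, pfs_by_course, patient_id, start_day) {
  cand <- courses[courses$patient_id == patient_id &
                    courses$start_day < start_day, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  # the comparator's progression/death must precede the index course start
  progressed <- vapply(seq_len(nrow(cand)), function(j) {
    p <- pfs_by_course[[cand$course_id[j]]]
    !is.null(p) && p$event && (cand$start_day[j] + p$days) <= start_day
  }, logical(1))
  cand <- cand[progressed, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand[which.max(cand$start_day), ]
}

#' Overall-survival comparison groups
#'
#' Each patient with at least one new treatment starting on or after the MTB
#' day is assigned to the category of the first such treatment; the OS origin
#' is that treatment's start day. Patients who never started a new treatment
#' after the MTB are excluded. For patients whose first post-MTB treatment is
#' molecularly guided and who received several guided courses, the origin is
#' the start of the first guided course (identical by construction).
#'
#' @param patients,courses cohort tables.
#' @return data frame `(patient_id, group, origin_day)`; `group` is the
#'   course category of the first post-MTB treatment.
#' @export
assign_os_groups <- function(patients, courses) {
  out <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    cand <- courses[courses$patient_id == p$patient_id &
                      !courses$pre_mtb &
                      courses$start_day >= p$mtb_day, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    first <- cand[which.min(cand$start_day), ]
    origin <- first$start_day
    if (first$category == "PGT") {
      pgts <- cand[cand$category == "PGT", ]
      origin <- min(pgts$start_day)
    }
    data.frame(patient_id = p$patient_id, group = first$category,
               origin_day = as.integer(origin))
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(patient_id = character(), group = character(),
                      origin_day = integer())
  rownames(res) <- NULL
  res
}

#' Favorable-factor score for a guided course
#'
#' Counts how many of three independent favorable prognostic factors apply:
#' tier-1 evidence behind the recommendation, a fusion/structural-variant
#' target, and treatment started before any disease progression since
#' enrollment. Not defined (`NA`) for hematologic malignancies.
#'
#' @param pgt_course a PGT course row.
#' @param recommendation the matching recommendation row.
#' @param patient the matching patient row.
#' @return integer 0-3, or `NA` for hematologic malignancies.
#' @export
favorable_factors <- function(pgt_course, recommendation, patient) {
  stopifnot(pgt_course$category == "PGT")
  if (patient$diagnosis_group == "HM") return(NA_integer_)
  as.integer((recommendation$tier == "T1") +
             (recommendation$aberration_class == "FUSION_SV") +
             (pgt_course$n_progressions_before_start == 0))
}

#' Derive all per-course endpoints
#'
#' Runs the full filter-and-derive pipeline: evaluability with reason codes,
#' best response, objective response, OCB, PFS, PFS ratio and the
#' favorable-factor score for every course in the cohort.
#'
#' @param cohort a `pgt_cohort`.
#' @param responses adjudicated assessments from [adjudicate()]; computed if
#'   missing.
#' @param config a [pgt_config()].
#' @return data frame with one row per course, class `pgt_endpoints`:
#'   `course_id, patient_id, category, baseline_state, evaluable, reason,
#'   best_response, objective_response, ocb, pfs_days, pfs_event, pfs_ratio,
#'   pfs_ratio_benefit, pfs_ratio_reason, favorable_factors`.
#' @export
derive_endpoints <- function(cohort, responses = NULL,
                             config = pgt_config()) {
  stopifnot(inherits(cohort, "pgt_cohort"))
  if (is.null(responses)) responses <- adjudicate(cohort, config)
  co <- cohort$courses
  n <- nrow(co)
  pat <- cohort$patients[match(co$patient_id, cohort$patients$patient_id), ]
  rec <- cohort$recommendations[
    match(co$recommendation_id, cohort$recommendations$recommendation_id), ]

  # pre-split the adjudicated assessments so each course sees only its rows
  ridx <- split(seq_len(nrow(responses)),
                factor(responses$course_id, levels = co$course_id))
  resp_for <- function(i) {
    jj <- ridx[[co$course_id[i]]]
    list(course_id = responses$course_id[jj], day = responses$day[jj],
         category = responses$category[jj])
  }
  # plain row-lists avoid data.frame row-extraction overhead in the loop
  co_rows <- do.call(Map, c(list(f = list), co))
  pat_rows <- do.call(Map, c(list(f = list), pat))
  courses_by_patient <- split(co, co$patient_id)

  ev <- vector("list", n); pfs <- vector("list", n)
  best <- character(n); ocb <- character(n)
  for (i in seq_len(n)) {
    ri <- resp_for(i)
    ev[[i]] <- is_evaluable(co_rows[[i]], ri, config)
    pfs[[i]] <- compute_pfs(co_rows[[i]], ri, pat_rows[[i]], config)
    best[i] <- best_response(co_rows[[i]], ri, config)
    ocb[i] <- if (ev[[i]]$evaluable)
      compute_ocb(co_rows[[i]], ri, best[i], config) else "NE"
  }
  pfs_by_course <- stats::setNames(pfs, co$course_id)

  ratio <- rep(NA_real_, n); benefit <- rep(NA, n)
  ratio_reason <- rep(NA_character_, n)
  ff <- rep(NA_integer_, n)
  rec_rows <- do.call(Map, c(list(f = list), rec))
  for (i in seq_len(n)) {
    if (co$category[i] != "PGT") next
    ff[i] <- favorable_factors(co_rows[[i]], rec_rows[[i]], pat_rows[[i]])
    if (!ev[[i]]$evaluable) {
      ratio_reason[i] <- "not evaluable"
      next
    }
    comp <- find_comparator(courses_by_patient[[co$patient_id[i]]],
                            pfs_by_course, co$patient_id[i],
                            co$start_day[i])
    pr <- pfs_ratio(pfs[[i]],
                    if (is.null(comp)) NULL else pfs_by_course[[comp$course_id]],
                    co_rows[[i]], comp, config)
    ratio_reason[i] <- pr$reason
    if (pr$eligible) {
      ratio[i] <- pr$ratio
      benefit[i] <- pr$benefit
    }
  }

  res <- data.frame(
    course_id = co$course_id,
    patient_id = co$patient_id,
    category = co$category,
    baseline_state = co$baseline_state,
    evaluable = vapply(ev, `[[`, logical(1), "evaluable"),
    reason = vapply(ev, `[[`, character(1), "reason"),
    best_response = best,
    objective_response = best %in% c("CR", "PR"),
    ocb = ocb,
    pfs_days = vapply(pfs, `[[`, integer(1), "days"),
    pfs_event = vapply(pfs, `[[`, logical(1), "event"),
    pfs_ratio = ratio,
    pfs_ratio_benefit = benefit,
    pfs_ratio_reason = ratio_reason,
    favorable_factors = ff)
  class(res) <- c("pgt_endpoints", "data.frame")
  res
}

#' Audit the evaluability filter
#'
#' Filter conservation: every input course is either in the analysis set or
#' carries exactly one reason-coded exclusion.
#'
#' @param endpoints a `pgt_endpoints` data frame.
#' @param category optional course category to restrict to (e.g. `"PGT"`).
#' @return list with `n_input`, `n_evaluable` and a named exclusion table.
#' @export
audit_filters <- function(endpoints, category = NULL) {
  e <- endpoints
  if (!is.null(category)) e <- e[e$category == category, ]
  excl <- table(e$reason[!e$evaluable])
  list(n_input = nrow(e), n_evaluable = sum(e$evaluable),
       exclusions = excl)
}
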