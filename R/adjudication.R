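# Response adjudication under the four modality rule sets.
#
# Imaging modalities are operationalized as percent-change bands on the
# target-lesion sum (or the SUV-derived quantity for PET): progression at or
# above +25%, partial response at or below -50% (CNS/RANO-style) or -30%
# (RECIST/PERCIST-style), complete response only at -100%, stable disease in
# the open interval between. Leukemia uses marrow/circulating blast rules.

#' Response thresholds for percent-change classification
#'
#' @param modality one of `"RECIST"`, `"RANO"`, `"PERCIST"`.
#' @param set `"paper"` uses the published waterfall bands (+25% progression
#'   boundary everywhere); `"recist11"` switches RECIST/PERCIST courses to the
#'   +20% progression boundary of RECIST 1.1.
#' @return list with `pr_cut` (fractional change, negative, inclusive),
#'   `pd_cut` (fractional change, positive, inclusive).
#' @export
response_thresholds <- function(modality, set = c("paper", "recist11")) {
  set <- match.arg(set)
  pr_cut <- if (modality == "RANO") -0.50 else -0.30
  pd_cut <- if (set == "recist11" && modality != "RANO") 0.20 else 0.25
  stopifnot(pr_cut < 0, pd_cut > 0)
  list(pr_cut = pr_cut, pd_cut = pd_cut)
}

#' Classify a percent change in measurable disease
#'
#' New lesions force progression regardless of the target-lesion change.
#' Total disappearance (-100%) is a complete response. Both band boundaries
#' are inclusive: change >= `pd_cut` is progression, change <= `pr_cut` is
#' a partial response; stable disease is the open interval between.
#'
#' @param baseline_sum baseline target-lesion sum, strictly positive.
#' @param current_sum current sum, non-negative.
#' @param thresholds a list from [response_thresholds()].
#' @param new_lesions logical; unequivocal new lesion(s) present.
#' @return one of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
#' @examples
#' th <- response_thresholds("RANO")
#' classify_target_change(100, 45, th, FALSE)   # "PR"
#' classify_target_change(100, 125, th, FALSE)  # "PD"
classify_target_change <- function(baseline_sum, current_sum, thresholds,
                                   new_lesions = FALSE) {
  if (!is.finite(baseline_sum) || baseline_sum <= 0)
    abort("baseline_sum must be > 0")
  if (!is.finite(current_sum) || current_sum < 0)
    abort("current_sum must be >= 0")
  if (new_lesions) return("PD")
  change <- (current_sum - baseline_sum) / baseline_sum
  if (change <= -1) return("CR")
  if (change >= thresholds$pd_cut) return("PD")
  if (change <= thresholds$pr_cut) return("PR")
  "SD"
}

#' Classify non-measurable disease
#'
#' Non-measurable disease supports only three outcomes: disappearance is a
#' complete response, unequivocal progression or new lesions is progression,
#' and persistence is "non-CR/non-PD". A partial response is never returned.
#'
#' @param status one of `"DISAPPEARED"`, `"PERSISTS"`,
#'   `"UNEQUIVOCAL_PROGRESSION"`.
#' @param new_lesions logical.
#' @return one of `"CR"`, `"NON_CR_NON_PD"`, `"PD"`.
#' @export
classify_nonmeasurable <- function(status, new_lesions = FALSE) {
  if (is.na(status) || !(status %in% NONMEASURABLE_STATUSES))
    abort("invalid nonmeasurable_status: ", status)
  if (new_lesions || status == "UNEQUIVOCAL_PROGRESSION") return("PD")
  if (status == "DISAPPEARED") return("CR")
  "NON_CR_NON_PD"
}

#' Classify a leukemia assessment from blast counts
#'
#' Rules on bone-marrow blast percentage, absolute circulating blasts and
#' extramedullary disease:
#' * CR: marrow < 5% blasts, no circulating blasts, no extramedullary
#'   disease.
#' * PR: marrow 5-25%, or a > 50% relative reduction from the baseline
#'   marrow count with at least a 10-point absolute reduction; in either
#'   case no circulating blasts and no extramedullary disease.
#' * PD: circulating blasts rise by more than 25% of the baseline absolute
#'   count (any appearance counts when the baseline count is zero), or
#'   marrow blasts rise more than 25 points above the nadir after a partial
#'   response, or more than 5 points above the nadir after a complete
#'   response.
#' * SD: failure to qualify for CR, PR or PD.
#'
#' When the marrow nadir is unknown it defaults to the cap of the achieved
#' category (5 for CR, 25 for PR), the most conservative value consistent
#' with that category.
#'
#' @param current,baseline lists with `marrow_blast_pct`,
#'   `circulating_blast_abs`, `extramedullary`.
#' @param prior_best best category achieved earlier in the course
#'   (`"CR"`, `"PR"`) or `NULL`.
#' @param nadir_marrow lowest marrow blast percentage observed so far;
#'   optional.
#' @return one of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_leukemia <- function(current, baseline, prior_best = NULL,
                              nadir_marrow = NULL) {
  m <- current$marrow_blast_pct
  if (is.na(m) || m < 0 || m > 100)
    abort("marrow_blast_pct must be in [0, 100]")
  circ <- current$circulating_blast_abs %||% NA_real_
  if (is.na(circ)) circ <- 0
  emd <- isTRUE(current$extramedullary)
  base_m <- baseline$marrow_blast_pct
  base_circ <- baseline$circulating_blast_abs %||% NA_real_
  if (is.na(base_circ)) base_circ <- 0

  # progression tests first: a record can never be both CR and PD
  circ_pd <- if (base_circ > 0) (circ - base_circ) > 0.25 * base_circ
             else circ > 0  # any appearance exceeds 25% of a zero baseline
  marrow_pd <- FALSE
  if (!is.null(prior_best) && prior_best %in% c("CR", "PR")) {
    nadir <- nadir_marrow %||% (if (prior_best == "CR") 5 else 25)
    rise_limit <- if (prior_best == "CR") 5 else 25
    marrow_pd <- (m - nadir) > rise_limit
  }
  if (circ_pd || marrow_pd) return("PD")

  if (m < 5 && circ == 0 && !emd) return("CR")
  if (circ == 0 && !emd) {
    if (m >= 5 && m <= 25) return("PR")
    if (is.na(base_m))
      abort("baseline marrow_blast_pct required for relative-reduction PR")
    if (base_m > 0 && (base_m - m) / base_m > 0.5 && (base_m - m) >= 10)
      return("PR")
  }
  "SD"
}

# classify one assessment row given its course; internal dispatch
classify_assessment <- function(course, assessment, baseline_assessment,
                                thresholds, prior_best = NULL,
                                nadir_marrow = NULL) {
  if (course$modality == "LEUKEMIA") {
    return(classify_leukemia(
      list(marrow_blast_pct = assessment$marrow_blast_pct,
           circulating_blast_abs = assessment$circulating_blast_abs,
           extramedullary = assessment$extramedullary),
      list(marrow_blast_pct = baseline_assessment$marrow_blast_pct,
           circulating_blast_abs = baseline_assessment$circulating_blast_abs),
      prior_best = prior_best, nadir_marrow = nadir_marrow))
  }
  if (course$baseline_state == "MEASURABLE") {
    classify_target_change(baseline_assessment$target_sum,
                           assessment$target_sum, thresholds,
                           isTRUE(assessment$new_lesions))
  } else {
    classify_nonmeasurable(assessment$nonmeasurable_status,
                           isTRUE(assessment$new_lesions))
  }
}

#' Adjudicate every assessment of every course
#'
#' Classifies each post-baseline assessment under the course's modality rule
#' set. The baseline is the earliest assessment of the course (required at
#' the course start day for measurable and leukemia courses). Courses with a
#' `NED` baseline have no response categories; a new-lesion or
#' unequivocal-progression assessment on such a course is recorded as
#' relapse (`PD`).
#'
#' @param cohort a `pgt_cohort`.
#' @param config a [pgt_config()].
#' @return data frame `(course_id, day, category)`, one row per post-baseline
#'   assessment, ordered by course then day.
#' @export
adjudicate <- function(cohort, config = pgt_config()) {
  stopifnot(inherits(cohort, "pgt_cohort"))
  a <- cohort$assessments[order(cohort$assessments$course_id,
                                cohort$assessments$day), ]
  co <- cohort$courses
  idx_split <- split(seq_len(nrow(a)),
                     factor(a$course_id, levels = co$course_id))
  out <- vector("list", nrow(co))
  for (i in seq_len(nrow(co))) {
    ii <- idx_split[[co$course_id[i]]]
    if (length(ii) == 0) next
    day <- a$day[ii]; ts <- a$target_sum[ii]
    st <- a$nonmeasurable_status[ii]; nl <- a$new_lesions[ii]
    mb <- a$marrow_blast_pct[ii]; cb <- a$circulating_blast_abs[ii]
    emd <- a$extramedullary[ii]
    bstate <- co$baseline_state[i]; modality <- co$modality[i]

    if (bstate == "NED") {
      pd <- nl | (!is.na(st) & st == "UNEQUIVOCAL_PROGRESSION")
      if (any(pd))
        out[[i]] <- list(course_id = rep(co$course_id[i], sum(pd)),
                         day = day[pd],
                         category = rep("PD", sum(pd)))
      next
    }
    if (length(ii) < 2) next
    thresholds <- response_thresholds(
      if (modality == "LEUKEMIA") "RECIST" else modality, config$thresholds)
    cats <- character(length(ii) - 1)
    prior_best <- NULL
    nadir <- mb[1]
    for (j in seq.int(2, length(ii))) {
      cats[j - 1] <- if (modality == "LEUKEMIA") {
        classify_leukemia(
          list(marrow_blast_pct = mb[j], circulating_blast_abs = cb[j],
               extramedullary = emd[j]),
          list(marrow_blast_pct = mb[1], circulating_blast_abs = cb[1]),
          prior_best = prior_best, nadir_marrow = nadir)
      } else if (bstate == "MEASURABLE") {
        classify_target_change(ts[1], ts[j], thresholds, isTRUE(nl[j]))
      } else {
        classify_nonmeasurable(st[j], isTRUE(nl[j]))
      }
      cc <- cats[j - 1]
      if (cc %in% c("CR", "PR") &&
          (is.null(prior_best) ||
             RESPONSE_RANK[[cc]] < RESPONSE_RANK[[prior_best]]))
        prior_best <- cc
      if (modality == "LEUKEMIA" && !is.na(mb[j]))
        nadir <- min(nadir, mb[j], na.rm = TRUE)
    }
    out[[i]] <- list(course_id = rep(co$course_id[i], length(cats)),
                     day = day[-1], category = cats)
  }
  keep <- out[!vapply(out, is.null, logical(1))]
  if (length(keep) == 0)
    return(data.frame(course_id = character(), day = integer(),
                      category = character()))
  res <- as.data.frame(data.table::rbindlist(keep))
  rownames(res) <- NULL
  res
}

#' Best response over a course
#'
#' Takes the best category over the adjudicated assessments of a course with
#' ordering CR > PR > SD > PD. A stable-disease (or non-CR/non-PD) finding is
#' countable only when achieved at 42 days (6 weeks) or later after the
#' course start; progression counts at any time. Courses with no qualifying
#' post-baseline assessment return `"NE"` (not evaluable) — a value, not an
#' error.
#'
#' @param course one row of the courses table.
#' @param responses adjudicated assessments for this course (rows of the
#'   [adjudicate()] output).
#' @param config a [pgt_config()].
#' @return one of `"CR"`, `"PR"`, `"SD"`, `"NON_CR_NON_PD"`, `"PD"`, `"NE"`.
#' @export
best_response <- function(course, responses, config = pgt_config()) {
  sel <- responses$course_id == course$course_id
  day <- responses$day[sel]
  category <- responses$category[sel]
  if (length(category) == 0) return("NE")
  qualifies <- category %in% c("CR", "PR", "PD") |
    (category %in% c("SD", "NON_CR_NON_PD") &
       (day - course$start_day) >= config$sd_min_day)
  category <- category[qualifies]
  if (length(category) == 0) return("NE")
  category[which.min(RESPONSE_RANK[category])]
}
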