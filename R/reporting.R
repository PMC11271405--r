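# Aggregate reporting: response/benefit summaries, stratified outcome
# tables with survival-at-2-years and per-stratum comparison p-values, and
# tidy figure-backing exports (waterfall / swimmer / survival curves).

#' Summarize best responses
#'
#' @param endpoints a `pgt_endpoints` data frame.
#' @param scope `"measurable"` restricts to evaluable courses with
#'   measurable baseline disease; `"evaluable"` additionally includes
#'   non-measurable disease, with non-CR/non-PD pooled as SD. Disease-free
#'   (NED) courses are never response-evaluable.
#' @param category course category to summarize (default `"PGT"`); `NULL`
#'   for all.
#' @return list with `n`, `counts` (named CR/PR/SD/PD), `rates` (whole
#'   percents, rounded half away from zero) and `orr` (objective response
#'   rate, CR+PR, whole percent).
#' @export
response_summary <- function(endpoints, scope = c("measurable", "evaluable"),
                             category = "PGT") {
  scope <- match.arg(scope)
  e <- endpoints[endpoints$evaluable, ]
  if (!is.null(category)) e <- e[e$category == category, ]
  e <- e[e$baseline_state != "NED", ]
  if (scope == "measurable") e <- e[e$baseline_state == "MEASURABLE", ]
  if (nrow(e) == 0) abort("empty scope for response_summary")
  resp <- e$best_response
  resp[resp == "NON_CR_NON_PD"] <- "SD"
  counts <- vapply(c("CR", "PR", "SD", "PD"),
                   function(cc) sum(resp == cc), integer(1))
  n <- nrow(e)
  list(n = n, counts = counts, rates = pct(counts, n),
       orr = pct(counts[["CR"]] + counts[["PR"]], n))
}

#' Summarize objective clinical benefit
#'
#' The denominator excludes courses whose benefit could not be adjudicated
#' (`ocb == "NE"`).
#'
#' @inheritParams response_summary
#' @return list with `n_assessable`, `n_benefit`, `rate` (whole percent)
#'   and the exact 95% binomial confidence interval of the proportion.
#' @export
ocb_summary <- function(endpoints, category = "PGT") {
  e <- endpoints[endpoints$evaluable, ]
  if (!is.null(category)) e <- e[e$category == category, ]
  e <- e[e$ocb != "NE", ]
  if (nrow(e) == 0) abort("no assessable courses")
  k <- sum(e$ocb == "YES")
  list(n_assessable = nrow(e), n_benefit = k, rate = pct(k, nrow(e)),
       ci = exact_binomial_ci(k, nrow(e)))
}

#' Summarize the intra-patient PFS ratio analysis
#'
#' @inheritParams response_summary
#' @return list with `n_assessable`, `n_benefit`, `rate` and exact 95% CI.
#' @export
pfs_ratio_summary <- function(endpoints, category = "PGT") {
  e <- endpoints
  if (!is.null(category)) e <- e[e$category == category, ]
  e <- e[!is.na(e$pfs_ratio), ]
  if (nrow(e) == 0) abort("no PFS-ratio-assessable courses")
  k <- sum(e$pfs_ratio_benefit)
  list(n_assessable = nrow(e), n_benefit = k, rate = pct(k, nrow(e)),
       ci = exact_binomial_ci(k, nrow(e)))
}

# Greenwood variance, complementary log-log 95% CI for S(t)
km_ci_at <- function(fit, t, level = 0.95) {
  s <- km_survival_at(fit, t)
  tab <- fit$table[fit$table$time <= t & fit$table$n_event > 0, ]
  if (nrow(tab) == 0 || s %in% c(0, 1)) return(c(NA_real_, NA_real_))
  gw <- sum(tab$n_event / (tab$n_risk * (tab$n_risk - tab$n_event)))
  se_cll <- sqrt(gw) / abs(log(s))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cl <- log(-log(s))
  exp(-exp(c(cl + z * se_cll, cl - z * se_cll)))
}

# per-course stratification covariates used by stratified_outcomes()
build_strata <- function(cohort, endpoints) {
  co <- cohort$courses
  rec <- cohort$recommendations[
    match(co$recommendation_id, cohort$recommendations$recommendation_id), ]
  pat <- cohort$patients[match(co$patient_id, cohort$patients$patient_id), ]
  data.frame(
    course_id = co$course_id,
    tier = rec$tier,
    tier_group = ifelse(rec$tier == "T1", "T1",
                        ifelse(rec$tier == "T2", "T2", "T3-5")),
    aberration_class = rec$aberration_class,
    disease_status = ifelse(co$n_progressions_before_start == 0,
                            "no_PD", "PD"),
    therapy_type = rec$therapy_type,
    cancer_type = pat$diagnosis_group,
    favorable_factors = endpoints$favorable_factors[
      match(co$course_id, endpoints$course_id)])
}

#' Stratified outcome table
#'
#' For each level of a stratification variable over evaluable guided
#' courses: n, 2-year progression-free survival with Greenwood/log-log 95%
#' CI, response rate, clinical-benefit rate, and comparison p-values versus
#' a declared reference stratum (log-rank for survival, chi-squared for
#' proportions).
#'
#' @param cohort a `pgt_cohort`.
#' @param endpoints matching `pgt_endpoints`.
#' @param stratum one of `"tier_group"`, `"aberration_class"`,
#'   `"disease_status"`, `"therapy_type"`, `"cancer_type"`,
#'   `"favorable_factors"`.
#' @param reference reference level for comparisons; must be a non-empty
#'   stratum.
#' @param at_day survival read-out day (default 730 = 2 years).
#' @param category course category analyzed (default `"PGT"`).
#' @return data frame of class `outcome_table`, one row per stratum.
#' @export
stratified_outcomes <- function(cohort, endpoints, stratum, reference,
                                at_day = 730L, category = "PGT") {
  strata <- build_strata(cohort, endpoints)
  e <- endpoints[endpoints$evaluable &
                   (is.null(category) | endpoints$category == category), ]
  g <- strata[[stratum]][match(e$course_id, strata$course_id)]
  keep <- !is.na(g)
  e <- e[keep, ]; g <- as.character(g[keep])
  levels <- unique(g[order(g)])
  counts <- table(g)
  empty <- setdiff(levels, names(counts)[counts > 0])
  if (length(empty)) {
    warning("dropping empty stratum: ", paste(empty, collapse = ", "))
    levels <- setdiff(levels, empty)
  }
  if (!(reference %in% levels)) abort("reference stratum missing: ", reference)

  ref_rows <- g == reference
  row_for <- function(lv) {
    rows <- g == lv
    fit <- km_fit(pmax(e$pfs_days[rows], 0.5), e$pfs_event[rows])
    s <- km_survival_at(fit, at_day)
    ci <- km_ci_at(fit, at_day)
    resp <- e$best_response[rows]
    resp_eval <- e$baseline_state[rows] != "NED"
    n_resp <- sum(resp[resp_eval] %in% c("CR", "PR"))
    ocb_rows <- e$ocb[rows] != "NE"
    n_ocb <- sum(e$ocb[rows][ocb_rows] == "YES")
    if (lv == reference) {
      p_pfs <- p_resp <- p_ocb <- NA_real_
    } else {
      both <- rows | ref_rows
      p_pfs <- logrank(pmax(e$pfs_days[both], 0.5), e$pfs_event[both],
                       ifelse(g[both] == reference, "ref", "cmp"))$p_value
      p_resp <- prop_p(n_resp, sum(resp_eval),
                       sum(e$best_response[ref_rows][
                         e$baseline_state[ref_rows] != "NED"] %in%
                           c("CR", "PR")),
                       sum(e$baseline_state[ref_rows] != "NED"))
      p_ocb <- prop_p(n_ocb, sum(ocb_rows),
                      sum(e$ocb[ref_rows][e$ocb[ref_rows] != "NE"] == "YES"),
                      sum(e$ocb[ref_rows] != "NE"))
    }
    data.frame(stratum = lv, n = sum(rows),
               pfs2y = 100 * s, pfs2y_lo = 100 * ci[1], pfs2y_hi = 100 * ci[2],
               response_pct = if (sum(resp_eval)) pct(n_resp, sum(resp_eval))
                              else NA_real_,
               ocb_pct = if (sum(ocb_rows)) pct(n_ocb, sum(ocb_rows))
                         else NA_real_,
               p_pfs = p_pfs, p_response = p_resp, p_ocb = p_ocb)
  }
  out <- do.call(rbind, lapply(levels, row_for))
  rownames(out) <- NULL
  class(out) <- c("outcome_table", "data.frame")
  out
}

# 2x2 chi-squared comparison of two proportions; NA when degenerate
prop_p <- function(k1, n1, k2, n2) {
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  chisq_prop(tab)$p_value
}

#' Figure-backing data exports
#'
#' * `waterfall` — best percent change in the target-lesion sum per
#'   evaluable measurable course, with its response category, ordered by
#'   descending change then course id;
#' * `swimmer` — one row per evaluable course with duration and response
#'   markers;
#' * `km_curves` — tidy per-category progression-free survival curves
#'   (time, at-risk, events, survival).
#'
#' @param cohort a `pgt_cohort`.
#' @param endpoints matching `pgt_endpoints`.
#' @param out_dir optional directory; when given, writes `waterfall.csv`,
#'   `swimmer.csv`, `km_curves.csv`.
#' @param category course category backing the waterfall/swimmer plots
#'   (default `"PGT"`); `NULL` for all. Survival curves always cover every
#'   category.
#' @return list of the three data frames, invisibly when writing.
#' @export
export_figure_data <- function(cohort, endpoints, out_dir = NULL,
                               category = "PGT") {
  a <- cohort$assessments
  co <- cohort$courses
  e_all <- endpoints[endpoints$evaluable, ]
  e <- e_all
  if (!is.null(category)) e <- e[e$category == category, ]

  meas <- e[e$baseline_state == "MEASURABLE", ]
  wf <- do.call(rbind, lapply(meas$course_id, function(id) {
    ca <- a[a$course_id == id & !is.na(a$target_sum), ]
    ca <- ca[order(ca$day), ]
    if (nrow(ca) < 2) return(NULL)
    base <- ca$target_sum[1]
    if (base <= 0) return(NULL)
    change <- 100 * (min(ca$target_sum[-1]) - base) / base
    data.frame(course_id = id, best_change_pct = change,
               category = e$best_response[e$course_id == id])
  }))
  if (is.null(wf))
    wf <- data.frame(course_id = character(), best_change_pct = numeric(),
                     category = character())
  wf <- wf[order(-wf$best_change_pct, wf$course_id), ]
  rownames(wf) <- NULL

  sw <- data.frame(course_id = e$course_id,
                   category = e$category,
                   duration_days = co$stop_day[match(e$course_id,
                                                     co$course_id)] -
                     co$start_day[match(e$course_id, co$course_id)],
                   best_response = e$best_response,
                   ocb = e$ocb,
                   pfs_days = e$pfs_days, pfs_event = e$pfs_event)
  sw <- sw[order(-sw$duration_days, sw$course_id), ]
  rownames(sw) <- NULL

  km <- do.call(rbind, lapply(split(e_all, e_all$category), function(ee) {
    if (nrow(ee) == 0 || !any(ee$pfs_event)) return(NULL)
    f <- km_fit(pmax(ee$pfs_days, 0.5), ee$pfs_event)
    cbind(category = ee$category[1], f$table)
  }))
  if (is.null(km))
    km <- data.frame(category = character(), time = numeric(),
                     n_risk = integer(), n_event = integer(),
                     n_censor = integer(), surv = numeric())
  rownames(km) <- NULL

  res <- list(waterfall = wf, swimmer = sw, km_curves = km)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res))
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
    return(invisible(res))
  }
  res
}
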