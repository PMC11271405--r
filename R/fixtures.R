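# Deterministic hand-built fixtures.
#
# "printed_counts" is a fully synthetic cohort constructed so that the
# adjudication + endpoint pipeline reproduces the published course-level
# accounting of the trial it emulates: 117 guided courses in 110 treated
# patients out of 256 with recommendations (385 enrolled), 99 evaluable
# (70 measurable: 6 CR / 19 PR / 24 SD / 21 PD; 20 non-measurable:
# 2 CR / 10 non-CR-non-PD / 8 PD; 9 disease-free at start), 97 assessable
# for clinical benefit with 53 benefits, and 31 assessable for the PFS
# ratio with 13 benefits. Every number is produced by running the pipeline,
# not asserted.

#' Registry of shipped fixtures
#'
#' * `"printed_counts"` — synthetic cohort reproducing the published
#'   course-level counts (see source header); returns a `pgt_cohort`.
#' * `"km_toy"` — five-subject survival sample with hand-computable
#'   product-limit values; returns `list(durations, events)`.
#' * `"leukemia_edge"` — blast records exercising every branch of the
#'   leukemia response rules; returns a data frame of labelled cases.
#'
#' @param name fixture name.
#' @return see above; unknown names are an error.
#' @export
make_fixture <- function(name) {
  switch(name,
         printed_counts = fixture_printed_counts(),
         km_toy = list(durations = c(1, 2, 3, 4, 5),
                       events = c(TRUE, FALSE, TRUE, FALSE, TRUE)),
         leukemia_edge = fixture_leukemia_edge(),
         abort("unknown fixture: ", name))
}

fixture_leukemia_edge <- function() {
  # one labelled case per rule branch; expected categories frozen here and
  # verified against classify_leukemia() in the test suite
  data.frame(
    label = c("cr", "pr_band", "pr_reduction", "pd_circ_rise",
              "pd_after_cr", "pd_after_pr", "sd"),
    marrow = c(3, 15, 30, 40, 12, 55, 70),
    circ = c(0, 0, 0, 130, 0, 0, 0),
    emd = FALSE,
    base_marrow = c(80, 80, 80, 40, 80, 80, 80),
    base_circ = c(0, 0, 0, 100, 0, 0, 0),
    prior_best = c(NA, NA, NA, NA, "CR", "PR", NA),
    nadir = c(NA, NA, NA, NA, 3, 20, NA),
    expected = c("CR", "PR", "PR", "PD", "PD", "PD", "SD"))
}

# ---- printed_counts construction -------------------------------------------

fixture_printed_counts <- function() {
  START <- 100L   # all index courses start on day 100; MTB on day 30
  FU <- 900L      # everyone followed to day 900, no deaths

  patients <- list(); recs <- list(); courses <- list(); assess <- list()
  pidx <- 0L; ridx <- 0L

  new_patient <- function(n_prog_days = integer()) {
    pidx <<- pidx + 1L
    pid <- sprintf("P%03d", pidx)
    patients[[pidx]] <<- data.frame(
      patient_id = pid, diagnosis_group = "SOLID", enrollment_day = 0L,
      enrollment_status = "FIRST_RELAPSE", mtb_day = 30L,
      death_day = NA_integer_, last_followup_day = FU,
      progression_days = encode_days(list(n_prog_days)))
    pid
  }
  new_rec <- function(pid, tier, abclass) {
    ridx <<- ridx + 1L
    id <- sprintf("R%03d", ridx)
    recs[[ridx]] <<- data.frame(
      recommendation_id = id, patient_id = pid, tier = tier,
      target_gene = "GENE", aberration_class = abclass,
      therapy_type = "TARGETED_MONO")
    id
  }
  add_course <- function(pid, cid, category, rec_id, start, stop, bstate,
                         n_prog, pre_mtb = FALSE) {
    courses[[length(courses) + 1]] <<- data.frame(
      course_id = cid, patient_id = pid, category = category,
      recommendation_id = rec_id, start_day = start, stop_day = stop,
      baseline_state = bstate, n_progressions_before_start = n_prog,
      modality = "RECIST", pre_mtb = pre_mtb)
  }
  add_assess <- function(cid, day, sum = NA_real_, status = NA_character_,
                         new = FALSE) {
    assess[[length(assess) + 1]] <<- data.frame(
      course_id = cid, day = as.integer(day), target_sum = sum,
      nonmeasurable_status = status, new_lesions = new,
      marrow_blast_pct = NA_real_, circulating_blast_abs = NA_real_,
      extramedullary = NA)
  }
  # prior progressed standard-of-care course: PD on day `pd_day`
  add_prior <- function(pid, cid, start, pd_day) {
    add_course(pid, cid, "SOC", NA_character_, start, pd_day, "MEASURABLE",
               1L, pre_mtb = start < 30L)
    add_assess(cid, start, sum = 100)
    add_assess(cid, pd_day, sum = 140)
  }

  cidx <- 0L
  pgt <- function(kind, tier, abclass, n_prog, with_prior = FALSE,
                  prior_pd = NA, start = START, pid = NULL) {
    cidx <<- cidx + 1L
    if (is.null(pid)) {
      pd_days <- integer()
      pid <- new_patient()
    }
    rec_id <- new_rec(pid, tier, abclass)
    cid <- sprintf("C%03d", cidx)
    if (with_prior) add_prior(pid, paste0(cid, "pre"), 0L, prior_pd)
    prog <- if (with_prior) prior_pd else integer()

    spec <- switch(kind,
      cr       = list(stop = start + 250L, base = "MEASURABLE",
                      resp = list(day = 60L, sum = 0)),
      pr       = list(stop = start + 250L, base = "MEASURABLE",
                      resp = list(day = 60L, sum = 50)),
      sd_rb    = list(stop = start + 260L, base = "MEASURABLE",
                      resp = list(day = 60L, sum = 90), pd = 250L),
      sd_yes   = list(stop = start + 250L, base = "MEASURABLE",
                      resp = list(day = 60L, sum = 90)),
      sd_no    = list(stop = start + 110L, base = "MEASURABLE",
                      resp = list(day = 45L, sum = 90), pd = 100L),
      sd_ne    = list(stop = start + 100L, base = "MEASURABLE",
                      resp = list(day = 45L, sum = 90)),
      pd       = list(stop = start + 40L, base = "MEASURABLE", pd = 35L),
      nm_cr    = list(stop = start + 250L, base = "NONMEASURABLE_EVALUABLE",
                      resp = list(day = 60L, status = "DISAPPEARED")),
      nm_sd    = list(stop = start + 250L, base = "NONMEASURABLE_EVALUABLE",
                      resp = list(day = 60L, status = "PERSISTS")),
      nm_no    = list(stop = start + 110L, base = "NONMEASURABLE_EVALUABLE",
                      resp = list(day = 45L, status = "PERSISTS"),
                      pd = 100L),
      nm_pd    = list(stop = start + 40L, base = "NONMEASURABLE_EVALUABLE",
                      pd = 35L),
      ned_yes  = list(stop = start + 250L, base = "NED"),
      ned_no   = list(stop = start + 150L, base = "NED", pd = 90L),
      ex_short = list(stop = start + 21L, base = "MEASURABLE"),
      ex_early = list(stop = start + 60L, base = "MEASURABLE", pd = 20L),
      ex_noeval = list(stop = start + 60L, base = "MEASURABLE"),
      abort("unknown kind ", kind))

    add_course(pid, cid, "PGT", rec_id, start, spec$stop, spec$base, n_prog)
    measurable <- spec$base == "MEASURABLE"
    if (spec$base != "NED")
      add_assess(cid, start,
                 sum = if (measurable) 100 else NA_real_,
                 status = if (measurable) NA_character_ else "PERSISTS")
    if (!is.null(spec$resp))
      add_assess(cid, start + spec$resp$day,
                 sum = spec$resp$sum %||% NA_real_,
                 status = spec$resp$status %||% NA_character_)
    if (!is.null(spec$pd)) {
      if (spec$base == "NED")
        add_assess(cid, start + spec$pd, new = TRUE)
      else
        add_assess(cid, start + spec$pd,
                   sum = if (measurable) 130 else NA_real_,
                   status = if (measurable) NA_character_
                            else "UNEQUIVOCAL_PROGRESSION")
      prog <- c(prog, start + spec$pd)
    }
    if (length(prog)) {
      i <- match(pid, vapply(patients, `[[`, character(1), "patient_id"))
      patients[[i]]$progression_days <<-
        encode_days(list(sort(unique(as.integer(prog)))))
    }
    pid
  }

  # ---- evaluable guided courses (99) --------------------------------------
  # measurable 70: 6 CR / 19 PR / 24 SD / 21 PD
  for (k in 1:6) pgt("cr", "T1", "FUSION_SV", 0L)
  for (k in 1:7) pgt("pr", "T1", "FUSION_SV", 0L)
  for (k in 1:6) {                      # six patients with two guided courses
    pid <- pgt("pr", "T1", "FUSION_SV", 0L)
    pgt("pr", "T1", "FUSION_SV", 0L, start = 400L, pid = pid)
  }
  for (k in 1:13) pgt("sd_rb", "T2", "SNV", 1L, with_prior = TRUE,
                      prior_pd = 50L)  # PFS 250 vs 50: ratio benefit
  for (k in 1:4) pgt("sd_yes", "T1", "SNV", 0L)
  for (k in 1:5) pgt("sd_no", "T3", "CNV", 1L)
  for (k in 1:2) pgt("sd_ne", "T1", "SNV", 0L)
  for (k in 1:18) pgt("pd", "T3", "HIGH_RNA_ONLY", 1L, with_prior = TRUE,
                      prior_pd = 100L) # PFS 35 vs 100: eligible, no benefit
  for (k in 1:3) pgt("pd", "T3", "CNV", 1L)
  # non-measurable 20: 2 CR / 10 non-CR-non-PD / 8 PD
  for (k in 1:2) pgt("nm_cr", "T1", "SNV", 0L)
  for (k in 1:6) pgt("nm_sd", "T1", "SNV", 0L)
  for (k in 1:4) pgt("nm_no", "T2", "SNV", 1L)
  for (k in 1:8) pgt("nm_pd", "T3", "CNV", 1L)
  # no evidence of disease at the start (9)
  for (k in 1:3) pgt("ned_yes", "T1", "HIGH_RNA_ONLY", 1L)
  for (k in 1:6) pgt("ned_no", "T1", "HIGH_RNA_ONLY", 1L)

  # ---- excluded guided courses (18) ---------------------------------------
  pid <- pgt("ex_short", "T3", "SNV", 1L)          # one patient, two short
  pgt("ex_short", "T3", "SNV", 1L, start = 400L, pid = pid)
  for (k in 1:12) pgt("ex_short", "T3", "SNV", 1L)
  for (k in 1:2) pgt("ex_early", "T3", "SNV", 1L)
  for (k in 1:2) pgt("ex_noeval", "T3", "SNV", 1L)

  # early-PD exclusions carry their progression day
  # (handled inside pgt(); nothing further)

  # ---- recommended-but-untreated and unrecommended patients ---------------
  stopifnot(pidx == 110L)
  while (pidx < 256L) {
    pid <- new_patient()
    new_rec(pid, "T3", "SNV")
  }
  while (pidx < 385L) new_patient()

  cohort <- as_cohort(do.call(rbind, patients), do.call(rbind, recs),
                      do.call(rbind, courses), do.call(rbind, assess))
  cohort
}
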