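course_row <- function(id = "C1", pid = "P1", category = "PGT",
                       start = 100L, stop = 300L, bstate = "MEASURABLE",
                       n_prog = 0L) {
  list(course_id = id, patient_id = pid, category = category,
       recommendation_id = if (category == "PGT") "R1" else NA_character_,
       start_day = start, stop_day = stop, baseline_state = bstate,
       n_progressions_before_start = n_prog, modality = "RECIST",
       pre_mtb = FALSE)
}

patient_row <- function(death = NA_integer_, fu = 900L) {
  list(patient_id = "P1", diagnosis_group = "SOLID", enrollment_day = 0L,
       enrollment_status = "FIRST_RELAPSE", mtb_day = 30L,
       death_day = death, last_followup_day = fu,
       progression_days = "")
}

resp <- function(id, days, cats)
  data.frame(course_id = rep(id, length(days)), day = days, category = cats)

test_that("evaluability needs 4 weeks, no early PD, and an evaluation", {
  r0 <- resp("C1", integer(), character())
  out <- is_evaluable(course_row(start = 100L, stop = 121L), r0)
  expect_false(out$evaluable); expect_equal(out$reason, "duration<4wk")

  out <- is_evaluable(course_row(), resp("C1", 120L, "PD"))
  expect_false(out$evaluable); expect_equal(out$reason, "early PD")
  # progression exactly on day 28 is not "within the first 4 weeks"
  out <- is_evaluable(course_row(), resp("C1", 128L, "PD"))
  expect_true(out$evaluable)

  out <- is_evaluable(course_row(start = 100L, stop = 160L),
                      resp("C1", 145L, "SD"))
  expect_true(out$evaluable); expect_equal(out$reason, "ok")

  out <- is_evaluable(course_row(), r0)
  expect_false(out$evaluable); expect_equal(out$reason, "no evaluation")
  # a disease-free course needs no response evaluation
  out <- is_evaluable(course_row(bstate = "NED"), r0)
  expect_true(out$evaluable)
})

test_that("PFS takes the first of progression and death, else censors", {
  cfg <- pgt_config(cutoff_day = 800L)
  co <- course_row(start = 100L)
  p_alive <- patient_row(fu = 900L)

  out <- compute_pfs(co, resp("C1", 250L, "PD"), patient_row(400L, 400L), cfg)
  expect_equal(out, list(days = 150L, event = TRUE))

  out <- compute_pfs(co, resp("C1", integer(), character()), p_alive, cfg)
  expect_equal(out, list(days = 700L, event = FALSE))  # cutoff < follow-up

  out <- compute_pfs(co, resp("C1", integer(), character()),
                     patient_row(300L, 300L), cfg)
  expect_equal(out, list(days = 200L, event = TRUE))  # death without PD

  expect_error(compute_pfs(co, resp("C1", 50L, "PD"), p_alive, cfg),
               "before course start")
})

test_that("clinical benefit branches by baseline state and the 24-week clock", {
  co <- course_row(start = 100L, stop = 360L)
  # measurable PR sustained past 168 days despite later progression
  expect_equal(compute_ocb(co, resp("C1", c(160L, 300L), c("PR", "PD")),
                           "PR"), "YES")
  # stable disease stopped early while still stable: not assessable
  co_short <- course_row(start = 100L, stop = 200L)
  expect_equal(compute_ocb(co_short, resp("C1", 145L, "SD"), "SD"), "NE")
  # stable disease progressing before 24 weeks: no benefit
  expect_equal(compute_ocb(co, resp("C1", c(145L, 200L), c("SD", "PD")),
                           "SD"), "NO")
  # disease-free at start: relapse before 24 weeks fails branch 3
  ned <- course_row(bstate = "NED", start = 100L, stop = 360L)
  expect_equal(compute_ocb(ned, resp("C1", 190L, "PD"), "NE"), "NO")
  expect_equal(compute_ocb(ned, resp("C1", integer(), character()), "NE"),
               "YES")
  # non-measurable disease control sustained
  nm <- course_row(bstate = "NONMEASURABLE_EVALUABLE", start = 100L,
                   stop = 360L)
  expect_equal(compute_ocb(nm, resp("C1", 160L, "NON_CR_NON_PD"),
                           "NON_CR_NON_PD"), "YES")
})

test_that("PFS ratio applies all five eligibility criteria and the 1.3 rule", {
  cfg <- pgt_config()
  pgt <- course_row("C2", start = 500L, stop = 720L)
  prior <- course_row("C1", category = "SOC", start = 100L, stop = 200L,
                      n_prog = 1L)
  pfs2 <- list(days = 200L, event = TRUE)
  pfs1 <- list(days = 100L, event = TRUE)

  out <- pfs_ratio(pfs2, pfs1, pgt, prior, cfg)
  expect_true(out$eligible); expect_equal(out$ratio, 2);
  expect_true(out$benefit)

  out <- pfs_ratio(list(days = 125L, event = TRUE), pfs1, pgt, prior, cfg)
  expect_true(out$eligible); expect_false(out$benefit)  # 1.25 <= 1.3

  # ratio > 1.3 but absolute gain under 4 weeks: no benefit
  out <- pfs_ratio(list(days = 40L, event = TRUE),
                   list(days = 28L, event = TRUE), pgt, prior, cfg)
  expect_true(out$eligible); expect_false(out$benefit)

  # censored index course shorter than the comparator: ineligible
  out <- pfs_ratio(list(days = 150L, event = FALSE),
                   list(days = 300L, event = TRUE), pgt, prior, cfg)
  expect_false(out$eligible)
  expect_match(out$reason, "censored")

  # censored but already longer than the comparator: eligible, ratio on
  # the censored duration
  out <- pfs_ratio(list(days = 400L, event = FALSE), pfs1, pgt, prior, cfg)
  expect_true(out$eligible); expect_equal(out$ratio, 4)

  out <- pfs_ratio(pfs2, list(days = 100L, event = FALSE), pgt, prior, cfg)
  expect_false(out$eligible)  # comparator never progressed

  prior_frontline <- course_row("C1", category = "SOC", start = 100L,
                                stop = 200L, n_prog = 0L)
  out <- pfs_ratio(pfs2, pfs1, pgt, prior_frontline, cfg)
  expect_false(out$eligible)  # comparator not for relapsed disease

  out <- pfs_ratio(pfs2, pfs1, pgt, NULL, cfg)
  expect_false(out$eligible); expect_equal(out$reason, "no comparator")

  short_prior <- course_row("C1", category = "SOC", start = 100L,
                            stop = 120L, n_prog = 1L)
  out <- pfs_ratio(pfs2, pfs1, pgt, short_prior, cfg)
  expect_false(out$eligible)  # comparator treatment under 4 weeks
})

test_that("benefit is invariant to common rescaling of both durations", {
  cfg <- pgt_config()
  pgt <- course_row("C2", start = 500L, stop = 900L)
  prior <- course_row("C1", category = "SOC", start = 100L, stop = 300L,
                      n_prog = 1L)
  set.seed(42)
  for (rep in 1:50) {
    d1 <- sample(28:300, 1); d2 <- sample(28:600, 1)
    base <- pfs_ratio(list(days = d2, event = TRUE),
                      list(days = d1, event = TRUE), pgt, prior, cfg)
    k <- stats::runif(1, 1, 4)
    scaled <- pfs_ratio(list(days = d2 * k, event = TRUE),
                        list(days = d1 * k, event = TRUE), pgt, prior, cfg)
    expect_equal(scaled$benefit, base$benefit)
  }
})

test_that("OS grouping keys on the first post-MTB treatment and partitions", {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3"), diagnosis_group = "SOLID",
    enrollment_day = 0L, enrollment_status = "DIAGNOSIS",
    mtb_day = 30L, death_day = NA_integer_, last_followup_day = 900L,
    progression_days = "")
  courses <- data.frame(
    course_id = c("A1", "A2", "B1", "B2"),
    patient_id = c("P1", "P1", "P2", "P2"),
    category = c("SOC", "PGT", "PGT", "PGT"),
    recommendation_id = c(NA, "R1", "R2", "R2"),
    start_day = c(50L, 200L, 100L, 300L), stop_day = c(150L, 400L, 250L, 500L),
    baseline_state = "MEASURABLE", n_progressions_before_start = 0L,
    modality = "RECIST", pre_mtb = FALSE)
  og <- assign_os_groups(patients, courses)
  expect_equal(og$group[og$patient_id == "P1"], "SOC")   # first, not best
  expect_equal(og$origin_day[og$patient_id == "P1"], 50L)
  expect_equal(og$group[og$patient_id == "P2"], "PGT")
  expect_equal(og$origin_day[og$patient_id == "P2"], 100L)  # first guided course
  expect_false("P3" %in% og$patient_id)                  # no post-MTB course
  expect_false(any(duplicated(og$patient_id)))           # partition
})

test_that("favorable factors count three features and are NA for leukemia", {
  rec <- list(tier = "T1", aberration_class = "FUSION_SV")
  pat <- patient_row(); pat$diagnosis_group <- "SOLID"
  expect_equal(favorable_factors(course_row(n_prog = 0L), rec, pat), 3L)
  rec2 <- list(tier = "T3", aberration_class = "SNV")
  expect_equal(favorable_factors(course_row(n_prog = 1L), rec2, pat), 0L)
  pat$diagnosis_group <- "HM"
  expect_true(is.na(favorable_factors(course_row(), rec, pat)))
})

test_that("filter conservation holds on fixture and simulated cohorts", {
  for (ch in list(make_fixture("printed_counts"),
                  simulate_cohort(sim_config(n_patients = 250, seed = 77)))) {
    ep <- derive_endpoints(ch)
    au <- audit_filters(ep, "PGT")
    expect_equal(au$n_input, au$n_evaluable + sum(au$exclusions))
    au_all <- audit_filters(ep)
    expect_equal(au_all$n_input, nrow(ch$courses))
    expect_equal(au_all$n_input, au_all$n_evaluable + sum(au_all$exclusions))
  }
})
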