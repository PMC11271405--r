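th_rano <- response_thresholds("RANO")
th_recist <- response_thresholds("RECIST")

test_that("percent-change bands match the published boundaries", {
  expect_equal(classify_target_change(100, 45, th_rano, FALSE), "PR")
  expect_equal(classify_target_change(100, 125, th_recist, FALSE), "PD")
  expect_equal(classify_target_change(100, 0, th_rano, FALSE), "CR")
  expect_equal(classify_target_change(100, 60, th_recist, TRUE), "PD")
  # boundary inclusivity: -50% RANO and +25% are in PR / PD, not SD
  expect_equal(classify_target_change(100, 50, th_rano, FALSE), "PR")
  expect_equal(classify_target_change(100, 50, th_recist, FALSE), "PR")
  expect_equal(classify_target_change(100, 70, th_recist, FALSE), "PR")
  expect_equal(classify_target_change(100, 70.5, th_recist, FALSE), "SD")
  expect_equal(classify_target_change(200, 250, th_rano, FALSE), "PD")
  expect_error(classify_target_change(0, 10, th_rano), "baseline_sum")
  # optional RECIST 1.1 progression boundary
  th11 <- response_thresholds("RECIST", "recist11")
  expect_equal(classify_target_change(100, 121, th11, FALSE), "PD")
  expect_equal(classify_target_change(100, 121, th_recist, FALSE), "SD")
  expect_equal(response_thresholds("RANO", "recist11")$pd_cut, 0.25)
})

test_that("classifier agrees with a flat truth-table oracle on both bands", {
  for (spec in list(list(th = th_rano, pr = -50), list(th = th_recist,
                                                      pr = -30))) {
    tab <- oracle_percent_table(spec$pr, 25)
    got <- vapply(tab$change, function(ch)
      classify_target_change(100, 100 + ch, spec$th, FALSE), character(1))
    expect_identical(got, tab$category)
  }
})

test_that("classify_target_change is monotone in the current sum", {
  sums <- seq(0, 300, by = 2.5)
  sev <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  for (th in list(th_rano, th_recist)) {
    cats <- vapply(sums, function(s)
      classify_target_change(100, s, th, FALSE), character(1))
    expect_true(all(diff(sev[cats]) >= 0))
  }
})

test_that("non-measurable classification has no PR and new lesions force PD", {
  expect_equal(classify_nonmeasurable("DISAPPEARED", FALSE), "CR")
  expect_equal(classify_nonmeasurable("PERSISTS", FALSE), "NON_CR_NON_PD")
  expect_equal(classify_nonmeasurable("PERSISTS", TRUE), "PD")
  expect_equal(classify_nonmeasurable("UNEQUIVOCAL_PROGRESSION", FALSE), "PD")
  expect_equal(classify_nonmeasurable("DISAPPEARED", TRUE), "PD")
  expect_error(classify_nonmeasurable(NA), "invalid")
})

test_that("leukemia rules cover every branch of the fixture", {
  fx <- make_fixture("leukemia_edge")
  for (i in seq_len(nrow(fx))) {
    got <- classify_leukemia(
      list(marrow_blast_pct = fx$marrow[i],
           circulating_blast_abs = fx$circ[i],
           extramedullary = fx$emd[i]),
      list(marrow_blast_pct = fx$base_marrow[i],
           circulating_blast_abs = fx$base_circ[i]),
      prior_best = if (is.na(fx$prior_best[i])) NULL else fx$prior_best[i],
      nadir_marrow = if (is.na(fx$nadir[i])) NULL else fx$nadir[i])
    expect_equal(got, fx$expected[i], label = fx$label[i])
  }
  expect_error(
    classify_leukemia(list(marrow_blast_pct = 101), list(marrow_blast_pct = 80)),
    "marrow_blast_pct")
})

test_that("rising marrow blasts never improve the leukemia category", {
  sev <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  grid <- seq(0, 100, by = 1)
  for (prior in list(NULL, "CR", "PR")) {
    nadir <- if (is.null(prior)) NULL else if (prior == "CR") 3 else 20
    cats <- vapply(grid, function(m)
      classify_leukemia(list(marrow_blast_pct = m, circulating_blast_abs = 0,
                             extramedullary = FALSE),
                        list(marrow_blast_pct = 80,
                             circulating_blast_abs = 0),
                        prior_best = prior, nadir_marrow = nadir),
      character(1))
    expect_true(all(diff(sev[cats]) >= 0),
                label = paste("prior", if (is.null(prior)) "none" else prior))
    expect_false(any(cats == "CR" & sev[cats] == 4))  # never CR and PD at once
  }
})

make_course_df <- function(start = 100L, stop = 300L,
                           bstate = "MEASURABLE", modality = "RECIST") {
  list(course_id = "C1", patient_id = "P1", category = "PGT",
       recommendation_id = "R1", start_day = start, stop_day = stop,
       baseline_state = bstate, n_progressions_before_start = 0L,
       modality = modality, pre_mtb = FALSE)
}

resp_df <- function(days, cats)
  data.frame(course_id = rep("C1", length(days)), day = days,
             category = cats)

test_that("best_response enforces the 6-week stable-disease rule", {
  course <- make_course_df()
  # SD achieved only before day 42 from start never counts
  expect_equal(best_response(course, resp_df(120L, "SD")), "NE")
  expect_equal(best_response(course, resp_df(c(120L, 150L), c("SD", "SD"))),
               "SD")
  expect_equal(best_response(course, resp_df(c(130L, 190L), c("PR", "PD"))),
               "PR")
  expect_equal(best_response(course, resp_df(c(120L, 160L), c("PD", "PD"))),
               "PD")
  expect_equal(best_response(course, resp_df(141L, "SD")), "NE")
  expect_equal(best_response(course, resp_df(142L, "SD")), "SD")  # inclusive
  expect_equal(best_response(course, resp_df(integer(), character())), "NE")
  # non-CR/non-PD obeys the same clock
  expect_equal(best_response(course, resp_df(120L, "NON_CR_NON_PD")), "NE")
  expect_equal(best_response(course, resp_df(160L, "NON_CR_NON_PD")),
               "NON_CR_NON_PD")
})

test_that("adjudication partitions assessments into single categories", {
  ch <- simulate_cohort(sim_config(n_patients = 150, seed = 9))
  resp <- adjudicate(ch)
  expect_true(all(resp$category %in%
                    c("CR", "PR", "SD", "NON_CR_NON_PD", "PD")))
  # one category per adjudicated post-baseline assessment
  expect_false(any(duplicated(resp[c("course_id", "day")])))
})
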