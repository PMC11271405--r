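# Synthetic cohort generator.
#
# The generator draws each course's best-response category from per-stratum
# probabilities FIRST, then constructs a lesion-sum (or blast) trajectory
# that realizes it, so the adjudication pipeline can be tested against known
# truth without stochastically inverting the classification rules. Where the
# drawn progression time cannot accommodate the drawn category (e.g. stable
# disease needs a qualifying scan at day 42 or later but progression strikes
# at day 35), the category is resolved deterministically to PD and the
# resolved value is what the generator reports as truth.

#' Simulation configuration
#'
#' Defaults encode the cohort structure of a large pediatric precision-
#' medicine trial: 385 tumors split 146/183/56 across CNS, non-CNS solid
#' and hematologic groups; molecular-tumor-board recommendation rates of
#' 0.73/0.62/0.64 by group; an uptake probability of 0.43 among recommended
#' patients; and per-covariate progression hazard ratios of 0.43 (tier-1
#' evidence), 0.42 (fusion target), 0.50 (no progression before treatment)
#' and 0.21 (non-hematologic malignancy).
#'
#' @param n_patients number of patients.
#' @param diagnosis_probs named probabilities over `CNS`, `SOLID`, `HM`.
#' @param rec_prob named per-group recommendation probabilities.
#' @param uptake_prob probability a recommended patient starts a guided
#'   course.
#' @param tier_probs named probabilities over tiers T1-T5.
#' @param aberration_probs named probabilities over aberration classes.
#' @param therapy_type_probs named probabilities over therapy types.
#' @param response_probs list of length-4 probability vectors
#'   (CR, PR, SD, PD) keyed by tier group (`T1`, `T2`, `T35`).
#' @param n_prog_probs probabilities of 0, 1, 2 progressions before the
#'   guided course.
#' @param log_hrs named log hazard ratios for covariates `tier1`, `fusion`,
#'   `no_pd`, `non_hm`.
#' @param base_hazard baseline daily progression hazard (covariates all 0).
#' @param weibull_shape shape of the event-time distribution; 1 =
#'   exponential, other values stress proportional-hazards violations over
#'   calendar rescaling.
#' @param cutoff_day administrative data-cutoff day.
#' @param post_prog_median_days median survival after progression, days.
#' @param nonpgt_prob probability that a patient without a guided course
#'   starts some other post-MTB treatment.
#' @param seed integer random seed; mandatory, no default randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    n_patients = 385L,
    diagnosis_probs = c(CNS = 146, SOLID = 183, HM = 56) / 385,
    rec_prob = c(CNS = 0.73, SOLID = 0.62, HM = 0.64),
    uptake_prob = 0.43,
    tier_probs = c(T1 = 0.20, T2 = 0.33, T3 = 0.28, T4 = 0.15, T5 = 0.04),
    aberration_probs = c(FUSION_SV = 0.16, SNV = 0.39, CNV = 0.14,
                         HIGH_RNA_ONLY = 0.24, OTHER = 0.07),
    therapy_type_probs = c(TARGETED_MONO = 0.74, TARGETED_DUAL = 0.12,
                           TARGETED_PLUS_CHEMO = 0.13, CHEMO = 0.01),
    response_probs = list(T1 = c(0.10, 0.29, 0.35, 0.26),
                          T2 = c(0.04, 0.14, 0.40, 0.42),
                          T35 = c(0.08, 0.23, 0.35, 0.34)),
    n_prog_probs = c(0.49, 0.43, 0.08),
    log_hrs = c(tier1 = log(0.43), fusion = log(0.42),
                no_pd = log(0.50), non_hm = log(0.21)),
    base_hazard = 0.0174,
    weibull_shape = 1,
    cutoff_day = 1750L,
    post_prog_median_days = 270,
    nonpgt_prob = 0.8,
    seed) {
  if (missing(seed)) abort("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  chk <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      abort("probabilities for ", what, " must be in [0,1] and sum to 1")
  }
  chk(cfg$diagnosis_probs, "diagnosis_probs")
  chk(cfg$tier_probs, "tier_probs")
  chk(cfg$aberration_probs, "aberration_probs")
  chk(cfg$therapy_type_probs, "therapy_type_probs")
  chk(cfg$n_prog_probs, "n_prog_probs")
  for (r in cfg$response_probs) chk(r, "response_probs")
  if (any(cfg$rec_prob < 0 | cfg$rec_prob > 1) ||
      cfg$uptake_prob < 0 || cfg$uptake_prob > 1)
    abort("rec_prob and uptake_prob must be in [0,1]")
  if (cfg$base_hazard <= 0 || cfg$weibull_shape <= 0)
    abort("base_hazard and weibull_shape must be positive")
  structure(cfg, class = "sim_config")
}

# derive a per-entity seed from the master seed; stays below 2^31
sub_seed <- function(seed, i, stream = 0L) {
  as.integer((as.double(seed) * 48271 + i * 1103 + stream * 7919) %% 2147483647)
}

# draw an event day (>= 1) from the configured hazard model
draw_event_day <- function(cfg, lp) {
  rate <- cfg$base_hazard * exp(lp)
  t <- if (cfg$weibull_shape == 1) stats::rexp(1, rate)
       else stats::rweibull(1, shape = cfg$weibull_shape,
                            scale = (1 / rate)^(1 / cfg$weibull_shape))
  max(1L, as.integer(round(t)))
}

# build assessment rows realizing `category` for an imaging course; returns
# list(assessments, realized, pd_day) with days relative to course start
realize_imaging <- function(category, pfs_day, window, measurable,
                            sd_min_day = 42L) {
  # a partial response cannot be determined for non-measurable disease;
  # a drawn PR is demoted to disease control before timing resolution
  if (!measurable && category == "PR") category <- "SD"
  pd_observed <- pfs_day <= window
  # progression on day 1 leaves no room for a pre-progression response scan
  if (pd_observed && pfs_day <= 1L) category <- "PD"
  # resolve impossibilities: SD needs a qualifying scan before progression
  if (category %in% c("SD", "NON_CR_NON_PD") && pd_observed &&
      pfs_day <= sd_min_day)
    category <- "PD"
  if (category == "PD" && !pd_observed) category <- "SD"
  if (category %in% c("SD", "NON_CR_NON_PD") && window <= sd_min_day)
    category <- if (pd_observed) "PD" else "NE"

  rows <- list()
  add <- function(day, sum = NA_real_, status = NA_character_, new = FALSE)
    rows[[length(rows) + 1]] <<- list(
      day = as.integer(day), target_sum = sum,
      nonmeasurable_status = status, new_lesions = new)

  if (measurable) {
    add(0, sum = 100)
    resp_sum <- switch(category, CR = 0, PR = 40, SD = 90,
                       NON_CR_NON_PD = 90, NA)
    if (category %in% c("CR", "PR")) {
      add(max(1L, min(45L, pfs_day - 1L)), sum = resp_sum)
    } else if (category %in% c("SD", "NON_CR_NON_PD")) {
      day <- if (pfs_day <= window) max(sd_min_day, min(60L, pfs_day - 1L))
             else min(60L, max(sd_min_day, window - 1L))
      add(day, sum = resp_sum)
    }
    if (category == "PD" || pd_observed)
      add(pfs_day, sum = 130, new = pfs_day %% 2 == 0)
  } else {
    add(0, status = "PERSISTS")
    resp_status <- switch(category, CR = "DISAPPEARED",
                          NON_CR_NON_PD = "PERSISTS", SD = "PERSISTS", NA)
    if (category == "SD") category <- "NON_CR_NON_PD"
    if (category %in% c("CR", "NON_CR_NON_PD")) {
      day <- if (pfs_day <= window) max(sd_min_day, min(60L, pfs_day - 1L))
             else min(60L, max(sd_min_day, window - 1L))
      if (category == "CR") day <- max(1L, min(45L, pfs_day - 1L))
      add(day, status = resp_status)
    }
    if (category == "PD" || pd_observed)
      add(pfs_day, status = "UNEQUIVOCAL_PROGRESSION")
  }
  list(assessments = data.table::rbindlist(rows), realized = category,
       pd_day = if (pd_observed) pfs_day else NA_integer_)
}

# blast-count trajectory for a leukemia course
realize_leukemia <- function(category, pfs_day, window) {
  pd_observed <- pfs_day <= window
  if (pd_observed && pfs_day <= 1L) category <- "PD"
  if (category %in% c("SD", "NON_CR_NON_PD") && pd_observed &&
      pfs_day <= 42L)
    category <- "PD"
  if (category == "PD" && !pd_observed) category <- "SD"
  if (category == "NON_CR_NON_PD") category <- "SD"
  if (category == "SD" && window <= 42L)
    category <- if (pd_observed) "PD" else "NE"
  rows <- list()
  add <- function(day, marrow, circ = 0)
    rows[[length(rows) + 1]] <<- list(
      day = as.integer(day), marrow_blast_pct = marrow,
      circulating_blast_abs = circ, extramedullary = FALSE)
  add(0, 80)
  resp_marrow <- switch(category, CR = 2, PR = 15, SD = 70, NA)
  if (category != "PD") {
    day <- if (category == "SD") {
      if (pd_observed) max(42L, min(60L, pfs_day - 1L))
      else min(60L, max(42L, window - 1L))
    } else max(1L, min(45L, pfs_day - 1L))
    add(day, resp_marrow)
  }
  if (category == "PD" || pd_observed) {
    # progression shows as reappearing circulating blasts (a bare marrow
    # rise without a prior response does not qualify as PD under the rules)
    prior_marrow <- if (category == "PD") 80 else resp_marrow
    add(pfs_day, min(100, prior_marrow + 30), circ = 2000)
  }
  list(assessments = data.table::rbindlist(rows), realized = category,
       pd_day = if (pd_observed) pfs_day else NA_integer_)
}

#' Simulate a cohort
#'
#' Generates the four cohort tables with the configured hazard and response
#' structure. Each patient consumes an independent sub-stream of the global
#' seed, so increasing `n_patients` leaves earlier patients' rows unchanged.
#'
#' The returned cohort carries a `truth` attribute: one row per course with
#' the realized best-response category the trajectory was constructed to
#' yield, the drawn progression day, and the hazard covariates — the oracle
#' for generator/adjudicator consistency checks and parameter-recovery
#' studies.
#'
#' @param config a [sim_config()].
#' @return a validated `pgt_cohort` with attribute `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  P <- vector("list", cfg$n_patients); R <- list(); CO <- list(); A <- list()
  TR <- list()
  rid <- 0L

  for (i in seq_len(cfg$n_patients)) {
    set.seed(sub_seed(cfg$seed, i))
    pid <- sprintf("P%04d", i)
    grp <- sample(DIAGNOSIS_GROUPS, 1, prob = cfg$diagnosis_probs)
    enroll <- as.integer(sample.int(1200L, 1) - 1L)
    mtb <- enroll + as.integer(sample(30:90, 1))
    status <- sample(ENROLLMENT_STATUSES, 1, prob = c(0.42, 0.48, 0.10))

    recommended <- stats::runif(1) < cfg$rec_prob[[grp]]
    rec_row <- NULL
    if (recommended) {
      rid <- rid + 1L
      rec_row <- list(
        recommendation_id = sprintf("R%04d", rid), patient_id = pid,
        tier = sample(TIERS, 1, prob = cfg$tier_probs),
        target_gene = sample(c("FGFR1", "ALK", "BRAF", "CDK4", "MTOR",
                               "VEGFA", "NTRK2", "KRAS", "ABL1", "PDGFRA"), 1),
        aberration_class = sample(ABERRATION_CLASSES, 1,
                                  prob = cfg$aberration_probs),
        therapy_type = sample(THERAPY_TYPES, 1,
                              prob = cfg$therapy_type_probs))
      R[[length(R) + 1]] <- rec_row
    }
    treated <- recommended && stats::runif(1) < cfg$uptake_prob

    prog_days <- integer()
    death_day <- NA_integer_
    courses <- list(); assess <- list()

    n_prog <- sample(0:2, 1, prob = cfg$n_prog_probs)
    start <- mtb + as.integer(sample(20:90, 1))

    # prior (pre-index) progressed treatment for patients with history
    if (n_prog >= 1) {
      p_start <- max(enroll + 5L, mtb - as.integer(sample(120:250, 1)))
      p_dur <- as.integer(sample(30:150, 1))
      p_pd <- p_start + p_dur
      if (p_pd >= start) p_pd <- start - 10L
      if (p_pd - p_start >= 28L) {
        cid <- paste0(pid, "_PRE")
        courses[[length(courses) + 1]] <- list(
          course_id = cid, patient_id = pid, category = "SOC",
          recommendation_id = NA_character_, start_day = p_start,
          stop_day = p_pd, baseline_state = "MEASURABLE",
          n_progressions_before_start = max(0L, n_prog - 1L),
          modality = if (grp == "CNS") "RANO"
                     else if (grp == "HM") "LEUKEMIA" else "RECIST",
          pre_mtb = p_start < mtb)
        if (grp == "HM") {
          assess[[length(assess) + 1]] <- list(
            course_id = rep(cid, 2), day = c(p_start, p_pd),
            target_sum = rep(NA_real_, 2),
            nonmeasurable_status = rep(NA_character_, 2),
            new_lesions = rep(FALSE, 2), marrow_blast_pct = c(60, 95),
            circulating_blast_abs = c(0, 5000),
            extramedullary = rep(FALSE, 2))
        } else {
          assess[[length(assess) + 1]] <- list(
            course_id = rep(cid, 2), day = c(p_start, p_pd),
            target_sum = c(100, 140),
            nonmeasurable_status = rep(NA_character_, 2),
            new_lesions = c(FALSE, FALSE),
            marrow_blast_pct = rep(NA_real_, 2),
            circulating_blast_abs = rep(NA_real_, 2),
            extramedullary = rep(NA, 2))
        }
        prog_days <- c(prog_days, p_pd)
      } else {
        n_prog <- 0L
      }
    }

    make_course <- function(cid, category, rec_id, tier1, fusion) {
      lp <- sum(cfg$log_hrs * c(tier1, fusion, n_prog == 0, grp != "HM"))
      pfs_day <- draw_event_day(cfg, lp)
      window <- max(2L, cfg$cutoff_day - start)
      tier_key <- if (is.null(rec_row) || category != "PGT") "T35"
                  else if (rec_row$tier == "T1") "T1"
                  else if (rec_row$tier == "T2") "T2" else "T35"
      probs <- if (category == "UGT") c(0.01, 0.02, 0.30, 0.67)
               else if (category != "PGT") c(0.03, 0.10, 0.37, 0.50)
               else cfg$response_probs[[tier_key]]
      category_drawn <- sample(c("CR", "PR", "SD", "PD"), 1, prob = probs)
      bstate <- sample(BASELINE_STATES, 1, prob = c(0.71, 0.20, 0.09))
      modality <- if (grp == "CNS") "RANO"
                  else if (grp == "HM") "LEUKEMIA"
                  else sample(c("RECIST", "PERCIST"), 1, prob = c(0.9, 0.1))
      if (grp == "HM") bstate <- "MEASURABLE"

      if (bstate == "NED") {
        pd_day <- if (pfs_day <= window) pfs_day else NA_integer_
        realized <- if (!is.na(pd_day)) "PD" else "NE"
        aa <- if (!is.na(pd_day))
          list(day = pd_day, target_sum = NA_real_,
               nonmeasurable_status = "UNEQUIVOCAL_PROGRESSION",
               new_lesions = TRUE)
        else NULL
      } else if (modality == "LEUKEMIA") {
        rl <- realize_leukemia(category_drawn, pfs_day, window)
        aa <- rl$assessments; realized <- rl$realized; pd_day <- rl$pd_day
      } else {
        rl <- realize_imaging(category_drawn, pfs_day, window,
                              bstate == "MEASURABLE")
        aa <- rl$assessments; realized <- rl$realized; pd_day <- rl$pd_day
      }
      dur_draw <- max(30L, as.integer(round(stats::rexp(1, 1 / 250))))
      stop_rel <- if (!is.na(pd_day)) pd_day else min(dur_draw, window)
      stop_day <- start + max(1L, stop_rel)

      if (!is.null(aa)) {
        nr <- length(aa$day)
        base <- list(course_id = rep(cid, nr), day = start + aa$day,
                     target_sum = rep(NA_real_, nr),
                     nonmeasurable_status = rep(NA_character_, nr),
                     new_lesions = rep(FALSE, nr),
                     marrow_blast_pct = rep(NA_real_, nr),
                     circulating_blast_abs = rep(NA_real_, nr),
                     extramedullary = rep(NA, nr))
        for (col in setdiff(intersect(names(aa), names(base)),
                            c("course_id", "day")))
          base[[col]] <- aa[[col]]
        assess[[length(assess) + 1]] <<- base
      }
      courses[[length(courses) + 1]] <<- list(
        course_id = cid, patient_id = pid, category = category,
        recommendation_id = rec_id, start_day = start, stop_day = stop_day,
        baseline_state = bstate,
        n_progressions_before_start = n_prog, modality = modality,
        pre_mtb = FALSE)
      if (!is.na(pd_day)) prog_days <<- c(prog_days, start + pd_day)
      TR[[length(TR) + 1]] <<- list(
        course_id = cid, category = category, realized = realized,
        pfs_day_drawn = pfs_day, pd_observed = !is.na(pd_day),
        tier1 = tier1, fusion = fusion, no_pd = n_prog == 0,
        non_hm = grp != "HM")
      pd_day
    }

    pd_rel <- NULL
    if (treated) {
      pd_rel <- make_course(paste0(pid, "_PGT"), "PGT",
                            rec_row$recommendation_id,
                            rec_row$tier == "T1",
                            rec_row$aberration_class == "FUSION_SV")
    } else if (stats::runif(1) < cfg$nonpgt_prob) {
      cat2 <- sample(c("SOC", "UGT", "OTHER"), 1, prob = c(0.55, 0.33, 0.12))
      pd_rel <- make_course(paste0(pid, "_NPG"), cat2, NA_character_,
                            FALSE, FALSE)
    }

    last_fu <- cfg$cutoff_day
    if (!is.null(pd_rel) && !is.na(pd_rel)) {
      post <- as.integer(round(stats::rexp(
        1, log(2) / cfg$post_prog_median_days)))
      dd <- start + pd_rel + max(1L, post)
      if (dd <= cfg$cutoff_day) { death_day <- dd; last_fu <- dd }
    }

    P[[i]] <- list(
      patient_id = pid, diagnosis_group = grp, enrollment_day = enroll,
      enrollment_status = status, mtb_day = mtb, death_day = death_day,
      last_followup_day = last_fu,
      progression_days = encode_days(list(sort(unique(prog_days)))))
    if (length(courses)) CO <- c(CO, courses)
    if (length(assess)) A <- c(A, assess)
  }

  bindrows <- function(x) as.data.frame(data.table::rbindlist(x))
  patients <- bindrows(P)
  recommendations <- if (length(R)) bindrows(R) else
    data.frame(recommendation_id = character(), patient_id = character(),
               tier = character(), target_gene = character(),
               aberration_class = character(), therapy_type = character())
  courses <- if (length(CO)) bindrows(CO) else
    data.frame(course_id = character(), patient_id = character(),
               category = character(), recommendation_id = character(),
               start_day = integer(), stop_day = integer(),
               baseline_state = character(),
               n_progressions_before_start = integer(),
               modality = character(), pre_mtb = logical())
  assessments <- if (length(A)) bindrows(A) else
    data.frame(course_id = character(), day = integer(),
               target_sum = numeric(), nonmeasurable_status = character(),
               new_lesions = logical(), marrow_blast_pct = numeric(),
               circulating_blast_abs = numeric(), extramedullary = logical())
  cohort <- as_cohort(patients, recommendations, courses, assessments)
  attr(cohort, "truth") <- bindrows(TR)
  attr(cohort, "config") <- cfg
  cohort
}

#' Write a simulated cohort with provenance
#'
#' Writes the four CSVs plus a `provenance.json` recording the configuration,
#' seed and package version.
#'
#' @param cohort a simulated `pgt_cohort`.
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_simulated <- function(cohort, dir) {
  paths <- write_cohort(cohort, dir)
  cfg <- attr(cohort, "config")
  prov <- list(config = unclass(cfg),
               package_version =
                 as.character(utils::packageVersion("pgtkit")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, provenance = file.path(dir, "provenance.json")))
}
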