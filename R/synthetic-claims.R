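#' Synthetic longitudinal claims with planted, labelled archetypes
#'
#' The generator emulates the structure of a national claims extract
#' (per-patient enrollment with demographics, dated prescriptions carrying
#' substance / days-supply / daily dose / care setting, dated ICD-10
#' diagnoses in primary or secondary position, 2002--2015) and plants one
#' treatment-change archetype and one prognosis archetype per patient, so
#' that every downstream classifier can be tested by label recovery.
#'
#' Planted gaps sit at least `margin_days` (14) away from every decision
#' threshold (60-day era gap, 120-day episode gap, end-of-window censoring
#' bounds), which makes the intended label provably unambiguous.
#'
#' @name synthetic-claims
NULL

change_archetypes <- function() c(
  "clean_discontinuation", "clean_dose_adjustment", "clean_persistent",
  "clean_reinitiation_same", "clean_reinitiation_switch", "clean_switch")

prognosis_archetypes <- function() c(
  "single_episode_remit", "remit_then_recur", "persisting")

# planted-change archetype -> category the pipeline must recover
archetype_to_category <- function(a) {
  c(clean_discontinuation = "discontinuation",
    clean_dose_adjustment = "dose_adjustment",
    clean_persistent = "persistent_use",
    clean_reinitiation_same = "reinitiation",
    clean_reinitiation_switch = "reinitiation",
    clean_switch = "switching")[a]
}

archetype_to_subtype <- function(a) {
  c(clean_reinitiation_same = "same_drug_same_dose",
    clean_reinitiation_switch = "within_class_switch")[a]
}

prognosis_to_category <- function(a) {
  c(single_episode_remit = "remittance",
    remit_then_recur = "recurrence",
    persisting = "persisting")[a]
}

# Lehmer-style stable hash of (root seed, patient index) -> per-patient seed.
# Kept below 2^31; all arithmetic stays inside double precision.
patient_stream_seed <- function(root, i) {
  s <- (as.double(root) %% 2147483647) + 1
  s <- (s * 48271) %% 2147483647
  s <- ((s + as.double(i)) * 69621) %% 2147483647
  s <- (s * 48271) %% 2147483647
  as.integer(s)
}

sample_weighted <- function(levels, weights) {
  levels[sample.int(length(levels), 1L, prob = weights)]
}

# published marginals of the study population (defaults; fully configurable)
default_demographics <- function() {
  list(
    age_bands = c("0-19" = 10, "20-29" = 28, "30-39" = 25, "40-49" = 31,
                  "50-59" = 37, "60-69" = 53, "70-79" = 68, "80+" = 20),
    female = 170 / 272,
    medical_aid = 20 / 272,
    income = stats::setNames(c(21, 20, 15, 18, 23, 17, 23, 25, 19, 36, 55),
                             0:10),
    disability = c(none = 225, mild = 32, severe = 15),
    parkinsons = 42 / 272
  )
}

# chain of 30-day refills with permissible gaps, from `from` (day, relative
# to index) until coverage reaches `until`; returns start/supply/dose rows
refill_run <- function(substance, dose, from, until, max_gap = 40L,
                       supply = 30L) {
  starts <- integer(0); supplies <- integer(0)
  cur <- from
  repeat {
    starts <- c(starts, cur)
    supplies <- c(supplies, supply)
    cur_end <- cur + supply
    if (cur_end >= until) break
    cur <- cur_end + sample.int(max_gap + 1L, 1L) - 1L # gap in 0..max_gap
  }
  data.frame(substance = substance, day = starts, days_supply = supplies,
             daily_dose = dose)
}

# prescription plan (days relative to index) for one change archetype
plan_change <- function(archetype, sub1, sub2, dose, followup, gap_days,
                        margin) {
  u <- sample.int(14L, 1L) - 1L # index-covering refill starts 0..13 days early
  s0 <- -u
  safe_gap <- gap_days - margin - 6L # in-era jitter gaps stay in 0..40
  big_gap_lo <- gap_days + margin # confirmed-gap jitter: 74..180
  switch(archetype,
    clean_persistent = {
      # stop refilling early enough that the closing supply ends exactly on
      # day `followup`, keeping every record inside the data window
      run <- refill_run(sub1, dose, s0, followup - 70L, max_gap = safe_gap)
      tail_end <- max(run$day + run$days_supply)
      if (tail_end < followup) # close out the window exactly: era end = day 730
        run <- rbind(run, data.frame(substance = sub1, day = tail_end,
                                     days_supply = followup - tail_end,
                                     daily_dose = dose))
      run
    },
    clean_discontinuation = {
      e <- 60L + sample.int(241L, 1L) - 1L # era-end target 60..300
      refill_run(sub1, dose, s0, e, max_gap = safe_gap)
    },
    clean_dose_adjustment = {
      b <- 40L + sample.int(211L, 1L) - 1L # boundary target 40..250
      run1 <- refill_run(sub1, dose, s0, b, max_gap = safe_gap)
      b_actual <- max(run1$day + run1$days_supply)
      dose2 <- if (stats::runif(1) < 0.5) dose * 2 else dose / 2
      run2 <- refill_run(sub1, dose2, b_actual,
                         b_actual + 60L + sample.int(141L, 1L) - 1L,
                         max_gap = safe_gap)
      rbind(run1, run2)
    },
    clean_switch = {
      b <- 40L + sample.int(211L, 1L) - 1L
      run1 <- refill_run(sub1, dose, s0, b, max_gap = safe_gap)
      b_actual <- max(run1$day + run1$days_supply)
      boundary_gap <- sample.int(safe_gap + 1L, 1L) - 1L # within-era gap ok
      run2 <- refill_run(sub2, dose, b_actual + boundary_gap,
                         b_actual + boundary_gap + 60L + sample.int(141L, 1L) - 1L,
                         max_gap = safe_gap)
      rbind(run1, run2)
    },
    clean_reinitiation_same = ,
    clean_reinitiation_switch = {
      e <- 60L + sample.int(191L, 1L) - 1L # first era ends 60..250 (+ refill jitter)
      run1 <- refill_run(sub1, dose, s0, e, max_gap = safe_gap)
      e_actual <- max(run1$day + run1$days_supply)
      g <- big_gap_lo + sample.int(107L, 1L) - 1L # confirmed gap 74..180
      restart <- e_actual + g
      sub_re <- if (archetype == "clean_reinitiation_same") sub1 else sub2
      run2 <- refill_run(sub_re, dose, restart,
                         restart + 60L + sample.int(91L, 1L) - 1L,
                         max_gap = safe_gap)
      rbind(run1, run2)
    },
    stop("unknown change archetype: ", archetype, call. = FALSE)
  )
}

# DIP diagnosis days (relative to index) for one prognosis archetype
plan_prognosis <- function(archetype, followup, episode_gap, margin) {
  remit_last_max <- followup - episode_gap - margin - 1L # last dx <= 595
  persist_last_min <- followup - episode_gap + margin # last dx >= 624
  small_gap <- function() 20L + sample.int(81L, 1L) - 1L # 20..100 (< 106)
  switch(archetype,
    single_episode_remit = {
      d <- 0L
      for (k in seq_len(sample.int(4L, 1L) - 1L)) {
        nxt <- d[length(d)] + small_gap()
        if (nxt > min(remit_last_max, 300L)) break
        d <- c(d, nxt)
      }
      d
    },
    remit_then_recur = {
      d <- 0L
      if (stats::runif(1) < 0.5) {
        nxt <- small_gap()
        if (nxt <= 200L) d <- c(d, nxt)
      }
      g <- episode_gap + margin + sample.int(181L, 1L) - 1L # 134..314
      r <- d[length(d)] + g
      d2 <- r
      if (stats::runif(1) < 0.5 && r + 100L < followup - 1L)
        d2 <- c(d2, r + small_gap())
      c(d, d2)
    },
    persisting = {
      d <- 0L
      while (d[length(d)] < persist_last_min)
        d <- c(d, d[length(d)] + 60L + sample.int(47L, 1L) - 1L) # gaps 60..106
      d
    },
    stop("unknown prognosis archetype: ", archetype, call. = FALSE)
  )
}

substances_of <- function(class, config) {
  names(config$offending_drugs)[config$offending_drugs == class]
}

base_doses <- c(1, 2, 2.5, 5, 10, 15, 20, 25, 50)

#' Generate a synthetic incident-DIP cohort with ground-truth labels
#'
#' Every generated patient satisfies the incident-case criteria by
#' construction: enrollment spans the whole data window, a DIP diagnosis
#' falls on the planted index date with no DIP diagnosis before it, and one
#' outpatient offending prescription covers the index date. One treatment-
#' change archetype and one prognosis archetype are planted per patient with
#' unambiguous margins (see [synthetic-claims]). Output is deterministic
#' given the seed; per-patient randomness comes from independent streams
#' hashed from (seed, patient index), so the records of patient i do not
#' depend on how many patients are generated.
#'
#' @param n_patients Number of eligible patients (>= 1).
#' @param class_mix Probabilities for (antipsychotic, gi_motility,
#'   flunarizine) at index; defaults to the study population shares
#'   (0.537, 0.415, 0.048). Must sum to 1 (tolerance 1e-9). Flunarizine is a
#'   single-member class, so archetypes that need a second substance fall
#'   back to their dose/same-drug counterparts there; the ground truth
#'   records what was actually planted.
#' @param archetype_mix Probabilities over the six treatment-change
#'   archetypes (named or in `change_archetypes()` order); default uniform.
#' @param prognosis_mix Probabilities over the three prognosis archetypes;
#'   default uniform.
#' @param seed Root seed (required).
#' @param config A [study_config()].
#' @param demographics Marginal distributions for age bands, sex, insurance,
#'   income decile and disability; defaults echo the study population.
#' @return List with `bundle` (a validated `"claims_bundle"`) and
#'   `ground_truth` (patient_id, eligible, exclusion_reason, planted_change,
#'   planted_reinit_subtype, planted_prognosis, planted_index_date,
#'   planted_class).
#' @export
generate_cohort <- function(n_patients,
                            class_mix = c(antipsychotic = 0.537,
                                          gi_motility = 0.415,
                                          flunarizine = 0.048),
                            archetype_mix = NULL,
                            prognosis_mix = NULL,
                            seed,
                            config = study_config(),
                            demographics = default_demographics()) {
  stopifnot(n_patients >= 1)
  if (missing(seed)) stop("config error: a seed is required", call. = FALSE)
  check_mix <- function(m, k, what) {
    if (length(m) != k || any(m < 0) || abs(sum(m) - 1) > 1e-9)
      stop("config error: ", what, " must be ", k,
           " nonnegative probabilities summing to 1", call. = FALSE)
    m
  }
  class_mix <- check_mix(class_mix, 3L, "class_mix")
  if (is.null(archetype_mix))
    archetype_mix <- rep(1 / 6, 6)
  archetype_mix <- check_mix(archetype_mix, 6L, "archetype_mix")
  if (is.null(prognosis_mix))
    prognosis_mix <- rep(1 / 3, 3)
  prognosis_mix <- check_mix(prognosis_mix, 3L, "prognosis_mix")

  accrual_days <- as.integer(config$accrual_end - config$accrual_start) + 1L
  patients <- lapply(seq_len(n_patients), function(i) {
    set.seed(patient_stream_seed(seed, i))
    pid <- sprintf("P%06d", i)

    change <- sample_weighted(change_archetypes(), archetype_mix)
    prog <- sample_weighted(prognosis_archetypes(), prognosis_mix)
    cls <- sample_weighted(offending_classes(), class_mix)
    # flunarizine is a single-member class: a planted within-class substance
    # switch is impossible there, so fall back to the nearest feasible
    # archetype; the planted class (and hence the class mix) is preserved
    # and the ground truth records the archetype actually planted
    if (cls == "flunarizine") {
      if (change == "clean_switch") change <- "clean_dose_adjustment"
      if (change == "clean_reinitiation_switch") change <- "clean_reinitiation_same"
    }
    subs <- substances_of(cls, config)
    sub1 <- sample(subs, 1L)
    sub2 <- if (length(subs) > 1L) sample(setdiff(subs, sub1), 1L) else sub1
    dose <- sample(base_doses, 1L)

    index_date <- config$accrual_start + sample.int(accrual_days, 1L) - 1L

    margin <- 14L
    rx_plan <- plan_change(change, sub1, sub2, dose, config$followup_days,
                           config$era_gap_days, margin)
    dx_days <- plan_prognosis(prog, config$followup_days,
                              config$dip_episode_gap_days, margin)

    rx <- tibble::new_tibble(list(
      patient_id = rep(pid, nrow(rx_plan)),
      substance = rx_plan$substance,
      start_date = index_date + rx_plan$day,
      days_supply = as.integer(rx_plan$days_supply),
      daily_dose = rx_plan$daily_dose,
      setting = rep("outpatient", nrow(rx_plan))
    ), nrow = nrow(rx_plan))
    dx <- tibble::new_tibble(list(
      patient_id = rep(pid, length(dx_days)),
      icd10 = sample(config$dip_codes, length(dx_days), replace = TRUE),
      date = index_date + dx_days,
      position = sample(c("primary", "secondary"), length(dx_days),
                        replace = TRUE, prob = c(0.8, 0.2))
    ), nrow = length(dx_days))
    if (stats::runif(1) < demographics$parkinsons) {
      # pre-existing Parkinson's disease inside the baseline lookback
      dx <- dplyr::bind_rows(dx, tibble::new_tibble(list(
        patient_id = pid, icd10 = "G20",
        date = index_date - (sample.int(config$pd_lookback_days + 1L, 1L) - 1L),
        position = sample(c("primary", "secondary"), 1L)), nrow = 1L))
    }

    band <- sample_weighted(names(demographics$age_bands),
                            demographics$age_bands)
    lohi <- switch(band, "0-19" = c(5L, 19L), "80+" = c(80L, 89L),
                   as.integer(strsplit(band, "-")[[1]]))
    age <- lohi[1] + sample.int(lohi[2] - lohi[1] + 1L, 1L) - 1L
    en <- tibble::new_tibble(nrow = 1L, list(
      patient_id = pid,
      observation_start = config$data_start,
      observation_end = config$data_end,
      birth_year = as.integer(format(index_date, "%Y")) - age,
      sex = if (stats::runif(1) < demographics$female) "female" else "male",
      insurance = if (stats::runif(1) < demographics$medical_aid)
        "medical_aid" else "national_health_insurance",
      income_decile = as.integer(sample_weighted(names(demographics$income),
                                                 demographics$income)),
      disability = sample_weighted(names(demographics$disability),
                                   demographics$disability)
    ))
    truth <- tibble::new_tibble(nrow = 1L, list(
      patient_id = pid,
      eligible = TRUE,
      exclusion_reason = NA_character_,
      planted_change = unname(archetype_to_category(change)),
      planted_reinit_subtype = unname(archetype_to_subtype(change)),
      planted_prognosis = unname(prognosis_to_category(prog)),
      planted_index_date = index_date,
      planted_class = cls
    ))
    list(rx = rx, dx = dx, en = en, truth = truth)
  })

  bundle <- validate_claims(
    dplyr::bind_rows(lapply(patients, `[[`, "rx")),
    dplyr::bind_rows(lapply(patients, `[[`, "dx")),
    dplyr::bind_rows(lapply(patients, `[[`, "en"))
  )
  list(bundle = bundle,
       ground_truth = dplyr::bind_rows(lapply(patients, `[[`, "truth")))
}

#' Add decoy records and ineligible decoy patients to a synthetic cohort
#'
#' Decoys exercise the parts of the pipeline that must ignore or exclude
#' records: non-offending prescriptions (nizatidine, an H2-receptor
#' antagonist sometimes substituted for GI motility drugs), unrelated and
#' comorbidity diagnoses (which vary the Charlson index), prevalent-DIP
#' patients whose prior diagnosis inside the washout window must exclude
#' them, and patients whose offending supply ends before the index date
#' (no-overlap exclusions). Decoys never touch eligible patients' planted
#' labels: added codes avoid the DIP and Parkinson's prefixes and added
#' drugs are off the offending lists.
#'
#' @param sim Result of [generate_cohort()].
#' @param seed Seed for the decoy stream.
#' @param config A [study_config()].
#' @param frac_extra_rx,frac_comorbid,frac_unrelated Per-eligible-patient
#'   probabilities of each record decoy.
#' @param n_prevalent,n_no_overlap Counts of ineligible decoy patients
#'   (defaults scale with cohort size).
#' @return A list like `sim` with augmented `bundle` and `ground_truth`.
#' @export
generate_decoys <- function(sim, seed, config = study_config(),
                            frac_extra_rx = 0.3, frac_comorbid = 0.4,
                            frac_unrelated = 0.3,
                            n_prevalent = NULL, n_no_overlap = NULL) {
  truth <- sim$ground_truth
  n_elig <- sum(truth$eligible)
  if (is.null(n_prevalent)) n_prevalent <- max(1L, round(0.05 * n_elig))
  if (is.null(n_no_overlap)) n_no_overlap <- max(1L, round(0.05 * n_elig))

  comorbid_pool <- c("I21", "I509", "J449", "E119", "E112", "C34",
                     "C771", "K254", "F00", "N18", "B18", "K74", "M05",
                     "G819", "I639")
  unrelated_pool <- c("K297", "J069", "M545", "R51", "A09")

  rx_add <- list(); dx_add <- list(); en_add <- list(); truth_add <- list()
  elig <- truth[truth$eligible, ]
  for (i in seq_len(nrow(elig))) {
    set.seed(patient_stream_seed(seed, i))
    pid <- elig$patient_id[i]
    idx <- elig$planted_index_date[i]
    if (stats::runif(1) < frac_extra_rx) {
      rx_add[[length(rx_add) + 1L]] <- tibble::tibble(
        patient_id = pid, substance = "nizatidine",
        start_date = idx + sample.int(601L, 1L) - 201L,
        days_supply = 30L, daily_dose = 300,
        setting = sample(c("outpatient", "inpatient"), 1L))
    }
    if (stats::runif(1) < frac_comorbid) {
      dx_add[[length(dx_add) + 1L]] <- tibble::tibble(
        patient_id = pid, icd10 = sample(comorbid_pool, 1L),
        date = idx - sample.int(config$cci_lookback_days, 1L),
        position = "secondary")
    }
    if (stats::runif(1) < frac_unrelated) {
      dx_add[[length(dx_add) + 1L]] <- tibble::tibble(
        patient_id = pid, icd10 = sample(unrelated_pool, 1L),
        date = idx + sample.int(600L, 1L) - 300L,
        position = "secondary")
    }
  }

  # ineligible decoy patients
  decoy_patient <- function(j, kind) {
    set.seed(patient_stream_seed(seed + 1L, j))
    pid <- sprintf("D%06d", j)
    if (kind == "washout") {
      # index early in accrual so the prior diagnosis predates the accrual
      # window (it cannot itself become the index) yet sits in the washout
      idx <- config$accrual_start + sample.int(299L, 1L) - 1L
      dxd <- c(idx - 300L, idx)
      rx_start <- idx - (sample.int(14L, 1L) - 1L)
      rx_supply <- 30L
      reason <- "washout"
    } else {
      idx <- config$accrual_start + sample.int(3000L, 1L) - 1L
      dxd <- idx
      rx_start <- idx - 60L # supply ends 30 days before index: no overlap
      rx_supply <- 30L
      reason <- "no_overlapping_prescription"
    }
    cls <- sample(offending_classes(), 1L)
    sub <- sample(substances_of(cls, config), 1L)
    list(
      rx = tibble::tibble(patient_id = pid, substance = sub,
                          start_date = rx_start, days_supply = rx_supply,
                          daily_dose = 10, setting = "outpatient"),
      dx = tibble::tibble(patient_id = pid,
                          icd10 = sample(config$dip_codes, length(dxd),
                                         replace = TRUE),
                          date = dxd, position = "primary"),
      en = tibble::tibble(patient_id = pid,
                          observation_start = config$data_start,
                          observation_end = config$data_end,
                          birth_year = 1950L, sex = "female",
                          insurance = "national_health_insurance",
                          income_decile = 5L, disability = "none"),
      truth = tibble::tibble(patient_id = pid, eligible = FALSE,
                             exclusion_reason = reason,
                             planted_change = NA_character_,
                             planted_reinit_subtype = NA_character_,
                             planted_prognosis = NA_character_,
                             planted_index_date = idx,
                             planted_class = NA_character_)
    )
  }
  decoys <- c(lapply(seq_len(n_prevalent), decoy_patient, kind = "washout"),
              lapply(n_prevalent + seq_len(n_no_overlap), decoy_patient,
                     kind = "no_overlap"))

  bundle <- validate_claims(
    dplyr::bind_rows(c(list(sim$bundle$prescriptions), rx_add,
                       lapply(decoys, `[[`, "rx"))),
    dplyr::bind_rows(c(list(sim$bundle$diagnoses), dx_add,
                       lapply(decoys, `[[`, "dx"))),
    dplyr::bind_rows(c(list(sim$bundle$enrollment),
                       lapply(decoys, `[[`, "en")))
  )
  list(bundle = bundle,
       ground_truth = dplyr::bind_rows(c(list(truth),
                                         lapply(decoys, `[[`, "truth"))))
}

#' Simulate a claims directory on disk
#'
#' Convenience wrapper: generates a cohort (plus decoys), and writes
#' `prescriptions.csv`, `diagnoses.csv`, `enrollment.csv`,
#' `ground_truth.csv` to `dir`.
#'
#' @param n Number of eligible patients.
#' @param seed Root seed.
#' @param dir Output directory.
#' @param config A [study_config()].
#' @param decoys Add decoy records/patients (default TRUE).
#' @param ... Passed to [generate_cohort()].
#' @return Invisibly, the simulation list.
#' @export
simulate_claims <- function(n, seed, dir, config = study_config(),
                            decoys = TRUE, ...) {
  sim <- generate_cohort(n, seed = seed, config = config, ...)
  if (decoys) sim <- generate_decoys(sim, seed = seed + 1L, config = config)
  write_claims(sim$bundle, dir)
  write_csv_plain(sim$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(sim)
}
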