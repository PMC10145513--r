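cfg <- study_config()

classify_rx <- function(rx, index_date = ANCHOR, config = cfg) {
  eras <- build_drug_eras(rx, config)
  classify_first_change(detect_boundary_events(eras, index_date, config),
                        index_date, config)
}

test_that("boundary scanning finds switches, dose changes, gaps and restarts in order", {
  # within-class substitution across consecutive prescriptions: switching
  rx <- dplyr::bind_rows(
    rx_tbl(0, 30, substance = "metoclopramide", dose = 10),
    rx_tbl(30, 30, substance = "domperidone", dose = 30))
  ev <- detect_boundary_events(build_drug_eras(rx, cfg), ANCHOR, cfg)
  expect_identical(ev$type[1], "SWITCH")
  expect_identical(ev$date[1], ANCHOR + 30)

  # same substance, dose doubled: DOSE
  rx <- dplyr::bind_rows(rx_tbl(0, 30, dose = 5), rx_tbl(30, 30, dose = 10))
  ev <- detect_boundary_events(build_drug_eras(rx, cfg), ANCHOR, cfg)
  expect_identical(ev$type[1], "DOSE")
  expect_identical(ev$date[1], ANCHOR + 30)

  # era ends, nothing after: GAP_START at the first uncovered day
  ev <- detect_boundary_events(build_drug_eras(rx_tbl(0, 30), cfg), ANCHOR, cfg)
  expect_identical(ev$type, "GAP_START")
  expect_identical(ev$date, ANCHOR + 30)

  expect_error(detect_boundary_events(build_drug_eras(rx_tbl(5, 10), cfg),
                                      ANCHOR, cfg), "contract violation")
})

test_that("first-change classification reproduces the five mutually exclusive categories", {
  # permanent discontinuation: era ends day 30, no further in-class supply
  out <- classify_rx(rx_tbl(0, 30))
  expect_identical(out$category, "discontinuation")
  expect_identical(out$days_from_index, 30L)
  expect_identical(out$disc_date, ANCHOR + 30)

  # reinitiation by within-class switch after a confirmed gap
  rx <- dplyr::bind_rows(
    rx_tbl(0, 30, substance = "metoclopramide", dose = 10),
    rx_tbl(100, 30, substance = "mosapride", dose = 15))
  out <- classify_rx(rx)
  expect_identical(out$category, "reinitiation")
  expect_identical(out$reinit_subtype, "within_class_switch")
  expect_identical(out$days_from_index, 100L)
  expect_identical(out$disc_date, ANCHOR + 30) # the gap start

  # monthly same-dose refills across the whole window: persistent use
  out <- classify_rx(rx_tbl(seq(0, 720, by = 30), 30))
  expect_identical(out$category, "persistent_use")
  expect_true(is.na(out$event_date))

  # switching and dose adjustment date at the new prescription's start
  rx <- dplyr::bind_rows(rx_tbl(0, 30, dose = 5), rx_tbl(30, 30, dose = 2.5))
  out <- classify_rx(rx)
  expect_identical(out$category, "dose_adjustment")
  expect_identical(out$days_from_index, 30L)

  # augmentation (second in-class substance added while the first continues)
  # changes the regimen composition: switching
  rx <- dplyr::bind_rows(rx_tbl(0, 80, substance = "haloperidol"),
                         rx_tbl(40, 30, substance = "risperidone", dose = 2))
  out <- classify_rx(rx)
  expect_identical(out$category, "switching")
  expect_identical(out$days_from_index, 40L)

  # resuming the same drug at the same dose after a permissible (<= 60 day)
  # gap is continued use, not a change
  rx <- dplyr::bind_rows(rx_tbl(0, 30), rx_tbl(80, 30), rx_tbl(160, 600))
  out <- classify_rx(rx)
  expect_identical(out$category, "persistent_use")
})

test_that("an unconfirmable trailing gap is censored into persistent use", {
  # era ends day 690: 40 days of window left, a >60-day gap cannot be seen
  out <- classify_rx(rx_tbl(seq(0, 660, by = 30), 30))
  expect_identical(out$category, "persistent_use")
  # era ends day 660: 70 remaining days confirm the gap
  out <- classify_rx(rx_tbl(seq(0, 630, by = 30), 30))
  expect_identical(out$category, "discontinuation")
  expect_identical(out$days_from_index, 660L)
})

test_that("reinitiation subtypes compare the regimens around the gap", {
  expect_identical(reinitiation_subtype(c(metoclopramide = 10), c(mosapride = 15)),
                   "within_class_switch")
  expect_identical(reinitiation_subtype(c(haloperidol = 5), c(haloperidol = 2.5)),
                   "same_drug_dose_adjusted")
  expect_identical(reinitiation_subtype(c(haloperidol = 5), c(haloperidol = 5)),
                   "same_drug_same_dose")
  expect_error(reinitiation_subtype(stats::setNames(numeric(0), character(0)),
                                    c(haloperidol = 5)), "contract violation")
})

test_that("classification equals the day-grid state-machine oracle on random streams", {
  set.seed(1207)
  n_checked <- 0L
  for (rep in 1:200) {
    rx <- random_rx_stream(class = sample(c("gi_motility", "antipsychotic"), 1))
    out <- classify_rx(rx)
    orc <- oracle_change(rx, ANCHOR, cfg$followup_days, cfg$era_gap_days,
                         cfg$dose_tolerance)
    expect_identical(out$category, orc$category)
    if (orc$category == "reinitiation")
      expect_identical(out$reinit_subtype, orc$subtype)
    if (!is.na(orc$day) && orc$category != "persistent_use")
      expect_identical(out$days_from_index, as.integer(orc$day))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 200L)
})

test_that("every cohort patient gets exactly one category and sane event dates", {
  sim <- generate_cohort(300, seed = 88L)
  res <- run_dip_pipeline(sim$bundle)
  expect_identical(sort(res$changes$patient_id), sort(res$cohort$patient_id))
  expect_true(all(res$changes$category %in%
                    c("discontinuation", "dose_adjustment", "persistent_use",
                      "reinitiation", "switching")))
  expect_identical(is.na(res$changes$event_date),
                   res$changes$category == "persistent_use")
  expect_identical(!is.na(res$changes$reinit_subtype),
                   res$changes$category == "reinitiation")
  d <- res$changes$days_from_index
  expect_true(all(is.na(d) | (d >= 0L & d < cfg$followup_days)))
  expect_equal(sum(res$tables$patterns$pct), 100, tolerance = 0.1 / 100)
})
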