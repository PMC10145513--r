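cfg <- study_config()

test_that("the three incident-case criteria decide inclusion and the index date", {
  # qualifying case: dx 2004-03-01, covering outpatient supply, no history
  rx <- rx_tbl(0, 14, substance = "metoclopramide", dose = 10,
               anchor = as.Date("2004-02-20"))
  dx <- dx_tbl(0, anchor = as.Date("2004-03-01"))
  sel <- select_incident_cases(mk_bundle(rx, dx), cfg)
  expect_identical(nrow(sel$cohort), 1L)
  expect_identical(sel$cohort$index_date, as.Date("2004-03-01"))
  expect_identical(sel$cohort$index_class, "gi_motility")

  # same patient with a DIP code 410 days earlier: washout exclusion
  dx2 <- dplyr::bind_rows(dx, dx_tbl(0, icd10 = "G251",
                                     anchor = as.Date("2003-01-15")))
  sel2 <- select_incident_cases(mk_bundle(rx, dx2), cfg)
  expect_identical(nrow(sel2$cohort), 0L)
  expect_identical(sel2$exclusions$reason, "washout")

  # supply ends before the diagnosis: no overlap
  rx3 <- rx_tbl(0, 14, substance = "metoclopramide",
                anchor = as.Date("2004-02-01")) # ends 2004-02-15
  sel3 <- select_incident_cases(mk_bundle(rx3, dx), cfg)
  expect_identical(sel3$exclusions$reason, "no_overlapping_prescription")

  # a DIP code on the index date itself is the index event, not an exclusion
  dx4 <- dplyr::bind_rows(dx, dx_tbl(0, icd10 = "G2110", position = "secondary",
                                     anchor = as.Date("2004-03-01")))
  sel4 <- select_incident_cases(mk_bundle(rx, dx4), cfg)
  expect_identical(nrow(sel4$cohort), 1L)
})

test_that("inclusion flags agree with a brute-force eligibility check on random synthetic patients", {
  sim <- generate_decoys(generate_cohort(200, seed = 31L), seed = 32L)
  sel <- select_incident_cases(sim$bundle, cfg)
  oracle <- oracle_eligibility(sim$bundle, cfg)
  expect_setequal(sel$cohort$patient_id, names(oracle)[oracle])
  # and the included set is exactly the generator's eligible set
  expect_setequal(sel$cohort$patient_id,
                  sim$ground_truth$patient_id[sim$ground_truth$eligible])
})

test_that("cohort selection is invariant to input row order and date translation", {
  sim <- generate_decoys(generate_cohort(60, seed = 77L), seed = 78L)
  b <- sim$bundle
  sel <- select_incident_cases(b, cfg)

  perm <- function(df) df[sample.int(nrow(df)), , drop = FALSE]
  set.seed(1)
  b2 <- validate_claims(perm(b$prescriptions), perm(b$diagnoses),
                        perm(b$enrollment))
  sel2 <- select_incident_cases(b2, cfg)
  expect_equal(sel2$cohort, sel$cohort)
  expect_equal(sel2$exclusions, sel$exclusions)

  k <- 40L # shift all dates and windows by k days
  shift <- function(df, cols) { for (col in cols) df[[col]] <- df[[col]] + k; df }
  b3 <- validate_claims(shift(b$prescriptions, "start_date"),
                        shift(b$diagnoses, "date"),
                        shift(b$enrollment, c("observation_start", "observation_end")))
  cfg3 <- study_config(accrual_start = cfg$accrual_start + k,
                       accrual_end = cfg$accrual_end + k,
                       data_start = cfg$data_start + k,
                       data_end = cfg$data_end + k)
  sel3 <- select_incident_cases(b3, cfg3)
  expect_equal(sel3$cohort$index_date, sel$cohort$index_date + k)
  # age is anchored to the calendar year of the index date, so a shift that
  # crosses a year boundary may move it; everything else is unchanged
  drop_age <- function(df) df[setdiff(names(df), c("age", "age_band"))]
  shifted <- sel3$cohort; shifted$index_date <- shifted$index_date - k
  expect_equal(drop_age(shifted), drop_age(sel$cohort))
})

test_that("multi-class coverage at index resolves by antipsychotic > gi_motility > flunarizine", {
  halo <- rx_tbl(-5, 30, substance = "haloperidol")
  levo <- rx_tbl(-3, 30, substance = "levosulpiride")
  flun <- rx_tbl(-2, 30, substance = "flunarizine")
  domp <- rx_tbl(-1, 30, substance = "domperidone")

  both <- dplyr::bind_rows(halo, levo)
  cls <- assign_index_class(both, ANCHOR, cfg)
  expect_identical(as.character(cls), "antipsychotic")
  expect_true(attr(cls, "tie"))

  expect_identical(as.character(assign_index_class(domp, ANCHOR, cfg)),
                   "gi_motility")
  expect_identical(as.character(assign_index_class(flun, ANCHOR, cfg)),
                   "flunarizine")
  expect_identical(
    as.character(assign_index_class(dplyr::bind_rows(levo, flun), ANCHOR, cfg)),
    "gi_motility")
  # inpatient-only or non-covering supply violates the caller contract
  expect_error(assign_index_class(rx_tbl(-40, 30), ANCHOR, cfg),
               "contract violation")
  expect_error(assign_index_class(rx_tbl(-5, 30, setting = "inpatient"),
                                  ANCHOR, cfg), "contract violation")
})

test_that("Charlson index applies Quan ICD-10 mappings, weights and hierarchies", {
  expect_identical(charlson_index(dx_tbl(integer(0)), ANCHOR, 365L), 0L)
  # myocardial infarction (1) + metastatic disease (6)
  dx <- dplyr::bind_rows(dx_tbl(-100, icd10 = "I21"),
                         dx_tbl(-30, icd10 = "C771"))
  expect_identical(charlson_index(dx, ANCHOR, 365L), 7L)
  # complicated diabetes supersedes uncomplicated: 2, not 3
  dx <- dplyr::bind_rows(dx_tbl(-10, icd10 = "E119"),
                         dx_tbl(-20, icd10 = "E112"))
  expect_identical(charlson_index(dx, ANCHOR, 365L), 2L)
  # severe liver supersedes mild liver
  dx <- dplyr::bind_rows(dx_tbl(-10, icd10 = "B18"),
                         dx_tbl(-20, icd10 = "K704"))
  expect_identical(charlson_index(dx, ANCHOR, 365L), 3L)
  # metastatic supersedes localized malignancy
  dx <- dplyr::bind_rows(dx_tbl(-10, icd10 = "C34"),
                         dx_tbl(-20, icd10 = "C78"))
  expect_identical(charlson_index(dx, ANCHOR, 365L), 6L)
  # one category counts once, sub-codes match by prefix
  dx <- dplyr::bind_rows(dx_tbl(-10, icd10 = "I21"),
                         dx_tbl(-40, icd10 = "I219"),
                         dx_tbl(-50, icd10 = "I252"))
  expect_identical(charlson_index(dx, ANCHOR, 365L), 1L)
  # window: [index - lookback, index - 1]; index-day and older codes ignored
  expect_identical(charlson_index(dx_tbl(0, icd10 = "I21"), ANCHOR, 365L), 0L)
  expect_identical(charlson_index(dx_tbl(-365, icd10 = "I21"), ANCHOR, 365L), 1L)
  expect_identical(charlson_index(dx_tbl(-366, icd10 = "I21"), ANCHOR, 365L), 0L)
  expect_error(charlson_index(dx, ANCHOR, -1), "lookback")
})

test_that("Parkinson's flag matches the G20 prefix within its lookback, index day included", {
  expect_true(pd_flag(dx_tbl(-400, icd10 = "G20"), ANCHOR, 730L))
  expect_false(pd_flag(dx_tbl(-800, icd10 = "G20"), ANCHOR, 730L))
  expect_false(pd_flag(dx_tbl(-400, icd10 = "G21"), ANCHOR, 730L))
  expect_true(pd_flag(dx_tbl(0, icd10 = "G209"), ANCHOR, 730L))
})
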