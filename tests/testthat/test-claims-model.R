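test_that("ICD-10 normalization uppercases, strips the dot, and is idempotent", {
  expect_identical(normalize_icd10("g21.1"), "G211")
  expect_identical(normalize_icd10("G25.1"), "G251")
  expect_identical(normalize_icd10("G20"), "G20")
  codes <- c("a00", "B99.9", " c341 ", "G2110")
  expect_identical(normalize_icd10(normalize_icd10(codes)),
                   normalize_icd10(codes))
  expect_error(normalize_icd10(""), "empty")
  expect_error(normalize_icd10("21A"), "malformed")
})

test_that("offending-drug classification uses the three disjoint class lists", {
  cfg <- study_config()
  expect_identical(classify_drug("levosulpiride", cfg), "gi_motility")
  expect_identical(classify_drug("haloperidol", cfg), "antipsychotic")
  expect_identical(classify_drug("flunarizine", cfg), "flunarizine")
  expect_true(is.na(classify_drug("nizatidine", cfg)))
  drugs <- default_offending_drugs()
  expect_length(drugs[drugs == "antipsychotic"], 13L)
  expect_length(drugs[drugs == "gi_motility"], 6L)
  expect_length(drugs[drugs == "flunarizine"], 1L)
  expect_error(
    study_config(offending_drugs = stats::setNames(
      c("antipsychotic", "gi_motility"), c("sulpiride", "sulpiride"))),
    "disjoint")
})

test_that("config validation rejects degenerate windows and empty code sets", {
  expect_error(study_config(era_gap_days = 0), "positive")
  expect_error(study_config(washout_days = -1), "positive")
  expect_error(study_config(dip_codes = character(0)), "nonempty")
})

test_that("a YAML study-config round-trips, including class -> drug mappings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "era_gap_days: 30",
    "dip_episode_gap_days: 90",
    "accrual_start: 2005-01-01",
    "offending_drugs:",
    "  antipsychotic: [haloperidol, risperidone]",
    "  gi_motility: [metoclopramide]"
  ), path)
  cfg <- read_study_config(path)
  expect_identical(cfg$era_gap_days, 30L)
  expect_identical(cfg$dip_episode_gap_days, 90L)
  expect_identical(cfg$accrual_start, as.Date("2005-01-01"))
  expect_identical(classify_drug("risperidone", cfg), "antipsychotic")
  expect_identical(cfg$followup_days, 730L) # untouched default
})

write_fixture <- function(lines) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

good_rx_lines <- c(
  "patient_id,substance,start_date,days_supply,daily_dose,setting",
  "P1,Metoclopramide,2005-03-01,14,10,outpatient",
  "P1,metoclopramide,2005-04-01,30,10,outpatient",
  "P2,haloperidol,2006-01-10,30,5,inpatient")
good_dx_lines <- c(
  "patient_id,icd10,date,position",
  "P1,G21.1,2005-03-05,primary",
  "P2,g25.1,2006-01-15,secondary")
good_en_lines <- c(
  paste0("patient_id,observation_start,observation_end,birth_year,sex,",
         "insurance,income_decile,disability"),
  "P1,2002-01-01,2015-12-31,1940,female,national_health_insurance,3,none",
  "P2,2002-01-01,2015-12-31,1975,male,medical_aid,10,mild")

test_that("reading a well-formed fixture yields normalized records with half-open supply intervals", {
  b <- read_claims(write_fixture(good_rx_lines), write_fixture(good_dx_lines),
                   write_fixture(good_en_lines))
  expect_s3_class(b$prescriptions, "tbl_df")
  expect_identical(nrow(b$prescriptions), 3L)
  expect_identical(b$prescriptions$substance[1], "metoclopramide")
  expect_identical(b$diagnoses$icd10, c("G211", "G251"))
  rx1 <- b$prescriptions[1, ]
  expect_true(covers_date(rx1, as.Date("2005-03-01")))
  expect_true(covers_date(rx1, as.Date("2005-03-14")))
  expect_false(covers_date(rx1, as.Date("2005-03-15"))) # exclusive end
  expect_identical(supply_end(rx1), as.Date("2005-03-15"))
})

test_that("schema and row-level violations fail with located messages", {
  bad_supply <- good_rx_lines
  bad_supply[2] <- "P1,metoclopramide,2005-03-01,0,10,outpatient"
  expect_error(
    read_claims(write_fixture(bad_supply), write_fixture(good_dx_lines),
                write_fixture(good_en_lines)),
    "row.*1.*days_supply")
  no_dose <- c("patient_id,substance,start_date,days_supply,setting",
               "P1,metoclopramide,2005-03-01,14,outpatient")
  expect_error(
    read_claims(write_fixture(no_dose), write_fixture(good_dx_lines),
                write_fixture(good_en_lines)),
    "missing column.*daily_dose")
  bad_setting <- good_rx_lines
  bad_setting[4] <- "P2,haloperidol,2006-01-10,30,5,er"
  expect_error(
    read_claims(write_fixture(bad_setting), write_fixture(good_dx_lines),
                write_fixture(good_en_lines)),
    "unknown setting.*er")
  bad_date <- good_rx_lines
  bad_date[3] <- "P1,metoclopramide,04/01/2005,30,10,outpatient"
  expect_error(
    read_claims(write_fixture(bad_date), write_fixture(good_dx_lines),
                write_fixture(good_en_lines)),
    "row.*2.*unparseable date")
  expect_error(
    read_claims("/nonexistent/rx.csv", write_fixture(good_dx_lines),
                write_fixture(good_en_lines)),
    "not found")
})

test_that("write_claims then read_claims reproduces random synthetic bundles exactly", {
  for (seed in c(101L, 202L)) {
    sim <- generate_cohort(25, seed = seed)
    dir <- withr::local_tempdir()
    write_claims(sim$bundle, dir)
    back <- read_claims(file.path(dir, "prescriptions.csv"),
                        file.path(dir, "diagnoses.csv"),
                        file.path(dir, "enrollment.csv"))
    expect_equal(back$prescriptions, sim$bundle$prescriptions)
    expect_equal(back$diagnoses, sim$bundle$diagnoses)
    expect_equal(back$enrollment, sim$bundle$enrollment)
  }
})
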