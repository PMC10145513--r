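# Shared helpers for the numbered analysis scripts: fixed paths, the study
# seed, and typed readers for the intermediate CSV outputs.

library(dipcohort)

CLAIMS_DIR <- "results/claims"
RESULTS_DIR <- "results"
STUDY_SEED <- 20260L
N_PATIENTS <- 2000L

read_claims_dir <- function(dir = CLAIMS_DIR) {
  read_claims(file.path(dir, "prescriptions.csv"),
              file.path(dir, "diagnoses.csv"),
              file.path(dir, "enrollment.csv"))
}

with_dates <- function(df, cols) {
  for (col in intersect(cols, names(df))) df[[col]] <- as.Date(df[[col]])
  tibble::as_tibble(df)
}

read_cohort_csv <- function(path = file.path(RESULTS_DIR, "cohort.csv")) {
  with_dates(utils::read.csv(path), "index_date")
}

read_changes_csv <- function(path = file.path(RESULTS_DIR, "changes.csv")) {
  with_dates(utils::read.csv(path), c("event_date", "disc_date"))
}

read_prognosis_csv <- function(path = file.path(RESULTS_DIR, "prognosis.csv")) {
  tibble::as_tibble(utils::read.csv(path))
}
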