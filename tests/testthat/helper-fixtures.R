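# In-code fixtures: small claims tables keyed by day offsets from a fixed
# anchor date, so tests read like the day-based rules they exercise.

ANCHOR <- as.Date("2006-06-15")

rx_tbl <- function(day, supply, substance = "haloperidol", dose = 5,
                   setting = "outpatient", pid = "P1", anchor = ANCHOR) {
  tibble::tibble(patient_id = pid, substance = substance,
                 start_date = anchor + day, days_supply = as.integer(supply),
                 daily_dose = dose, setting = setting)
}

dx_tbl <- function(day, icd10 = "G211", position = "primary", pid = "P1",
                   anchor = ANCHOR) {
  tibble::tibble(patient_id = pid, icd10 = icd10, date = anchor + day,
                 position = position)
}

en_tbl <- function(pid = "P1", birth_year = 1950L, sex = "female",
                   insurance = "national_health_insurance",
                   income_decile = 5L, disability = "none",
                   obs_start = as.Date("2002-01-01"),
                   obs_end = as.Date("2015-12-31")) {
  tibble::tibble(patient_id = pid, observation_start = obs_start,
                 observation_end = obs_end, birth_year = birth_year,
                 sex = sex, insurance = insurance,
                 income_decile = income_decile, disability = disability)
}

mk_bundle <- function(rx, dx, en = NULL) {
  if (is.null(en)) {
    pids <- sort(unique(c(rx$patient_id, dx$patient_id)))
    en <- dplyr::bind_rows(lapply(pids, en_tbl))
  }
  validate_claims(rx, dx, en)
}

# random one-class prescription stream guaranteed to cover day 0, with
# overlaps, dose changes, substance changes and gaps of all sizes
random_rx_stream <- function(pid = "P1", class = "gi_motility",
                             cfg = study_config(), anchor = ANCHOR) {
  subs <- names(cfg$offending_drugs)[cfg$offending_drugs == class]
  n_rx <- sample(2:12, 1)
  day <- -sample(0:13, 1)
  rows <- vector("list", n_rx)
  cur_end <- -Inf
  for (i in seq_len(n_rx)) {
    supply <- if (i == 1) sample(14:40, 1) else sample(7:40, 1)
    rows[[i]] <- rx_tbl(day, supply, substance = sample(subs, 1),
                        dose = sample(c(1, 2, 5, 10, 20), 1), pid = pid,
                        anchor = anchor)
    cur_end <- max(cur_end, day + supply)
    day <- cur_end + sample(-15:90, 1)
  }
  dplyr::bind_rows(rows)
}
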