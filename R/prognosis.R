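#' Group DIP diagnosis dates into episodes under the 4-month rule
#'
#' Diagnosis dates in the follow-up window are clustered by single linkage:
#' consecutive dates at most `dip_episode_gap_days` (default 120, i.e. 4
#' months) apart belong to one episode; a longer diagnosis-free gap starts a
#' new one. An episode is remitted iff a full diagnosis-free run of
#' `dip_episode_gap_days` after its last diagnosis is observable inside the
#' window -- i.e. `min(next diagnosis, window end) - last_dx >
#' dip_episode_gap_days`. An episode whose last diagnosis falls within
#' `dip_episode_gap_days` of the window end can never confirm remittance
#' (right-censoring).
#'
#' @param dip_dx_dates DIP diagnosis dates for one patient inside
#'   `[index_date, index_date + followup_days)`; must include the index
#'   date.
#' @param index_date Index date.
#' @param config A [study_config()].
#' @return Tibble, one row per episode in date order: `first_dx`, `last_dx`,
#'   `n_dx`, `remitted`.
#' @export
build_dip_episodes <- function(dip_dx_dates, index_date, config = study_config()) {
  d <- sort(unique(as.Date(dip_dx_dates)))
  if (length(d) == 0L)
    stop("contract violation: no DIP diagnosis dates (the index diagnosis always exists)",
         call. = FALSE)
  win_end <- index_date + config$followup_days
  stopifnot(all(d >= index_date), all(d < win_end))
  new_ep <- c(TRUE, diff(as.integer(d)) > config$dip_episode_gap_days)
  ep <- cumsum(new_ep)
  groups <- split(d, ep)
  first_dx <- as.Date(unname(vapply(groups, function(g) min(as.integer(g)),
                                    numeric(1))), origin = "1970-01-01")
  last_dx <- as.Date(unname(vapply(groups, function(g) max(as.integer(g)),
                                   numeric(1))), origin = "1970-01-01")
  bound <- c(first_dx[-1], win_end) # next episode's first dx, or window end
  tibble::new_tibble(list(
    first_dx = first_dx, last_dx = last_dx, n_dx = unname(lengths(groups)),
    remitted = as.integer(bound - last_dx) > config$dip_episode_gap_days
  ), nrow = length(groups))
}

#' Classify a patient's first prognosis
#'
#' From the ordered episodes of [build_dip_episodes()] (the first contains
#' the index date):
#' \itemize{
#'   \item the index episode never confirms remittance inside follow-up ->
#'     `persisting`;
#'   \item it remits and a later episode exists -> `recurrence`, with
#'     `time_to_recurrence` = first diagnosis of the second episode minus
#'     index;
#'   \item it remits with no later episode -> `remittance`.
#' }
#' `time_to_remittance` (last diagnosis of the index episode minus index) is
#' reported whenever the index episode remits: a patient whose only DIP
#' claim is the index visit remits at day 0. Only the first prognosis is
#' classified; later cycles are out of scope.
#'
#' @param episodes Episode tibble.
#' @param index_date Index date.
#' @param config A [study_config()].
#' @return One-row tibble: `category`, `time_to_remittance`,
#'   `time_to_recurrence` (days; NA where not applicable).
#' @export
classify_prognosis <- function(episodes, index_date, config = study_config()) {
  stopifnot(nrow(episodes) >= 1L,
            episodes$first_dx[1] <= index_date)
  row <- function(cat, ttr = NA_integer_, ttrec = NA_integer_)
    tibble::new_tibble(list(category = cat, time_to_remittance = ttr,
                            time_to_recurrence = ttrec), nrow = 1L)
  if (!episodes$remitted[1]) return(row("persisting"))
  ttr <- as.integer(episodes$last_dx[1] - index_date)
  if (nrow(episodes) >= 2L)
    return(row("recurrence", ttr, as.integer(episodes$first_dx[2] - index_date)))
  row("remittance", ttr)
}

#' Classify prognoses for a whole cohort
#'
#' Uses every DIP diagnosis date (primary or secondary) in the follow-up
#' window, regardless of whether an offending prescription accompanies it:
#' the prescription-overlap rule applies at the index date only.
#'
#' @param bundle A `"claims_bundle"`.
#' @param cohort Cohort tibble from [select_incident_cases()].
#' @param config A [study_config()].
#' @return Tibble keyed by `patient_id`: `category`, `time_to_remittance`,
#'   `time_to_recurrence`.
#' @export
classify_cohort_prognosis <- function(bundle, cohort, config = study_config()) {
  dx <- bundle$diagnoses
  is_dip <- icd10_matches(dx$icd10, config$dip_codes)
  dx <- dx[is_dip, , drop = FALSE]
  dx_split <- split(dx$date, dx$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    idx <- cohort$index_date[i]
    dates <- dx_split[[pid]]
    dates <- dates[dates >= idx & dates < idx + config$followup_days]
    eps <- build_dip_episodes(dates, idx, config)
    classify_prognosis(eps, idx, config)
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(c(list(patient_id = cohort$patient_id), as.list(out)),
                     nrow = nrow(cohort))
}
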