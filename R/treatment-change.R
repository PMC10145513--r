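#' Scan prescription boundaries for candidate treatment-change events
#'
#' Walks the index-class drug eras of one patient through the follow-up
#' window `[index_date, index_date + followup_days)` and emits, in date
#' order:
#' \describe{
#'   \item{SWITCH}{the substance set changes between consecutive non-empty
#'     regimen segments inside an era (addition, substitution, or removal
#'     with the era continuing);}
#'   \item{DOSE}{the substance set is unchanged but some substance's total
#'     daily dose changes beyond the relative tolerance;}
#'   \item{GAP_START}{an era ends (the first uncovered day after its last
#'     supply);}
#'   \item{RESTART}{the next era begins inside the window.}
#' }
#' An in-era permissible gap (`<= era_gap_days` uncovered days) emits no
#' event by itself: the regimens on either side of it are compared directly,
#' so resuming the same drug at the same dose after a short gap is continued
#' use. A substance change subsumes a simultaneous dose change (SWITCH
#' before DOSE on one date). Only events strictly after the index date and
#' strictly inside the window are emitted.
#'
#' @param eras Era tibble from [build_drug_eras()] for the patient's index
#'   class; one era must cover the index date.
#' @param index_date Index date.
#' @param config A [study_config()].
#' @return Tibble: `date`, `type`, plus `pre_regimen`/`post_regimen`
#'   list-columns for SWITCH/DOSE/RESTART and GAP_START rows.
#' @export
detect_boundary_events <- function(eras, index_date, config = study_config()) {
  win_end <- index_date + config$followup_days
  covering <- which(eras$start <= index_date & index_date < eras$end)
  if (length(covering) != 1L)
    stop("contract violation: no era covers the index date", call. = FALSE)

  ev_date <- numeric(0); ev_type <- character(0)
  ev_pre <- list(); ev_post <- list()
  emit <- function(date, type, pre = NULL, post = NULL) {
    n <- length(ev_date) + 1L
    ev_date[n] <<- as.numeric(date)
    ev_type[n] <<- type
    ev_pre[[n]] <<- pre %||% NA
    ev_post[[n]] <<- post %||% NA
  }

  for (k in seq(covering, nrow(eras))) {
    era <- eras[k, ]
    if (era$start >= win_end) break
    rx <- era$prescriptions[[1]]
    segs <- era_segments(rx)
    segs <- segs[lengths(segs$regimen) > 0L, , drop = FALSE] # non-empty only
    if (k > covering && era$start > index_date && era$start < win_end) {
      emit(era$start, "RESTART", post = segs$regimen[[1]])
    }
    if (nrow(segs) >= 2L) {
      for (j in 2:nrow(segs)) {
        t <- segs$start[j]
        if (t <= index_date || t >= win_end) next
        cmp <- compare_regimens(segs$regimen[[j - 1]], segs$regimen[[j]],
                                config$dose_tolerance)
        if (cmp == "switch")
          emit(t, "SWITCH", pre = segs$regimen[[j - 1]], post = segs$regimen[[j]])
        else if (cmp == "dose")
          emit(t, "DOSE", pre = segs$regimen[[j - 1]], post = segs$regimen[[j]])
      }
    }
    if (era$end > index_date && era$end < win_end)
      emit(era$end, "GAP_START", pre = segs$regimen[[nrow(segs)]])
  }
  if (length(ev_date) == 0L)
    return(tibble::new_tibble(list(date = as.Date(character(0)),
                                   type = character(0),
                                   pre_regimen = list(),
                                   post_regimen = list()), nrow = 0L))
  prio <- c(SWITCH = 1L, DOSE = 2L, GAP_START = 3L, RESTART = 4L)
  o <- order(ev_date, prio[ev_type])
  tibble::new_tibble(list(
    date = as.Date(ev_date[o], origin = "1970-01-01"),
    type = ev_type[o],
    pre_regimen = ev_pre[o],
    post_regimen = ev_post[o]
  ), nrow = length(o))
}

#' Reinitiation subtype from the regimens around a confirmed gap
#'
#' @param pre_gap,post_gap Non-empty named regimen vectors of the same
#'   offending class (substance -> total daily dose).
#' @param tol Relative dose tolerance.
#' @return `"within_class_switch"` if the substance sets differ,
#'   `"same_drug_dose_adjusted"` if the set is unchanged but a dose differs,
#'   else `"same_drug_same_dose"`.
#' @export
reinitiation_subtype <- function(pre_gap, post_gap, tol = 1e-6) {
  if (length(pre_gap) == 0L || length(post_gap) == 0L)
    stop("contract violation: empty regimen around a reinitiation gap",
         call. = FALSE)
  switch(compare_regimens(pre_gap, post_gap, tol),
         switch = "within_class_switch",
         dose = "same_drug_dose_adjusted",
         same = "same_drug_same_dose")
}

#' Classify a patient's first treatment change
#'
#' The five categories are mutually exclusive and resolved from the ordered
#' event stream of [detect_boundary_events()]:
#' \itemize{
#'   \item first SWITCH -> `switching` (altering drugs within the class
#'     across consecutive prescriptions);
#'   \item first DOSE -> `dose_adjustment`;
#'   \item first GAP_START resolves by lookahead: a later RESTART inside the
#'     window -> `reinitiation` dated at the restart (restarting the
#'     discontinued drug, or switching within the class after a temporary
#'     discontinuation), with subtype from [reinitiation_subtype()];
#'     no RESTART and more than `era_gap_days` of window remaining ->
#'     `discontinuation` dated at the era end (absence of a new prescription
#'     for more than 60 days); no RESTART but too little window left to
#'     confirm the gap -> `persistent_use`;
#'   \item no events at all -> `persistent_use`.
#' }
#'
#' @param events Event tibble from [detect_boundary_events()].
#' @param index_date Index date.
#' @param config A [study_config()].
#' @return One-row tibble: `category`, `reinit_subtype` (NA unless
#'   reinitiation), `event_date` (NA for persistent use), `days_from_index`,
#'   and `disc_date` -- the first era end for patients who discontinued
#'   temporarily (reinitiation) or permanently (discontinuation), NA
#'   otherwise; used for the pooled time-to-discontinuation summary.
#' @export
classify_first_change <- function(events, index_date, config = study_config()) {
  win_end <- index_date + config$followup_days
  res <- function(category, subtype = NA_character_, date = as.Date(NA),
                  disc = as.Date(NA)) {
    tibble::new_tibble(list(category = category, reinit_subtype = subtype,
                            event_date = date,
                            days_from_index = as.integer(date - index_date),
                            disc_date = disc), nrow = 1L)
  }
  if (nrow(events) == 0L) return(res("persistent_use"))
  first <- events[1, ]
  if (first$type == "SWITCH") return(res("switching", date = first$date))
  if (first$type == "DOSE") return(res("dose_adjustment", date = first$date))
  # first event is GAP_START (RESTART cannot precede the index era's end)
  gap_date <- first$date
  later <- events[events$date > gap_date & events$type == "RESTART", , drop = FALSE]
  if (nrow(later) > 0L) {
    restart <- later[1, ]
    subtype <- reinitiation_subtype(first$pre_regimen[[1]],
                                    restart$post_regimen[[1]],
                                    config$dose_tolerance)
    return(res("reinitiation", subtype = subtype, date = restart$date,
               disc = gap_date))
  }
  if (as.integer(win_end - gap_date) > config$era_gap_days)
    return(res("discontinuation", date = gap_date, disc = gap_date))
  res("persistent_use") # gap unconfirmable before follow-up ends
}

#' Classify first treatment changes for a whole cohort
#'
#' Restricts each patient's prescriptions to their index offending class
#' (patients are counted once, in the class of their index exposure; other
#' offending classes are ignored), builds eras, scans boundaries and
#' classifies the first change.
#'
#' @param bundle A `"claims_bundle"`.
#' @param cohort Cohort tibble from [select_incident_cases()].
#' @param config A [study_config()].
#' @return Tibble keyed by `patient_id` with the columns of
#'   [classify_first_change()] plus `index_class`.
#' @export
classify_cohort_changes <- function(bundle, cohort, config = study_config()) {
  rx_all <- as.data.frame(bundle$prescriptions)
  rx_all$class <- classify_drug(rx_all$substance, config)
  rx_split <- split(seq_len(nrow(rx_all)), rx_all$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    prx <- rx_all[rx_split[[pid]] %||% integer(0), , drop = FALSE]
    prx <- prx[!is.na(prx$class) & prx$class == cohort$index_class[i], ,
               drop = FALSE]
    eras <- build_drug_eras(prx, config)
    events <- detect_boundary_events(eras, cohort$index_date[i], config)
    classify_first_change(events, cohort$index_date[i], config)
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(c(list(patient_id = cohort$patient_id,
                            index_class = cohort$index_class),
                       as.list(out)), nrow = nrow(cohort))
}
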