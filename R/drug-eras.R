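#' Build continuous drug-exposure eras under the permissible-gap rule
#'
#' Continued use is defined as consecutive prescriptions with an uncovered
#' gap of at most `era_gap_days` (default 60) between them. Supply intervals
#' are half-open `[start, start + days_supply)`; the gap between a
#' prescription and the era so far is `start - cumulative supply end` in
#' uncovered days, and a gap `<= era_gap_days` keeps the era alive. Merging
#' is maximal: two prescriptions share an era iff they are linked by a chain
#' of such gaps. Overlapping refills are taken at face value (no
#' stockpiling shift).
#'
#' @param prescriptions Prescription tibble for one patient, already
#'   restricted to one offending class.
#' @param config A [study_config()].
#' @return Tibble, one row per era, ordered by start: `start`, `end`
#'   (exclusive, the max supply end over constituents), `n_prescriptions`,
#'   and a list-column `prescriptions` with the constituent rows sorted by
#'   start date.
#' @export
build_drug_eras <- function(prescriptions, config = study_config()) {
  if (nrow(prescriptions) == 0L)
    return(tibble::tibble(start = as.Date(character(0)),
                          end = as.Date(character(0)),
                          n_prescriptions = integer(0),
                          prescriptions = list()))
  rx <- as.data.frame(prescriptions)
  rx <- rx[order(rx$start_date, rx$substance), , drop = FALSE]
  ends <- supply_end(rx)
  cum_end <- cummax(as.integer(ends))
  # gap precedes each prescription after the first; > gap_days starts a new era
  new_era <- c(TRUE, as.integer(rx$start_date[-1]) -
                 cum_end[-nrow(rx)] > config$era_gap_days)
  era_id <- cumsum(new_era)
  groups <- split(seq_len(nrow(rx)), era_id)
  tibble::new_tibble(list(
    start = as.Date(unname(vapply(groups, function(i) min(rx$start_date[i]),
                                  numeric(1))), origin = "1970-01-01"),
    end = as.Date(unname(vapply(groups, function(i) max(as.integer(ends[i])),
                                numeric(1))), origin = "1970-01-01"),
    n_prescriptions = unname(lengths(groups)),
    prescriptions = unname(lapply(groups, function(i) rx[i, , drop = FALSE]))
  ), nrow = length(groups))
}

#' Regimen (substance -> total daily dose) active on a date
#'
#' Sums `daily_dose` over every prescription whose half-open supply interval
#' contains the date, per substance. Two same-day refills of one substance
#' add up.
#'
#' @param prescriptions Prescription tibble (e.g. an era's constituents).
#' @param date A single date.
#' @return Named numeric vector (sorted by substance); empty if no supply is
#'   active.
#' @export
regimen_at <- function(prescriptions, date) {
  act <- prescriptions[covers_date(prescriptions, date), , drop = FALSE]
  if (nrow(act) == 0L) return(stats::setNames(numeric(0), character(0)))
  tot <- tapply(act$daily_dose, act$substance, sum)
  stats::setNames(as.numeric(tot), names(tot))[sort(names(tot))]
}

#' Segment an era into runs of constant regimen
#'
#' Breakpoints are every constituent prescription's start and supply end;
#' each segment carries the regimen active throughout it. Segments with an
#' empty regimen (an in-era permissible gap) are kept so callers can see
#' uncovered spans.
#'
#' @param era_rx Constituent prescriptions of one era.
#' @return Tibble: `start`, `end` (half-open day spans) and list-column
#'   `regimen`.
#' @keywords internal
era_segments <- function(era_rx) {
  cuts <- sort(unique(c(as.integer(era_rx$start_date),
                        as.integer(supply_end(era_rx)))))
  starts <- cuts[-length(cuts)]
  tibble::new_tibble(list(
    start = as.Date(starts, origin = "1970-01-01"),
    end = as.Date(cuts[-1], origin = "1970-01-01"),
    regimen = lapply(starts, function(s)
      regimen_at(era_rx, as.Date(s, origin = "1970-01-01")))
  ), nrow = length(starts))
}

#' Compare two regimens
#' @return "same", "dose" (same substance set, some total dose differs beyond
#'   the relative tolerance), or "switch" (different substance set).
#' @keywords internal
compare_regimens <- function(a, b, tol = 1e-6) {
  if (!identical(names(a), names(b))) return("switch")
  if (length(a) == 0L) return("same")
  rel <- abs(a - b) / pmax(abs(a), abs(b))
  if (any(rel > tol)) "dose" else "same"
}
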