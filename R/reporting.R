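#' One-decimal percentage, rounded half away from zero
#'
#' `100 * numerator / denominator`, rounded to one decimal with ties going
#' away from zero (the convention of printed clinical tables, unlike
#' [round()]'s banker's rounding). A zero denominator yields `NA` with a
#' warning.
#'
#' @param numerator,denominator Nonnegative counts, `numerator <=
#'   denominator` elementwise.
#' @return Numeric vector of one-decimal percentages.
#' @export
#' @examples
#' proportion(170, 272) # 62.5
proportion <- function(numerator, denominator) {
  stopifnot(all(numerator >= 0), all(numerator <= denominator | denominator == 0))
  out <- rep(NA_real_, length(numerator))
  ok <- denominator > 0
  if (any(!ok)) warning("zero denominator: proportion undefined, reported as NA")
  x <- 100 * numerator[ok] / denominator[ok]
  out[ok] <- sign(x) * floor(abs(x) * 10 + 0.5) / 10
  out
}

#' Descriptive time-to-event summary
#'
#' Median and quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); mean and standard deviation are the usual
#' sample statistics. An empty input yields an all-NA row with a warning.
#'
#' @param durations Nonnegative durations in days.
#' @return One-row tibble: `n`, `median`, `q1`, `q3`, `mean`, `sd`.
#' @export
time_summary <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0L) {
    warning("empty duration set: blank time summary")
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, mean = NA_real_, sd = NA_real_))
  }
  stopifnot(all(durations >= 0))
  q <- stats::quantile(durations, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(durations), median = q[2], q1 = q[1], q3 = q[3],
                 mean = mean(durations), sd = stats::sd(durations))
}

count_pct <- function(values, levels, denominator = length(values)) {
  counts <- vapply(levels, function(l) sum(values == l), integer(1))
  tibble::tibble(level = levels, count = counts,
                 pct = proportion(counts, rep(denominator, length(counts))))
}

#' Baseline characteristics table
#'
#' One row per level of each baseline characteristic (age band, sex,
#' insurance, income decile, disability, Parkinson's disease, offending
#' class at index) with count and one-decimal percentage of the cohort, plus
#' a Charlson-index row carrying mean and SD.
#'
#' @param cohort Cohort tibble from [select_incident_cases()].
#' @return Tibble: `section`, `level`, `count`, `pct`, `mean`, `sd`.
#' @export
baseline_table <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  n <- nrow(cohort)
  sec <- function(section, tab) tibble::tibble(section = section, tab,
                                               mean = NA_real_, sd = NA_real_)
  dplyr::bind_rows(
    sec("n", tibble::tibble(level = "patients", count = n,
                            pct = proportion(n, n))),
    sec("age_band", count_pct(cohort$age_band,
                              c("0-19", "20-29", "30-39", "40-49", "50-59",
                                "60-69", "70-79", "80+"), n)),
    sec("sex", count_pct(cohort$sex, c("male", "female"), n)),
    sec("insurance", count_pct(cohort$insurance,
                               c("national_health_insurance", "medical_aid"), n)),
    sec("income_decile", count_pct(as.character(cohort$income_decile),
                                   as.character(0:10), n)),
    sec("disability", count_pct(cohort$disability,
                                c("none", "mild", "severe"), n)),
    tibble::tibble(section = "cci", level = "charlson_index",
                   count = NA_integer_, pct = NA_real_,
                   mean = mean(cohort$cci), sd = stats::sd(cohort$cci)),
    sec("parkinsons_disease", tibble::tibble(
      level = "G20_within_2y", count = sum(cohort$pd),
      pct = proportion(sum(cohort$pd), n))),
    sec("offending_class", count_pct(cohort$index_class, offending_classes(), n))
  )
}

#' Category levels of the first treatment change, in display order
#' @return Character vector of the five mutually exclusive categories.
#' @export
change_categories <- function() c("discontinuation", "dose_adjustment",
                                  "persistent_use", "reinitiation", "switching")

#' Category levels of the DIP prognosis, in display order
#' @return Character vector of the three prognosis categories.
#' @export
prognosis_categories <- function() c("remittance", "recurrence", "persisting")

#' Reinitiation subtype levels, in display order
#' @return Character vector of the three reinitiation subtypes.
#' @export
reinit_subtypes <- function() c("same_drug_same_dose", "same_drug_dose_adjusted",
                                "within_class_switch")

#' Category shares overall and within strata
#'
#' Counts and one-decimal percentages of `var` levels; with `by`, within
#' each stratum (within-stratum denominators).
#'
#' @param df Data frame.
#' @param var Column name holding the category.
#' @param levels Category levels, in display order.
#' @param by Optional stratum column name.
#' @return Tibble: (`stratum`,) `level`, `count`, `pct`.
#' @export
share_table <- function(df, var, levels, by = NULL) {
  if (is.null(by)) return(count_pct(df[[var]], levels))
  strata <- sort(unique(df[[by]]))
  dplyr::bind_rows(lapply(strata, function(s) {
    tibble::tibble(stratum = s,
                   count_pct(df[[var]][df[[by]] == s], levels))
  }))
}

#' Prognosis distribution by type of treatment change
#'
#' Rows are treatment-change categories, with reinitiation split into its
#' three subtypes; columns are the within-row distribution of prognosis
#' categories (row percentages sum to 100 up to rounding).
#'
#' @param changes Treatment-change tibble (patient_id, category,
#'   reinit_subtype).
#' @param prognoses Prognosis tibble (patient_id, category).
#' @return Tibble: `change`, `n`, then `<prognosis>_count` /
#'   `<prognosis>_pct` column pairs.
#' @export
crosstab_prognosis_by_change <- function(changes, prognoses) {
  if (!setequal(changes$patient_id, prognoses$patient_id) ||
      anyDuplicated(changes$patient_id) || anyDuplicated(prognoses$patient_id))
    stop("consistency error: changes and prognoses must cover the same patients exactly",
         call. = FALSE)
  merged <- dplyr::inner_join(
    changes[c("patient_id", "category", "reinit_subtype")],
    stats::setNames(prognoses[c("patient_id", "category")],
                    c("patient_id", "prognosis")),
    by = "patient_id")
  merged$row_label <- ifelse(merged$category == "reinitiation",
                             paste0("reinitiation:", merged$reinit_subtype),
                             merged$category)
  labels <- c("discontinuation", "dose_adjustment", "persistent_use",
              paste0("reinitiation:", reinit_subtypes()), "switching")
  rows <- lapply(labels, function(l) {
    sub <- merged[merged$row_label == l, , drop = FALSE]
    out <- tibble::tibble(change = l, n = nrow(sub))
    for (p in prognosis_categories()) {
      out[[paste0(p, "_count")]] <- sum(sub$prognosis == p)
      out[[paste0(p, "_pct")]] <- if (nrow(sub)) proportion(sum(sub$prognosis == p),
                                                            nrow(sub)) else NA_real_
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Time-to-event summaries by offending class
#'
#' Summarizes, overall and per index class: time to the first treatment
#' modification (patients with an event date), time to any discontinuation
#' -- temporary or permanent, i.e. the first era end for patients whose
#' first change was discontinuation or reinitiation --, time to remittance
#' (patients whose index episode remitted) and time to recurrence.
#'
#' @param changes Tibble from [classify_cohort_changes()].
#' @param prognoses Tibble from [classify_cohort_prognosis()] joined with
#'   the cohort's `index_class` (column required).
#' @return Tibble: `measure`, `stratum`, and the [time_summary()] columns.
#' @export
time_tables <- function(changes, prognoses) {
  strata <- function(df, col, f) {
    all_row <- tibble::tibble(stratum = "all", f(df))
    per <- lapply(sort(unique(df[[col]])), function(s)
      tibble::tibble(stratum = s, f(df[df[[col]] == s, , drop = FALSE])))
    dplyr::bind_rows(c(list(all_row), per))
  }
  suppressWarnings(dplyr::bind_rows(
    tibble::tibble(measure = "first_change",
                   strata(changes, "index_class",
                          function(d) time_summary(d$days_from_index))),
    tibble::tibble(measure = "any_discontinuation",
                   strata(changes, "index_class", function(d)
                     time_summary(as.integer(d$disc_date - d$event_date +
                                               d$days_from_index)))),
    tibble::tibble(measure = "remittance",
                   strata(prognoses, "index_class",
                          function(d) time_summary(d$time_to_remittance))),
    tibble::tibble(measure = "recurrence",
                   strata(prognoses, "index_class",
                          function(d) time_summary(d$time_to_recurrence)))
  ))
}

#' Render a summary table as an aligned-text block
#'
#' @param title Block title.
#' @param df The table to render.
#' @return Character vector of text lines (title, rule, header, rows).
#' @export
format_block <- function(title, df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- ifelse(is.na(df[[j]]), "",
                                          formatC(df[[j]], format = "fg",
                                                  digits = 7))
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(x) max(nchar(as.character(x)), 0L),
                        integer(1)))
  fmt_row <- function(vals) paste(mapply(formatC, as.character(vals),
                                         width = widths), collapse = "  ")
  c(title, strrep("-", nchar(title)), fmt_row(names(df)),
    apply(df, 1, fmt_row), "")
}
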