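#' Run the full analysis pipeline on a claims bundle
#'
#' Chains incident-case selection, index-class exposure eras, first
#' treatment-change classification, DIP-episode prognosis classification,
#' and the descriptive tables.
#'
#' @param bundle A validated `"claims_bundle"`.
#' @param config A [study_config()].
#' @return List: `cohort`, `exclusions`, `changes`, `prognosis`, `eras`
#'   (diagnostic, one row per index-class era), and `tables` (list of
#'   `baseline`, `patterns`, `patterns_by_class`, `patterns_by_sex`,
#'   `prognosis`, `prognosis_by_class`, `prognosis_by_sex`,
#'   `reinit_subtypes`, `crosstab`, `times`).
#' @export
run_dip_pipeline <- function(bundle, config = study_config()) {
  sel <- select_incident_cases(bundle, config)
  cohort <- sel$cohort
  if (nrow(cohort) == 0L)
    return(list(cohort = cohort, exclusions = sel$exclusions,
                changes = NULL, prognosis = NULL, eras = NULL, tables = NULL))

  changes <- classify_cohort_changes(bundle, cohort, config)
  prognosis <- classify_cohort_prognosis(bundle, cohort, config)
  key <- cohort[c("patient_id", "index_class", "sex")]
  changes <- dplyr::left_join(changes, key[c("patient_id", "sex")],
                              by = "patient_id")
  prognosis <- dplyr::left_join(prognosis, key, by = "patient_id")

  eras <- eras_table(bundle, cohort, config)

  reinit <- changes[changes$category == "reinitiation", , drop = FALSE]
  tables <- list(
    baseline = baseline_table(cohort),
    patterns = share_table(changes, "category", change_categories()),
    patterns_by_class = share_table(changes, "category", change_categories(),
                                    by = "index_class"),
    patterns_by_sex = share_table(changes, "category", change_categories(),
                                  by = "sex"),
    prognosis = share_table(prognosis, "category", prognosis_categories()),
    prognosis_by_class = share_table(prognosis, "category",
                                     prognosis_categories(), by = "index_class"),
    prognosis_by_sex = share_table(prognosis, "category",
                                   prognosis_categories(), by = "sex"),
    reinit_subtypes = if (nrow(reinit))
      share_table(reinit, "reinit_subtype", reinit_subtypes()) else NULL,
    crosstab = crosstab_prognosis_by_change(changes, prognosis),
    times = time_tables(changes, prognosis)
  )
  list(cohort = cohort, exclusions = sel$exclusions, changes = changes,
       prognosis = prognosis, eras = eras, tables = tables)
}

#' Diagnostic table of index-class drug eras for a cohort
#'
#' One row per continuous exposure era of each cohort patient's index
#' offending class: patient, class, era start, exclusive end, and the number
#' of constituent prescriptions.
#'
#' @param bundle A `"claims_bundle"`.
#' @param cohort Cohort tibble from [select_incident_cases()].
#' @param config A [study_config()].
#' @return Tibble: `patient_id`, `class`, `start`, `end`, `n_prescriptions`.
#' @export
eras_table <- function(bundle, cohort, config = study_config()) {
  rx_all <- as.data.frame(bundle$prescriptions)
  rx_all$class <- classify_drug(rx_all$substance, config)
  rx_split <- split(seq_len(nrow(rx_all)), rx_all$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    prx <- rx_all[rx_split[[pid]] %||% integer(0), , drop = FALSE]
    prx <- prx[!is.na(prx$class) & prx$class == cohort$index_class[i], ,
               drop = FALSE]
    eras <- build_drug_eras(prx, config)
    tibble::new_tibble(list(
      patient_id = rep(pid, nrow(eras)),
      class = rep(cohort$index_class[i], nrow(eras)),
      start = eras$start, end = eras$end,
      n_prescriptions = eras$n_prescriptions), nrow = nrow(eras))
  })
  dplyr::bind_rows(rows)
}

#' Write pipeline outputs to a directory
#'
#' Emits `cohort.csv`, `exclusions.csv`, `changes.csv`, `prognosis.csv`,
#' `eras.csv`, `patterns_by_class.csv`, `prognosis_by_class.csv`,
#' `crosstab.csv`, `times.csv`, and the aligned-text `baseline_table.txt`
#' plus `report.txt`.
#'
#' @param result List from [run_dip_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_plain(result$cohort, file.path(dir, "cohort.csv"))
  write_csv_plain(result$exclusions, file.path(dir, "exclusions.csv"))
  write_csv_plain(result$changes, file.path(dir, "changes.csv"))
  write_csv_plain(result$prognosis, file.path(dir, "prognosis.csv"))
  write_csv_plain(result$eras, file.path(dir, "eras.csv"))
  write_csv_plain(result$tables$patterns_by_class,
                  file.path(dir, "patterns_by_class.csv"))
  write_csv_plain(result$tables$prognosis_by_class,
                  file.path(dir, "prognosis_by_class.csv"))
  write_csv_plain(result$tables$crosstab, file.path(dir, "crosstab.csv"))
  write_csv_plain(result$tables$times, file.path(dir, "times.csv"))
  writeLines(format_block("Baseline characteristics", result$tables$baseline),
             file.path(dir, "baseline_table.txt"))
  writeLines(render_report(result), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render the full aligned-text report
#'
#' @param result List from [run_dip_pipeline()].
#' @return Character vector of report lines.
#' @export
render_report <- function(result) {
  t <- result$tables
  c(format_block(sprintf("Cohort: %d incident cases, %d exclusions",
                         nrow(result$cohort), nrow(result$exclusions)),
                 as.data.frame(table(reason = result$exclusions$reason))),
    format_block("Baseline characteristics", t$baseline),
    format_block("First treatment change", t$patterns),
    format_block("First treatment change by offending class",
                 t$patterns_by_class),
    format_block("Prognosis", t$prognosis),
    format_block("Prognosis by offending class", t$prognosis_by_class),
    if (!is.null(t$reinit_subtypes))
      format_block("Reinitiation subtypes", t$reinit_subtypes),
    format_block("Prognosis by type of treatment change", t$crosstab),
    format_block("Times to event (days)", t$times))
}
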