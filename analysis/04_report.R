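#!/usr/bin/env Rscript
# Stage 4 -- descriptive reporting.
#
# Rebuilds the descriptive outputs from the staged tables: baseline
# characteristics, treatment-pattern and prognosis proportions (overall, by
# offending class, by sex), reinitiation subtypes, the prognosis-by-change
# cross-tabulation, and time-to-event summaries. Writes the CSV tables and
# the aligned-text report, then prints the report.

source("analysis/common.R")

cohort <- read_cohort_csv()
changes <- merge(read_changes_csv(),
                 cohort[c("patient_id", "sex")], by = "patient_id")
prognosis <- merge(read_prognosis_csv(),
                   cohort[c("patient_id", "index_class", "sex")],
                   by = "patient_id")
exclusions <- tibble::as_tibble(
  utils::read.csv(file.path(RESULTS_DIR, "exclusions.csv")))

reinit <- changes[changes$category == "reinitiation", ]
tables <- list(
  baseline = baseline_table(cohort),
  patterns = share_table(changes, "category", change_categories()),
  patterns_by_class = share_table(changes, "category",
                                  change_categories(),
                                  by = "index_class"),
  patterns_by_sex = share_table(changes, "category",
                                change_categories(), by = "sex"),
  prognosis = share_table(prognosis, "category",
                          prognosis_categories()),
  prognosis_by_class = share_table(prognosis, "category",
                                   prognosis_categories(),
                                   by = "index_class"),
  prognosis_by_sex = share_table(prognosis, "category",
                                 prognosis_categories(),
                                 by = "sex"),
  reinit_subtypes = share_table(reinit, "reinit_subtype",
                                reinit_subtypes()),
  crosstab = crosstab_prognosis_by_change(changes, prognosis),
  times = time_tables(changes, prognosis)
)

for (nm in c("patterns_by_class", "prognosis_by_class", "crosstab", "times"))
  write_csv_plain(tables[[nm]], file.path(RESULTS_DIR, paste0(nm, ".csv")))

result <- list(cohort = cohort, exclusions = exclusions, tables = tables)
report <- render_report(result)
writeLines(report, file.path(RESULTS_DIR, "report.txt"))
writeLines(format_block("Baseline characteristics", tables$baseline),
           file.path(RESULTS_DIR, "baseline_table.txt"))
message("Wrote ", RESULTS_DIR,
        "/patterns_by_class.csv, prognosis_by_class.csv, crosstab.csv, ",
        "times.csv, baseline_table.txt, report.txt\n")
cat(report, sep = "\n")
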