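#!/usr/bin/env Rscript
# Stage 3 -- classify treatment changes and prognoses.
#
# For every cohort patient: builds the index-class drug eras under the
# 60-day permissible-gap rule, scans prescription boundaries for the first
# treatment change (discontinuation / dose adjustment / persistent use /
# reinitiation with subtype / switching), and groups DIP diagnosis dates
# into episodes under the 4-month rule to classify the prognosis
# (remittance / recurrence / persisting). Writes changes.csv, prognosis.csv
# and the eras.csv diagnostic.

source("analysis/common.R")

bundle <- read_claims_dir()
cohort <- read_cohort_csv()

changes <- classify_cohort_changes(bundle, cohort)
prognosis <- classify_cohort_prognosis(bundle, cohort)
eras <- eras_table(bundle, cohort)

message("First treatment change:")
print(table(changes$category))
message("Reinitiation subtypes:")
print(table(changes$reinit_subtype, useNA = "no"))
message("Prognosis:")
print(table(prognosis$category))
message("Drug eras built: ", nrow(eras), " (",
        round(nrow(eras) / nrow(cohort), 2), " per patient)")

write_csv_plain(changes, file.path(RESULTS_DIR, "changes.csv"))
write_csv_plain(prognosis, file.path(RESULTS_DIR, "prognosis.csv"))
write_csv_plain(eras, file.path(RESULTS_DIR, "eras.csv"))
message("Wrote ", RESULTS_DIR, "/changes.csv, prognosis.csv, eras.csv")
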