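#!/usr/bin/env Rscript
# Stage 2 -- select the incident cohort.
#
# Applies the three incident-case criteria (earliest DIP diagnosis in
# 2004-2013 as index date; no DIP diagnosis in the prior 730 days; an
# outpatient offending-drug supply covering the index date) and computes
# baseline covariates (demographics, Charlson index over 365 days,
# Parkinson's disease over 730 days). Writes cohort.csv and exclusions.csv.

source("analysis/common.R")

bundle <- read_claims_dir()
sel <- select_incident_cases(bundle)

message("Incident cases: ", nrow(sel$cohort),
        " | excluded patients: ", nrow(sel$exclusions))
print(table(sel$exclusions$reason))
message("Index offending class:")
print(table(sel$cohort$index_class))
message("CCI mean (SD): ", round(mean(sel$cohort$cci), 2), " (",
        round(stats::sd(sel$cohort$cci), 2), ")")

write_csv_plain(sel$cohort, file.path(RESULTS_DIR, "cohort.csv"))
write_csv_plain(sel$exclusions,
                            file.path(RESULTS_DIR, "exclusions.csv"))
message("Wrote ", RESULTS_DIR, "/cohort.csv and exclusions.csv")
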