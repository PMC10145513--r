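#!/usr/bin/env Rscript
# Stage 1 -- simulate the claims extract.
#
# Generates the synthetic longitudinal claims the study runs on: 2,000
# eligible incident-DIP patients with planted treatment-change and prognosis
# archetypes, plus decoy records (non-offending drugs, comorbidity codes)
# and decoy patients that the cohort builder must exclude (prevalent DIP,
# no index-date supply overlap). Writes prescriptions.csv, diagnoses.csv,
# enrollment.csv and ground_truth.csv under results/claims/.

source("analysis/common.R")

message("Simulating ", N_PATIENTS, " eligible patients (seed ", STUDY_SEED, ") ...")
sim <- simulate_claims(N_PATIENTS, seed = STUDY_SEED, dir = CLAIMS_DIR)

b <- sim$bundle
tr <- sim$ground_truth
message("  prescriptions: ", nrow(b$prescriptions),
        " | diagnoses: ", nrow(b$diagnoses),
        " | patients: ", nrow(b$enrollment))
message("  planted eligible: ", sum(tr$eligible),
        " | planted decoy patients: ", sum(!tr$eligible))
message("  planted change archetypes:")
print(table(tr$planted_change, useNA = "ifany"))
message("  planted prognosis archetypes:")
print(table(tr$planted_prognosis, useNA = "ifany"))
message("Claims written to ", CLAIMS_DIR, "/")
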