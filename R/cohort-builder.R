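#' Quan ICD-10 coding of the 17 Charlson comorbidity categories
#'
#' Each category is a set of normalized ICD-10 prefixes (Quan et al. 2005
#' enhanced ICD-10 coding) with the original Charlson weight.
#' @keywords internal
charlson_map <- function() {
  list(
    mi = list(weight = 1L, codes = c("I21", "I22", "I252")),
    chf = list(weight = 1L, codes = c("I099", "I110", "I130", "I132", "I255",
                                      "I420", "I425", "I426", "I427", "I428",
                                      "I429", "I43", "I50", "P290")),
    pvd = list(weight = 1L, codes = c("I70", "I71", "I731", "I738", "I739",
                                      "I771", "I790", "I792", "K551", "K558",
                                      "K559", "Z958", "Z959")),
    cevd = list(weight = 1L, codes = c("G45", "G46", "H340", "I60", "I61",
                                       "I62", "I63", "I64", "I65", "I66",
                                       "I67", "I68", "I69")),
    dementia = list(weight = 1L, codes = c("F00", "F01", "F02", "F03", "F051",
                                           "G30", "G311")),
    copd = list(weight = 1L, codes = c("I278", "I279", "J40", "J41", "J42",
                                       "J43", "J44", "J45", "J46", "J47",
                                       "J60", "J61", "J62", "J63", "J64",
                                       "J65", "J66", "J67", "J684", "J701",
                                       "J703")),
    rheum = list(weight = 1L, codes = c("M05", "M06", "M315", "M32", "M33",
                                        "M34", "M351", "M353", "M360")),
    pud = list(weight = 1L, codes = c("K25", "K26", "K27", "K28")),
    mild_liver = list(weight = 1L, codes = c("B18", "K700", "K701", "K702",
                                             "K703", "K709", "K713", "K714",
                                             "K715", "K717", "K73", "K74",
                                             "K760", "K762", "K763", "K764",
                                             "K768", "K769", "Z944")),
    diab_uncomp = list(weight = 1L, codes = c("E100", "E101", "E106", "E108",
                                              "E109", "E110", "E111", "E116",
                                              "E118", "E119", "E120", "E121",
                                              "E126", "E128", "E129", "E130",
                                              "E131", "E136", "E138", "E139",
                                              "E140", "E141", "E146", "E148",
                                              "E149")),
    diab_comp = list(weight = 2L, codes = c("E102", "E103", "E104", "E105",
                                            "E107", "E112", "E113", "E114",
                                            "E115", "E117", "E122", "E123",
                                            "E124", "E125", "E127", "E132",
                                            "E133", "E134", "E135", "E137",
                                            "E142", "E143", "E144", "E145",
                                            "E147")),
    paralysis = list(weight = 2L, codes = c("G041", "G114", "G801", "G802",
                                            "G81", "G82", "G830", "G831",
                                            "G832", "G833", "G834", "G839")),
    renal = list(weight = 2L, codes = c("I120", "I131", "N032", "N033", "N034",
                                        "N035", "N036", "N037", "N052", "N053",
                                        "N054", "N055", "N056", "N057", "N18",
                                        "N19", "N250", "Z490", "Z491", "Z492",
                                        "Z940", "Z992")),
    cancer = list(weight = 2L, codes = c(
      paste0("C0", 0:9), paste0("C1", 0:9), paste0("C2", 0:6),
      paste0("C3", c(0:4, 7:9)), paste0("C4", c(0, 1, 3, 5:9)),
      paste0("C5", 0:8), paste0("C6", 0:9), paste0("C7", 0:6),
      paste0("C8", c(1:5, 8)), paste0("C9", 0:7))),
    severe_liver = list(weight = 3L, codes = c("I850", "I859", "I864", "I982",
                                               "K704", "K711", "K721", "K729",
                                               "K765", "K766", "K767")),
    mets = list(weight = 6L, codes = c("C77", "C78", "C79", "C80")),
    hiv = list(weight = 6L, codes = c("B20", "B21", "B22", "B24"))
  )
}

#' Charlson comorbidity index from ICD-10 diagnoses
#'
#' Maps diagnoses recorded in `[index_date - lookback_days, index_date - 1]`
#' (primary or secondary) to the 17 Charlson categories by normalized-prefix
#' match and sums the original Charlson weights. Hierarchy rules: complicated
#' diabetes supersedes uncomplicated diabetes; metastatic solid tumour
#' supersedes non-metastatic malignancy; moderate/severe liver disease
#' supersedes mild liver disease. Each category counts once.
#'
#' @param diagnoses Diagnosis tibble (normalized codes) for one patient.
#' @param index_date Index date.
#' @param lookback_days Lookback length in days (> 0).
#' @return Integer score >= 0.
#' @export
charlson_index <- function(diagnoses, index_date, lookback_days = 365L) {
  if (lookback_days <= 0) stop("config error: lookback_days must be > 0",
                               call. = FALSE)
  win <- diagnoses$date >= index_date - lookback_days &
    diagnoses$date <= index_date - 1L
  codes <- unique(diagnoses$icd10[win])
  if (length(codes) == 0L) return(0L)
  cmap <- charlson_map()
  present <- vapply(cmap, function(cat) any(icd10_matches(codes, cat$codes)),
                    logical(1))
  if (present[["diab_comp"]]) present[["diab_uncomp"]] <- FALSE
  if (present[["mets"]]) present[["cancer"]] <- FALSE
  if (present[["severe_liver"]]) present[["mild_liver"]] <- FALSE
  sum(vapply(cmap[present], `[[`, integer(1), "weight"))
}

#' Parkinson's disease flag
#'
#' TRUE iff any diagnosis whose normalized code starts with the configured
#' prefix (default G20), in primary or secondary position, falls in
#' `[index_date - lookback_days, index_date]`. The index date itself is
#' included ("within 2 years" up to and including diagnosis day); note G21x
#' codes do not match the G20 prefix.
#'
#' @inheritParams charlson_index
#' @param code Normalized code prefix (default `"G20"`).
#' @return Logical scalar.
#' @export
pd_flag <- function(diagnoses, index_date, lookback_days = 730L, code = "G20") {
  win <- diagnoses$date >= index_date - lookback_days &
    diagnoses$date <= index_date
  any(startsWith(diagnoses$icd10[win], code))
}

#' Age-band labels (decade bands, 0-19 pooled, 80+ open)
#' @keywords internal
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 19, 29, 39, 49, 59, 69, 79, Inf),
      labels = c("0-19", "20-29", "30-39", "40-49", "50-59",
                 "60-69", "70-79", "80+"))
}

#' Assign the offending class at the index date
#'
#' When outpatient prescriptions of more than one offending class cover the
#' index date, the fixed priority antipsychotic > gi_motility > flunarizine
#' resolves the tie (so the rarer, higher-risk psychiatric exposure is not
#' masked); ties are reported via the `tie` attribute.
#'
#' @param prescriptions Prescription tibble for one patient.
#' @param index_date Index date.
#' @param config A [study_config()].
#' @return Single class label with attribute `tie` (logical).
#' @export
assign_index_class <- function(prescriptions, index_date, config = study_config()) {
  cls <- classify_drug(prescriptions$substance, config)
  qualifies <- !is.na(cls) & prescriptions$setting == "outpatient" &
    covers_date(prescriptions, index_date)
  covering <- unique(cls[qualifies])
  if (length(covering) == 0L)
    stop("contract violation: no outpatient offending prescription covers the index date",
         call. = FALSE)
  ordered <- offending_classes()[offending_classes() %in% covering]
  structure(ordered[1], tie = length(covering) > 1L)
}

#' Select incident DIP cases and compute baseline covariates
#'
#' Applies the three incident-case criteria to every patient in the bundle:
#' (1) at least one DIP diagnosis (G21.1 drug-induced secondary parkinsonism
#' or G25.1 drug-induced tremor; primary or secondary position) within the
#' accrual window -- the earliest such date is the index date; (2) no DIP
#' diagnosis in the washout window `[index - washout_days, index - 1]`
#' (a DIP code on the index date itself is the index event, not an
#' exclusion); (3) at least one outpatient offending-drug prescription whose
#' supply interval contains the index date.
#'
#' Baseline covariates are computed as of the index date: age band (index
#' year minus birth year), sex, insurance, income decile, disability,
#' Charlson comorbidity index over the configured lookback (excluding the
#' index date), and a Parkinson's disease flag over its lookback (including
#' the index date). Patients whose enrollment does not cover the full
#' washout window are flagged (`short_lookback`), not excluded.
#'
#' @param bundle A validated `"claims_bundle"`.
#' @param config A [study_config()].
#' @return List with `cohort` (one row per included patient) and
#'   `exclusions` (patient_id, reason) tibbles.
#' @export
select_incident_cases <- function(bundle, config = study_config()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dx <- bundle$diagnoses
  if (nrow(dx) == 0L)
    warning("empty diagnosis table: no candidates, returning empty cohort")
  is_dip <- icd10_matches(dx$icd10, config$dip_codes)
  if (length(is_dip) == 0L) is_dip <- logical(0)

  en <- as.data.frame(bundle$enrollment)
  rx_df <- as.data.frame(bundle$prescriptions)
  dx_df <- as.data.frame(dx)
  rx_split <- split(seq_len(nrow(rx_df)), rx_df$patient_id)
  dx_split <- split(seq_len(nrow(dx_df)), dx_df$patient_id)
  pids <- sort(unique(en$patient_id))
  en_at <- match(pids, en$patient_id)

  keep <- logical(length(pids))
  index_date <- rep(as.Date(NA), length(pids))
  index_class <- character(length(pids)); tie <- logical(length(pids))
  cci <- integer(length(pids)); pd <- logical(length(pids))
  excl_reason <- character(length(pids))
  for (k in seq_along(pids)) {
    pid <- pids[k]
    pdx <- dx_df[dx_split[[pid]] %||% integer(0), , drop = FALSE]
    dip_dates <- sort(pdx$date[icd10_matches(pdx$icd10, config$dip_codes)])
    in_accrual <- dip_dates[dip_dates >= config$accrual_start &
                              dip_dates <= config$accrual_end]
    if (length(in_accrual) == 0L) {
      excl_reason[k] <- "no_dip_diagnosis_in_accrual"
      next
    }
    idx <- in_accrual[1]
    if (any(dip_dates >= idx - config$washout_days & dip_dates <= idx - 1L)) {
      excl_reason[k] <- "washout"
      next
    }
    prx <- rx_df[rx_split[[pid]] %||% integer(0), , drop = FALSE]
    cls <- classify_drug(prx$substance, config)
    qualifies <- !is.na(cls) & prx$setting == "outpatient" &
      covers_date(prx, idx)
    if (!any(qualifies)) {
      excl_reason[k] <- "no_overlapping_prescription"
      next
    }
    ic <- assign_index_class(prx, idx, config)
    keep[k] <- TRUE
    index_date[k] <- idx
    index_class[k] <- as.character(ic)
    tie[k] <- attr(ic, "tie")
    cci[k] <- charlson_index(pdx, idx, config$cci_lookback_days)
    pd[k] <- pd_flag(pdx, idx, config$pd_lookback_days, config$pd_code)
  }
  ek <- en_at[keep]
  age <- as.integer(format(index_date[keep], "%Y")) - en$birth_year[ek]
  cohort <- tibble::tibble(
    patient_id = pids[keep],
    index_date = index_date[keep],
    index_class = index_class[keep],
    index_class_tie = tie[keep],
    age = age,
    age_band = as.character(age_band(age)),
    sex = en$sex[ek],
    insurance = en$insurance[ek],
    income_decile = en$income_decile[ek],
    disability = en$disability[ek],
    cci = cci[keep],
    pd = pd[keep],
    short_lookback = en$observation_start[ek] > index_date[keep] - config$washout_days
  )
  exclusions <- tibble::tibble(patient_id = pids[!keep],
                               reason = excl_reason[!keep])
  list(cohort = cohort, exclusions = exclusions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
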