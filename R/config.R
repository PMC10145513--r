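#' Default offending-drug lists
#'
#' The three therapeutic classes with an established risk of drug-induced
#' parkinsonism that were available in South Korea during 2002--2015:
#' 13 typical and atypical antipsychotics, 6 gastrointestinal (GI) motility
#' drugs, and flunarizine. Substances are normalized lowercase names; the
#' lists are mutually exclusive.
#'
#' @return Named character vector mapping substance to offending class
#'   (`"antipsychotic"`, `"gi_motility"`, `"flunarizine"`).
#' @export
default_offending_drugs <- function() {
  antipsychotics <- c(
    "amisulpride", "aripiprazole", "chlorpromazine", "clozapine",
    "haloperidol", "olanzapine", "paliperidone", "perphenazine",
    "pimozide", "quetiapine", "risperidone", "sulpiride", "ziprasidone"
  )
  gi_motility <- c(
    "clebopride", "domperidone", "itopride", "levosulpiride",
    "metoclopramide", "mosapride"
  )
  stats::setNames(
    c(rep("antipsychotic", length(antipsychotics)),
      rep("gi_motility", length(gi_motility)),
      "flunarizine"),
    c(antipsychotics, gi_motility, "flunarizine")
  )
}

#' Offending-class labels in tie-break priority order
#' @keywords internal
offending_classes <- function() c("antipsychotic", "gi_motility", "flunarizine")

#' Study configuration
#'
#' Assembles the design parameters of the analysis: the accrual and data
#' windows, washout and follow-up lengths, the permissible-gap rule for drug
#' eras, the diagnosis-episode gap, comorbidity lookback windows, the
#' diagnosis code sets and the offending-drug lists.
#'
#' All windows are in days; "two years" is 730 days and "one year" 365 days
#' so that window arithmetic is deterministic (calendar-month arithmetic
#' varies with month length).
#'
#' @param accrual_start,accrual_end Accrual window for the index diagnosis
#'   (defaults 2004-01-01 to 2013-12-31).
#' @param data_start,data_end Observable data window (defaults 2002-01-01 to
#'   2015-12-31); the two pre-accrual years provide washout lookback.
#' @param washout_days Length of the pre-index period that must be free of
#'   DIP diagnoses for the case to be incident (default 730).
#' @param followup_days Follow-up length from the index date (default 730).
#' @param era_gap_days Maximum uncovered gap, in days, between consecutive
#'   prescriptions that still counts as continued use (default 60).
#' @param dip_episode_gap_days Maximum gap between DIP diagnosis dates within
#'   one episode; a longer diagnosis-free run is a remittance (default 120,
#'   i.e. 4 months).
#' @param cci_lookback_days Charlson comorbidity lookback before the index
#'   date, exclusive of the index date itself (default 365).
#' @param pd_lookback_days Parkinson's disease (G20) lookback, inclusive of
#'   the index date (default 730).
#' @param dip_codes Normalized ICD-10 prefixes defining DIP
#'   (default `c("G211", "G251")`).
#' @param pd_code Normalized ICD-10 prefix for Parkinson's disease
#'   (default `"G20"`).
#' @param offending_drugs Named character vector, substance -> class; defaults
#'   to [default_offending_drugs()].
#' @param dose_tolerance Relative tolerance when comparing total daily doses
#'   (default 1e-6; claims doses are exact rationals, the tolerance guards
#'   float I/O).
#' @return A list of class `"dip_config"`.
#' @export
study_config <- function(accrual_start = as.Date("2004-01-01"),
                         accrual_end = as.Date("2013-12-31"),
                         data_start = as.Date("2002-01-01"),
                         data_end = as.Date("2015-12-31"),
                         washout_days = 730L,
                         followup_days = 730L,
                         era_gap_days = 60L,
                         dip_episode_gap_days = 120L,
                         cci_lookback_days = 365L,
                         pd_lookback_days = 730L,
                         dip_codes = c("G211", "G251"),
                         pd_code = "G20",
                         offending_drugs = default_offending_drugs(),
                         dose_tolerance = 1e-6) {
  cfg <- list(
    accrual_start = as.Date(accrual_start),
    accrual_end = as.Date(accrual_end),
    data_start = as.Date(data_start),
    data_end = as.Date(data_end),
    washout_days = as.integer(washout_days),
    followup_days = as.integer(followup_days),
    era_gap_days = as.integer(era_gap_days),
    dip_episode_gap_days = as.integer(dip_episode_gap_days),
    cci_lookback_days = as.integer(cci_lookback_days),
    pd_lookback_days = as.integer(pd_lookback_days),
    dip_codes = vapply(dip_codes, normalize_icd10, character(1), USE.NAMES = FALSE),
    pd_code = normalize_icd10(pd_code),
    offending_drugs = offending_drugs,
    dose_tolerance = dose_tolerance
  )
  class(cfg) <- "dip_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  windows <- c("washout_days", "followup_days", "era_gap_days",
               "dip_episode_gap_days", "cci_lookback_days", "pd_lookback_days")
  for (w in windows) {
    if (!is.finite(cfg[[w]]) || cfg[[w]] <= 0L)
      stop("config error: ", w, " must be a positive number of days", call. = FALSE)
  }
  if (length(cfg$dip_codes) == 0L)
    stop("config error: dip_codes must be nonempty", call. = FALSE)
  drugs <- cfg$offending_drugs
  if (is.null(names(drugs)) || any(names(drugs) == ""))
    stop("config error: offending_drugs must be a named substance -> class vector",
         call. = FALSE)
  if (anyDuplicated(names(drugs)))
    stop("config error: offending-drug lists must be disjoint (duplicate substance: ",
         paste(unique(names(drugs)[duplicated(names(drugs))]), collapse = ", "), ")",
         call. = FALSE)
  if (!all(drugs %in% offending_classes()))
    stop("config error: unknown offending class in drug list", call. = FALSE)
  invisible(cfg)
}

#' Read a study configuration from a YAML (or JSON-as-YAML) document
#'
#' Fields mirror [study_config()] arguments; absent fields keep their
#' defaults. `offending_drugs` may be given as a mapping class -> substance
#' list, which is flattened to the substance -> class form.
#'
#' @param path Path to the YAML file.
#' @return A `"dip_config"` list.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # flatten class -> substances mapping if present
  if (!is.null(raw$offending_drugs) && is.list(raw$offending_drugs)) {
    od <- raw$offending_drugs
    raw$offending_drugs <- stats::setNames(
      rep(names(od), lengths(od)), unlist(od, use.names = FALSE))
  }
  args <- raw[intersect(names(raw), names(formals(study_config)))]
  for (d in c("accrual_start", "accrual_end", "data_start", "data_end"))
    if (!is.null(args[[d]])) args[[d]] <- as.Date(args[[d]])
  do.call(study_config, args)
}
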