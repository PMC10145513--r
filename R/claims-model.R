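#' Normalize an ICD-10 code
#'
#' Uppercases the code and strips the dot, so `"g21.1"` becomes `"G211"`.
#' Downstream matching is by exact prefix on the normalized form: a recorded
#' sub-code such as `"G2110"` matches the study code `"G211"`.
#'
#' @param raw_code Character vector of raw codes.
#' @return Normalized codes. Idempotent.
#' @export
#' @examples
#' normalize_icd10("g21.1")  # "G211"
normalize_icd10 <- function(raw_code) {
  if (length(raw_code) == 0L) return(character(0))
  if (any(is.na(raw_code)) || any(!nzchar(trimws(raw_code))))
    stop("validation error: empty ICD-10 code", call. = FALSE)
  out <- toupper(gsub(".", "", trimws(raw_code), fixed = TRUE))
  if (any(!grepl("^[A-Z][0-9A-Z]*$", out)))
    stop("validation error: malformed ICD-10 code: ",
         paste(raw_code[!grepl("^[A-Z][0-9A-Z]*$", out)], collapse = ", "),
         call. = FALSE)
  out
}

#' Does a normalized code match any of a set of code prefixes?
#' @keywords internal
icd10_matches <- function(codes, prefixes) {
  if (length(codes) == 0L) return(logical(0))
  Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
}

#' Classify a substance into its offending-drug class
#'
#' @param substance Character vector of normalized lowercase substance names.
#' @param config A [study_config()].
#' @return Character vector: `"antipsychotic"`, `"gi_motility"`,
#'   `"flunarizine"`, or `NA` for substances on none of the lists
#'   (e.g. nizatidine).
#' @export
classify_drug <- function(substance, config = study_config()) {
  unname(config$offending_drugs[substance])
}

prescription_columns <- c("patient_id", "substance", "start_date",
                          "days_supply", "daily_dose", "setting")
diagnosis_columns <- c("patient_id", "icd10", "date", "position")
enrollment_columns <- c("patient_id", "observation_start", "observation_end",
                        "birth_year", "sex", "insurance", "income_decile",
                        "disability")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

parse_date_column <- function(x, what, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) | is.na(x))
  if (length(bad))
    stop("row-level error in ", what, ", column ", col, ", row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": unparseable date", call. = FALSE)
  d
}

row_check <- function(ok, what, msg) {
  bad <- which(!ok)
  if (length(bad))
    stop("row-level error in ", what, ", row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ", msg, call. = FALSE)
}

#' Validate a claims bundle
#'
#' Checks schema and record-level invariants: positive integer days of
#' supply, positive daily dose, known setting/position/sex levels, ordered
#' enrollment windows, income decile in 0--10, and normalizes ICD-10 codes
#' and substance names in place.
#'
#' @param prescriptions,diagnoses,enrollment Data frames with the documented
#'   columns.
#' @return A list of class `"claims_bundle"` with elements `prescriptions`,
#'   `diagnoses`, `enrollment` as tibbles with parsed dates.
#' @export
validate_claims <- function(prescriptions, diagnoses, enrollment) {
  check_columns(prescriptions, prescription_columns, "prescriptions")
  check_columns(diagnoses, diagnosis_columns, "diagnoses")
  check_columns(enrollment, enrollment_columns, "enrollment")

  rx <- tibble::as_tibble(prescriptions)[prescription_columns]
  rx$patient_id <- as.character(rx$patient_id)
  rx$substance <- tolower(trimws(as.character(rx$substance)))
  if (!inherits(rx$start_date, "Date"))
    rx$start_date <- parse_date_column(rx$start_date, "prescriptions", "start_date")
  rx$days_supply <- as.integer(rx$days_supply)
  row_check(!is.na(rx$days_supply) & rx$days_supply >= 1L,
            "prescriptions", "days_supply must be an integer >= 1")
  rx$daily_dose <- as.numeric(rx$daily_dose)
  row_check(!is.na(rx$daily_dose) & rx$daily_dose > 0,
            "prescriptions", "daily_dose must be > 0")
  if (!all(rx$setting %in% c("outpatient", "inpatient")))
    stop("schema error in prescriptions: unknown setting value(s): ",
         paste(unique(setdiff(rx$setting, c("outpatient", "inpatient"))),
               collapse = ", "), call. = FALSE)

  dx <- tibble::as_tibble(diagnoses)[diagnosis_columns]
  dx$patient_id <- as.character(dx$patient_id)
  dx$icd10 <- normalize_icd10(as.character(dx$icd10))
  if (!inherits(dx$date, "Date"))
    dx$date <- parse_date_column(dx$date, "diagnoses", "date")
  if (!all(dx$position %in% c("primary", "secondary")))
    stop("schema error in diagnoses: unknown position value(s): ",
         paste(unique(setdiff(dx$position, c("primary", "secondary"))),
               collapse = ", "), call. = FALSE)

  en <- tibble::as_tibble(enrollment)[enrollment_columns]
  en$patient_id <- as.character(en$patient_id)
  if (!inherits(en$observation_start, "Date"))
    en$observation_start <- parse_date_column(en$observation_start,
                                              "enrollment", "observation_start")
  if (!inherits(en$observation_end, "Date"))
    en$observation_end <- parse_date_column(en$observation_end,
                                            "enrollment", "observation_end")
  row_check(en$observation_start <= en$observation_end,
            "enrollment", "observation_start after observation_end")
  en$birth_year <- as.integer(en$birth_year)
  row_check(!is.na(en$birth_year), "enrollment", "unparseable birth_year")
  if (!all(en$sex %in% c("male", "female")))
    stop("schema error in enrollment: unknown sex value(s)", call. = FALSE)
  if (!all(en$insurance %in% c("national_health_insurance", "medical_aid")))
    stop("schema error in enrollment: unknown insurance value(s)", call. = FALSE)
  en$income_decile <- as.integer(en$income_decile)
  row_check(!is.na(en$income_decile) & en$income_decile >= 0L & en$income_decile <= 10L,
            "enrollment", "income_decile must be in 0..10")
  if (!all(en$disability %in% c("none", "mild", "severe")))
    stop("schema error in enrollment: unknown disability value(s)", call. = FALSE)
  row_check(!duplicated(en$patient_id), "enrollment",
            "duplicate patient_id in enrollment")

  structure(list(prescriptions = rx, diagnoses = dx, enrollment = en),
            class = "claims_bundle")
}

#' Read a claims bundle from delimited text files
#'
#' Files are UTF-8 comma-separated with a header row, one record type per
#' file; dates are ISO-8601. All records are validated on read.
#'
#' @param prescriptions_path,diagnoses_path,enrollment_path File paths.
#' @param config A [study_config()]; currently only carried along for
#'   downstream steps.
#' @return A validated `"claims_bundle"`.
#' @export
read_claims <- function(prescriptions_path, diagnoses_path, enrollment_path,
                        config = study_config()) {
  for (p in c(prescriptions_path, diagnoses_path, enrollment_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  rx <- utils::read.csv(prescriptions_path, colClasses = "character",
                        fileEncoding = "UTF-8")
  dx <- utils::read.csv(diagnoses_path, colClasses = "character",
                        fileEncoding = "UTF-8")
  en <- utils::read.csv(enrollment_path, colClasses = "character",
                        fileEncoding = "UTF-8")
  validate_claims(rx, dx, en)
}

#' Write a claims bundle to a directory
#'
#' Emits `prescriptions.csv`, `diagnoses.csv`, `enrollment.csv` in the
#' documented schema; [read_claims()] on the output reproduces the bundle
#' exactly.
#'
#' @param bundle A `"claims_bundle"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_claims <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("prescriptions.csv", "diagnoses.csv", "enrollment.csv"))
  write_csv_plain(bundle$prescriptions, paths[1])
  write_csv_plain(bundle$diagnoses, paths[2])
  write_csv_plain(bundle$enrollment, paths[3])
  invisible(paths)
}

#' Write a table as plain deterministic CSV
#'
#' Locale-independent writer used for every file the pipeline emits: dates
#' are formatted ISO-8601, nothing is quoted, row names are dropped.
#'
#' @param df Data frame or tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_csv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (inherits(df[[j]], "Date"))
    df[[j]] <- format(df[[j]], "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Half-open supply interval helpers
#'
#' A prescription covers the day range `[start_date, start_date +
#' days_supply)`: the supply end is exclusive, so a 30-day supply starting
#' day 0 covers days 0..29 and ends on day 30.
#'
#' @param rx Prescription tibble.
#' @return `supply_end()` returns the exclusive end date;
#'   `covers_date()` a logical vector.
#' @name supply-interval
NULL

#' @rdname supply-interval
#' @export
supply_end <- function(rx) rx$start_date + rx$days_supply

#' @rdname supply-interval
#' @param date A single date.
#' @export
covers_date <- function(rx, date) {
  rx$start_date <= date & date < supply_end(rx)
}
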