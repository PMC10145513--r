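# Independent brute-force oracles. These deliberately share no code with the
# implementation: eras and treatment changes are replayed on an explicit day
# grid, episodes by a direct gap scan, quartiles by hand interpolation.

# day-grid regimen: loop over prescriptions, sum doses covering the date
oracle_regimen <- function(rx, date) {
  out <- list()
  for (i in seq_len(nrow(rx))) {
    if (rx$start_date[i] <= date &&
        date < rx$start_date[i] + rx$days_supply[i]) {
      s <- rx$substance[i]
      out[[s]] <- (out[[s]] %||% 0) + rx$daily_dose[i]
    }
  }
  if (length(out) == 0L) return(stats::setNames(numeric(0), character(0)))
  v <- unlist(out)
  v[sort(names(v))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mark covered days on a grid, close uncovered runs <= gap, extract blocks;
# returns day offsets relative to `anchor` (start inclusive, end exclusive)
oracle_eras <- function(starts, supplies, gap) {
  lo <- min(starts)
  cov <- rep(FALSE, max(starts + supplies) - lo)
  for (i in seq_along(starts))
    cov[(starts[i] - lo + 1L):(starts[i] + supplies[i] - lo)] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  blocks <- list(); cur <- NULL
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) {
      if (is.null(cur)) cur <- c(begins[j], ends[j]) else cur[2] <- ends[j]
    } else if (r$lengths[j] > gap && !is.null(cur)) {
      blocks <- c(blocks, list(cur)); cur <- NULL
    }
  }
  if (!is.null(cur)) blocks <- c(blocks, list(cur))
  data.frame(start = vapply(blocks, `[`, numeric(1), 1) - 1L + lo,
             end = vapply(blocks, `[`, numeric(1), 2) + lo)
}

# replay the follow-up day grid as a state machine: track the last non-empty
# regimen and the uncovered-run length; the first change falls out directly
oracle_change <- function(rx, index_date, followup = 730L, gap = 60L,
                          tol = 1e-6) {
  cmp <- function(a, b) {
    if (!identical(names(a), names(b))) return("switch")
    if (length(a) && any(abs(a - b) / pmax(abs(a), abs(b)) > tol)) return("dose")
    "same"
  }
  regs <- lapply(0:(followup - 1L), function(d) oracle_regimen(rx, index_date + d))
  prev <- regs[[1L]]
  stopifnot(length(prev) > 0L) # index day must be covered
  gap_len <- 0L
  for (d in seq_len(followup - 1L)) {
    cur <- regs[[d + 1L]]
    if (length(cur) == 0L) { gap_len <- gap_len + 1L; next }
    verdict <- cmp(prev, cur)
    if (gap_len > gap) {
      subtype <- switch(verdict, switch = "within_class_switch",
                        dose = "same_drug_dose_adjusted",
                        same = "same_drug_same_dose")
      return(list(category = "reinitiation", subtype = subtype, day = d))
    }
    if (verdict == "switch")
      return(list(category = "switching", subtype = NA_character_, day = d))
    if (verdict == "dose")
      return(list(category = "dose_adjustment", subtype = NA_character_, day = d))
    prev <- cur; gap_len <- 0L
  }
  covered <- vapply(regs, length, integer(1)) > 0L
  era_end <- max(which(covered)) # first uncovered day offset (1-based index - 1 + 1)
  if (followup - era_end > gap)
    list(category = "discontinuation", subtype = NA_character_, day = era_end)
  else
    list(category = "persistent_use", subtype = NA_character_, day = NA_integer_)
}

# direct gap scan over sorted diagnosis-day offsets
oracle_episodes <- function(days, gap, followup = 730L) {
  d <- sort(unique(days))
  eps <- list(); cur <- d[1]
  for (x in d[-1]) {
    if (x - cur[length(cur)] > gap) { eps <- c(eps, list(cur)); cur <- x }
    else cur <- c(cur, x)
  }
  eps <- c(eps, list(cur))
  data.frame(
    first = vapply(eps, min, numeric(1)),
    last = vapply(eps, max, numeric(1)),
    remitted = vapply(seq_along(eps), function(i) {
      bound <- if (i < length(eps)) min(eps[[i + 1]]) else followup
      bound - max(eps[[i]]) > gap
    }, logical(1))
  )
}

oracle_prognosis <- function(days, gap = 120L, followup = 730L) {
  eps <- oracle_episodes(days, gap, followup)
  if (!eps$remitted[1]) return(list(category = "persisting",
                                    ttr = NA_integer_, ttrec = NA_integer_))
  if (nrow(eps) >= 2L) return(list(category = "recurrence",
                                   ttr = eps$last[1], ttrec = eps$first[2]))
  list(category = "remittance", ttr = eps$last[1], ttrec = NA_integer_)
}

# direct check of the three incident-case criteria for every enrolled patient
oracle_eligibility <- function(bundle, cfg) {
  pids <- sort(unique(bundle$enrollment$patient_id))
  vapply(pids, function(pid) {
    dx <- bundle$diagnoses[bundle$diagnoses$patient_id == pid, ]
    dip <- dx$date[Reduce(`|`, lapply(cfg$dip_codes,
                                      function(p) startsWith(dx$icd10, p)))]
    cand <- sort(dip[dip >= cfg$accrual_start & dip <= cfg$accrual_end])
    if (length(cand) == 0L) return(FALSE)
    idx <- cand[1]
    if (any(dip >= idx - cfg$washout_days & dip <= idx - 1L)) return(FALSE)
    rx <- bundle$prescriptions[bundle$prescriptions$patient_id == pid, ]
    cls <- unname(cfg$offending_drugs[rx$substance])
    any(!is.na(cls) & rx$setting == "outpatient" & rx$start_date <= idx &
          idx < rx$start_date + rx$days_supply)
  }, logical(1))
}

# sort-and-interpolate quartiles (linear interpolation between order stats)
oracle_quartile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# matrix-based replay of the same day grid, for bulk equivalence checks:
# doses are accumulated into a followup x substance matrix and the state
# machine walks its rows
oracle_change_fast <- function(rx, index_date, followup = 730L, gap = 60L,
                               tol = 1e-6) {
  subs <- sort(unique(rx$substance))
  M <- matrix(0, nrow = followup, ncol = length(subs),
              dimnames = list(NULL, subs))
  d0 <- as.integer(rx$start_date - index_date)
  d1 <- d0 + rx$days_supply - 1L
  for (i in seq_len(nrow(rx))) {
    lo <- max(0L, d0[i]); hi <- min(followup - 1L, d1[i])
    if (lo <= hi) {
      j <- match(rx$substance[i], subs)
      M[(lo:hi) + 1L, j] <- M[(lo:hi) + 1L, j] + rx$daily_dose[i]
    }
  }
  active <- M > 0
  any_active <- rowSums(active) > 0L
  stopifnot(any_active[1L])
  cmp_rows <- function(a, b) {
    if (!identical(which(active[a, ]), which(active[b, ]))) return("switch")
    va <- M[a, active[a, ]]; vb <- M[b, active[b, ]]
    if (any(abs(va - vb) / pmax(abs(va), abs(vb)) > tol)) return("dose")
    "same"
  }
  prev <- 1L; gap_len <- 0L
  for (d in 2:followup) {
    if (!any_active[d]) { gap_len <- gap_len + 1L; next }
    verdict <- cmp_rows(prev, d)
    if (gap_len > gap)
      return(list(category = "reinitiation",
                  subtype = switch(verdict, switch = "within_class_switch",
                                   dose = "same_drug_dose_adjusted",
                                   same = "same_drug_same_dose"),
                  day = d - 1L))
    if (verdict == "switch")
      return(list(category = "switching", subtype = NA_character_, day = d - 1L))
    if (verdict == "dose")
      return(list(category = "dose_adjustment", subtype = NA_character_,
                  day = d - 1L))
    prev <- d; gap_len <- 0L
  }
  era_end <- max(which(any_active)) # last covered day is era_end - 1 as offset
  if (followup - era_end > gap)
    list(category = "discontinuation", subtype = NA_character_, day = era_end)
  else
    list(category = "persistent_use", subtype = NA_character_, day = NA_integer_)
}
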