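# New-user cohort selection: index date with one-year antidepressant washout,
# fixed-precedence eligibility rules, treatment-episode construction (episode
# closed by a > 120-day dispensing gap), and the follow-up window.

#' Cohort-builder configuration
#'
#' @param accrual_start,accrual_end Accrual window for index dates (ISO
#'   strings or Dates). Defaults 2015-01-01 to 2017-12-31.
#' @param study_end Administrative end of follow-up; default 2018-12-31.
#' @param washout_days Required antidepressant-free days before index (365).
#' @param episode_gap_days Drug-free days (between the end of one supply run
#'   and the next dispense) that close a treatment episode when exceeded (120).
#' @param age_min,age_max Inclusive age bounds at index (18, 64).
#' @return Named list of class `adc_cohort_config`.
#' @export
cohort_config <- function(accrual_start = "2015-01-01",
                          accrual_end = "2017-12-31",
                          study_end = "2018-12-31",
                          washout_days = 365L, episode_gap_days = 120L,
                          age_min = 18L, age_max = 64L) {
  cfg <- list(accrual_start = as.Date(accrual_start),
              accrual_end = as.Date(accrual_end),
              study_end = as.Date(study_end),
              washout_days = as.integer(washout_days),
              episode_gap_days = as.integer(episode_gap_days),
              age_min = as.integer(age_min), age_max = as.integer(age_max))
  if (cfg$accrual_start > cfg$accrual_end)
    stop("accrual_start is after accrual_end", call. = FALSE)
  if (cfg$accrual_end > cfg$study_end)
    stop("accrual window extends past study_end", call. = FALSE)
  structure(cfg, class = "adc_cohort_config")
}

#' Find a patient's index date
#'
#' The index date is the first antidepressant dispense date inside the
#' accrual window preceded by at least `washout_days` antidepressant-free
#' days. All antidepressants dispensed on that date are returned so that
#' multi-drug initiation can be excluded downstream.
#'
#' @param rx Prescriptions of one patient (`drug_id`, `dispense_date`,
#'   `days_supplied`).
#' @param catalog An `adc_catalog` used to restrict to antidepressants.
#' @param config A [cohort_config()].
#' @return `NULL` when no date qualifies, else a list with `index_date`
#'   (Date) and `index_drugs` (character vector).
#' @export
find_index <- function(rx, catalog, config = cohort_config()) {
  rx <- as.data.table(rx)
  known <- rx$drug_id %in% catalog$drug_id
  ad <- rx[known][is_antidepressant(catalog, drug_id)]
  if (nrow(ad) == 0L) return(NULL)
  d <- sort(unique(.as_day(ad$dispense_date)))
  lo <- .as_day(config$accrual_start); hi <- .as_day(config$accrual_end)
  for (day in d[d >= lo & d <= hi]) {
    prior <- d[d < day & d >= day - config$washout_days]
    if (length(prior) == 0L) {
      drugs <- sort(unique(ad[.as_day(dispense_date) == day, drug_id]))
      return(list(index_date = .as_date(day), index_drugs = drugs))
    }
  }
  NULL
}

#' Construct the treatment-episode end for one patient
#'
#' Scanning antidepressant dispenses from the index date, the episode ends at
#' the last covered day of the supply run preceding the first drug-free gap
#' longer than `gap_days` (gap measured between the end of one supply run and
#' the next dispense date), capped at `study_end`.
#'
#' @param rx Antidepressant prescriptions of one patient.
#' @param index_date Index date.
#' @param config A [cohort_config()].
#' @return Episode end (Date).
#' @export
build_episode <- function(rx, index_date, config = cohort_config()) {
  rx <- as.data.table(rx)
  idx <- .as_day(index_date)
  d <- rx[, .(s = .as_day(dispense_date),
              e = .as_day(dispense_date) + as.integer(days_supplied) - 1L)]
  d <- d[s >= idx]
  setorder(d, s)
  cur_end <- d$e[1L]
  if (nrow(d) > 1L) for (i in 2L:nrow(d)) {
    if (d$s[i] - cur_end - 1L > config$episode_gap_days) break
    cur_end <- max(cur_end, d$e[i])
  }
  .as_date(min(cur_end, .as_day(config$study_end)))
}

.exclusion_levels <- c("none", "prior_ect", "bipolar_or_schizo", "cns_disease",
                       "age", "no_mdd_dx", "multi_drug_index",
                       "washout_violation")

# completed calendar years between two integer days (birthday convention)
.calendar_age <- function(birth_day, at_day) {
  b <- as.POSIXlt(.as_date(birth_day)); a <- as.POSIXlt(.as_date(at_day))
  a$year - b$year - as.integer(a$mon < b$mon | (a$mon == b$mon & a$mday < b$mday))
}

.dx_match <- function(codes, prefixes) {
  pat <- paste0("^(", paste(prefixes, collapse = "|"), ")")
  grepl(pat, codes)
}

#' Apply the eligibility rules to one indexed patient
#'
#' Rules are checked in fixed precedence order and the first failure is
#' recorded: prior ECT; bipolar/schizophrenia codes (F30.x, F31.x, F20.x)
#' during baseline or follow-up; CNS disease (F00.x-F09.x) during baseline or
#' follow-up; age 18-64 at index; an MDD code (F32.x/F33.x) during baseline
#' (inclusive of the index date); multi-drug index.
#'
#' @param patient One-row demographics (`birth_date`, `sex`).
#' @param dx Diagnoses of the patient (`icd10_code`, `date`).
#' @param proc Procedures of the patient (`code`, `date`).
#' @param index List from [find_index()].
#' @param follow_up_end Date; needed because some exclusions look at
#'   follow-up diagnoses.
#' @param config A [cohort_config()].
#' @return List with `exclusion_reason` (one of
#'   `none, prior_ect, bipolar_or_schizo, cns_disease, age, no_mdd_dx,
#'   multi_drug_index`) and `age_at_index`.
#' @export
apply_eligibility <- function(patient, dx, proc, index, follow_up_end,
                              config = cohort_config()) {
  if (is.null(patient$birth_date) || is.na(patient$birth_date) ||
      is.null(patient$sex) || is.na(patient$sex))
    stop("patient record is missing birth_date or sex", call. = FALSE)
  idx <- .as_day(index$index_date)
  fup <- .as_day(follow_up_end)
  base_lo <- idx - config$washout_days
  if (is.null(dx) || !nrow(as.data.table(dx)))
    dx <- data.table(icd10_code = character(), date = as.Date(character()))
  if (is.null(proc) || !nrow(as.data.table(proc)))
    proc <- data.table(code = character(), date = as.Date(character()))
  dxw <- as.data.table(dx)
  dxw <- dxw[.as_day(date) >= base_lo & .as_day(date) <= fup]
  age <- .calendar_age(.as_day(patient$birth_date), idx)

  reason <- "none"
  if (nrow(as.data.table(proc)[code == "ECT" & .as_day(date) < idx])) {
    reason <- "prior_ect"
  } else if (any(.dx_match(dxw$icd10_code, c("F20", "F30", "F31")))) {
    reason <- "bipolar_or_schizo"
  } else if (any(.dx_match(dxw$icd10_code, paste0("F0", 0:9)))) {
    reason <- "cns_disease"
  } else if (age < config$age_min || age > config$age_max) {
    reason <- "age"
  } else if (!any(.dx_match(dxw[.as_day(date) <= idx]$icd10_code,
                            c("F32", "F33")))) {
    reason <- "no_mdd_dx"
  } else if (length(index$index_drugs) >= 2L) {
    reason <- "multi_drug_index"
  }
  list(exclusion_reason = reason, age_at_index = as.integer(age))
}

#' Build the new-user cohort from record tables
#'
#' Screens every patient appearing in the prescriptions table: assigns the
#' index date (one-year washout), builds the treatment episode and follow-up
#' window, and applies the eligibility rules in fixed precedence order.
#' Patients whose first in-window antidepressant dispense violates the
#' washout (and who never qualify later) are recorded with reason
#' `washout_violation`; patients with no antidepressant in the accrual
#' window at all are not screened.
#'
#' @param tables List of record tables: `patients`, `prescriptions`,
#'   `diagnoses`, `visits`, `procedures` (as produced by
#'   [generate_population()] or read from delimited files).
#' @param catalog An `adc_catalog`.
#' @param config A [cohort_config()].
#' @return A `data.table`, one row per screened patient: `patient_id`,
#'   `index_date`, `index_drug` (`+`-joined when multiple), `age_at_index`,
#'   `sex`, `index_setting`, `episode_end`, `follow_up_end`,
#'   `exclusion_reason`.
#' @export
build_cohort <- function(tables, catalog = load_drug_catalog(),
                         config = cohort_config()) {
  rx <- as.data.frame(tables$prescriptions)
  pat <- as.data.frame(tables$patients)
  dx <- as.data.frame(tables$diagnoses)
  proc <- as.data.frame(tables$procedures)
  vis <- as.data.frame(tables$visits)

  is_ad <- stats::setNames(catalog$is_antidepressant, catalog$drug_id)
  rx_drug <- as.character(rx$drug_id)
  ad_flag <- !is.na(is_ad[rx_drug]) & is_ad[rx_drug]
  r_id <- as.character(rx$patient_id)[ad_flag]
  r_drug <- rx_drug[ad_flag]
  r_day <- .as_day(rx$dispense_date)[ad_flag]
  r_sup <- as.integer(rx$days_supplied)[ad_flag]
  rx_by <- split(seq_along(r_id), r_id)

  d_id <- as.character(dx$patient_id)
  d_code <- as.character(dx$icd10_code)
  d_day <- .as_day(dx$date)
  dx_by <- split(seq_along(d_id), d_id)
  p_id <- as.character(proc$patient_id)
  p_ect <- as.character(proc$code) == "ECT"
  p_day <- .as_day(proc$date)
  proc_by <- split(seq_along(p_id), p_id)
  v_id <- as.character(vis$patient_id)
  v_day <- .as_day(vis$date)
  v_inp <- as.character(vis$setting) == "inpatient"
  vis_by <- split(seq_along(v_id), v_id)

  birth <- stats::setNames(.as_day(pat$birth_date), as.character(pat$patient_id))
  sexv <- stats::setNames(as.character(pat$sex), as.character(pat$patient_id))

  lo <- .as_day(config$accrual_start); hi <- .as_day(config$accrual_end)
  send <- .as_day(config$study_end)
  wash <- config$washout_days; gap <- config$episode_gap_days

  ids <- names(rx_by)
  n <- length(ids)
  o_id <- character(n); o_idx <- integer(n); o_drug <- character(n)
  o_age <- integer(n); o_sex <- character(n); o_set <- character(n)
  o_epi <- integer(n); o_fup <- integer(n); o_reason <- character(n)
  keep_row <- logical(n)

  for (k in seq_len(n)) {
    pid <- ids[k]
    w <- rx_by[[pid]]
    days <- r_day[w]
    inwin <- days >= lo & days <= hi
    if (!any(inwin)) next  # no antidepressant in accrual window: not screened
    keep_row[k] <- TRUE
    o_id[k] <- pid; o_sex[k] <- sexv[pid]

    ud <- sort(unique(days))
    idx <- NA_integer_
    for (day in ud[ud >= lo & ud <= hi]) {
      if (!any(ud < day & ud >= day - wash)) { idx <- day; break }
    }
    if (is.na(idx)) {
      o_reason[k] <- "washout_violation"
      o_idx[k] <- NA_integer_; o_epi[k] <- NA_integer_; o_fup[k] <- NA_integer_
      o_drug[k] <- NA_character_; o_age[k] <- NA_integer_
      o_set[k] <- NA_character_
      next
    }
    o_idx[k] <- idx
    o_drug[k] <- paste(sort(unique(r_drug[w][days == idx])), collapse = "+")
    idx_drugs_n <- length(unique(r_drug[w][days == idx]))

    # episode: gap measured from end of supply run to next dispense
    sup <- r_sup[w]
    post <- which(days >= idx)
    oo <- post[order(days[post])]
    ds <- days[oo]; de <- ds + sup[oo] - 1L
    cur_end <- de[1L]
    if (length(oo) > 1L) for (j in 2L:length(oo)) {
      if (ds[j] - cur_end - 1L > gap) break
      if (de[j] > cur_end) cur_end <- de[j]
    }
    epi <- min(cur_end, send)
    fup <- min(epi, send)
    o_epi[k] <- epi; o_fup[k] <- fup

    # eligibility, fixed precedence
    dxi <- dx_by[[pid]]
    codes <- if (is.null(dxi)) character(0) else d_code[dxi]
    cdays <- if (is.null(dxi)) integer(0) else d_day[dxi]
    inobs <- cdays >= idx - wash & cdays <= fup
    pri <- proc_by[[pid]]
    age <- .calendar_age(birth[pid], idx)
    o_age[k] <- as.integer(age)
    reason <- "none"
    if (!is.null(pri) && any(p_ect[pri] & p_day[pri] < idx)) {
      reason <- "prior_ect"
    } else if (any(grepl("^(F20|F30|F31)", codes[inobs]))) {
      reason <- "bipolar_or_schizo"
    } else if (any(grepl("^F0[0-9]", codes[inobs]))) {
      reason <- "cns_disease"
    } else if (age < config$age_min || age > config$age_max) {
      reason <- "age"
    } else if (!any(grepl("^(F32|F33)", codes[inobs & cdays <= idx]))) {
      reason <- "no_mdd_dx"
    } else if (idx_drugs_n >= 2L) {
      reason <- "multi_drug_index"
    }
    o_reason[k] <- reason

    vi <- vis_by[[pid]]
    o_set[k] <- if (!is.null(vi) && any(v_day[vi] == idx & v_inp[vi]))
      "inpatient" else "outpatient"
  }
  data.table(patient_id = o_id, index_date = .as_date(o_idx),
             index_drug = o_drug, age_at_index = o_age, sex = o_sex,
             index_setting = o_set, episode_end = .as_date(o_epi),
             follow_up_end = .as_date(o_fup),
             exclusion_reason = o_reason)[keep_row][]
}

#' Exclusion-flow summary
#'
#' @param cohort Output of [build_cohort()].
#' @return `data.table` with one row per exclusion reason (screened order)
#'   plus the eligible count.
#' @export
exclusion_flow <- function(cohort) {
  cohort <- as.data.table(cohort)
  out <- data.table(reason = .exclusion_levels)
  cnt <- cohort[, .N, by = exclusion_reason]
  out <- merge(out, cnt, by.x = "reason", by.y = "exclusion_reason",
               all.x = TRUE, sort = FALSE)
  out[is.na(N), N := 0L]
  setnames(out, "N", "n")
  out[]
}
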