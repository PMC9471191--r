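# Converts a patient's prescription stream into merged exposure intervals,
# classifies every medication change (switch / add-on / attempt), assigns
# sequential treatment levels and per-level durations.
#
# All date arithmetic is closed-interval and day-granular: a d-day supply
# starting at s covers [s, s + d - 1]; overlap([a,b],[c,d]) =
# max(0, min(b,d) - max(a,c) + 1).
#
# The exported functions wrap plain-vector internals (.merge_runs,
# .exposure_runs, .levels_core) that the cohort-scale driver calls directly;
# per-patient data.table allocation is too slow for 10^4-patient cohorts.

.as_day <- function(x) {
  if (inherits(x, "Date")) return(as.integer(x))
  if (is.character(x)) return(as.integer(as.Date(x)))
  as.integer(x)
}

.as_date <- function(x) as.Date(x, origin = "1970-01-01")

#' Pattern-engine configuration
#'
#' @param grace_days Maximum same-drug supply gap (days) still treated as
#'   continuous exposure.
#' @param overlap_min_days Minimum overlap (days) with every continuing
#'   regimen drug for a change to count as an add-on.
#' @param supply_min_days Minimum merged supply (days) for a new drug to be a
#'   switch/add-on candidate; shorter supplies are attempts.
#' @param event_window_days New qualifying drugs starting within this many
#'   days of each other form one (possibly multi-drug) transition event.
#' @param max_levels_analyzed Levels beyond this are recorded but ignored by
#'   the concordance classifier.
#' @return A named list of class `adc_pattern_config`.
#' @export
pattern_config <- function(grace_days = 14L, overlap_min_days = 30L,
                           supply_min_days = 30L, event_window_days = 14L,
                           max_levels_analyzed = 3L) {
  cfg <- list(grace_days = as.integer(grace_days),
              overlap_min_days = as.integer(overlap_min_days),
              supply_min_days = as.integer(supply_min_days),
              event_window_days = as.integer(event_window_days),
              max_levels_analyzed = as.integer(max_levels_analyzed))
  for (nm in names(cfg))
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("pattern_config: '", nm, "' must be a non-negative integer",
           call. = FALSE)
  structure(cfg, class = "adc_pattern_config")
}

# merge sorted-by-construction supply runs of ONE drug
.merge_runs <- function(s, e, grace) {
  o <- order(s, e); s <- s[o]; e <- e[o]
  n <- length(s)
  ms <- integer(n); me <- integer(n); k <- 1L
  ms[1L] <- s[1L]; me[1L] <- e[1L]
  if (n > 1L) for (i in 2L:n) {
    if (s[i] - me[k] - 1L <= grace) {
      if (e[i] > me[k]) me[k] <- e[i]
    } else {
      k <- k + 1L; ms[k] <- s[i]; me[k] <- e[i]
    }
  }
  list(s = ms[seq_len(k)], e = me[seq_len(k)])
}

# merged intervals for all drugs of one patient; plain vectors sorted by
# (start, drug)
.exposure_runs <- function(drug, s, e, grace) {
  out_d <- character(0); out_s <- integer(0); out_e <- integer(0)
  for (dr in unique(drug)) {
    w <- drug == dr
    m <- .merge_runs(s[w], e[w], grace)
    out_d <- c(out_d, rep(dr, length(m$s)))
    out_s <- c(out_s, m$s); out_e <- c(out_e, m$e)
  }
  o <- order(out_s, out_d)
  list(drug = out_d[o], s = out_s[o], e = out_e[o])
}

# total overlap (days) between interval sets (integer vectors)
.overlap_days <- function(s1, e1, s2, e2) {
  tot <- 0L
  for (i in seq_along(s1))
    tot <- tot + sum(pmax(0L, pmin(e1[i], e2) - pmax(s1[i], s2) + 1L))
  tot
}

#' Merge a prescription stream into continuous exposure intervals
#'
#' Within each drug, supply runs that overlap or are separated by at most
#' `grace_days` drug-free days are merged into one interval.
#'
#' @param rx `data.table`/data.frame with columns `drug_id`, `dispense_date`
#'   (Date or ISO string) and `days_supplied` (positive integer); one patient.
#' @param grace_days Grace period in days (default 14).
#' @return A `data.table` with columns `drug_id`, `start`, `end` (Date) and
#'   `supplied_days` (`end - start + 1`), ordered by start date.
#' @export
merge_exposures <- function(rx, grace_days = 14L) {
  rx <- as.data.frame(rx)
  if (nrow(rx) == 0L)
    return(data.table(drug_id = character(), start = as.Date(character()),
                      end = as.Date(character()), supplied_days = integer()))
  if (any(is.na(rx$days_supplied)) || any(rx$days_supplied < 1L))
    stop("days_supplied must be a positive integer", call. = FALSE)
  s <- .as_day(rx$dispense_date)
  m <- .exposure_runs(as.character(rx$drug_id), s,
                      s + as.integer(rx$days_supplied) - 1L,
                      as.integer(grace_days))
  data.table(drug_id = m$drug, start = .as_date(m$s), end = .as_date(m$e),
             supplied_days = m$e - m$s + 1L)
}

#' Classify a single medication change
#'
#' Applies the supply-overlap rules to one candidate drug interval against
#' the current regimen: a candidate supplied fewer than `supply_min` days is
#' an attempt; otherwise it is an add-on when it overlaps every continuing
#' regimen drug by at least `overlap_min` days, else a switch.
#'
#' @param regimen_intervals `data.table` with `drug_id`, `start`, `end`:
#'   exposure of the current regimen drugs (one or more rows per drug).
#' @param candidate One-row `data.table`/list with `drug_id`, `start`, `end`
#'   for the new drug's merged interval; the drug must not be in the regimen.
#' @param overlap_min,supply_min Day thresholds (defaults 30).
#' @return A list with `kind` (`"switch"|"add_on"|"attempt"`), `new_drugs`,
#'   `dropped_drugs`, `multi_drug`, `overlap_days` (minimum overlap across
#'   regimen drugs) and `event_date`.
#' @export
classify_change <- function(regimen_intervals, candidate,
                            overlap_min = 30L, supply_min = 30L) {
  reg <- as.data.frame(regimen_intervals)
  cand <- as.list(candidate)
  if (cand$drug_id %in% reg$drug_id)
    stop("candidate drug '", cand$drug_id, "' is already in the regimen",
         call. = FALSE)
  cs <- .as_day(cand$start); ce <- .as_day(cand$end)
  supplied <- ce - cs + 1L
  rs <- .as_day(reg$start); re <- .as_day(reg$end)
  drugs <- unique(reg$drug_id)
  ovl <- vapply(drugs, function(d)
    .overlap_days(rs[reg$drug_id == d], re[reg$drug_id == d], cs, ce),
    integer(1))
  min_ovl <- if (length(ovl)) min(ovl) else 0L
  if (supplied < supply_min) {
    kind <- "attempt"; dropped <- character(0)
  } else if (length(ovl) && all(ovl >= overlap_min)) {
    kind <- "add_on"; dropped <- character(0)
  } else {
    kind <- "switch"
    dropped <- drugs[ovl < overlap_min]
  }
  list(kind = kind, new_drugs = cand$drug_id, dropped_drugs = dropped,
       multi_drug = FALSE, overlap_days = as.integer(min_ovl),
       event_date = .as_date(cs))
}

# level construction on plain vectors; returns plain lists.
# iv_*: merged intervals sorted by (start, drug), already clipped.
.levels_core <- function(iv_drug, iv_s, iv_e, idx, index_drugs, fup, cfg) {
  supplied <- iv_e - iv_s + 1L
  n <- length(iv_drug)
  # coverage lookup per drug for overlap computations
  cov_idx <- split(seq_len(n), iv_drug)

  consumed <- iv_drug %in% index_drugs & iv_s <= idx
  regimen <- sort(unique(index_drugs))
  lev_start <- idx; lev_idx <- 1L; entry <- "initial"
  L <- list(level_index = integer(0), regimen = character(0),
            entry_pattern = character(0), start = integer(0), end = integer(0))
  TR <- list(event_date = integer(0), kind = character(0),
             new_drugs = character(0), dropped_drugs = character(0),
             multi_drug = logical(0), overlap_days = integer(0),
             from_level = integer(0))
  push_level <- function(end_day) {
    L$level_index <<- c(L$level_index, lev_idx)
    L$regimen <<- c(L$regimen, paste(regimen, collapse = "+"))
    L$entry_pattern <<- c(L$entry_pattern, entry)
    L$start <<- c(L$start, lev_start); L$end <<- c(L$end, end_day)
  }
  push_tr <- function(date, kind, nd, dd, multi, ovl) {
    TR$event_date <<- c(TR$event_date, date)
    TR$kind <<- c(TR$kind, kind)
    TR$new_drugs <<- c(TR$new_drugs, paste(nd, collapse = "+"))
    TR$dropped_drugs <<- c(TR$dropped_drugs, paste(dd, collapse = "+"))
    TR$multi_drug <<- c(TR$multi_drug, multi)
    TR$overlap_days <<- c(TR$overlap_days, as.integer(ovl))
    TR$from_level <<- c(TR$from_level, lev_idx)
  }
  reg_overlaps <- function(cand) {  # cand: indices of candidate intervals
    vapply(regimen, function(r) {
      ri <- cov_idx[[r]]
      tot <- 0L
      for (j in cand)
        tot <- tot + .overlap_days(iv_s[ri], iv_e[ri], iv_s[j], iv_e[j])
      tot
    }, integer(1))
  }

  i <- 1L
  while (i <= n) {
    if (consumed[i]) { i <- i + 1L; next }
    drug <- iv_drug[i]; st <- iv_s[i]
    if (drug %in% regimen) { consumed[i] <- TRUE; i <- i + 1L; next }
    if (supplied[i] < cfg$supply_min_days) {
      # attempt: level unchanged, drug ineligible for the next-level regimen
      push_tr(st, "attempt", drug, character(0), FALSE, min(reg_overlaps(i)))
      consumed[i] <- TRUE; i <- i + 1L; next
    }
    # same-day runs of current regimen drugs are continuations (regimen
    # membership is evaluated at the start of the day)
    consumed[!consumed & iv_s == st & iv_drug %in% regimen] <- TRUE
    grp <- which(!consumed & iv_s >= st &
                   iv_s <= st + cfg$event_window_days &
                   supplied >= cfg$supply_min_days &
                   !(iv_drug %in% regimen))
    grp <- grp[!duplicated(iv_drug[grp])]
    new_drugs <- sort(iv_drug[grp])
    if (st == lev_start) {
      # degenerate: absorb into the current regimen, no event
      regimen <- sort(union(regimen, new_drugs))
      consumed[grp] <- TRUE; i <- i + 1L; next
    }
    ovl <- reg_overlaps(grp)
    if (all(ovl >= cfg$overlap_min_days)) {
      kind <- "add_on"; dropped <- character(0)
      new_regimen <- sort(union(regimen, new_drugs))
    } else {
      kind <- "switch"
      dropped <- regimen[ovl < cfg$overlap_min_days]
      new_regimen <- sort(union(new_drugs, regimen[ovl >= cfg$overlap_min_days]))
    }
    push_tr(st, kind, new_drugs, dropped, length(new_drugs) >= 2L, min(ovl))
    push_level(st - 1L)
    regimen <- new_regimen; lev_start <- st
    lev_idx <- lev_idx + 1L; entry <- kind
    consumed[grp] <- TRUE
    i <- i + 1L
  }
  push_level(fup)
  list(levels = L, transitions = TR)
}

#' Assign treatment levels from merged exposure intervals
#'
#' Scans a patient's merged intervals in date order. The index drug(s) form
#' the level-1 regimen. Each later interval of a drug outside the current
#' regimen is a candidate: supplied below `supply_min_days` it is an attempt
#' (level unchanged, drug excluded from regimens); otherwise qualifying
#' candidates starting within `event_window_days` of each other are grouped
#' into one transition event classified switch/add-on by the overlap rule,
#' and the level increments by one. Level k ends the day before level k+1
#' starts; the last level ends at `follow_up_end`.
#'
#' A qualifying candidate starting exactly on the current level's start date
#' is absorbed into the current regimen without an event (degenerate corner;
#' cannot arise for cohorts with single-drug index dates).
#'
#' @param intervals Output of [merge_exposures()] for one patient (all
#'   drugs, antidepressant or adjunct).
#' @param index_date Cohort entry date; an interval of each index drug must
#'   cover it.
#' @param index_drugs Character vector (length 1 for eligible cohorts).
#' @param follow_up_end Last day of follow-up; exposure is clipped here.
#' @param config A [pattern_config()].
#' @return List with `levels` (one row per level: `level_index`, `regimen`
#'   as `+`-joined sorted drug ids, `entry_pattern`, `start`, `end`,
#'   `duration_days`, `duration_bin`) and `transitions` (one row per event:
#'   `event_date`, `kind`, `new_drugs`, `dropped_drugs`, `multi_drug`,
#'   `overlap_days`, `from_level`).
#' @export
build_levels <- function(intervals, index_date, index_drugs, follow_up_end,
                         config = pattern_config()) {
  iv <- as.data.frame(intervals)
  idx <- .as_day(index_date); fup <- .as_day(follow_up_end)
  if (fup < idx) stop("follow_up_end precedes index_date", call. = FALSE)
  s <- pmax(.as_day(iv$start), idx); e <- pmin(.as_day(iv$end), fup)
  keep <- s <= e
  drug <- as.character(iv$drug_id)[keep]; s <- s[keep]; e <- e[keep]
  o <- order(s, drug)
  drug <- drug[o]; s <- s[o]; e <- e[o]
  for (d in index_drugs)
    if (!any(drug == d & s <= idx & e >= idx))
      stop("no exposure interval of index drug '", d,
           "' covers the index date", call. = FALSE)
  res <- .levels_core(drug, s, e, idx, index_drugs, fup, config)
  .levels_as_tables(res)
}

.levels_as_tables <- function(res, patient_id = NULL) {
  L <- res$levels; TR <- res$transitions
  levels <- data.table(level_index = L$level_index, regimen = L$regimen,
                       entry_pattern = L$entry_pattern,
                       start = .as_date(L$start), end = .as_date(L$end))
  levels[, duration_days := as.integer(L$end - L$start + 1L)]
  levels[, duration_bin := bin_duration(duration_days)]
  transitions <- data.table(event_date = .as_date(TR$event_date),
                            kind = TR$kind, new_drugs = TR$new_drugs,
                            dropped_drugs = TR$dropped_drugs,
                            multi_drug = TR$multi_drug,
                            overlap_days = TR$overlap_days,
                            from_level = TR$from_level)
  if (!is.null(patient_id)) {
    levels[, patient_id := patient_id]
    transitions[, patient_id := rep(patient_id, nrow(transitions))]
  }
  list(levels = levels[], transitions = transitions[])
}

#' Bin a treatment-level duration into the reporting week bins
#'
#' Bin edges partition the positive integers: `lt2w` = 1-13 days, `w2_4` =
#' 14-27, `w4_6` = 28-41, `w6_8` = 42-55, `gt8w` = 56+.
#'
#' @param duration_days Positive integer vector.
#' @return Factor with levels `lt2w, w2_4, w4_6, w6_8, gt8w`.
#' @export
bin_duration <- function(duration_days) {
  if (any(is.na(duration_days)) || any(duration_days < 1))
    stop("duration_days must be positive", call. = FALSE)
  cut(as.integer(duration_days), breaks = c(0L, 13L, 27L, 41L, 55L, Inf),
      labels = c("lt2w", "w2_4", "w4_6", "w6_8", "gt8w"), right = TRUE)
}

#' Run the pattern engine over a cohort
#'
#' @param cohort Cohort table from [build_cohort()]; only eligible rows
#'   (`exclusion_reason == "none"`) are processed.
#' @param prescriptions Prescription table (all drugs, all patients).
#' @param config A [pattern_config()].
#' @return List of two `data.table`s, `levels` and `transitions`, each with a
#'   `patient_id` column prepended.
#' @export
build_patterns <- function(cohort, prescriptions, config = pattern_config()) {
  cohort <- as.data.frame(cohort)
  cohort <- cohort[cohort$exclusion_reason == "none", , drop = FALSE]
  rx <- as.data.frame(prescriptions)
  keep <- rx$patient_id %in% cohort$patient_id
  if (any(is.na(rx$days_supplied[keep])) || any(rx$days_supplied[keep] < 1L))
    stop("days_supplied must be a positive integer", call. = FALSE)
  p_id <- as.character(rx$patient_id[keep])
  p_drug <- as.character(rx$drug_id[keep])
  p_s <- .as_day(rx$dispense_date[keep])
  p_e <- p_s + as.integer(rx$days_supplied[keep]) - 1L
  by_pat <- split(seq_along(p_id), p_id)

  idx_all <- .as_day(cohort$index_date)
  fup_all <- .as_day(cohort$follow_up_end)
  acc <- vector("list", nrow(cohort))
  for (k in seq_len(nrow(cohort))) {
    pid <- as.character(cohort$patient_id[k])
    w <- by_pat[[pid]]
    m <- .exposure_runs(p_drug[w], p_s[w], p_e[w], config$grace_days)
    idx <- idx_all[k]; fup <- fup_all[k]
    s <- pmax(m$s, idx); e <- pmin(m$e, fup)
    ok <- s <= e
    drug <- m$drug[ok]; s <- s[ok]; e <- e[ok]
    o <- order(s, drug)
    index_drugs <- strsplit(cohort$index_drug[k], "+", fixed = TRUE)[[1L]]
    for (d in index_drugs)
      if (!any(drug == d & s <= idx & e >= idx))
        stop("patient ", pid, ": no exposure interval of index drug '", d,
             "' covers the index date", call. = FALSE)
    acc[[k]] <- .levels_core(drug[o], s[o], e[o], idx, index_drugs, fup, config)
  }
  nl <- vapply(acc, function(a) length(a$levels$level_index), integer(1))
  nt <- vapply(acc, function(a) length(a$transitions$kind), integer(1))
  pull <- function(part, field) unlist(lapply(acc, function(a) a[[part]][[field]]),
                                       use.names = FALSE)
  levels <- data.table(
    patient_id = rep(as.character(cohort$patient_id), nl),
    level_index = pull("levels", "level_index"),
    regimen = pull("levels", "regimen"),
    entry_pattern = pull("levels", "entry_pattern"),
    start = .as_date(pull("levels", "start")),
    end = .as_date(pull("levels", "end")))
  levels[, duration_days := as.integer(end - start + 1L)]
  levels[, duration_bin := bin_duration(duration_days)]
  transitions <- data.table(
    patient_id = rep(as.character(cohort$patient_id), nt),
    event_date = .as_date(pull("transitions", "event_date")),
    kind = pull("transitions", "kind"),
    new_drugs = pull("transitions", "new_drugs"),
    dropped_drugs = pull("transitions", "dropped_drugs"),
    multi_drug = pull("transitions", "multi_drug"),
    overlap_days = pull("transitions", "overlap_days"),
    from_level = pull("transitions", "from_level"))
  list(levels = levels[], transitions = transitions[])
}
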