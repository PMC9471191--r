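# Scores realized treatment levels 1-3 against the CANMAT stepwise algorithm.
# Duration never affects the flags; attempts never affect the flags.

.reason_levels <- c("nonrecommended_initial", "nonrecommended_switch_drug",
                    "multi_switch", "nonrecommended_adjunct", "multi_add")

#' Concordance flag for level 1
#'
#' Level 1 is concordant if and only if the index drug is a first-line
#' monotherapy antidepressant.
#'
#' @param index_drug Drug id (single drug; multi-drug initiators are excluded
#'   from the cohort upstream).
#' @param tiers A `canmat_tiers` object.
#' @return List with `concordant` (logical) and `reason`
#'   (`"nonrecommended_initial"` or `NULL`).
#' @export
classify_level1 <- function(index_drug, tiers) {
  ok <- monotherapy_status(tiers, index_drug) == "first"
  list(concordant = ok,
       reason = if (ok) NULL else "nonrecommended_initial")
}

#' Concordance flag for one switch/add-on transition
#'
#' A switch is concordant when it replaces the regimen with a single drug in
#' the switch-eligible set (superior-efficacy or second-/third-line
#' antidepressants by default); a multi-drug switch is discordant
#' (`multi_switch`). An add-on is concordant when it adds a single drug whose
#' adjunct line is in the eligible set; a multi-drug add-on is discordant
#' (`multi_add`).
#'
#' @param event One transition (list or one-row data.frame with `kind`,
#'   `new_drugs` as a `+`-joined string or character vector).
#' @param tiers A `canmat_tiers` object.
#' @return List with `concordant` and `reasons` (character, possibly empty).
#' @export
classify_transition <- function(event, tiers) {
  kind <- as.character(event$kind)
  if (kind == "attempt")
    stop("attempts are not transitions between levels", call. = FALSE)
  drugs <- event$new_drugs
  if (length(drugs) == 1L && grepl("+", drugs, fixed = TRUE))
    drugs <- strsplit(drugs, "+", fixed = TRUE)[[1L]]
  if (kind == "switch") {
    if (length(drugs) >= 2L)
      return(list(concordant = FALSE, reasons = "multi_switch"))
    if (switch_eligible(tiers, drugs))
      return(list(concordant = TRUE, reasons = character(0)))
    return(list(concordant = FALSE, reasons = "nonrecommended_switch_drug"))
  }
  if (kind == "add_on") {
    if (length(drugs) >= 2L)
      return(list(concordant = FALSE, reasons = "multi_add"))
    if (adjunct_eligible(tiers, drugs))
      return(list(concordant = TRUE, reasons = character(0)))
    return(list(concordant = FALSE, reasons = "nonrecommended_adjunct"))
  }
  stop("unknown transition kind '", kind, "'", call. = FALSE)
}

#' Concordance result for one patient
#'
#' Combines the level-1 flag with the flags of the transitions into levels 2
#' and 3. Levels beyond 3 are ignored; a patient is concordant overall if and
#' only if every realized level up to 3 is concordant. Attempts are neutral.
#' `optimized` marks patients who realized at least two levels.
#'
#' @param levels Levels table of one patient (from [build_levels()]).
#' @param transitions Transitions table of the same patient.
#' @param tiers A `canmat_tiers` object.
#' @param max_levels Levels analyzed (default 3).
#' @return List with `level_flags` (character vector of length `max_levels`
#'   in `concordant|discordant|not_reached`), `overall`, `reasons`
#'   (character), `optimized`, `changed` (any switch/add-on/attempt event).
#' @export
classify_patient <- function(levels, transitions, tiers, max_levels = 3L) {
  levels <- as.data.table(levels)
  transitions <- as.data.table(transitions)
  flags <- rep("not_reached", max_levels)
  reasons <- character(0)

  idx_drug <- levels[level_index == 1L, regimen]
  l1 <- classify_level1(idx_drug, tiers)
  flags[1L] <- if (l1$concordant) "concordant" else "discordant"
  reasons <- c(reasons, l1$reason)

  steps <- transitions[kind != "attempt"][order(event_date)]
  n_real <- min(max(levels$level_index), max_levels)
  if (n_real >= 2L) for (lv in 2L:n_real) {
    ev <- steps[lv - 1L]
    cl <- classify_transition(ev, tiers)
    flags[lv] <- if (cl$concordant) "concordant" else "discordant"
    reasons <- c(reasons, cl$reasons)
  }
  list(level_flags = flags,
       overall = !any(flags == "discordant"),
       reasons = unique(reasons),
       optimized = max(levels$level_index) >= 2L,
       changed = nrow(transitions) > 0L)
}

#' Classify a whole cohort
#'
#' @param patterns List with `levels` and `transitions` from
#'   [build_patterns()].
#' @param tiers A `canmat_tiers` object.
#' @param max_levels Levels analyzed (default 3).
#' @return `data.table` with one row per patient: `patient_id`, `level1`,
#'   `level2`, `level3` flags, `overall`, `reasons` (comma-joined),
#'   `optimized` (reached level >= 2) and `changed` (any event incl.
#'   attempts).
#' @export
classify_cohort <- function(patterns, tiers, max_levels = 3L) {
  lev <- as.data.table(patterns$levels)
  tr <- as.data.table(patterns$transitions)

  base <- lev[, .(max_level = max(level_index)), by = patient_id]
  l1 <- lev[level_index == 1L, .(patient_id, regimen)]
  l1[, ok := monotherapy_status(tiers, regimen) == "first"]
  base <- merge(base, l1[, .(patient_id, l1_ok = ok)], by = "patient_id")

  steps <- tr[kind != "attempt"][order(patient_id, event_date)]
  if (nrow(steps)) {
    steps[, step := seq_len(.N), by = patient_id]
    steps <- steps[step <= max_levels - 1L]
    steps[, ok := FALSE]
    steps[, reason := NA_character_]
    sw <- steps$kind == "switch"; ao <- steps$kind == "add_on"
    steps[sw & multi_drug, `:=`(ok = FALSE, reason = "multi_switch")]
    steps[ao & multi_drug, `:=`(ok = FALSE, reason = "multi_add")]
    ssw <- sw & !steps$multi_drug
    if (any(ssw)) {
      okv <- switch_eligible(tiers, steps$new_drugs[ssw])
      steps$ok[ssw] <- okv
      steps$reason[ssw] <- ifelse(okv, NA_character_, "nonrecommended_switch_drug")
    }
    sao <- ao & !steps$multi_drug
    if (any(sao)) {
      okv <- adjunct_eligible(tiers, steps$new_drugs[sao])
      steps$ok[sao] <- okv
      steps$reason[sao] <- ifelse(okv, NA_character_, "nonrecommended_adjunct")
    }
    flag_of <- function(n) {
      x <- steps[step == n, .(patient_id,
                              f = ifelse(ok, "concordant", "discordant"))]
      x
    }
    agg <- steps[, .(all_ok = all(ok),
                     step_reasons = paste(unique(stats::na.omit(reason)),
                                          collapse = ",")), by = patient_id]
    base <- Reduce(function(b, n) {
      merge(b, stats::setNames(flag_of(n),
                               c("patient_id", paste0("f", n + 1L))),
            by = "patient_id", all.x = TRUE)
    }, seq_len(max_levels - 1L), base)
    base <- merge(base, agg, by = "patient_id", all.x = TRUE)
  } else {
    for (lvn in 2L:max_levels)
      set(base, j = paste0("f", lvn), value = NA_character_)
    base[, `:=`(all_ok = NA, step_reasons = NA_character_)]
  }
  base[is.na(all_ok), `:=`(all_ok = TRUE, step_reasons = "")]
  changed_ids <- unique(tr$patient_id)
  out <- data.table(
    patient_id = base$patient_id,
    level1 = ifelse(base$l1_ok, "concordant", "discordant"),
    level2 = ifelse(is.na(base$f2), "not_reached", base$f2),
    level3 = if (max_levels >= 3L) ifelse(is.na(base$f3), "not_reached", base$f3)
    else "not_reached",
    overall = base$l1_ok & base$all_ok,
    reasons = trimws(paste0(ifelse(base$l1_ok, "", "nonrecommended_initial,"),
                            base$step_reasons), whitespace = ","),
    optimized = base$max_level >= 2L,
    changed = base$patient_id %in% changed_ids)
  setorder(out, patient_id)
  out[]
}
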