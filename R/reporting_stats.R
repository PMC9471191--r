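# Descriptive tables, the Cochran-Armitage trend test, the discordance flow
# and healthcare-utilization metrics.

#' Cochran-Armitage test for trend in proportions
#'
#' Standard trend statistic over k ordered binomial groups with scores
#' `s_i`: `T = sum s_i (x_i - n_i p)`, `Var(T) = p(1-p) (sum n_i s_i^2 -
#' (sum n_i s_i)^2 / N)`, `Z = T / sqrt(Var)`, two-sided normal p-value.
#' No continuity correction by default.
#'
#' @param counts Successes per ordered group.
#' @param totals Denominators per group.
#' @param scores Ordinal scores (default `1..k`); `Z` is invariant to affine
#'   rescaling.
#' @param continuity Apply a continuity correction of half the minimum score
#'   spacing to `|T|`.
#' @return List of class `adc_trend_test` with `Z`, `abs_Z`, `p`, `scores`,
#'   `counts`, `totals`.
#' @export
cochran_armitage <- function(counts, totals, scores = seq_along(counts),
                             continuity = FALSE) {
  k <- length(counts)
  if (k < 2L || length(totals) != k || length(scores) != k)
    stop("counts, totals and scores must have equal length >= 2", call. = FALSE)
  if (any(counts < 0) || any(counts > totals))
    stop("require 0 <= counts <= totals", call. = FALSE)
  N <- sum(totals); pbar <- sum(counts) / N
  if (pbar <= 0 || pbar >= 1)
    stop("all-success or all-failure table: trend statistic undefined",
         call. = FALSE)
  Tstat <- sum(scores * (counts - totals * pbar))
  V <- pbar * (1 - pbar) * (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  if (continuity) {
    cc <- min(diff(sort(scores))) / 2
    Tstat <- sign(Tstat) * max(0, abs(Tstat) - cc)
  }
  Z <- Tstat / sqrt(V)
  structure(list(Z = Z, abs_Z = abs(Z), p = 2 * pnorm(-abs(Z)),
                 scores = scores, counts = counts, totals = totals),
            class = "adc_trend_test")
}

#' @export
print.adc_trend_test <- function(x, ...) {
  cat(sprintf("Cochran-Armitage trend test: Z = %.4f, p = %.4g\n", x$Z, x$p))
  invisible(x)
}

#' Concordance proportions overall and by index year
#'
#' Three proportion families: overall concordance and first-line initiation
#' (denominator: all eligible patients) and optimized-treatment concordance
#' (denominator: patients with a medication change after recommended
#' first-line initiation; numerator: concordant overall).
#'
#' @param concordance Output of [classify_cohort()].
#' @param cohort Output of [build_cohort()] (eligible rows used).
#' @return `data.table` with columns `family`, `year` (`"all"` plus each
#'   index year), `n`, `denominator`, `percent`.
#' @export
proportion_table <- function(concordance, cohort) {
  co <- as.data.table(cohort)[exclusion_reason == "none",
                              .(patient_id, index_date)]
  cc <- merge(as.data.table(concordance), co, by = "patient_id")
  cc[, index_year := format(index_date, "%Y")]
  fam <- function(num, den, fam_name) {
    d <- data.table(year = cc$index_year[den], num = num[den])
    per_year <- d[, .(n = sum(num), denominator = .N), by = year][order(year)]
    out <- rbind(data.table(year = "all", n = sum(d$num), denominator = nrow(d)),
                 per_year)
    out[, `:=`(family = fam_name,
               percent = ifelse(denominator > 0, 100 * n / denominator, NA_real_))]
    out
  }
  all_true <- rep(TRUE, nrow(cc))
  out <- rbind(
    fam(cc$overall, all_true, "overall"),
    fam(cc$level1 == "concordant", all_true, "first_line"),
    fam(cc$overall, cc$level1 == "concordant" & cc$changed, "optimized"))
  setcolorder(out, c("family", "year", "n", "denominator", "percent"))
  out[]
}

#' Trend test over the yearly rows of a proportion family
#'
#' @param prop_table Output of [proportion_table()].
#' @param family One of `"overall"`, `"first_line"`, `"optimized"`.
#' @param ... Passed to [cochran_armitage()].
#' @return An `adc_trend_test`.
#' @export
concordance_trend <- function(prop_table, family = "overall", ...) {
  pt <- as.data.frame(prop_table)
  rows <- pt[pt$family == family & pt$year != "all", , drop = FALSE]
  rows <- rows[order(rows$year), ]
  cochran_armitage(rows$n, rows$denominator, ...)
}

.summarise_durations <- function(d) {
  bins <- table(bin_duration(d))
  out <- data.table(n = length(d), mean = mean(d), sd = sd(d),
                    median = as.numeric(median(d)),
                    q1 = as.numeric(quantile(d, 0.25)),
                    q3 = as.numeric(quantile(d, 0.75)))
  for (b in names(bins)) {
    out[[paste0("n_", b)]] <- as.integer(bins[[b]])
    out[[paste0("pct_", b)]] <- 100 * bins[[b]] / length(d)
  }
  out
}

#' Per-level treatment-duration summary
#'
#' Level 1 is split into patients who kept the index drug only versus those
#' with any medication change (including attempt-only patients); level 2 into
#' patients who stopped there versus those who entered level 3.
#'
#' @param levels Levels table from [build_patterns()].
#' @param transitions Transitions table (defines "any change"); when `NULL`,
#'   change is inferred from reaching level 2.
#' @return `data.table`, one row per (level, subgroup), with n, mean, SD,
#'   median, Q1, Q3 and duration-bin counts/percentages.
#' @export
duration_table <- function(levels, transitions = NULL) {
  lv <- as.data.table(levels)
  maxlev <- lv[, .(max_level = max(level_index)), by = patient_id]
  changed_ids <- if (!is.null(transitions) && nrow(as.data.table(transitions)))
    unique(as.data.table(transitions)$patient_id)
  else maxlev[max_level >= 2L, patient_id]
  l1 <- lv[level_index == 1L]
  l2 <- lv[level_index == 2L]
  l3 <- lv[level_index == 3L]
  block <- function(d, level, subgroup) {
    if (!length(d)) return(NULL)
    cbind(data.table(level = level, subgroup = subgroup),
          .summarise_durations(d))
  }
  rbindlist(list(
    block(l1[!(patient_id %in% changed_ids), duration_days], 1L, "only_index_drug"),
    block(l1[patient_id %in% changed_ids, duration_days], 1L, "with_change"),
    block(l1$duration_days, 1L, "total"),
    block(l2[patient_id %in% maxlev[max_level == 2L, patient_id], duration_days],
          2L, "stopped_at_level2"),
    block(l2[patient_id %in% maxlev[max_level >= 3L, patient_id], duration_days],
          2L, "with_change"),
    block(l2$duration_days, 2L, "total"),
    block(l3$duration_days, 3L, "total")), use.names = TRUE, fill = TRUE)[]
}

.first_steps <- function(transitions) {
  tr <- as.data.table(transitions)[kind != "attempt"][order(patient_id, event_date)]
  tr[, step := seq_len(.N), by = patient_id]
  tr
}

#' Medication-change pattern table (first three levels)
#'
#' @param levels Levels table.
#' @param transitions Transitions table.
#' @return List with `summary` (patients with any change; switch / add-on
#'   counts into level 2; attempt-only count), `top_switch_drugs`,
#'   `top_addon_drugs` (drug frequency among first transitions, percentages
#'   over switchers resp. add-on patients) and `subsequent` (patterns 1a-1c,
#'   2a-2c: second transition kind or unchanged).
#' @export
pattern_table <- function(levels, transitions) {
  lv <- as.data.table(levels)
  tr <- as.data.table(transitions)
  n_total <- uniqueN(lv$patient_id)
  changed_ids <- unique(tr$patient_id)
  maxlev <- lv[, .(max_level = max(level_index)), by = patient_id]
  steps <- .first_steps(tr)
  first <- steps[step == 1L]
  attempt_only <- setdiff(changed_ids, first$patient_id)

  top <- function(first_kind) {
    f <- first[kind == first_kind]
    if (!nrow(f)) return(data.table(drug_id = character(), n = integer(),
                                    percent = numeric()))
    drugs <- unlist(strsplit(f$new_drugs, "+", fixed = TRUE))
    tt <- as.data.table(table(drug_id = drugs))
    setnames(tt, "N", "n")
    tt[, percent := 100 * n / nrow(f)]
    tt[order(-n)]
  }
  subseq <- function(first_kind, label) {
    f <- first[kind == first_kind]
    nxt <- steps[step == 2L & patient_id %in% f$patient_id]
    data.table(
      first_kind = first_kind,
      pattern = paste0(label, c("a", "b", "c")),
      description = c("unchanged", "switch", "add_on"),
      n = c(nrow(f) - nrow(nxt), sum(nxt$kind == "switch"),
            sum(nxt$kind == "add_on")),
      denominator = nrow(f))
  }
  summary <- data.table(
    measure = c("patients", "with_any_change", "switch_l1_l2", "addon_l1_l2",
                "attempt_only_l1"),
    n = c(n_total, length(changed_ids), sum(first$kind == "switch"),
          sum(first$kind == "add_on"), length(attempt_only)))
  summary[, percent := 100 * n / n_total]
  sub <- rbind(subseq("switch", "1"), subseq("add_on", "2"))
  sub[, percent := ifelse(denominator > 0, 100 * n / denominator, NA_real_)]
  list(summary = summary[], top_switch_drugs = top("switch"),
       top_addon_drugs = top("add_on"), subsequent = sub[])
}

#' Discordance flow from level 1 to level 2 among first-line initiators
#'
#' @param concordance Output of [classify_cohort()].
#' @param transitions Transitions table.
#' @return List with `counts` (first-line initiators; with any change;
#'   optimized, i.e. moved to level 2) and `strategies`: per first-transition
#'   strategy (switch / add-on) the number of patients, the number and
#'   percentage with a discordant level-2 pattern, and the multi-drug
#'   sub-count.
#' @export
discordance_flow <- function(concordance, transitions) {
  cc <- as.data.table(concordance)
  fl <- cc[level1 == "concordant"]
  first <- .first_steps(transitions)[step == 1L]
  first <- first[patient_id %in% fl$patient_id]
  first <- merge(first, fl[, .(patient_id, level2)], by = "patient_id")
  strat <- first[, .(
    n = .N,
    discordant_n = sum(level2 == "discordant"),
    discordant_pct = 100 * sum(level2 == "discordant") / .N,
    multi_drug_n = sum(multi_drug & level2 == "discordant")), by = kind]
  setnames(strat, "kind", "strategy")
  counts <- data.table(
    measure = c("first_line_initiators", "with_any_change", "optimized"),
    n = c(nrow(fl), sum(fl$changed), sum(fl$optimized)))
  list(counts = counts, strategies = strat[order(strategy)])
}

#' Healthcare-utilization summary
#'
#' Person-years use 365.25-day years; visit counts are distinct visit dates
#' per patient; inter-visit intervals are pooled across patients.
#'
#' @param cohort Cohort rows of the patients to summarize (eligible).
#' @param visits Visits table.
#' @param ids Optional subset of patient ids.
#' @return One-row `data.table`: `n`, `person_years`,
#'   `visits_per_person_year`, `hospitalizations_per_person_year`,
#'   `follow_up_median`/`_q1`/`_q3` (days), `visit_interval_median`/`_q1`/
#'   `_q3`, `hospital_stay_median`/`_q1`/`_q3`.
#' @export
utilization_summary <- function(cohort, visits, ids = NULL) {
  co <- as.data.table(cohort)[exclusion_reason == "none"]
  if (!is.null(ids)) co <- co[patient_id %in% ids]
  vis <- as.data.table(visits)[patient_id %in% co$patient_id]
  fup <- as.numeric(.as_day(co$follow_up_end) - .as_day(co$index_date) + 1L)
  py <- sum(fup) / 365.25
  vis <- unique(vis, by = c("patient_id", "date"))
  ivl <- vis[order(date), .(iv = diff(.as_day(date))), by = patient_id]$iv
  hosp <- as.data.table(visits)[patient_id %in% co$patient_id &
                                  setting == "inpatient" & !is.na(admission_date)]
  stay <- as.numeric(.as_day(hosp$discharge_date) - .as_day(hosp$admission_date) + 1L)
  q <- function(x, p) if (length(x)) as.numeric(quantile(x, p)) else NA_real_
  data.table(
    n = nrow(co), person_years = py,
    visits_per_person_year = if (py > 0) nrow(vis) / py else NA_real_,
    hospitalizations_per_person_year = if (py > 0) nrow(hosp) / py else NA_real_,
    follow_up_median = q(fup, .5), follow_up_q1 = q(fup, .25),
    follow_up_q3 = q(fup, .75),
    visit_interval_median = q(ivl, .5), visit_interval_q1 = q(ivl, .25),
    visit_interval_q3 = q(ivl, .75),
    hospital_stay_median = q(stay, .5), hospital_stay_q1 = q(stay, .25),
    hospital_stay_q3 = q(stay, .75))
}

#' Utilization of concordant vs discordant optimized patients
#'
#' Restricted to first-line initiators with a subsequent medication change;
#' stratified by overall concordance.
#'
#' @param cohort,visits,concordance Pipeline tables.
#' @return `data.table`, one row per stratum.
#' @export
utilization_by_concordance <- function(cohort, visits, concordance) {
  cc <- as.data.table(concordance)[level1 == "concordant" & changed == TRUE]
  rbind(
    cbind(stratum = "concordant",
          utilization_summary(cohort, visits, cc[overall == TRUE, patient_id])),
    cbind(stratum = "discordant",
          utilization_summary(cohort, visits, cc[overall == FALSE, patient_id])))
}

#' Worked-example trend tests from the published yearly table
#'
#' Reconstructs the per-year denominators from the printed (n, proportion)
#' pairs as `round(100 * n / proportion)` and runs the trend test on each of
#' the three families.
#'
#' @param path TSV with columns `family`, `year`, `concordant_n`,
#'   `proportion_pct`; defaults to the shipped worked example.
#' @return `data.table` with `family`, `abs_Z`, `p`, `denominator_sum`,
#'   `numerator_sum`.
#' @export
trend_worked_example <- function(path = system.file("extdata", "trend_by_year.tsv",
                                                    package = "adconcord",
                                                    mustWork = TRUE)) {
  tb <- fread(path, sep = "\t")
  tb[, denominator := as.integer(round(100 * concordant_n / proportion_pct))]
  tb[, {
    tt <- cochran_armitage(concordant_n, denominator)
    .(abs_Z = tt$abs_Z, p = tt$p, denominator_sum = sum(denominator),
      numerator_sum = sum(concordant_n))
  }, by = family][]
}

#' Worked-example proportions from printed numerator/denominator pairs
#'
#' @param path TSV with `label`, `numerator`, `denominator`, `reported_pct`;
#'   defaults to the shipped file.
#' @return `data.table` with a recomputed `percent` column.
#' @export
reported_proportions <- function(path = system.file("extdata",
                                                    "reported_proportions.tsv",
                                                    package = "adconcord",
                                                    mustWork = TRUE)) {
  tb <- fread(path, sep = "\t")
  tb[, percent := 100 * numerator / denominator]
  tb[]
}

#' Run the full analysis pipeline on record tables
#'
#' @param tables Record tables (`patients`, `prescriptions`, `diagnoses`,
#'   `visits`, `procedures`).
#' @param catalog,tiers Knowledge tables.
#' @param cohort_cfg,pattern_cfg Stage configurations.
#' @return List with `cohort`, `levels`, `transitions`, `concordance`.
#' @export
run_pipeline <- function(tables, catalog = load_drug_catalog(),
                         tiers = load_tier_table(catalog = catalog),
                         cohort_cfg = cohort_config(),
                         pattern_cfg = pattern_config()) {
  cohort <- build_cohort(tables, catalog, cohort_cfg)
  patterns <- build_patterns(cohort, tables$prescriptions, pattern_cfg)
  concordance <- classify_cohort(patterns, tiers,
                                 pattern_cfg$max_levels_analyzed)
  list(cohort = cohort, levels = patterns$levels,
       transitions = patterns$transitions, concordance = concordance)
}
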