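# Small hand-built timelines with known classifications, for tests and
# documentation. Each fixture returns the five record tables for one (or a
# panel of) synthetic patients.

.fixture_names <- c("addon_35d_overlap", "switch_20d_overlap",
                    "attempt_15d_supply", "grace_gap_10d",
                    "multi_switch_2drugs", "washout_violation",
                    "episode_gap_130d", "exclusion_panel")

.fx_tables <- function(pid, rx, birth = "1985-06-15", sex = "F",
                       dx_code = "F32.1", dx_date = NULL, proc = NULL,
                       index = "2015-02-01") {
  rx <- as.data.table(rx)
  rx[, `:=`(patient_id = pid, setting = "outpatient")]
  rx[, dispense_date := as.Date(dispense_date)]
  dx <- data.table(patient_id = pid, icd10_code = dx_code,
                   date = as.Date(if (is.null(dx_date)) index else dx_date))
  vis <- data.table(patient_id = pid, date = as.Date(index),
                    setting = "outpatient",
                    admission_date = as.Date(NA), discharge_date = as.Date(NA))
  proc <- if (is.null(proc))
    data.table(patient_id = character(), code = character(),
               date = as.Date(character()))
  else {
    proc <- as.data.table(proc)
    proc[, patient_id := pid]
    setcolorder(proc, c("patient_id", "code", "date"))
    proc
  }
  list(patients = data.table(patient_id = pid, birth_date = as.Date(birth),
                             sex = sex),
       prescriptions = rx[, .(patient_id, drug_id, dispense_date,
                              days_supplied, setting)],
       diagnoses = dx, visits = vis, procedures = proc)
}

.fx_day <- function(d) as.Date("2015-02-01") + d

#' Hand-built record-table fixtures
#'
#' Documented timelines exercising one rule each (day 0 = the index date,
#' 2015-02-01, drug A = sertraline, B = escitalopram, C = venlafaxine):
#'
#' * `addon_35d_overlap` - A 60 days from day 0; B 35 days from day 25
#'   (35-day overlap): add-on.
#' * `switch_20d_overlap` - A 40 days; B 40 days from day 20 (20-day
#'   overlap): switch.
#' * `attempt_15d_supply` - A 60 days; B 15 days from day 50: attempt.
#' * `grace_gap_10d` - A 30 days at day 0 and again at day 40 (10 drug-free
#'   days): one merged exposure interval.
#' * `multi_switch_2drugs` - A 30 days; B and C 40 days each from day 30:
#'   one multi-drug switch event.
#' * `washout_violation` - an antidepressant 200 days before the candidate
#'   index dispense: no index date.
#' * `episode_gap_130d` - two 28-day dispenses separated by 130 drug-free
#'   days: the episode ends with the first supply run.
#' * `exclusion_panel` - nine patients hitting each eligibility rule once
#'   (plus one eligible).
#'
#' @param name Fixture name.
#' @return List of record tables (`patients`, `prescriptions`, `diagnoses`,
#'   `visits`, `procedures`).
#' @export
make_fixture <- function(name) {
  if (!name %in% .fixture_names)
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixture_names, collapse = ", "), call. = FALSE)
  A <- "sertraline"; B <- "escitalopram"; C <- "venlafaxine"
  d <- .fx_day
  switch(name,
    addon_35d_overlap = .fx_tables("FX1", data.table(
      drug_id = c(A, B), dispense_date = d(c(0, 25)),
      days_supplied = c(60L, 35L))),
    switch_20d_overlap = .fx_tables("FX1", data.table(
      drug_id = c(A, B), dispense_date = d(c(0, 20)),
      days_supplied = c(40L, 40L))),
    attempt_15d_supply = .fx_tables("FX1", data.table(
      drug_id = c(A, B), dispense_date = d(c(0, 50)),
      days_supplied = c(60L, 15L))),
    grace_gap_10d = .fx_tables("FX1", data.table(
      drug_id = c(A, A), dispense_date = d(c(0, 40)),
      days_supplied = c(30L, 30L))),
    multi_switch_2drugs = .fx_tables("FX1", data.table(
      drug_id = c(A, B, C), dispense_date = d(c(0, 30, 30)),
      days_supplied = c(30L, 40L, 40L))),
    washout_violation = .fx_tables("FX1", data.table(
      drug_id = c(A, A, A), dispense_date = d(c(-200, 0, 28)),
      days_supplied = c(28L, 28L, 28L))),
    episode_gap_130d = .fx_tables("FX1", data.table(
      drug_id = c(A, A), dispense_date = d(c(0, 158)),
      days_supplied = c(28L, 28L))),
    exclusion_panel = .fx_exclusion_panel())
}

.fx_exclusion_panel <- function() {
  A <- "sertraline"; B <- "escitalopram"
  d <- .fx_day
  base_rx <- function() data.table(drug_id = A, dispense_date = d(0),
                                   days_supplied = 28L)
  pts <- list(
    eligible = .fx_tables("EP01", base_rx()),
    prior_ect = .fx_tables("EP02", base_rx(),
                           proc = data.table(code = "ECT", date = d(-50))),
    bipolar = .fx_tables("EP03", base_rx(), dx_code = "F31.1"),
    schizo = .fx_tables("EP04", base_rx(), dx_code = "F20.0"),
    cns = .fx_tables("EP05", base_rx(), dx_code = "F06.8"),
    age_young = .fx_tables("EP06", base_rx(), birth = "1998-01-01"),  # 17y
    age_old = .fx_tables("EP07", base_rx(), birth = "1950-01-01"),    # 65y
    no_mdd = .fx_tables("EP08", base_rx(), dx_code = "F41.1"),
    multi = .fx_tables("EP09", data.table(
      drug_id = c(A, B), dispense_date = d(c(0, 0)),
      days_supplied = c(28L, 28L))),
    washout = .fx_tables("EP10", data.table(
      drug_id = c(A, A), dispense_date = d(c(-200, 0)),
      days_supplied = c(28L, 28L))))
  # bipolar/schizo/cns patients still carry an MDD code so only the
  # exclusion diagnosis trips; add it as a second diagnosis row
  extra_mdd <- data.table(patient_id = c("EP03", "EP04", "EP05"),
                          icd10_code = "F32.1", date = d(0))
  out <- list(
    patients = rbindlist(lapply(pts, `[[`, "patients")),
    prescriptions = rbindlist(lapply(pts, `[[`, "prescriptions")),
    diagnoses = rbind(rbindlist(lapply(pts, `[[`, "diagnoses")), extra_mdd),
    visits = rbindlist(lapply(pts, `[[`, "visits")),
    procedures = rbindlist(lapply(pts, `[[`, "procedures")))
  out
}
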