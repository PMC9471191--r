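# Synthetic patient-level EMR generator. Emulates a 2015-2017 accrual window
# with follow-up through 2018, ICD-10 coded MDD plus exclusion diagnoses,
# single- and multi-drug initiation, and medication-change propensities and
# level durations shaped like the source cohort. Every patient carries a
# ground-truth row (never read by the analysis stages) so the whole pipeline
# can be tested by label recovery.

#' Simulation configuration
#'
#' Defaults encode the published cohort's stated world: accrual 2015-2017
#' with follow-up through 2018, the observed age and sex mix, escitalopram
#' the modal initiator, 15.57% of eligible patients moving beyond level 1,
#' and log-normal level durations with medians 28 / 64.5 / 70.5 days.
#' `n_patients` counts *screened* patients; the sequential exclusion
#' probabilities are derived from the published screening funnel, so roughly
#' 47% of screened patients emerge eligible.
#'
#' @param n_patients Number of screened patients.
#' @param seed Integer RNG seed; same seed reproduces identical tables.
#' @param accrual_start,accrual_end,study_end Study calendar (ISO dates).
#' @param age_distribution Named weights over `18-30, 31-40, 41-50, 51-64`.
#' @param female_fraction Probability a patient is female.
#' @param index_drug_weights Named probabilities over the initiator drugs.
#' @param p_prior_ect,p_excluded_dx,p_age_out,p_multi_drug_index,
#'   p_washout_violation,p_no_mdd Sequential exclusion probabilities;
#'   `p_excluded_dx` is a named pair `(bipolar_or_schizo, cns_disease)`.
#' @param p_change Probability an eligible patient realizes >= 2 levels.
#' @param p_switch_given_change P(level-2 entry is a switch | >= 2 levels).
#' @param p_l3_given_switch,p_l3_given_addon P(enter level 3 | level-2 entry
#'   kind).
#' @param l3_switch_after_switch,l3_switch_after_addon P(level-3 entry is a
#'   switch | previous kind).
#' @param p_l4_given_l3 P(enter level 4 | reached level 3).
#' @param p_multi_switch,p_multi_add Probability a switch / add-on event
#'   involves two new drugs at a time.
#' @param switch_drug_weights,adjunct_drug_weights Named sampling weights for
#'   new switch targets and adjuncts (mixing recommended and
#'   non-recommended agents so that ~7.5% of single switches and ~27% of
#'   single add-ons are discordant).
#' @param p_attempt Probability of one attempt event (short-supply drug).
#' @param level_duration_model List of `c(median, sdlog)` pairs for levels
#'   1 (no change), 1 (changers), 2, 3+, plus `min_level2plus` (days).
#' @param refill_days Dispensing quantum in days (28).
#' @param visit_interval_model `c(shape, scale)` of the gamma inter-visit
#'   distribution in days.
#' @param p_inpatient_index,p_hospitalization Probability of an inpatient
#'   index visit / of one hospitalization during follow-up.
#' @param hospital_stay_model `c(meanlog, sdlog)` of the stay length (days).
#' @return Validated list of class `adc_sim_config`.
#' @export
sim_config <- function(n_patients = 1000L, seed = 1L,
                       accrual_start = "2015-01-01",
                       accrual_end = "2017-12-31",
                       study_end = "2018-12-31",
                       age_distribution = c("18-30" = 0.3989, "31-40" = 0.2619,
                                            "41-50" = 0.1434, "51-64" = 0.1958),
                       female_fraction = 0.6625,
                       index_drug_weights = c(
                         escitalopram = 0.2937, sertraline = 0.1791,
                         mirtazapine = 0.1026, venlafaxine = 0.1011,
                         paroxetine = 0.0883, fluoxetine = 0.06,
                         citalopram = 0.045, duloxetine = 0.04,
                         fluvoxamine = 0.025, agomelatine = 0.015,
                         bupropion = 0.009, mianserin = 0.0054,
                         trazodone = 0.015, amitriptyline = 0.009,
                         clomipramine = 0.006, maprotiline = 0.004,
                         reboxetine = 0.0018),
                       p_prior_ect = 38 / 40856,
                       p_excluded_dx = c(bipolar_or_schizo = 0.025313,
                                         cns_disease = 0.010848),
                       p_age_out = 6888 / 39342,
                       p_multi_drug_index = 12697 / 32454,
                       p_washout_violation = 0.02,
                       p_no_mdd = 0.01,
                       p_change = 0.1557,
                       p_switch_given_change = 1601 / 2952,
                       p_l3_given_switch = 647 / 1601,
                       p_l3_given_addon = 817 / 1351,
                       l3_switch_after_switch = 427 / 647,
                       l3_switch_after_addon = 813 / 817,
                       p_l4_given_l3 = 723 / 1522,
                       p_multi_switch = 359 / 1528,
                       p_multi_add = 57 / 1301,
                       switch_drug_weights = c(
                         escitalopram = 0.21, venlafaxine = 0.16,
                         mirtazapine = 0.13, sertraline = 0.11,
                         trazodone = 0.07, amitriptyline = 0.05,
                         clomipramine = 0.04, reboxetine = 0.03,
                         maprotiline = 0.02, moclobemide = 0.0147,
                         doxepin = 0.03, imipramine = 0.03,
                         levomilnacipran = 0.03,
                         fluoxetine = 0.025, paroxetine = 0.020,
                         duloxetine = 0.015, agomelatine = 0.0103,
                         citalopram = 0.005),
                       adjunct_drug_weights = c(
                         mirtazapine = 0.225, quetiapine = 0.16,
                         trazodone = 0.14, olanzapine = 0.06,
                         aripiprazole = 0.055, lithium = 0.05,
                         risperidone = 0.0422,
                         venlafaxine = 0.09, escitalopram = 0.07,
                         fluoxetine = 0.05, buspirone = 0.04,
                         duloxetine = 0.0178),
                       p_attempt = 0.0091,
                       level_duration_model = list(
                         l1 = c(median = 28, sdlog = 1.2),
                         l1_change = c(median = 28, sdlog = 1.1),
                         l2 = c(median = 64.5, sdlog = 0.94),
                         l3 = c(median = 70.5, sdlog = 1.02),
                         min_level2plus = 30),
                       refill_days = 28L,
                       visit_interval_model = c(shape = 2, scale = 16.7),
                       p_inpatient_index = 0.0047,
                       p_hospitalization = 0.02,
                       hospital_stay_model = c(meanlog = log(38), sdlog = 0.59)) {
  cfg <- as.list(environment())
  cfg$n_patients <- as.integer(n_patients)
  cfg$seed <- as.integer(seed)
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L)
    stop("sim_config: 'n_patients' must be a non-negative integer", call. = FALSE)
  for (nm in c("female_fraction", "p_prior_ect", "p_age_out",
               "p_multi_drug_index", "p_washout_violation", "p_no_mdd",
               "p_change", "p_switch_given_change", "p_l3_given_switch",
               "p_l3_given_addon", "l3_switch_after_switch",
               "l3_switch_after_addon", "p_l4_given_l3", "p_multi_switch",
               "p_multi_add", "p_attempt", "p_inpatient_index",
               "p_hospitalization")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (any(cfg$p_excluded_dx < 0) || sum(cfg$p_excluded_dx) > 1)
    stop("sim_config: 'p_excluded_dx' must be probabilities", call. = FALSE)
  for (nm in c("age_distribution", "index_drug_weights",
               "switch_drug_weights", "adjunct_drug_weights")) {
    w <- cfg[[nm]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("sim_config: '", nm, "' weights must be non-negative and sum to 1",
           call. = FALSE)
  }
  cfg$accrual_start <- as.Date(accrual_start)
  cfg$accrual_end <- as.Date(accrual_end)
  cfg$study_end <- as.Date(study_end)
  if (cfg$accrual_start > cfg$accrual_end || cfg$accrual_end > cfg$study_end)
    stop("sim_config: require accrual_start <= accrual_end <= study_end",
         call. = FALSE)
  structure(cfg, class = "adc_sim_config")
}

.rlnorm_med <- function(n, median, sdlog, minimum = 1) {
  pmax(round(rlnorm(n, meanlog = log(median), sdlog = sdlog)), minimum)
}

.mdd_codes <- c("F32.0", "F32.1", "F32.2", "F32.9",
                "F33.0", "F33.1", "F33.2", "F33.9")

# sample one drug from a weight vector, excluding already-used drugs
.draw_drug <- function(weights, used) {
  w <- weights[!(names(weights) %in% used)]
  if (!length(w)) stop("drug pool exhausted", call. = FALSE)
  sample(names(w), 1L, prob = w)
}

# refill schedule covering [cs, ce] in quanta of `refill` days
.refills <- function(cs, ce, refill) {
  len <- ce - cs + 1L
  starts <- seq.int(cs, ce, by = refill)
  supply <- rep(refill, length(starts))
  supply[length(supply)] <- len - (length(starts) - 1L) * refill
  list(s = starts, supply = as.integer(supply))
}

#' Generate a synthetic EMR population
#'
#' @param config A [sim_config()].
#' @param mode `"clean"` (prescriptions exactly realize the intended level
#'   structure; used for recovery tests) or `"noisy"` (adds refill jitter,
#'   overlapping tails, same-drug gaps and extra short attempts).
#' @return List with record tables `patients`, `prescriptions`, `diagnoses`,
#'   `visits`, `procedures`, and `ground_truth` (one row per patient;
#'   analysis stages must never read it).
#' @export
generate_population <- function(config = sim_config(),
                                mode = c("clean", "noisy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "adc_sim_config"))
  n <- config$n_patients
  empty <- function() list(
    patients = data.table(patient_id = character(), birth_date = as.Date(character()),
                          sex = character()),
    prescriptions = data.table(patient_id = character(), drug_id = character(),
                               dispense_date = as.Date(character()),
                               days_supplied = integer(), setting = character()),
    diagnoses = data.table(patient_id = character(), icd10_code = character(),
                           date = as.Date(character())),
    visits = data.table(patient_id = character(), date = as.Date(character()),
                        setting = character(), admission_date = as.Date(character()),
                        discharge_date = as.Date(character())),
    procedures = data.table(patient_id = character(), code = character(),
                            date = as.Date(character())),
    ground_truth = data.table(patient_id = character(), eligible = logical(),
                              exclusion_reason = character(), sex = character(),
                              index_date = as.Date(character()),
                              index_drug = character(), n_levels = integer(),
                              regimens = character(), entry_patterns = character(),
                              durations = character(), has_attempt = logical(),
                              intended_concordant = logical(),
                              follow_up_end = as.Date(character())))
  if (n == 0L) return(empty())

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  tiers <- load_tier_table()
  acc_lo <- .as_day(config$accrual_start)
  acc_hi <- .as_day(config$accrual_end)
  send <- .as_day(config$study_end)
  ldm <- config$level_duration_model
  min2 <- ldm$min_level2plus
  refill <- as.integer(config$refill_days)

  ids <- sprintf("P%06d", seq_len(n))

  # sequential exclusion assignment (one reason per patient)
  u <- runif(n)
  reason <- rep("none", n)
  p <- config$p_prior_ect
  reason[u < p] <- "prior_ect"
  free <- reason == "none"
  u2 <- runif(n)
  dxp <- config$p_excluded_dx
  reason[free & u2 < dxp[["bipolar_or_schizo"]]] <- "bipolar_or_schizo"
  reason[free & u2 >= dxp[["bipolar_or_schizo"]] &
           u2 < sum(dxp)] <- "cns_disease"
  free <- reason == "none"
  reason[free & runif(n) < config$p_age_out] <- "age"
  free <- reason == "none"
  reason[free & runif(n) < config$p_multi_drug_index] <- "multi_drug_index"
  free <- reason == "none"
  reason[free & runif(n) < config$p_washout_violation] <- "washout_violation"
  free <- reason == "none"
  reason[free & runif(n) < config$p_no_mdd] <- "no_mdd_dx"

  # demographics
  female <- runif(n) < config$female_fraction
  sexv <- ifelse(female, "F", "M")
  bins <- sample(names(config$age_distribution), n, replace = TRUE,
                 prob = config$age_distribution)
  lo_age <- c("18-30" = 18L, "31-40" = 31L, "41-50" = 41L, "51-64" = 51L)
  hi_age <- c("18-30" = 30L, "31-40" = 40L, "41-50" = 50L, "51-64" = 64L)
  age <- lo_age[bins] + floor(runif(n) * (hi_age[bins] - lo_age[bins] + 1L))
  out_young <- runif(n) < 0.5
  age[reason == "age"] <- ifelse(out_young[reason == "age"],
                                 10L + floor(runif(sum(reason == "age")) * 8L),
                                 65L + floor(runif(sum(reason == "age")) * 16L))

  index_day <- acc_lo + floor(runif(n) * (acc_hi - acc_lo + 1L))
  index_day[reason == "washout_violation"] <-
    acc_lo + floor(runif(sum(reason == "washout_violation")) * 151L)
  # birth date such that floor(days / 365.25) == age at index
  birth_day <- index_day - as.integer(round(age * 365.25)) -
    (20L + floor(runif(n) * 320L))

  drug1 <- sample(names(config$index_drug_weights), n, replace = TRUE,
                  prob = config$index_drug_weights)

  rx_l <- vector("list", n); dx_l <- vector("list", n)
  vis_l <- vector("list", n); proc_l <- vector("list", n)
  gt_l <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- ids[i]; rs <- reason[i]; idx <- index_day[i]
    eligible <- rs == "none"
    changer <- eligible && runif(1) < config$p_change

    # ---- intended level structure -------------------------------------
    regs <- list(drug1[i]); kinds <- "initial"
    durs <- if (changer)
      .rlnorm_med(1, ldm$l1_change["median"], ldm$l1_change["sdlog"])
    else
      .rlnorm_med(1, ldm$l1["median"], ldm$l1["sdlog"])
    if (changer) {
      k2 <- if (runif(1) < config$p_switch_given_change) "switch" else "add_on"
      go3 <- runif(1) < if (k2 == "switch") config$p_l3_given_switch else
        config$p_l3_given_addon
      k3 <- if (go3) {
        psw <- if (k2 == "switch") config$l3_switch_after_switch else
          config$l3_switch_after_addon
        if (runif(1) < psw) "switch" else "add_on"
      } else NA_character_
      k4 <- if (go3 && runif(1) < config$p_l4_given_l3) {
        if (runif(1) < config$l3_switch_after_switch) "switch" else "add_on"
      } else NA_character_
      used <- drug1[i]
      for (kk in stats::na.omit(c(k2, k3, k4))) {
        pool <- if (kk == "switch") config$switch_drug_weights else
          config$adjunct_drug_weights
        p_multi <- if (kk == "switch") config$p_multi_switch else
          config$p_multi_add
        d1 <- .draw_drug(pool, used); used <- c(used, d1)
        nd <- d1
        if (runif(1) < p_multi) {
          d2 <- .draw_drug(pool, used); used <- c(used, d2)
          nd <- c(nd, d2)
        }
        prev <- regs[[length(regs)]]
        regs[[length(regs) + 1L]] <- if (kk == "switch") sort(nd) else
          sort(c(prev, nd))
        kinds <- c(kinds, kk)
        model <- if (length(regs) == 2L) ldm$l2 else ldm$l3
        durs <- c(durs, .rlnorm_med(1, model["median"], model["sdlog"],
                                    minimum = min2))
      }
    } else if (!eligible) {
      durs <- .rlnorm_med(1, ldm$l1["median"], ldm$l1["sdlog"])
    }

    # censor at study_end: keep level k (k >= 2) only when >= 30 days remain
    starts <- idx + cumsum(c(0L, head(durs, -1L)))
    keep <- c(TRUE, (send - starts[-1L]) >= (min2 - 1L))[seq_along(durs)]
    keep <- cumprod(keep) > 0
    regs <- regs[keep]; kinds <- kinds[keep]; durs <- durs[keep]
    starts <- starts[keep]
    ends <- pmin(starts + durs - 1L, send)
    durs <- ends - starts + 1L
    n_lev <- length(regs)
    fup_end <- ends[n_lev]

    # ---- attempt event ------------------------------------------------
    has_att <- FALSE; att_drug <- NA_character_
    if (eligible && runif(1) < config$p_attempt && durs[1L] >= 6L) {
      has_att <- TRUE
      att_drug <- .draw_drug(config$index_drug_weights,
                             unique(unlist(regs)))
      att_start <- starts[1L] + 1L
      att_supply <- min(14L, durs[1L] - 1L)
    }

    # ---- prescriptions ------------------------------------------------
    # per-drug contiguous coverage across the consecutive levels it belongs to
    rx_s <- integer(0); rx_sup <- integer(0); rx_drug <- character(0)
    all_drugs <- unique(unlist(regs))
    for (dr in all_drugs) {
      in_lev <- vapply(regs, function(r) dr %in% r, logical(1))
      cs <- starts[which(in_lev)[1L]]
      ce <- ends[max(which(in_lev))]
      rf <- .refills(cs, ce, refill)
      rx_s <- c(rx_s, rf$s); rx_sup <- c(rx_sup, rf$supply)
      rx_drug <- c(rx_drug, rep(dr, length(rf$s)))
    }
    if (has_att) {
      rx_s <- c(rx_s, att_start); rx_sup <- c(rx_sup, att_supply)
      rx_drug <- c(rx_drug, att_drug)
    }
    if (rs == "multi_drug_index") {
      d2 <- .draw_drug(config$index_drug_weights, drug1[i])
      rf <- .refills(starts[1L], ends[1L], refill)
      rx_s <- c(rx_s, rf$s); rx_sup <- c(rx_sup, rf$supply)
      rx_drug <- c(rx_drug, rep(d2, length(rf$s)))
    }
    if (rs == "washout_violation") {
      rx_s <- c(rx_s, idx - 200L); rx_sup <- c(rx_sup, refill)
      rx_drug <- c(rx_drug, drug1[i])
    }

    if (mode == "noisy" && eligible) {
      first_of_drug <- !duplicated(rx_drug)
      jit <- integer(length(rx_s))
      late <- !first_of_drug
      jit[late] <- sample(0:5, sum(late), replace = TRUE)
      early <- late & runif(length(rx_s)) < 0.1
      jit[early] <- -sample(1:5, sum(early), replace = TRUE)
      if (runif(1) < 0.05 && sum(late) > 0) {  # one long same-drug gap
        j <- sample(which(late), 1L)
        jit[j] <- sample(16:40, 1L)
      }
      rx_s <- pmax(rx_s + jit, idx)
      if (runif(1) < 0.02) {  # extra stray attempt
        dr <- .draw_drug(config$index_drug_weights, unique(rx_drug))
        rx_s <- c(rx_s, starts[1L] + 2L); rx_sup <- c(rx_sup, 7L)
        rx_drug <- c(rx_drug, dr)
      }
    }

    rx_l[[i]] <- data.table(patient_id = pid, drug_id = rx_drug,
                            dispense_date = rx_s, days_supplied = rx_sup)

    # ---- diagnoses ----------------------------------------------------
    dd <- data.table(icd10_code = character(0), date = integer(0))
    if (rs != "no_mdd_dx")
      dd <- rbind(dd, data.table(icd10_code = sample(.mdd_codes, 1L),
                                 date = idx))
    if (rs == "bipolar_or_schizo")
      dd <- rbind(dd, data.table(
        icd10_code = sample(c("F31.1", "F31.9", "F20.0", "F30.1"), 1L),
        date = idx + floor(runif(1) * max(1L, min(100L, fup_end - idx + 1L)))))
    if (rs == "cns_disease")
      dd <- rbind(dd, data.table(
        icd10_code = sample(c("F06.8", "F03.9", "F07.0"), 1L),
        date = idx + floor(runif(1) * max(1L, min(100L, fup_end - idx + 1L)))))
    if (nrow(dd)) dd[, patient_id := pid]
    dx_l[[i]] <- dd

    # ---- procedures ---------------------------------------------------
    if (rs == "prior_ect")
      proc_l[[i]] <- data.table(patient_id = pid, code = "ECT",
                                date = idx - 100L)

    # ---- visits -------------------------------------------------------
    vdays <- idx
    t <- idx
    repeat {
      t <- t + max(1L, round(rgamma(1, shape = config$visit_interval_model["shape"],
                                    scale = config$visit_interval_model["scale"])))
      if (t > fup_end) break
      vdays <- c(vdays, t)
    }
    vset <- rep("outpatient", length(vdays))
    vadm <- rep(NA_integer_, length(vdays)); vdis <- rep(NA_integer_, length(vdays))
    if (runif(1) < config$p_inpatient_index) {
      vset[1L] <- "inpatient"
      stay <- max(1L, round(rlnorm(1, config$hospital_stay_model["meanlog"],
                                   config$hospital_stay_model["sdlog"])))
      vadm[1L] <- idx; vdis[1L] <- idx + stay - 1L
    } else if (length(vdays) > 1L && runif(1) < config$p_hospitalization) {
      j <- sample(2:length(vdays), 1L)
      vset[j] <- "inpatient"
      stay <- max(1L, round(rlnorm(1, config$hospital_stay_model["meanlog"],
                                   config$hospital_stay_model["sdlog"])))
      vadm[j] <- vdays[j]; vdis[j] <- vdays[j] + stay - 1L
    }
    vis_l[[i]] <- data.table(patient_id = pid, date = vdays, setting = vset,
                             admission_date = vadm, discharge_date = vdis)

    # ---- ground-truth label (inline tier lookups, not the classifier) --
    conc <- NA
    if (eligible) {
      line1 <- tiers$monotherapy_line[drug1[i]]
      conc <- !is.na(line1) && line1 == "first"
      if (n_lev >= 2L) for (lv in 2L:min(n_lev, 3L)) {
        nd <- setdiff(regs[[lv]], if (kinds[lv] == "add_on") regs[[lv - 1L]]
                      else character(0))
        if (kinds[lv] == "switch") nd <- regs[[lv]]
        if (length(nd) >= 2L) { conc <- FALSE; next }
        if (kinds[lv] == "switch") {
          ml <- tiers$monotherapy_line[nd]
          ok <- (!is.na(ml) && ml %in% c("second", "third")) ||
            nd %in% tiers$superior_efficacy ||
            (tiers$switch_allow_any_first_line && !is.na(ml) && ml == "first")
        } else {
          al <- tiers$adjunct_line[nd]
          ok <- !is.na(al) && al %in% tiers$adjunct_eligible_lines
        }
        if (!ok) conc <- FALSE
      }
    }
    gt_l[[i]] <- data.table(
      patient_id = pid, eligible = eligible, exclusion_reason = rs,
      sex = sexv[i], index_date = idx, index_drug = drug1[i],
      n_levels = if (eligible) n_lev else NA_integer_,
      regimens = if (eligible)
        paste(vapply(regs, paste, "", collapse = "+"), collapse = "|") else NA_character_,
      entry_patterns = if (eligible) paste(kinds, collapse = "|") else NA_character_,
      durations = if (eligible) paste(durs, collapse = "|") else NA_character_,
      has_attempt = has_att, intended_concordant = conc,
      follow_up_end = fup_end)
  }

  to_date <- function(dt, cols) {
    for (cc in cols) set(dt, j = cc, value = .as_date(dt[[cc]]))
    dt
  }
  rx <- to_date(rbindlist(rx_l), "dispense_date")
  rx[, setting := "outpatient"]
  dx <- to_date(rbindlist(dx_l, fill = TRUE), "date")
  setcolorder(dx, c("patient_id", "icd10_code", "date"))
  vis <- to_date(rbindlist(vis_l), c("date", "admission_date", "discharge_date"))
  proc <- proc_l[!vapply(proc_l, is.null, logical(1))]
  proc <- if (length(proc)) to_date(rbindlist(proc), "date") else
    data.table(patient_id = character(), code = character(),
               date = as.Date(character()))
  gt <- to_date(rbindlist(gt_l), c("index_date", "follow_up_end"))
  pats <- data.table(patient_id = ids, birth_date = .as_date(birth_day),
                     sex = sexv)
  list(patients = pats, prescriptions = rx[order(patient_id, dispense_date, drug_id)],
       diagnoses = dx[order(patient_id, date)], visits = vis[order(patient_id, date)],
       procedures = proc, ground_truth = gt)
}

#' Write a population to delimited files
#'
#' One TSV per table; ground truth goes to `ground_truth.tsv` and is never
#' read by the analysis stages.
#'
#' @param population List from [generate_population()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(population))
    fwrite(population[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t")
  invisible(dir)
}

#' Read record tables written by [write_population()]
#'
#' @param dir Directory containing the TSV tables.
#' @param with_truth Also read `ground_truth.tsv` when present.
#' @return List of `data.table`s.
#' @export
read_population <- function(dir, with_truth = FALSE) {
  nm <- c("patients", "prescriptions", "diagnoses", "visits", "procedures")
  if (with_truth) nm <- c(nm, "ground_truth")
  out <- lapply(nm, function(x) {
    f <- file.path(dir, paste0(x, ".tsv"))
    if (!file.exists(f)) stop("missing table file: ", f, call. = FALSE)
    dt <- fread(f, sep = "\t")
    for (cc in intersect(names(dt), c("dispense_date", "date", "birth_date",
                                      "admission_date", "discharge_date",
                                      "index_date", "follow_up_end")))
      set(dt, j = cc, value = as.Date(dt[[cc]]))
    dt
  })
  stats::setNames(out, nm)
}
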