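catalog <- load_drug_catalog()
cfg <- cohort_config()
d0 <- as.Date("2015-02-01")

rx_tbl <- function(drug, date, supply)
  data.frame(drug_id = drug, dispense_date = as.Date(date),
             days_supplied = supply)

test_that("find_index enforces the one-year washout", {
  # prior AD five months earlier: washout violated, no index
  rx <- rx_tbl("sertraline", c("2014-09-01", "2015-03-01"), c(28, 28))
  expect_null(find_index(rx, catalog, cfg))
  # no prior AD ever: index at first dispense
  rx <- rx_tbl("sertraline", "2016-05-10", 28)
  idx <- find_index(rx, catalog, cfg)
  expect_identical(idx$index_date, as.Date("2016-05-10"))
  expect_identical(idx$index_drugs, "sertraline")
  # two different ADs on the same day: both returned
  rx <- rx_tbl(c("sertraline", "escitalopram"), "2015-03-01", c(28, 28))
  idx <- find_index(rx, catalog, cfg)
  expect_identical(length(idx$index_drugs), 2L)
  # a later dispense can qualify once the washout has elapsed
  rx <- rx_tbl("sertraline", c("2014-09-01", "2016-05-01"), c(28, 28))
  idx <- find_index(rx, catalog, cfg)
  expect_identical(idx$index_date, as.Date("2016-05-01"))
  # non-antidepressants never define an index
  rx <- rx_tbl("quetiapine", "2015-03-01", 28)
  expect_null(find_index(rx, catalog, cfg))
})

test_that("washout boundary is exactly 365 days", {
  rx <- rx_tbl("sertraline", c("2015-01-10", "2016-01-09"), c(7, 28))
  expect_null(find_index(rx_tbl("sertraline", "2015-01-10", 7), catalog,
                         cohort_config(accrual_start = "2015-06-01")))
  # 365 days after: still inside washout; 366: qualifies
  idx <- find_index(rx, catalog, cfg)
  expect_identical(idx$index_date, as.Date("2015-01-10"))  # first itself is clean
  rx2 <- rx_tbl("sertraline", c("2014-12-10", "2015-12-10"), c(7, 28))
  expect_null(find_index(rx2, catalog, cfg))  # gap = 365 days, still inside
  rx3 <- rx_tbl("sertraline", c("2014-12-10", "2015-12-11"), c(7, 28))
  idx3 <- find_index(rx3, catalog, cfg)
  expect_identical(idx3$index_date, as.Date("2015-12-11"))
})

test_that("build_episode closes after a >120-day dispensing gap", {
  # dispenses at day 0 and day 130 (gap from supply end: 130 - 28 = 102 <= 120)
  rx <- rx_tbl(c("sertraline", "sertraline"), d0 + c(0, 130), c(28, 28))
  expect_identical(build_episode(rx, d0, cfg), d0 + 157)
  # fixture: 130 drug-free days between supply end and next dispense
  rx <- rx_tbl(c("sertraline", "sertraline"), d0 + c(0, 158), c(28, 28))
  expect_identical(build_episode(rx, d0, cfg), d0 + 27)
  # gap of exactly 120 free days continues the episode
  rx <- rx_tbl(c("sertraline", "sertraline"), d0 + c(0, 148), c(28, 28))
  expect_identical(build_episode(rx, d0, cfg), d0 + 175)
  # continuous dispensing runs to study_end
  days <- seq(0, 1500, by = 28)
  rx <- rx_tbl(rep("sertraline", length(days)), d0 + days, 28)
  expect_identical(build_episode(rx, d0, cfg), cfg$study_end)
})

test_that("build_episode equals the day-by-day oracle on random dispense sets", {
  set.seed(31)
  for (case in 1:200) {
    k <- sample(1:6, 1L)
    day <- sort(sample(0:400, k))
    supply <- sample(1:60, k, replace = TRUE)
    rx <- rx_tbl(rep("sertraline", k), d0 + day, supply)
    got <- as.integer(build_episode(rx, d0 + day[1], cfg) - d0)
    want <- oracle_episode(day, supply, day[1], gap = 120L,
                           send = as.integer(cfg$study_end - d0))
    expect_identical(got, want, info = paste("case", case))
  }
})

test_that("eligibility rules fire once each on the exclusion panel", {
  fx <- make_fixture("exclusion_panel")
  cohort <- build_cohort(fx, catalog, cfg)
  got <- setNames(cohort$exclusion_reason, cohort$patient_id)
  expect_identical(got[["EP01"]], "none")
  expect_identical(got[["EP02"]], "prior_ect")
  expect_identical(got[["EP03"]], "bipolar_or_schizo")
  expect_identical(got[["EP04"]], "bipolar_or_schizo")
  expect_identical(got[["EP05"]], "cns_disease")
  expect_identical(got[["EP06"]], "age")
  expect_identical(got[["EP07"]], "age")
  expect_identical(got[["EP08"]], "no_mdd_dx")
  expect_identical(got[["EP09"]], "multi_drug_index")
  expect_identical(got[["EP10"]], "washout_violation")
  # partition: one reason per screened patient, counts sum to screened total
  fl <- exclusion_flow(cohort)
  expect_identical(sum(fl$n), nrow(cohort))
})

test_that("a follow-up bipolar diagnosis excludes the patient", {
  fx <- make_fixture("exclusion_panel")
  # make EP01 develop F31 100 days after index, inside follow-up
  fx$prescriptions <- rbind(fx$prescriptions,
                            data.frame(patient_id = "EP01", drug_id = "sertraline",
                                       dispense_date = d0 + c(28, 56, 84, 112),
                                       days_supplied = 28, setting = "outpatient"))
  fx$diagnoses <- rbind(fx$diagnoses,
                        data.frame(patient_id = "EP01", icd10_code = "F31.9",
                                   date = d0 + 100))
  cohort <- build_cohort(fx, catalog, cfg)
  expect_identical(cohort[cohort$patient_id == "EP01", ]$exclusion_reason,
                   "bipolar_or_schizo")
})

test_that("age boundaries are inclusive 18-64 at index", {
  fx <- make_fixture("addon_35d_overlap")
  for (case in list(list(birth = "1997-02-01", ok = TRUE),   # exactly 18
                    list(birth = "1997-02-02", ok = FALSE),  # 17 (turns 18 next day)
                    list(birth = "1950-02-02", ok = TRUE),   # 64, 65 next day
                    list(birth = "1950-02-01", ok = FALSE))) { # 65 at index
    fx$patients$birth_date <- as.Date(case$birth)
    cohort <- build_cohort(fx, catalog, cfg)
    expect_identical(cohort$exclusion_reason == "none", case$ok,
                     info = case$birth)
  }
})

test_that("follow-up is capped at study_end and monotone in it", {
  days <- seq(0, 1500, by = 28)
  fx <- make_fixture("addon_35d_overlap")
  fx$prescriptions <- data.frame(patient_id = "FX1", drug_id = "sertraline",
                                 dispense_date = d0 + days, days_supplied = 28,
                                 setting = "outpatient")
  c1 <- build_cohort(fx, catalog, cohort_config(study_end = "2017-12-31"))
  c2 <- build_cohort(fx, catalog, cohort_config(study_end = "2018-12-31"))
  expect_identical(c1$follow_up_end, as.Date("2017-12-31"))
  expect_identical(c2$follow_up_end, as.Date("2018-12-31"))
  expect_true(c2$follow_up_end >= c1$follow_up_end)
  expect_true(all(c1$follow_up_end == pmin(c1$episode_end, as.Date("2017-12-31"))))
})

test_that("index minimality holds on generated data", {
  pop <- generate_population(sim_config(n_patients = 300, seed = 9))
  cohort <- build_cohort(pop, catalog, cfg)
  rx <- pop$prescriptions
  ad <- rx[is_antidepressant(catalog, rx$drug_id)]
  m <- merge(ad, cohort[cohort$exclusion_reason != "washout_violation", ],
             by = "patient_id")
  gap <- as.integer(m$index_date - m$dispense_date)
  expect_true(all(!(gap >= 1 & gap <= 365)))
})
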