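test_that("cochran_armitage matches the base-R trend test on random tables", {
  set.seed(5)
  for (case in 1:25) {
    k <- sample(2:5, 1L)
    totals <- sample(20:200, k)
    counts <- rbinom(k, totals, runif(1, 0.2, 0.8))
    if (sum(counts) == 0 || sum(counts) == sum(totals)) next
    got <- cochran_armitage(counts, totals)
    ref <- suppressWarnings(stats::prop.trend.test(counts, totals))
    expect_equal(got$Z^2, unname(ref$statistic), tolerance = 1e-10,
                 info = paste("case", case))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("cochran_armitage agrees with a permutation oracle on a tiny table", {
  counts <- c(2, 3, 5); totals <- c(10, 10, 10)
  got <- cochran_armitage(counts, totals)
  set.seed(8)
  p_perm <- permutation_trend_p(counts, totals, n_rep = 20000L)
  # Monte-Carlo error ~ 2*sqrt(p(1-p)/n) ~ 0.007; allow a normal-approx gap too
  expect_lt(abs(got$p - p_perm), 0.03)
})

test_that("trend statistic is zero for equal proportions and invariant to scores", {
  z0 <- cochran_armitage(c(10, 20, 30), c(100, 200, 300))
  expect_equal(z0$Z, 0)
  a <- cochran_armitage(c(5, 9, 20), c(40, 40, 40), scores = 1:3)
  b <- cochran_armitage(c(5, 9, 20), c(40, 40, 40), scores = c(10, 30, 50))
  expect_equal(a$Z, b$Z, tolerance = 1e-12)
  expect_error(cochran_armitage(c(0, 0), c(5, 5)), "undefined")
  expect_error(cochran_armitage(c(6, 1), c(5, 5)), "counts")
})

mk_tables <- function() {
  # 8 eligible patients across 2 index years; 5 concordant overall
  cohort <- data.table::data.table(
    patient_id = sprintf("p%d", 1:8),
    index_date = as.Date(c(rep("2015-03-01", 4), rep("2016-03-01", 4))),
    follow_up_end = as.Date(c(rep("2015-08-28", 4), rep("2016-08-28", 4))),
    exclusion_reason = "none")
  concordance <- data.table::data.table(
    patient_id = sprintf("p%d", 1:8),
    level1 = c(rep("concordant", 7), "discordant"),
    level2 = c("concordant", "discordant", rep("not_reached", 5), "not_reached"),
    level3 = "not_reached",
    overall = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    reasons = "", optimized = c(TRUE, TRUE, rep(FALSE, 6)),
    changed = c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  list(cohort = cohort, concordance = concordance)
}

test_that("proportion_table computes the three families on the right denominators", {
  tb <- mk_tables()
  pt <- proportion_table(tb$concordance, tb$cohort)
  allr <- as.data.frame(pt[pt$year == "all", ])
  ov <- allr[allr$family == "overall", ]
  expect_identical(ov$n, 5L); expect_identical(ov$denominator, 8L)
  expect_equal(ov$percent, 62.5)
  fl <- allr[allr$family == "first_line", ]
  expect_identical(fl$n, 7L); expect_identical(fl$denominator, 8L)
  # optimized family: first-line concordant AND changed = p1,p2,p3
  op <- allr[allr$family == "optimized", ]
  expect_identical(op$denominator, 3L)
  expect_identical(op$n, 2L)  # p1, p3 concordant overall
  # zero-concordant stratum
  cc0 <- tb$concordance; cc0$overall <- FALSE
  pt0 <- proportion_table(cc0, tb$cohort)
  expect_equal(pt0[pt0$family == "overall" & pt0$year == "all", ]$percent, 0)
})

test_that("duration_table summarizes and partitions", {
  lev <- data.table::data.table(
    patient_id = c("a", "b", "c", "c"),
    level_index = c(1L, 1L, 1L, 2L),
    regimen = "x", entry_pattern = c("initial", "initial", "initial", "switch"),
    start = as.Date("2015-01-01"),
    end = as.Date("2015-01-28"),
    duration_days = c(28L, 28L, 28L, 35L),
    duration_bin = bin_duration(c(28L, 28L, 28L, 35L)))
  dt <- duration_table(lev)
  l1tot <- as.data.frame(dt[dt$level == 1 & dt$subgroup == "total", ])
  expect_identical(l1tot$n, 3L)
  expect_equal(l1tot$median, 28)
  expect_equal(l1tot$pct_w4_6, 100)
  # subgroup partition: only_index + with_change = total
  expect_identical(
    dt[dt$level == 1 & dt$subgroup == "only_index_drug", ]$n +
      dt[dt$level == 1 & dt$subgroup == "with_change", ]$n,
    l1tot$n)
})

test_that("pattern_table counts subsequent patterns on the right denominators", {
  d0 <- as.Date("2015-02-01")
  lev <- data.table::rbindlist(lapply(sprintf("p%d", 1:5), function(p)
    data.table::data.table(patient_id = p, level_index = 1L, regimen = "a",
                           entry_pattern = "initial", start = d0, end = d0 + 29,
                           duration_days = 30L, duration_bin = bin_duration(30))))
  lev <- rbind(lev, data.table::rbindlist(lapply(sprintf("p%d", 1:4), function(p)
    data.table::data.table(patient_id = p, level_index = 2L, regimen = "b",
                           entry_pattern = "switch", start = d0 + 30, end = d0 + 69,
                           duration_days = 40L, duration_bin = bin_duration(40)))))
  tr <- data.table::rbindlist(list(
    data.table::data.table(patient_id = sprintf("p%d", 1:4),
                           event_date = d0 + 30, kind = "switch",
                           new_drugs = "b", dropped_drugs = "a",
                           multi_drug = FALSE, overlap_days = 0L, from_level = 1L),
    data.table::data.table(patient_id = "p4", event_date = d0 + 70,
                           kind = "switch", new_drugs = "c", dropped_drugs = "b",
                           multi_drug = FALSE, overlap_days = 0L, from_level = 2L)))
  pt <- pattern_table(lev, tr)
  s <- as.data.frame(pt$summary)
  expect_identical(s[s$measure == "switch_l1_l2", ]$n, 4L)
  expect_identical(s[s$measure == "addon_l1_l2", ]$n, 0L)
  sub <- as.data.frame(pt$subsequent)
  expect_identical(sub[sub$pattern == "1a", ]$n, 3L)
  expect_identical(sub[sub$pattern == "1b", ]$n, 1L)
  expect_identical(sub[sub$pattern == "1a", ]$denominator, 4L)
  # subsequent patterns partition the first-transition count
  expect_identical(sum(sub[sub$first_kind == "switch", ]$n), 4L)
  expect_equal(sub[sub$pattern == "1b", ]$percent, 25)
  expect_identical(nrow(pt$top_switch_drugs), 1L)
  expect_equal(pt$top_switch_drugs$percent, 100)
})

test_that("discordance_flow reports per-strategy discordance", {
  cc <- data.table::data.table(
    patient_id = sprintf("p%d", 1:6),
    level1 = "concordant",
    level2 = c("discordant", "concordant", "concordant", "discordant",
               "concordant", "not_reached"),
    level3 = "not_reached",
    overall = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    reasons = "", optimized = c(rep(TRUE, 5), FALSE),
    changed = c(rep(TRUE, 5), FALSE))
  d0 <- as.Date("2015-02-01")
  tr <- data.table::data.table(
    patient_id = sprintf("p%d", 1:5), event_date = d0 + 30,
    kind = c("switch", "switch", "add_on", "add_on", "add_on"),
    new_drugs = "x", dropped_drugs = "",
    multi_drug = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    overlap_days = 0L, from_level = 1L)
  fl <- discordance_flow(cc, tr)
  st <- as.data.frame(fl$strategies)
  sw <- st[st$strategy == "switch", ]
  expect_identical(sw$n, 2L); expect_identical(sw$discordant_n, 1L)
  expect_equal(sw$discordant_pct, 50)
  expect_identical(sw$multi_drug_n, 1L)
  ao <- st[st$strategy == "add_on", ]
  expect_identical(ao$n, 3L); expect_identical(ao$discordant_n, 1L)
  cnt <- as.data.frame(fl$counts)
  expect_identical(cnt[cnt$measure == "optimized", ]$n, 5L)
  expect_identical(cnt[cnt$measure == "with_any_change", ]$n, 5L)
  # zero-discordant variant
  cc2 <- data.table::copy(cc); cc2$level2 <- "concordant"
  fl2 <- discordance_flow(cc2, tr)
  expect_true(all(fl2$strategies$discordant_pct == 0))
})

test_that("utilization rates use person-years and distinct visit dates", {
  d0 <- as.Date("2015-01-01")
  cohort <- data.table::data.table(
    patient_id = c("a", "b"), index_date = d0,
    follow_up_end = d0 + round(0.5 * 365.25) - 1,
    exclusion_reason = "none")
  visits <- data.table::data.table(
    patient_id = c(rep("a", 7), rep("b", 6)),
    date = d0 + c(seq(0, 180, by = 30), seq(0, 150, by = 30)),
    setting = "outpatient",
    admission_date = as.Date(NA), discharge_date = as.Date(NA))
  u <- utilization_summary(cohort, visits)
  expect_equal(u$person_years, 2 * (round(0.5 * 365.25)) / 365.25)
  expect_equal(u$visits_per_person_year, 13 / u$person_years)
  expect_equal(u$visit_interval_median, 30)
  expect_true(is.na(u$hospital_stay_median))
})

test_that("the shipped worked-example files recompute internally", {
  tw <- as.data.frame(trend_worked_example())
  expect_identical(sort(tw$family), sort(c("overall", "first_line", "optimized")))
  rp <- as.data.frame(reported_proportions())
  expect_identical(nrow(rp), 6L)
  expect_true(all(abs(rp$percent - rp$reported_pct) <= 0.01))
})
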