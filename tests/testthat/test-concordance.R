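catalog <- load_drug_catalog()
tiers <- load_tier_table(catalog = catalog)
initiators <- names(sim_config(n_patients = 1L)$index_drug_weights)

test_that("level-1 concordance means a first-line index drug", {
  expect_true(classify_level1("escitalopram", tiers)$concordant)
  r <- classify_level1("quetiapine", tiers)  # unlisted for monotherapy
  expect_false(r$concordant)
  expect_identical(r$reason, "nonrecommended_initial")
  # exactly 12 of the 17 observed initiators are concordant
  flags <- vapply(initiators, function(d) classify_level1(d, tiers)$concordant,
                  logical(1))
  expect_identical(sum(flags), 12L)
})

test_that("transition classification covers all rule branches", {
  ev <- function(kind, drugs) list(kind = kind, new_drugs = drugs)
  r <- classify_transition(ev("switch", "escitalopram+venlafaxine"), tiers)
  expect_false(r$concordant); expect_identical(r$reasons, "multi_switch")
  r <- classify_transition(ev("add_on", "lithium+quetiapine"), tiers)
  expect_false(r$concordant); expect_identical(r$reasons, "multi_add")
  expect_true(classify_transition(ev("add_on", "quetiapine"), tiers)$concordant)
  r <- classify_transition(ev("add_on", "buspirone"), tiers)
  expect_false(r$concordant)
  expect_identical(r$reasons, "nonrecommended_adjunct")
  expect_true(classify_transition(ev("switch", "venlafaxine"), tiers)$concordant)
  r <- classify_transition(ev("switch", "fluoxetine"), tiers)  # plain first-line
  expect_false(r$concordant)
  expect_identical(r$reasons, "nonrecommended_switch_drug")
  expect_error(classify_transition(ev("attempt", "sertraline"), tiers),
               "not transitions")
})

levels_row <- function(pid, idx, reg, entry, s, d)
  data.table::data.table(patient_id = pid, level_index = idx, regimen = reg,
                         entry_pattern = entry,
                         start = as.Date("2015-02-01") + s,
                         end = as.Date("2015-02-01") + s + d - 1L,
                         duration_days = d, duration_bin = bin_duration(d))

tr_row <- function(pid, day, kind, nd, multi = FALSE)
  data.table::data.table(patient_id = pid, event_date = as.Date("2015-02-01") + day,
                         kind = kind, new_drugs = nd, dropped_drugs = "",
                         multi_drug = multi, overlap_days = 0L,
                         from_level = 1L)

test_that("classify_patient combines levels by conjunction", {
  # level 1 only, first-line
  res <- classify_patient(levels_row("p", 1L, "escitalopram", "initial", 0L, 40L),
                          tr_row("p", 1L, "attempt", "x")[0], tiers)
  expect_true(res$overall)
  expect_identical(res$level_flags, c("concordant", "not_reached", "not_reached"))
  expect_false(res$optimized)
  # concordant switch then discordant multi-add
  lev <- rbind(levels_row("p", 1L, "escitalopram", "initial", 0L, 40L),
               levels_row("p", 2L, "venlafaxine", "switch", 40L, 50L),
               levels_row("p", 3L, "lithium+quetiapine+venlafaxine", "add_on", 90L, 40L))
  tr <- rbind(tr_row("p", 40L, "switch", "venlafaxine"),
              tr_row("p", 90L, "add_on", "lithium+quetiapine", multi = TRUE))
  res3 <- classify_patient(lev, tr, tiers)
  expect_false(res3$overall)
  expect_identical(res3$level_flags, c("concordant", "concordant", "discordant"))
  expect_identical(res3$reasons, "multi_add")
  expect_true(res3$optimized)
  # discordant level 1 makes the patient discordant despite concordant later steps
  lev2 <- rbind(levels_row("p", 1L, "trazodone", "initial", 0L, 40L),
                levels_row("p", 2L, "venlafaxine", "switch", 40L, 50L))
  res <- classify_patient(lev2, tr_row("p", 40L, "switch", "venlafaxine"), tiers)
  expect_false(res$overall)
  expect_identical(res$reasons, "nonrecommended_initial")
  # levels beyond 3 are ignored
  lev4 <- rbind(lev,
                levels_row("p", 4L, "buspirone", "add_on", 130L, 40L))
  tr4 <- rbind(tr, tr_row("p", 130L, "add_on", "buspirone"))
  res4 <- classify_patient(lev4, tr4, tiers)
  expect_identical(res4$level_flags, res3$level_flags)
  expect_identical(res4$overall, res3$overall)
})

test_that("attempts are neutral for concordance", {
  lev <- levels_row("p", 1L, "escitalopram", "initial", 0L, 40L)
  tr <- tr_row("p", 10L, "attempt", "buspirone")
  res <- classify_patient(lev, tr, tiers)
  expect_true(res$overall)
  expect_true(res$changed)
  expect_false(res$optimized)
})

test_that("classify_cohort matches classify_patient row by row", {
  pop <- generate_population(sim_config(n_patients = 300, seed = 17))
  res <- run_pipeline(pop)
  cc <- res$concordance
  for (pid in sample(cc$patient_id, 40)) {
    one <- classify_patient(res$levels[patient_id == pid],
                            res$transitions[patient_id == pid], tiers)
    row <- cc[patient_id == pid]
    expect_identical(row$overall, one$overall, info = pid)
    expect_identical(row$level2, one$level_flags[2], info = pid)
    expect_identical(sort(strsplit(row$reasons, ",")[[1]]),
                     sort(one$reasons), info = pid)
  }
})

test_that("enlarging recommended sets never turns concordant into discordant", {
  pop <- generate_population(sim_config(n_patients = 500, seed = 23))
  pat <- build_patterns(build_cohort(pop), pop$prescriptions)
  strict <- classify_cohort(pat, load_tier_table(
    catalog = catalog, adjunct_eligible_lines = c("first", "second")))
  broad <- classify_cohort(pat, load_tier_table(
    catalog = catalog, switch_allow_any_first_line = TRUE))
  default <- classify_cohort(pat, tiers)
  expect_true(all(!(strict$overall & !default$overall)))
  expect_true(all(!(default$overall & !broad$overall)))
})

test_that("optimized patients partition into concordant and discordant", {
  pop <- generate_population(sim_config(n_patients = 500, seed = 29))
  res <- run_pipeline(pop)
  cc <- res$concordance
  opt <- cc[optimized == TRUE]
  expect_identical(nrow(opt), sum(opt$overall) + sum(!opt$overall))
  # reason completeness: every discordant patient carries >= 1 reason
  expect_true(all(nchar(cc[overall == FALSE, reasons]) > 0))
  expect_true(all(cc[overall == TRUE, reasons] == ""))
})
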